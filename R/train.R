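#' Training configuration
#'
#' Defaults are the published operating point: mini-batch SGD with batch
#' size 8, initial learning rate 2e-3, momentum 0.9, weight decay 1e-4, and a
#' poly learning-rate schedule with power 0.9 over 150 epochs. The schedule
#' steps once per epoch by default (an epoch is one pass over the training
#' patches); `scheduleUnit = "update"` steps it per parameter update instead.
#'
#' @param batchSize patches per SGD update.
#' @param baseLR initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weightDecay L2 penalty coefficient.
#' @param power poly-schedule exponent in (0, 1].
#' @param epochs maximum number of epochs.
#' @param seed seed controlling batch shuffling (per-epoch streams are
#'   derived from it, so resumed runs reproduce interrupted ones exactly).
#' @param valEvery validate every this many epochs (when a validation set is
#'   given).
#' @param checkpointPath optional RDS path; the best-by-validation-Dice and
#'   latest states are written there (`<path>` and `<path>.last`).
#' @param scheduleUnit `"epoch"` or `"update"`.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(batchSize = 8L, baseLR = 2e-3, momentum = 0.9,
                        weightDecay = 1e-4, power = 0.9, epochs = 150L,
                        seed = 1L, valEvery = 10L, checkpointPath = NULL,
                        scheduleUnit = c("epoch", "update")) {
    stopifnot(batchSize >= 1, baseLR > 0, momentum >= 0, weightDecay >= 0,
              power > 0, power <= 1, epochs >= 1)
    structure(list(batchSize = as.integer(batchSize), baseLR = baseLR,
                   momentum = momentum, weightDecay = weightDecay,
                   power = power, epochs = as.integer(epochs),
                   seed = as.integer(seed), valEvery = as.integer(valEvery),
                   checkpointPath = checkpointPath,
                   scheduleUnit = match.arg(scheduleUnit)),
              class = "trainConfig")
}

#' Poly learning-rate schedule
#'
#' `lr = baseLR * (1 - iter / maxIter)^power`: the learning rate decays
#' monotonically from `baseLR` at `iter = 0` to exactly 0 at `iter =
#' maxIter`.
#'
#' @param iter current iteration (0-based).
#' @param maxIter total iterations.
#' @param baseLR initial learning rate.
#' @param power exponent in (0, 1].
#' @return the learning rate.
#' @examples
#' polyLR(0, 150)            # 2e-3
#' polyLR(75, 150)           # 2e-3 * 0.5^0.9
#' @export
polyLR <- function(iter, maxIter, baseLR = 2e-3, power = 0.9) {
    if (iter > maxIter) {
        warning("iter > maxIter; learning rate clamped to 0")
        return(0)
    }
    if (iter < 0) stop("iter must be >= 0")
    baseLR * (1 - iter / maxIter)^power
}

#' Train a cascade model
#'
#' Mini-batch SGD with momentum and weight decay. Each update runs the
#' forward pass, builds the bidirectional supervision targets from the
#' current side predictions (frozen — no gradient flows through targets),
#' evaluates the weighted side + fusion loss, and backpropagates. Batch
#' order is derived deterministically from `cfg$seed` and the epoch number,
#' so a run is exactly reproducible and a resumed run continues an
#' interrupted one bit-for-bit.
#'
#' @param model a [CascadeModel-class] (ignored when `resumeFrom` is given).
#' @param patches training patches: list of `list(image, label)`.
#' @param lossCfg a [lossConfig()].
#' @param cfg a [trainConfig()].
#' @param valPatches optional validation patches; validation Dice (fused map
#'   thresholded at 0.5) is logged every `cfg$valEvery` epochs and selects
#'   the best checkpoint.
#' @param resumeFrom optional checkpoint path written by a previous run.
#' @param stopAfter optional epoch at which to stop early (the learning-rate
#'   schedule still spans `cfg$epochs`); useful with checkpointing to split a
#'   run across sessions.
#' @param verbose print a line per validation.
#' @return list with `model` (final), `best` (`list(model, dice, epoch)`,
#'   when validated) and `history` (per-epoch data frame: lr, loss, side and
#'   fusion terms, validation Dice).
#' @export
trainModel <- function(model, patches, lossCfg = lossConfig(),
                       cfg = trainConfig(), valPatches = NULL,
                       resumeFrom = NULL, stopAfter = NULL, verbose = FALSE) {
    if (!length(patches)) stop("training set is empty")
    velocity <- paramMap(model@params, function(x) x * 0)
    startEpoch <- 1L
    best <- NULL
    if (!is.null(resumeFrom)) {
        ck <- loadCheckpoint(resumeFrom)
        model <- ck$model
        velocity <- ck$extra$velocity
        startEpoch <- ck$extra$epoch + 1L
        best <- ck$extra$best
    }
    lastEpoch <- if (is.null(stopAfter)) cfg$epochs
                 else min(cfg$epochs, as.integer(stopAfter))
    if (startEpoch > lastEpoch)
        return(list(model = model, best = best, history = NULL))
    nTrain <- length(patches)
    updatesPerEpoch <- ceiling(nTrain / cfg$batchSize)
    totalUpdates <- cfg$epochs * updatesPerEpoch
    hist <- vector("list", lastEpoch)
    for (epoch in seq(startEpoch, lastEpoch)) {
        ord <- withSeed(cfg$seed + 10007L * epoch, sample.int(nTrain))
        lrEpoch <- polyLR(epoch - 1L, cfg$epochs, cfg$baseLR, cfg$power)
        epochLoss <- c(total = 0, side = 0, fuse = 0)
        for (u in seq_len(updatesPerEpoch)) {
            lr <- if (cfg$scheduleUnit == "epoch") lrEpoch
                  else polyLR((epoch - 1L) * updatesPerEpoch + u - 1L,
                              totalUpdates, cfg$baseLR, cfg$power)
            sel <- ord[((u - 1L) * cfg$batchSize + 1L):
                           min(u * cfg$batchSize, nTrain)]
            gacc <- NULL
            bl <- c(total = 0, side = 0, fuse = 0)
            for (k in sel) {
                pt <- patches[[k]]
                fw <- vcForward(model, pt$image, cache = TRUE)
                pairs <- buildTargets(pt$label, fw$sideL2H, fw$sideH2L)
                tl <- totalLossGrad(fw, pairs, pt$label, lossCfg)
                if (!is.finite(tl$total))
                    stop(sprintf(paste0("non-finite loss at epoch %d ",
                                        "(side = %g, fuse = %g)"),
                                 epoch, tl$side, tl$fuse))
                g <- vcBackward(model, fw, tl$gmaps)
                gacc <- if (is.null(gacc)) g
                        else paramWalk(gacc, g, `+`)
                bl <- bl + c(tl$total, tl$side, tl$fuse)
            }
            nb <- length(sel)
            model@params <- local({
                mom <- cfg$momentum; wd <- cfg$weightDecay
                # v <- mom v + (g / nb + wd p); p <- p - lr v
                velocity <<- paramWalk(velocity,
                                       paramWalk(gacc, model@params,
                                                 function(g, p) g / nb + wd * p),
                                       function(v, g) mom * v + g)
                paramWalk(model@params, velocity,
                          function(p, v) p - lr * v)
            })
            epochLoss <- epochLoss + bl / nb
        }
        epochLoss <- epochLoss / updatesPerEpoch
        valDice <- NA_real_
        if (!is.null(valPatches) && (epoch %% cfg$valEvery == 0L ||
                                     epoch == cfg$epochs)) {
            valDice <- meanDice(model, valPatches)
            if (is.null(best) || valDice > best$dice)
                best <- list(model = model, dice = valDice, epoch = epoch)
            if (verbose)
                message(sprintf("epoch %d: loss %.4f, val Dice %.4f",
                                epoch, epochLoss["total"], valDice))
        }
        hist[[epoch]] <- data.frame(epoch = epoch, lr = lrEpoch,
                                    loss = epochLoss["total"],
                                    side = epochLoss["side"],
                                    fuse = epochLoss["fuse"],
                                    valDice = valDice)
        if (!is.null(cfg$checkpointPath)) {
            saveCheckpoint(model, paste0(cfg$checkpointPath, ".last"),
                           extra = list(velocity = velocity, epoch = epoch,
                                        best = best))
            if (!is.null(best) && identical(best$epoch, epoch))
                saveCheckpoint(best$model, cfg$checkpointPath,
                               extra = list(dice = best$dice, epoch = epoch))
        }
    }
    list(model = model, best = best,
         history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
}

# mean Dice of thresholded fused maps over a patch set
meanDice <- function(model, patches, threshold = 0.5) {
    mean(vapply(patches, function(pt) {
        fw <- vcForward(model, pt$image)
        diceFromMasks(pt$label, (fw$fused >= threshold) + 0)
    }, numeric(1)))
}
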