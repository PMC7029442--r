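#' Pixel-level confusion counts
#'
#' Compares a binary segmentation with the ground truth pixel by pixel,
#' optionally restricted to a mask (e.g. the camera field of view).
#'
#' @param pred binary prediction matrix.
#' @param gt binary ground-truth matrix.
#' @param mask optional binary matrix; only `mask == 1` pixels are counted.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, gt, mask = NULL) {
    if (!identical(dim(pred), dim(gt)))
        stop("prediction and ground truth dimensions differ")
    if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
        stop("inputs must be binary")
    if (!is.null(mask)) {
        keep <- mask == 1
        pred <- pred[keep]; gt <- gt[keep]
    }
    new("ConfusionCounts",
        tp = sum(pred == 1 & gt == 1), fp = sum(pred == 1 & gt == 0),
        tn = sum(pred == 0 & gt == 0), fn = sum(pred == 0 & gt == 1))
}

#' Sensitivity, specificity, accuracy, precision and F1 from counts
#'
#' `Se = TP / (TP + FN)`, `Sp = TN / (TN + FP)`,
#' `Acc = (TP + TN) / (TP + TN + FP + FN)`, `Pr = TP / (TP + FP)`,
#' `F1 = 2 Pr Se / (Pr + Se)`. Ratios with a zero denominator are returned
#' as 0 with a warning.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named numeric vector `c(Se, Sp, Acc, Pr, F1)`.
#' @export
metricsFromCounts <- function(counts) {
    stopifnot(is(counts, "ConfusionCounts"))
    tp <- unname(counts@tp); fp <- unname(counts@fp)
    tn <- unname(counts@tn); fn <- unname(counts@fn)
    if (tp + fp + tn + fn == 0) stop("no pixels to evaluate")
    safeDiv <- function(num, den, what) {
        if (den == 0) {
            warning(what, " undefined (0/0); returning 0")
            return(0)
        }
        num / den
    }
    se <- safeDiv(tp, tp + fn, "sensitivity")
    sp <- safeDiv(tn, tn + fp, "specificity")
    acc <- (tp + tn) / (tp + tn + fp + fn)
    pr <- safeDiv(tp, tp + fp, "precision")
    f1 <- safeDiv(2 * pr * se, pr + se, "F1")
    c(Se = se, Sp = sp, Acc = acc, Pr = pr, F1 = f1)
}

#' Dice overlap of two binary masks
#'
#' `2 |GT intersect SR| / (|GT| + |SR|)`; two empty masks give 1 by
#' convention. Algebraically identical to the F1 score computed from the
#' corresponding confusion counts.
#'
#' @param gt,pred binary matrices of equal size.
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceFromMasks <- function(gt, pred) {
    if (!identical(dim(gt), dim(pred))) stop("mask dimensions differ")
    denom <- sum(gt == 1) + sum(pred == 1)
    if (denom == 0) return(1)
    2 * sum(gt == 1 & pred == 1) / denom
}

#' ROC curve and AUC of a probability map
#'
#' Sweeps the true/false positive rates over every distinct predicted value
#' and integrates the curve with the trapezoidal rule. Equals the
#' Mann-Whitney statistic (probability a random vessel pixel scores above a
#' random background pixel, ties counted one half).
#'
#' @param prob probability map in `[0, 1]`.
#' @param gt binary ground truth.
#' @param mask optional binary evaluation mask.
#' @return `list(curve = data.frame(threshold, fpr, tpr), auc)`.
#' @export
rocAuc <- function(prob, gt, mask = NULL) {
    if (!identical(dim(prob), dim(gt)))
        stop("probability map and ground truth dimensions differ")
    if (!is.null(mask)) {
        keep <- mask == 1
        prob <- prob[keep]; gt <- gt[keep]
    }
    npos <- sum(gt == 1); nneg <- sum(gt == 0)
    if (npos == 0 || nneg == 0)
        stop("ROC undefined: ground truth contains a single class")
    o <- order(prob, decreasing = TRUE)
    p <- prob[o]; y <- gt[o]
    # pool tied thresholds
    last <- cumsum(rle(p)$lengths)
    tp <- cumsum(y == 1)[last]
    fp <- cumsum(y == 0)[last]
    curve <- data.frame(threshold = p[last], fpr = fp / nneg, tpr = tp / npos)
    curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), curve)
    auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
    list(curve = curve, auc = auc)
}

#' Evaluate a directory of probability maps against ground-truth labels
#'
#' Pairs files by basename stem (`<id>_pred.*` with `<id>_label.*`, or equal
#' stems), binarises the fused probability maps at `threshold`, computes all
#' metrics per image and an aggregate row obtained by pooling the raw
#' confusion counts over all images (so the pooled accuracy is the accuracy
#' over the concatenated pixels, not a mean of per-image ratios). Ids present
#' on only one side are reported with a warning and skipped.
#'
#' @param predDir directory of probability maps (TIFF or PNG).
#' @param gtDir directory of binary labels.
#' @param threshold binarisation threshold for the confusion-based metrics.
#' @param fovDir optional directory of field-of-view masks (matching stems);
#'   when given, metrics are restricted to the mask.
#' @param outPrefix optional path prefix: writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param predSuffix,gtSuffix,fovSuffix filename suffixes stripped ahead of
#'   stem matching.
#' @return data.frame of per-image rows plus an `"aggregate"` row.
#' @export
evaluateDataset <- function(predDir, gtDir, threshold = 0.5, fovDir = NULL,
                            outPrefix = NULL, predSuffix = "_pred",
                            gtSuffix = "_label", fovSuffix = "_fov") {
    stems <- function(dir, suffix) {
        f <- list.files(dir, pattern = "\\.(png|tif|tiff)$")
        s <- sub(paste0(suffix, "$"), "", tools::file_path_sans_ext(f))
        stats::setNames(file.path(dir, f), s)
    }
    preds <- stems(predDir, predSuffix)
    gts <- stems(gtDir, gtSuffix)
    common <- intersect(names(preds), names(gts))
    extra <- union(setdiff(names(preds), common), setdiff(names(gts), common))
    if (length(extra))
        warning("unmatched ids skipped: ", paste(extra, collapse = ", "))
    fovs <- if (!is.null(fovDir)) stems(fovDir, fovSuffix) else NULL
    rows <- list()
    pool <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    pooledProb <- list(); pooledGt <- list()
    for (id in common) {
        prob <- readImageFile(preds[[id]])
        if (length(dim(prob)) == 3L) prob <- prob[, , 1]
        gt <- readImageFile(gts[[id]])
        if (length(dim(gt)) == 3L) gt <- gt[, , 1]
        gt <- (gt > 0) + 0
        mask <- NULL
        if (!is.null(fovs) && id %in% names(fovs)) {
            mask <- readImageFile(fovs[[id]])
            if (length(dim(mask)) == 3L) mask <- mask[, , 1]
            mask <- (mask > 0) + 0
        }
        cc <- confusionCounts((prob >= threshold) + 0, gt, mask)
        m <- metricsFromCounts(cc)
        auc <- rocAuc(prob, gt, mask)$auc
        dice <- unname(m["F1"])
        rows[[id]] <- data.frame(id = id, t(m), Dice = dice, AUC = auc)
        pool <- pool + c(cc@tp, cc@fp, cc@tn, cc@fn)
        keep <- if (is.null(mask)) TRUE else mask == 1
        pooledProb[[id]] <- prob[keep]; pooledGt[[id]] <- gt[keep]
    }
    if (!length(rows)) {
        warning("no matching prediction/label pairs found")
        return(data.frame())
    }
    aggC <- new("ConfusionCounts", tp = pool["tp"], fp = pool["fp"],
                tn = pool["tn"], fn = pool["fn"])
    aggM <- metricsFromCounts(aggC)
    aggAuc <- rocAuc(matrix(unlist(pooledProb), ncol = 1),
                     matrix(unlist(pooledGt), ncol = 1))$auc
    res <- rbind(do.call(rbind, rows),
                 data.frame(id = "aggregate", t(aggM),
                            Dice = unname(aggM["F1"]), AUC = aggAuc))
    rownames(res) <- NULL
    if (!is.null(outPrefix)) {
        write.csv(res, paste0(outPrefix, ".csv"), row.names = FALSE)
        jsonlite::write_json(res, paste0(outPrefix, ".json"),
                             dataframe = "rows", digits = NA)
    }
    res
}
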