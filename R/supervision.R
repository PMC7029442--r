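#' Loss configuration
#'
#' Defaults follow the method's published operating point: positive-class
#' threshold `eta = 0.4`, negative-class scaling `lambda = 1.1`, and loss
#' weights `wSide = 0.5`, `wFuse = 1.2`.
#'
#' @param eta threshold in `[0, 1)`: pixels whose target exceeds `eta` form
#'   the positive class, pixels with target exactly 0 the negative class, and
#'   targets in `(0, eta]` are excluded from the loss.
#' @param lambda multiplier on the negative-class weight.
#' @param wSide,wFuse weights of the summed side losses and the fusion loss.
#' @param fusionLoss `"balanced_bce"` (default) or `"l1"` for the fused map.
#' @return list of class `lossConfig`.
#' @export
lossConfig <- function(eta = 0.4, lambda = 1.1, wSide = 0.5, wFuse = 1.2,
                       fusionLoss = c("balanced_bce", "l1")) {
    if (eta < 0 || eta >= 1) stop("'eta' must be in [0, 1)")
    if (wSide < 0 || wFuse < 0) stop("loss weights must be >= 0")
    structure(list(eta = eta, lambda = lambda, wSide = wSide, wFuse = wFuse,
                   fusionLoss = match.arg(fusionLoss)),
              class = "lossConfig")
}

#' Build the bidirectional diameter-specific supervision targets
#'
#' Stage `d`'s low-to-high target is the ground truth minus the summed
#' predictions of the shallower stages, `clamp(Y - sum_{i<d} P_i^l2h, 0, 1)`;
#' its high-to-low target subtracts the deeper stages,
#' `clamp(Y - sum_{i>d} P_i^h2l, 0, 1)`. The subtracted predictions are
#' constants (no gradient flows through a target), so each stage is pushed to
#' explain exactly the residual vessel mass — thin residuals for shallow
#' stages in the l2h direction, thick residuals for deep stages in h2l — and
#' the shared-gradient degeneracy of a single additive target is avoided. The
#' first stage's l2h target and the last stage's h2l target are the ground
#' truth itself. Before clamping, the pair sums to
#' `2 Y - sum_{i<d} P_i^l2h - sum_{i>d} P_i^h2l` exactly.
#'
#' @param Y binary ground-truth matrix.
#' @param sidesL2H,sidesH2L lists of D post-sigmoid side prediction matrices.
#' @return list of D [SupervisionPair-class] objects.
#' @export
buildTargets <- function(Y, sidesL2H, sidesH2L) {
    D <- length(sidesL2H)
    if (length(sidesH2L) != D) stop("side map lists must have equal length")
    for (p in c(sidesL2H, sidesH2L))
        if (!identical(dim(p), dim(Y))) stop("side map dimension mismatch")
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    # cumulative prediction sums, treated as constants
    cumBelow <- vector("list", D)  # sum_{i<d} P_i^l2h
    cumAbove <- vector("list", D)  # sum_{i>d} P_i^h2l
    acc <- 0 * Y
    for (d in seq_len(D)) {
        cumBelow[[d]] <- acc
        acc <- acc + sidesL2H[[d]]
    }
    acc <- 0 * Y
    for (d in rev(seq_len(D))) {
        cumAbove[[d]] <- acc
        acc <- acc + sidesH2L[[d]]
    }
    lapply(seq_len(D), function(d)
        new("SupervisionPair",
            yL2H = clamp01(Y - cumBelow[[d]]),
            yH2L = clamp01(Y - cumAbove[[d]]),
            scale = as.integer(d)))
}

# class-balanced BCE with threshold eta; returns loss and optionally the
# gradient w.r.t. pred. Positive weight |Y-|/N, negative weight lambda |Y+|/N,
# mean-normalised over the N = |Y+| + |Y-| contributing pixels.
bbceCore <- function(pred, target, eta, lambda, grad = FALSE) {
    pos <- target > eta
    neg <- target == 0
    npos <- sum(pos); nneg <- sum(neg)
    n <- npos + nneg
    if (n == 0) {
        warning("no pixels in the positive or negative class; loss is 0")
        return(list(loss = 0,
                    grad = if (grad) array(0, dim(pred)) else NULL))
    }
    beta <- nneg / n
    wneg <- lambda * npos / n
    p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
    loss <- (-beta * sum(log(p[pos])) - wneg * sum(log(1 - p[neg]))) / n
    g <- NULL
    if (grad) {
        g <- array(0, dim(pred))
        g[pos] <- -beta / p[pos] / n
        g[neg] <- wneg / (1 - p[neg]) / n
    }
    list(loss = loss, grad = g)
}

#' Class-balanced thresholded cross-entropy
#'
#' Vessel pixels are a small minority, so plain cross-entropy collapses to
#' the background class. This loss weights the positive set `Y+ = {target >
#' eta}` by `|Y-| / N` and the negative set `Y- = {target == 0}` by
#' `lambda |Y+| / N` (with `N = |Y+| + |Y-|`), and excludes pixels with
#' target in `(0, eta]` — soft residual targets too weak to count as vessel
#' but not background either. The weighted sum is divided by `N` (mean
#' normalisation, so the scale is patch-size invariant).
#'
#' @param pred probability map (values clipped into `(0, 1)` internally).
#' @param target map in `[0, 1]` (binary ground truth or a soft cascade
#'   target).
#' @param eta,lambda see [lossConfig()].
#' @return non-negative scalar loss.
#' @export
balancedBCE <- function(pred, target, eta = 0.4, lambda = 1.1) {
    if (!identical(dim(pred), dim(target)))
        stop("pred and target dimensions differ")
    bbceCore(pred, target, eta, lambda)$loss
}

# mean absolute error and its gradient
l1Core <- function(pred, target, grad = FALSE) {
    n <- length(pred)
    list(loss = sum(abs(pred - target)) / n,
         grad = if (grad) sign(pred - target) / n else NULL)
}

#' Total cascade loss
#'
#' `L = wSide * sum_d [L(P_d^l2h, Y_d^l2h) + L(P_d^h2l, Y_d^h2l)] + wFuse *
#' L_fuse(P, Y)`, where each side term is the class-balanced cross-entropy
#' against that stage's supervision target and the fusion term compares the
#' fused map with the ground truth (balanced BCE by default, L1 optionally).
#'
#' @param output a [CascadeOutput-class] (or the list returned by the
#'   internal forward pass).
#' @param pairs list of [SupervisionPair-class] from [buildTargets()].
#' @param Y binary ground-truth matrix.
#' @param cfg a [lossConfig()].
#' @return list with `total`, `side` (sum), `fuse`, and `sideTerms` (a
#'   `D x 2` matrix of per-stage, per-direction losses).
#' @export
totalLoss <- function(output, pairs, Y, cfg = lossConfig()) {
    tl <- totalLossGrad(output, pairs, Y, cfg, grad = FALSE)
    tl[c("total", "side", "fuse", "sideTerms")]
}

# loss plus gradients w.r.t. the 11 probability maps (targets are constants)
totalLossGrad <- function(output, pairs, Y, cfg, grad = TRUE) {
    sideL2H <- if (is(output, "CascadeOutput")) output@sideL2H else output$sideL2H
    sideH2L <- if (is(output, "CascadeOutput")) output@sideH2L else output$sideH2L
    fused <- if (is(output, "CascadeOutput")) output@fused else output$fused
    D <- length(sideL2H)
    sideTerms <- matrix(0, D, 2, dimnames = list(NULL, c("l2h", "h2l")))
    gL2H <- gH2L <- vector("list", D)
    for (d in seq_len(D)) {
        a <- bbceCore(sideL2H[[d]], pairs[[d]]@yL2H, cfg$eta, cfg$lambda, grad)
        b <- bbceCore(sideH2L[[d]], pairs[[d]]@yH2L, cfg$eta, cfg$lambda, grad)
        sideTerms[d, ] <- c(a$loss, b$loss)
        if (grad) {
            gL2H[[d]] <- cfg$wSide * a$grad
            gH2L[[d]] <- cfg$wSide * b$grad
        }
    }
    fu <- if (cfg$fusionLoss == "l1") l1Core(fused, Y, grad)
          else bbceCore(fused, Y, cfg$eta, cfg$lambda, grad)
    side <- sum(sideTerms)
    res <- list(total = cfg$wSide * side + cfg$wFuse * fu$loss,
                side = side, fuse = fu$loss, sideTerms = sideTerms)
    if (grad) {
        res$gmaps <- list(gL2H = gL2H, gH2L = gH2L,
                          gFused = cfg$wFuse * fu$grad)
    }
    res
}

# central-difference gradient of f (scalar) w.r.t. each element of x
numericGradient <- function(f, x, eps = 1e-5) {
    g <- array(0, dim(x))
    for (i in seq_along(x)) {
        xp <- x; xp[i] <- xp[i] + eps
        xm <- x; xm[i] <- xm[i] - eps
        g[i] <- (f(xp) - f(xm)) / (2 * eps)
    }
    g
}

#' Gradient degeneracy of naive additive multi-stage supervision
#'
#' If every stage is supervised through the single additive reconstruction
#' `Y* = sum_i P_i` with one common loss `L(Y*, Y)`, the chain rule gives
#' `dL/dP_i = dL/dY*` for every stage: all stages receive identical
#' gradients and none can specialise to a diameter scale. This diagnostic
#' evaluates those gradients numerically and returns the maximum over stage
#' pairs of the mean absolute gradient difference — which is zero (to
#' numerical precision) for the naive scheme, and materially nonzero for the
#' bidirectional scheme (see [cascadeGradientSpread()]).
#'
#' @param preds list of `D >= 2` prediction matrices in (0, 1).
#' @param Y binary ground-truth matrix.
#' @param loss `"balanced_bce"` or `"l1"`.
#' @param eta,lambda balanced-BCE parameters.
#' @param eps finite-difference step.
#' @return maximum pairwise mean absolute gradient discrepancy.
#' @export
naiveGradientDegeneracy <- function(preds, Y, loss = c("balanced_bce", "l1"),
                                    eta = 0.4, lambda = 1.1, eps = 1e-5) {
    loss <- match.arg(loss)
    D <- length(preds)
    if (D < 2) stop("need at least two stages")
    lossFun <- function(ystar)
        if (loss == "l1") l1Core(ystar, Y)$loss
        else bbceCore(ystar, Y, eta, lambda)$loss
    others <- Reduce(`+`, preds)
    grads <- lapply(seq_len(D), function(i) {
        rest <- others - preds[[i]]
        numericGradient(function(p) lossFun(rest + p), preds[[i]], eps)
    })
    maxPairwiseMeanDiff(grads)
}

#' Per-stage gradient spread under bidirectional supervision
#'
#' The counterpart of [naiveGradientDegeneracy()]: each stage's predictions
#' are scored against its own complementary targets (built once from the
#' current predictions and frozen), `L = sum_d L(P_d^l2h, Y_d^l2h) +
#' L(P_d^h2l, Y_d^h2l)`, and the same maximum pairwise mean absolute
#' gradient discrepancy is returned — here across the l2h stages. Generic
#' random inputs give a clearly nonzero spread: stages receive different
#' learning signals.
#'
#' @param predsL2H,predsH2L lists of D prediction matrices in (0, 1).
#' @inheritParams naiveGradientDegeneracy
#' @export
cascadeGradientSpread <- function(predsL2H, predsH2L, Y, eta = 0.4,
                                  lambda = 1.1, eps = 1e-5) {
    pairs <- buildTargets(Y, predsL2H, predsH2L)  # frozen targets
    grads <- lapply(seq_along(predsL2H), function(d)
        numericGradient(function(p)
            bbceCore(p, pairs[[d]]@yL2H, eta, lambda)$loss +
            bbceCore(predsH2L[[d]], pairs[[d]]@yH2L, eta, lambda)$loss,
            predsL2H[[d]], eps))
    maxPairwiseMeanDiff(grads)
}

maxPairwiseMeanDiff <- function(grads) {
    D <- length(grads)
    mx <- 0
    for (i in seq_len(D - 1))
        for (j in seq(i + 1, D))
            mx <- max(mx, mean(abs(grads[[i]] - grads[[j]])))
    mx
}
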