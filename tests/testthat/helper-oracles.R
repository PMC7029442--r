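# Independent reference implementations used as test oracles. These are
# deliberately naive (nested loops, pairwise enumeration) and share no code
# with the package internals they check.

# dilated convolution by direct evaluation of the defining sum
naiveDilatedConv <- function(x, w, rate) {
    H <- dim(x)[1]; W <- dim(x)[2]
    Cin <- dim(w)[3]; Cout <- dim(w)[4]
    kh <- dim(w)[1]; kw <- dim(w)[2]
    ph <- (kh + 1) / 2; pw <- (kw + 1) / 2   # centre tap (1-based)
    out <- array(0, c(H, W, Cout))
    for (o in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
        s <- 0
        for (c in seq_len(Cin)) for (p in seq_len(kh)) for (q in seq_len(kw)) {
            si <- i + rate * (p - ph); sj <- j + rate * (q - pw)
            if (si >= 1 && si <= H && sj >= 1 && sj <= W)
                s <- s + x[si, sj, c] * w[p, q, c, o]
        }
        out[i, j, o] <- s
    }
    out
}

# AUC as the Mann-Whitney statistic: P(score+ > score-) with ties at 1/2
mannWhitneyAUC <- function(prob, gt) {
    pos <- prob[gt == 1]; neg <- prob[gt == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
}

# pixel-centre distance rasterisation of one segment
naiveRasterCount <- function(H, W, from, to, width) {
    cnt <- 0
    d <- to - from
    len2 <- sum(d^2)
    for (i in seq_len(H)) for (j in seq_len(W)) {
        t <- if (len2 > 0) ((i - from[1]) * d[1] + (j - from[2]) * d[2]) / len2 else 0
        t <- min(max(t, 0), 1)
        p <- from + t * d
        if (sum((c(i, j) - p)^2) <= (width / 2)^2) cnt <- cnt + 1
    }
    cnt
}

# small deterministic test scene with known thin + thick strokes
twoStrokeScene <- function(H = 64, W = 64, w1 = 2, w2 = 8) {
    lab <- matrix(0, H, W); wm <- matrix(0, H, W)
    s1 <- rasterizeStroke(lab, wm, c(16, 5), c(16, W - 4), w1)
    s2 <- rasterizeStroke(s1$label, s1$widthMap, c(44, 5), c(44, W - 4), w2)
    img <- array(0.5, c(H, W, 3))
    new("SyntheticScene", image = img, label = s2$label,
        widthMap = s2$widthMap, fovMask = matrix(1, H, W))
}

# tiny patches for smoke-training tests
smokePatches <- function(n = 2, size = 50, seed = 7) {
    lapply(seq_len(n), function(i) {
        sc <- generateScene(synthParams(imageSize = c(size, size), nTrees = 2,
                                        widthRange = c(1, 6),
                                        nBrightLesions = 1, nDarkLesions = 1,
                                        lesionRadiusRange = c(3, 6),
                                        seed = seed + i))
        list(image = sceneImage(sc), label = sceneLabel(sc))
    })
}

tinyModel <- function(wm = 0.03, K = 2, seed = 5)
    buildModel(networkConfig(widthMultiplier = wm, ddcm = ddcmConfig(K = K),
                             seed = seed))
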