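test_that("confusion counts match a per-pixel loop oracle", {
    gt <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), 2, 5)
    pred <- matrix(c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0), 2, 5)
    cc <- confusionCounts(pred, gt)
    # loop oracle
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(gt)) {
        if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1
        if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1
        if (pred[i] == 0 && gt[i] == 0) tn <- tn + 1
        if (pred[i] == 0 && gt[i] == 1) fn <- fn + 1
    }
    expect_equal(c(cc@tp, cc@fp, cc@tn, cc@fn), c(tp, fp, tn, fn))
    expect_equal(c(cc@tp, cc@fp, cc@tn, cc@fn), c(3, 1, 5, 1))

    # identity and complement predictions
    id <- confusionCounts(gt, gt)
    expect_equal(c(id@fp, id@fn), c(0, 0))
    nc <- confusionCounts(1 - gt, gt)
    expect_equal(c(nc@tp, nc@tn), c(0, 0))
    expect_error(confusionCounts(matrix(0.5, 2, 5), gt), "binary")
    # mask restriction
    mask <- matrix(0, 2, 5); mask[, 1:2] <- 1
    cm <- confusionCounts(pred, gt, mask)
    expect_equal(cm@tp + cm@fp + cm@tn + cm@fn, 4)
})

test_that("metrics agree with hand evaluation of the defining ratios", {
    cc <- new("ConfusionCounts", tp = 3, fp = 1, tn = 5, fn = 1)
    m <- metricsFromCounts(cc)
    expect_equal(unname(m["Se"]), 0.75)
    expect_equal(unname(m["Sp"]), 5 / 6)
    expect_equal(unname(m["Acc"]), 0.8)
    expect_equal(unname(m["Pr"]), 0.75)
    expect_equal(unname(m["F1"]), 0.75)

    perfect <- metricsFromCounts(new("ConfusionCounts", tp = 4, fp = 0,
                                     tn = 6, fn = 0))
    expect_true(all(perfect == 1))
    # 0/0 conventions (several ratios degenerate at once)
    w <- testthat::capture_warnings(
        z <- metricsFromCounts(new("ConfusionCounts", tp = 0, fp = 0,
                                   tn = 5, fn = 0)))
    expect_true(any(grepl("precision", w)))
    expect_equal(unname(z["Se"]), 0)
    m0 <- suppressWarnings(
        metricsFromCounts(new("ConfusionCounts", tp = 0, fp = 1,
                              tn = 5, fn = 2)))
    expect_equal(unname(m0["Se"]), 0)
})

test_that("Dice equals F1 on random mask pairs and honours conventions", {
    expect_equal(diceFromMasks(matrix(1, 3, 3), matrix(1, 3, 3)), 1)
    a <- matrix(c(1, 1, 0, 0), 2, 2); b <- matrix(c(0, 0, 1, 1), 2, 2)
    expect_equal(diceFromMasks(a, b), 0)
    expect_equal(diceFromMasks(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
    set.seed(12)
    for (trial in 1:1000) {
        gt <- matrix(rbinom(30, 1, runif(1, 0.2, 0.8)), 5, 6)
        pr <- matrix(rbinom(30, 1, runif(1, 0.2, 0.8)), 5, 6)
        d <- diceFromMasks(gt, pr)
        f1 <- suppressWarnings(
            unname(metricsFromCounts(confusionCounts(pr, gt))["F1"]))
        if (sum(gt) + sum(pr) > 0) expect_equal(d, f1, tolerance = 1e-12)
    }
})

test_that("trapezoidal AUC equals the Mann-Whitney oracle", {
    set.seed(4)
    gt <- matrix(rbinom(20, 1, 0.5), 4, 5)
    while (length(unique(as.vector(gt))) < 2) gt <- matrix(rbinom(20, 1, 0.5), 4, 5)
    prob <- matrix(runif(20), 4, 5)
    expect_equal(rocAuc(prob, gt)$auc, mannWhitneyAUC(prob, gt),
                 tolerance = 1e-12)
    # with heavy ties
    probT <- matrix(sample(c(0.2, 0.5, 0.8), 20, TRUE), 4, 5)
    expect_equal(rocAuc(probT, gt)$auc, mannWhitneyAUC(probT, gt),
                 tolerance = 1e-12)
    # larger instances
    for (trial in 1:5) {
        n <- 40 * 50
        gt2 <- matrix(rbinom(n, 1, 0.3), 40, 50)
        p2 <- matrix(pmin(pmax(gt2 * 0.3 + runif(n), 0), 1), 40, 50)
        expect_equal(rocAuc(p2, gt2)$auc, mannWhitneyAUC(p2, gt2),
                     tolerance = 1e-10)
    }
    # degenerate extremes
    expect_equal(rocAuc(gt + 0, gt)$auc, 1)
    expect_equal(rocAuc(1 - gt, gt)$auc, 0)
    expect_error(rocAuc(prob, matrix(1, 4, 5)), "single class")
})

test_that("all metrics are invariant under a common pixel permutation", {
    set.seed(8)
    gt <- matrix(rbinom(48, 1, 0.4), 6, 8)
    prob <- matrix(runif(48), 6, 8)
    perm <- sample(48)
    gtP <- matrix(gt[perm], 6, 8); probP <- matrix(prob[perm], 6, 8)
    m1 <- suppressWarnings(metricsFromCounts(confusionCounts((prob >= .5) + 0, gt)))
    m2 <- suppressWarnings(metricsFromCounts(confusionCounts((probP >= .5) + 0, gtP)))
    expect_equal(m1, m2)
    expect_equal(rocAuc(prob, gt)$auc, rocAuc(probP, gtP)$auc)
})

test_that("dataset evaluation pools counts and flags unmatched ids", {
    dir <- withr::local_tempdir()
    predDir <- file.path(dir, "pred"); gtDir <- file.path(dir, "gt")
    dir.create(predDir); dir.create(gtDir)
    set.seed(19)
    probs <- list(); gts <- list()
    for (id in c("a", "b")) {
        gt <- matrix(rbinom(100, 1, 0.35), 10, 10)
        prob <- pmin(pmax(gt * 0.5 + runif(100, 0, 0.5), 0), 1)
        tiff::writeTIFF(prob, file.path(predDir, paste0(id, "_pred.tif")),
                        bits.per.sample = 32L)
        png::writePNG(gt + 0, file.path(gtDir, paste0(id, "_label.png")))
        probs[[id]] <- prob; gts[[id]] <- gt
    }
    res <- evaluateDataset(predDir, gtDir)
    expect_equal(nrow(res), 3L)
    agg <- res[res$id == "aggregate", ]
    # concatenation oracle: pooled metrics equal metrics on concatenated pixels
    allProb <- c(probs$a, probs$b); allGt <- c(gts$a, gts$b)
    cc <- confusionCounts(matrix((allProb >= 0.5) + 0, ncol = 1),
                          matrix(allGt, ncol = 1))
    mo <- metricsFromCounts(cc)
    expect_equal(agg$Acc, unname(mo["Acc"]), tolerance = 1e-12)
    expect_equal(agg$F1, unname(mo["F1"]), tolerance = 1e-12)
    expect_equal(agg$AUC, mannWhitneyAUC(allProb, allGt), tolerance = 1e-10)

    # single image: aggregate equals the per-image row
    file.remove(file.path(predDir, "b_pred.tif"))
    res1 <- suppressWarnings(evaluateDataset(predDir, gtDir))
    expect_equal(res1[1, -1], res1[2, -1], ignore_attr = TRUE)
    w2 <- testthat::capture_warnings(evaluateDataset(predDir, gtDir))
    expect_true(any(grepl("unmatched", w2)))

    # empty intersection: empty report with a warning
    file.remove(file.path(predDir, "a_pred.tif"))
    w3 <- testthat::capture_warnings(resE <- evaluateDataset(predDir, gtDir))
    expect_true(any(grepl("no matching", w3)))
    expect_equal(nrow(resE), 0L)
})
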