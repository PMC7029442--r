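test_that("empty scenes and determinism behave as specified", {
    p0 <- synthParams(imageSize = c(64, 64), nTrees = 0, nBrightLesions = 0,
                      nDarkLesions = 0, seed = 3)
    sc0 <- generateScene(p0)
    expect_true(all(sceneLabel(sc0) == 0))
    expect_true(all(widthMap(sc0) == 0))

    p <- synthParams(imageSize = c(80, 96), seed = 11)
    a <- generateScene(p); b <- generateScene(p)
    expect_identical(sceneImage(a), sceneImage(b))
    expect_identical(sceneLabel(a), sceneLabel(b))
    expect_identical(widthMap(a), widthMap(b))
    # scene generation must not consume the caller's RNG stream
    set.seed(1); before <- runif(3)
    set.seed(1); invisible(generateScene(p)); after <- runif(3)
    expect_identical(before, after)
    # different seed, different scene
    sc2 <- generateScene(synthParams(imageSize = c(80, 96), seed = 12))
    expect_false(identical(sceneLabel(a), sceneLabel(sc2)))
})

test_that("stroke rasterisation matches the pixel-centre distance oracle", {
    lab <- matrix(0, 256, 256); wm <- matrix(0, 256, 256)
    s <- rasterizeStroke(lab, wm, c(128, 78), c(128, 177), width = 5)
    expect_equal(sum(s$label), naiveRasterCount(256, 256, c(128, 78),
                                                c(128, 177), 5))
    expect_true(all(s$widthMap[s$label == 1] == 5))
    # a diagonal stroke too
    s2 <- rasterizeStroke(lab, wm, c(30, 40), c(90, 100), width = 3)
    expect_equal(sum(s2$label), naiveRasterCount(256, 256, c(30, 40),
                                                 c(90, 100), 3))
})

test_that("vessel pixel count grows monotonically with stroke width", {
    counts <- vapply(1:6, function(w) {
        s <- rasterizeStroke(matrix(0, 128, 128), matrix(0, 128, 128),
                             c(64, 14), c(64, 113), width = w)
        sum(s$label)
    }, numeric(1))
    expect_true(all(diff(counts) > 0))
})

test_that("width partition is an exact disjoint decomposition of the label", {
    sc <- twoStrokeScene(w1 = 2, w2 = 8)
    part <- widthPartition(sc, edges = 5)
    expect_length(part, 2L)
    # counting oracle: direct per-pixel binning
    wm <- widthMap(sc)
    expect_equal(sum(part[[1]]), sum(wm > 0 & wm <= 5))
    expect_equal(sum(part[[2]]), sum(wm > 5))
    expect_true(all(part[[1]] * part[[2]] == 0))
    expect_equal(part[[1]] + part[[2]], sceneLabel(sc))

    # single bin returns the label itself
    expect_equal(widthPartition(sc)[[1]], sceneLabel(sc))
    # all widths below the first edge land in map 1
    p2 <- widthPartition(sc, edges = c(100, 200))
    expect_equal(p2[[1]], sceneLabel(sc))
    expect_true(all(p2[[2]] == 0) && all(p2[[3]] == 0))
    expect_error(widthPartition(sc, edges = c(5, 3)), "increasing")
})

test_that("partition identity holds across generated scenes and edge sets", {
    for (seed in 1:5) {
        sc <- generateScene(synthParams(imageSize = c(64, 64), seed = seed))
        for (edges in list(numeric(), 2, c(2, 4), c(1.5, 3, 4.5))) {
            part <- widthPartition(sc, edges)
            expect_equal(Reduce(`+`, part), sceneLabel(sc))
            for (i in seq_along(part)[-1])
                expect_true(all(part[[i - 1]] * part[[i]] == 0))
        }
    }
})

test_that("invalid generator parameters are rejected", {
    expect_error(synthParams(imageSize = c(32, 32), widthRange = c(4, 40)),
                 "exceeds")
    expect_error(synthParams(widthRange = c(0.5, 3)), "1 <= min")
    expect_error(synthParams(nTrees = -1), ">= 0")
    expect_error(synthParams(backgroundGradient = 1.5), "\\[0, 1\\]")
})

test_that("scenes survive a save/load round trip", {
    dir <- withr::local_tempdir()
    sc <- generateScene(synthParams(imageSize = c(48, 48), seed = 21))
    saveScene(sc, dir, "t1")
    back <- loadScene(dir, "t1")
    expect_identical(sceneLabel(back), sceneLabel(sc))
    expect_identical(fovMask(back), fovMask(sc))
    # image quantised to 8 bits, widths stored as float32
    expect_equal(sceneImage(back), sceneImage(sc), tolerance = 1 / 255)
    expect_equal(widthMap(back), widthMap(sc), tolerance = 1e-5)
    expect_identical(widthMap(back) > 0, sceneLabel(back) == 1)
})
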