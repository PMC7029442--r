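test_that("parameter count matches an independent per-layer arithmetic count", {
    cfg <- networkConfig(widthMultiplier = 0.125, ddcm = ddcmConfig(K = 3),
                         seed = 1)
    model <- buildModel(cfg)
    # independent count: backbone convs + DDCMs + heads + fusion
    chans <- pmax(1, ceiling(c(64, 128, 256, 512, 512) * 0.125))
    convs <- c(2, 2, 3, 3, 3)
    expected <- 0
    cin <- 3
    for (d in 1:5) {
        ch <- chans[d]
        for (i in seq_len(convs[d])) {
            expected <- expected + 3 * 3 * cin * ch + ch
            cin <- ch
        }
        # one DDCM per conv: K branches of (3x3 CxC + C) + (1x1 CxC + C)
        expected <- expected + convs[d] * 3 * (9 * ch * ch + ch + ch * ch + ch)
        expected <- expected + 2 * (ch + 1)          # two 1x1 heads
    }
    expected <- expected + 10 + 1                    # 1x1 fusion over 10 maps
    expect_equal(nParams(model), expected)
})

test_that("weight initialisation is seed-deterministic", {
    cfg <- networkConfig(widthMultiplier = 0.06, ddcm = ddcmConfig(K = 2),
                         seed = 33)
    expect_identical(buildModel(cfg)@params, buildModel(cfg)@params)
    cfg2 <- cfg; cfg2$seed <- 34L
    expect_false(identical(buildModel(cfg)@params, buildModel(cfg2)@params))
})

test_that("all 11 maps come back at input resolution for arbitrary sizes", {
    model <- tinyModel()
    set.seed(6)
    sizes <- cbind(sample(16:80, 4), sample(16:80, 4))
    for (k in seq_len(nrow(sizes))) {
        h <- sizes[k, 1]; w <- sizes[k, 2]
        out <- forwardPass(model, array(runif(h * w * 3), c(h, w, 3)))
        expect_equal(dim(fusedMap(out)), c(h, w))
        for (m in c(sideMaps(out, "l2h"), sideMaps(out, "h2l")))
            expect_equal(dim(m), c(h, w))
    }
    expect_error(forwardPass(model, array(0.5, c(10, 10, 3))), "at least")
})

test_that("block strides follow the 1, 2, 4, 8, 16 schedule", {
    model <- tinyModel()
    fw <- vesselcascade:::vcForward(model, array(0.5, c(64, 64, 3)))
    expect_equal(fw$nativeDims[, 1], c(64, 32, 16, 8, 4))
    expect_equal(fw$nativeDims[, 2], c(64, 32, 16, 8, 4))
})

test_that("eval-mode forward is bitwise reproducible", {
    model <- tinyModel(seed = 17)
    img <- array(runif(64 * 64 * 3), c(64, 64, 3))
    a <- forwardPass(model, img); b <- forwardPass(model, img)
    expect_identical(fusedMap(a), fusedMap(b))
    expect_identical(sideMaps(a, "l2h"), sideMaps(b, "l2h"))
    expect_identical(sideMaps(a, "h2l"), sideMaps(b, "h2l"))
})

test_that("zero fusion weights give a constant 0.5 fused map", {
    model <- tinyModel()
    model@params$fuse$w[] <- 0
    model@params$fuse$b[] <- 0
    out <- forwardPass(model, array(runif(50 * 50 * 3), c(50, 50, 3)))
    expect_true(all(fusedMap(out) == 0.5))
})

test_that("a width-shrunk model runs forward on a 50x50 input", {
    model <- buildModel(networkConfig(widthMultiplier = 0.125, seed = 2))
    out <- forwardPass(model, array(runif(50 * 50 * 3), c(50, 50, 3)))
    expect_s4_class(out, "CascadeOutput")
    expect_true(all(fusedMap(out) > 0 & fusedMap(out) < 1))
})

test_that("bilinear upsampling is exact on the reference cases", {
    # factor 1 is the identity
    m <- matrix(rnorm(12), 3, 4)
    expect_identical(upsampleBilinear(m, factor = 1), m)
    # constants are preserved at any size (up to rounding)
    expect_equal(upsampleBilinear(matrix(0.3, 2, 2), size = c(9, 7)),
                 matrix(0.3, 9, 7), tolerance = 1e-14)
    # hand-evaluated 2x upsample of a 2x2 ramp (half-pixel centres):
    # source coords for the 4 outputs per axis are -.25, .25, .75, 1.25
    # -> clamped weights 0, .25, .75, 1
    r <- matrix(c(0, 2, 1, 3), 2, 2)  # column-major: [0 1; 2 3]
    up <- upsampleBilinear(r, factor = 2)
    wr <- c(0, 0.25, 0.75, 1)
    expected <- outer(wr * 2, wr * 1, `+`)  # value = 2*row frac + 1*col frac
    expect_equal(up, expected, tolerance = 1e-12)
})

test_that("backbone weight loading validates shapes", {
    model <- tinyModel(wm = 0.03, K = 1, seed = 4)
    dir <- withr::local_tempdir()
    ckpt <- file.path(dir, "bb.rds")
    ch <- modelConfig(model)$channels
    good <- list(conv1_1 = list(w = array(0.1, c(3, 3, 3, ch[1])),
                                b = numeric(ch[1])))
    saveRDS(good, ckpt)
    m2 <- loadBackboneWeights(model, ckpt)
    expect_equal(m2@params$blocks[[1]]$convs[[1]]$w, good$conv1_1$w)
    bad <- list(conv2_1 = list(w = array(0, c(3, 3, 7, 9)), b = numeric(9)))
    saveRDS(bad, ckpt)
    expect_error(loadBackboneWeights(model, ckpt), "conv2_1")
})

test_that("checkpoints round-trip the model exactly", {
    model <- tinyModel(seed = 8)
    dir <- withr::local_tempdir()
    p <- file.path(dir, "m.rds")
    saveCheckpoint(model, p, extra = list(epoch = 3L))
    back <- loadCheckpoint(p)
    expect_identical(back$model@params, model@params)
    expect_identical(back$extra$epoch, 3L)
})
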