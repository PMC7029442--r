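#' Parameters for the synthetic fundus-scene generator
#'
#' The generator emulates the gross properties of fundus photographs that
#' matter for vessel segmentation: dark curvilinear vessel trees of varying
#' diameter, tortuosity and branching; a smooth reddish background with a
#' radial illumination falloff; bright and dark lesion spots that perturb the
#' local background; additive sensor noise; and a circular camera field of
#' view. Every vessel pixel carries its nominal stroke width, so the ground
#' truth can be decomposed exactly into per-diameter maps.
#'
#' @param imageSize integer `c(rows, cols)`.
#' @param nTrees number of vessel trees (>= 0).
#' @param widthRange `c(min, max)` stroke width in pixels, `1 <= min <= max`.
#' @param tortuosity curvature amplitude (>= 0): standard deviation scale of
#'   the per-step heading perturbation of the vessel random walk.
#' @param nBrightLesions,nDarkLesions lesion counts (>= 0).
#' @param lesionRadiusRange lesion radius range in pixels.
#' @param backgroundGradient radial illumination falloff amplitude in [0, 1].
#' @param noiseSigma additive gaussian noise standard deviation (>= 0).
#' @param seed integer; identical parameters (including the seed) give a
#'   bit-identical scene.
#' @return list of class `synthParams`.
#' @export
synthParams <- function(imageSize = c(128L, 128L), nTrees = 4L,
                        widthRange = c(1, 6), tortuosity = 0.5,
                        nBrightLesions = 2L, nDarkLesions = 2L,
                        lesionRadiusRange = c(4, 12),
                        backgroundGradient = 0.3, noiseSigma = 0.02,
                        seed = 1L) {
    if (length(imageSize) != 2L || any(imageSize < 8))
        stop("imageSize must be c(rows, cols) with both >= 8")
    if (widthRange[1] < 1 || widthRange[2] < widthRange[1])
        stop("widthRange must satisfy 1 <= min <= max")
    if (widthRange[2] > min(imageSize))
        stop("widthRange exceeds the image size")
    if (nTrees < 0 || nBrightLesions < 0 || nDarkLesions < 0)
        stop("counts must be >= 0")
    if (tortuosity < 0 || noiseSigma < 0)
        stop("tortuosity and noiseSigma must be >= 0")
    if (backgroundGradient < 0 || backgroundGradient > 1)
        stop("backgroundGradient must be in [0, 1]")
    structure(list(imageSize = as.integer(imageSize),
                   nTrees = as.integer(nTrees),
                   widthRange = as.numeric(widthRange),
                   tortuosity = tortuosity,
                   nBrightLesions = as.integer(nBrightLesions),
                   nDarkLesions = as.integer(nDarkLesions),
                   lesionRadiusRange = as.numeric(lesionRadiusRange),
                   backgroundGradient = backgroundGradient,
                   noiseSigma = noiseSigma, seed = as.integer(seed)),
              class = "synthParams")
}

#' Rasterise a vessel stroke
#'
#' Marks every pixel whose centre lies within `width / 2` of the segment
#' `from`–`to` as vessel, and records the nominal stroke width in the width
#' map (crossings keep the maximum width, so binning at overlaps is
#' unambiguous). Coordinates are 1-based `(row, col)` pixel centres.
#'
#' @param label,widthMap matrices to update.
#' @param from,to numeric `c(row, col)` segment endpoints.
#' @param width stroke width in pixels.
#' @return list with the updated `label` and `widthMap`.
#' @export
rasterizeStroke <- function(label, widthMap, from, to, width) {
    label <- label + 0       # force copies: cpp_raster_segment writes in place
    widthMap <- widthMap + 0
    cpp_raster_segment(label, widthMap, from[1] - 1, from[2] - 1,
                       to[1] - 1, to[2] - 1, width)
    list(label = label, widthMap = widthMap)
}

# grow one vessel tree as a branching random walk; draws segments in place
# on env$label / env$widthMap and shades env$shade with per-pixel darkening
growTree <- function(env, p) {
    H <- p$imageSize[1]; W <- p$imageSize[2]
    cr <- c((H + 1) / 2, (W + 1) / 2)
    rad <- 0.45 * min(H, W)
    ang <- runif(1, 0, 2 * pi)
    start <- cr + rad * c(sin(ang), cos(ang))
    heading <- ang + pi + runif(1, -0.4, 0.4)   # roughly toward the centre
    w0 <- runif(1, p$widthRange[1], p$widthRange[2])
    len0 <- runif(1, 0.6, 1.0) * min(H, W)
    stack <- list(list(pos = start, heading = heading, width = w0,
                       remaining = len0, depth = 0L))
    step <- 2.5
    maxDepth <- 3L
    while (length(stack)) {
        br <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        pos <- br$pos; heading <- br$heading
        remaining <- br$remaining
        total <- remaining
        width <- br$width
        while (remaining > 0) {
            heading <- heading + rnorm(1, sd = 0.35 * p$tortuosity)
            nxt <- pos + step * c(sin(heading), cos(heading))
            # taper the nominal width toward the tip, never below 1 px
            frac <- remaining / total
            w <- max(1, width * (0.6 + 0.4 * frac))
            inFov <- ((nxt[1] - cr[1])^2 + (nxt[2] - cr[2])^2) <= rad^2
            if (!inFov) break
            cpp_raster_segment(env$label, env$widthMap, pos[1] - 1, pos[2] - 1,
                               nxt[1] - 1, nxt[2] - 1, w)
            pos <- nxt
            remaining <- remaining - step
            if (br$depth < maxDepth && runif(1) < 0.04 && remaining > 4 * step)
                stack[[length(stack) + 1L]] <-
                    list(pos = pos,
                         heading = heading + sample(c(-1, 1), 1) *
                             runif(1, 0.5, 0.9),
                         width = max(1, w * 0.7),
                         remaining = remaining * runif(1, 0.4, 0.8),
                         depth = br$depth + 1L)
        }
    }
}

#' Generate a synthetic fundus scene
#'
#' Deterministic for a fixed parameter set: the RNG stream is derived from
#' `params$seed` and the caller's RNG state is untouched.
#'
#' @param params a [synthParams()].
#' @return a [SyntheticScene-class].
#' @examples
#' sc <- generateScene(synthParams(imageSize = c(64, 64), seed = 7))
#' sum(sceneLabel(sc))
#' @export
generateScene <- function(params) {
    stopifnot(inherits(params, "synthParams"))
    p <- params
    H <- p$imageSize[1]; W <- p$imageSize[2]
    withSeed(p$seed, {
        rows <- matrix(seq_len(H), H, W)
        cols <- matrix(seq_len(W), H, W, byrow = TRUE)
        cr <- c((H + 1) / 2, (W + 1) / 2)
        rad <- 0.5 * min(H, W)
        r2 <- ((rows - cr[1])^2 + (cols - cr[2])^2)
        fov <- (r2 <= rad^2) + 0
        # radial illumination falloff over a reddish fundus base colour
        illum <- 1 - p$backgroundGradient * pmin(r2 / rad^2, 1)
        base <- c(0.72, 0.42, 0.22)
        img <- array(0, c(H, W, 3))
        for (ch in 1:3) img[, , ch] <- base[ch] * illum
        # lesions: bright (drusen/exudate-like) and dark (haemorrhage-like)
        nles <- p$nBrightLesions + p$nDarkLesions
        if (nles > 0) {
            kind <- rep(c(1, -1), c(p$nBrightLesions, p$nDarkLesions))
            for (k in seq_len(nles)) {
                lr <- runif(1, p$lesionRadiusRange[1], p$lesionRadiusRange[2])
                ctr <- cr + runif(2, -0.35, 0.35) * c(H, W)
                amp <- kind[k] * runif(1, 0.15, 0.3)
                bump <- amp * exp(-(((rows - ctr[1])^2 + (cols - ctr[2])^2) /
                                        (0.5 * lr^2)))
                for (ch in 1:3) img[, , ch] <- img[, , ch] + bump
            }
        }
        env <- new.env()
        env$label <- matrix(0, H, W)
        env$widthMap <- matrix(0, H, W)
        for (t in seq_len(p$nTrees)) growTree(env, p)
        # vessels rendered as dark red: strong dampening in green/blue
        vessel <- env$label
        dark <- c(0.55, 0.25, 0.2)
        for (ch in 1:3)
            img[, , ch] <- img[, , ch] * (1 - vessel) +
                img[, , ch] * dark[ch] * vessel
        if (p$noiseSigma > 0)
            img <- img + array(rnorm(length(img), sd = p$noiseSigma), dim(img))
        img <- pmin(pmax(img, 0), 1)
        new("SyntheticScene", image = img, label = env$label,
            widthMap = env$widthMap, fovMask = fov)
    })
}

#' Decompose the vessel label by diameter
#'
#' Splits the ground truth `Y` into `D = length(edges) + 1` disjoint binary
#' maps by binning each vessel pixel's stroke width at the given thresholds:
#' map `d` holds the pixels with width in `(edges[d-1], edges[d]]` (first bin
#' `(0, edges[1]]`, last bin `(edges[D-1], Inf)`). The maps are pairwise
#' disjoint and sum elementwise to the label — the exact per-diameter
#' decomposition the cascade's supervision approximates.
#'
#' @param scene a [SyntheticScene-class].
#' @param edges strictly increasing width thresholds (possibly empty, giving
#'   the single map `Y` itself).
#' @return list of `length(edges) + 1` binary matrices.
#' @export
widthPartition <- function(scene, edges = numeric()) {
    stopifnot(is(scene, "SyntheticScene"))
    if (length(edges) && any(diff(edges) <= 0))
        stop("bin edges must be strictly increasing")
    D <- length(edges) + 1L
    wm <- scene@widthMap
    lab <- scene@label
    bin <- matrix(findInterval(wm, c(0, edges), left.open = TRUE), nrow(wm))
    lapply(seq_len(D), function(d) (lab == 1 & bin == d) + 0)
}

#' Write / read a scene as paired image files
#'
#' `<id>_image.png` (RGB), `<id>_label.png` and `<id>_fov.png` (binary,
#' 8-bit) and `<id>_width.tif` (32-bit float TIFF). `loadScene` inverts the
#' round trip exactly up to 8-bit quantisation of the image.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if needed).
#' @param id scene identifier used as filename stem.
#' @return `saveScene` the id invisibly; `loadScene` a
#'   [SyntheticScene-class].
#' @export
saveScene <- function(scene, dir, id) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    png::writePNG(scene@image, file.path(dir, paste0(id, "_image.png")))
    png::writePNG(scene@label, file.path(dir, paste0(id, "_label.png")))
    png::writePNG(scene@fovMask, file.path(dir, paste0(id, "_fov.png")))
    # widths stored as float32 scaled into [0, 1] (max representable 255 px)
    tiff::writeTIFF(scene@widthMap / 255,
                    file.path(dir, paste0(id, "_width.tif")),
                    bits.per.sample = 32L, reduce = FALSE)
    invisible(id)
}

#' @rdname saveScene
#' @export
loadScene <- function(dir, id) {
    img <- png::readPNG(file.path(dir, paste0(id, "_image.png")))
    lab <- png::readPNG(file.path(dir, paste0(id, "_label.png")))
    fov <- png::readPNG(file.path(dir, paste0(id, "_fov.png")))
    wm <- tiff::readTIFF(file.path(dir, paste0(id, "_width.tif"))) * 255
    new("SyntheticScene", image = img, label = (lab > 0.5) + 0,
        widthMap = wm, fovMask = (fov > 0.5) + 0)
}
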