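#' Describe a dataset layout on disk
#'
#' Filename patterns contain a single `%s` that is replaced by the image id;
#' ids are discovered by matching the image pattern against the files in
#' `root` (or given explicitly). Supported image formats: PNG, TIFF, JPEG and
#' PPM/PGM.
#'
#' @param name one of `"DRIVE"`, `"STARE"`, `"HRF"`, `"CHASE_DB1"`,
#'   `"SYNTH"` — selects the split scheme used by [makeSplits()].
#' @param root dataset directory.
#' @param imagePattern,labelPattern,fovPattern `sprintf`-style filename
#'   patterns (`fovPattern` optional).
#' @param ids explicit id vector (otherwise discovered from `root`).
#' @param split explicit split description: for `"SYNTH"` a
#'   `list(train =, test =)` of ids (required); for `"HRF"` an optional
#'   `list(train =, test =)` overriding the first-38/next-9 default.
#' @return list of class `datasetSpec`.
#' @export
datasetSpec <- function(name = c("SYNTH", "DRIVE", "STARE", "HRF", "CHASE_DB1"),
                        root, imagePattern = "%s_image.png",
                        labelPattern = "%s_label.png", fovPattern = NULL,
                        ids = NULL, split = NULL) {
    name <- match.arg(name)
    if (!grepl("%s", imagePattern, fixed = TRUE) ||
        !grepl("%s", labelPattern, fixed = TRUE))
        stop("filename patterns must contain a single %s placeholder")
    structure(list(name = name, root = root, imagePattern = imagePattern,
                   labelPattern = labelPattern, fovPattern = fovPattern,
                   ids = ids, split = split),
              class = "datasetSpec")
}

#' @rdname datasetSpec
#' @export
datasetIds <- function(spec) {
    if (!is.null(spec$ids)) return(spec$ids)
    if (!dir.exists(spec$root)) stop("dataset root not found: ", spec$root)
    esc <- gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", spec$imagePattern)
    rx <- paste0("^", gsub("%s", "(.+)", esc, fixed = TRUE), "$")
    f <- list.files(spec$root)
    m <- regmatches(f, regexec(rx, f))
    sort(vapply(m[lengths(m) == 2L], `[`, character(1), 2L))
}

# minimal PPM/PGM reader (P2/P3/P5/P6); returns [rows x cols (x 3)] in [0,1]
readPNM <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    tokens <- character()
    # header tokens may be interleaved with comments
    readToken <- function() {
        repeat {
            ch <- readChar(con, 1L, useBytes = TRUE)
            if (length(ch) == 0) stop("unexpected end of PNM header")
            if (ch == "#") {
                repeat {
                    ch <- readChar(con, 1L, useBytes = TRUE)
                    if (!length(ch) || ch == "\n") break
                }
            } else if (!grepl("[[:space:]]", ch)) break
        }
        tok <- ch
        repeat {
            ch <- readChar(con, 1L, useBytes = TRUE)
            if (!length(ch) || grepl("[[:space:]]", ch)) break
            tok <- paste0(tok, ch)
        }
        tok
    }
    magic <- readToken()
    if (!magic %in% c("P2", "P3", "P5", "P6"))
        stop("unsupported PNM magic: ", magic)
    w <- as.integer(readToken()); h <- as.integer(readToken())
    mx <- as.integer(readToken())
    nch <- if (magic %in% c("P3", "P6")) 3L else 1L
    n <- w * h * nch
    vals <- if (magic %in% c("P5", "P6")) {
        if (mx > 255) stop("16-bit PNM not supported")
        as.integer(readBin(con, "raw", n))
    } else {
        txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
        txt <- gsub("#[^\n]*", "", txt)
        toks <- strsplit(txt, "[[:space:]]+")[[1]]
        as.integer(toks[nzchar(toks)])[seq_len(n)]
    }
    # PNM is row-major, channels interleaved
    if (nch == 3L) {
        a <- array(vals, c(3L, w, h))
        aperm(a, c(3L, 2L, 1L)) / mx
    } else {
        t(matrix(vals, w, h)) / mx
    }
}

#' Read an image file as a numeric array
#'
#' Dispatches on the extension: PNG and TIFF through their native readers,
#' JPEG through EBImage, PPM/PGM through a built-in parser. Values are scaled
#' to `[0, 1]`; the first two dimensions are rows and columns.
#'
#' @param path file path.
#' @return numeric matrix or `rows x cols x channels` array.
#' @export
readImageFile <- function(path) {
    if (!file.exists(path)) stop("cannot read file: ", path)
    ext <- tolower(tools::file_ext(path))
    img <- switch(ext,
        png = png::readPNG(path),
        tif = , tiff = tiff::readTIFF(path),
        jpg = , jpeg = {
            x <- EBImage::imageData(EBImage::readImage(path))
            if (length(dim(x)) == 3L) aperm(x, c(2L, 1L, 3L)) else t(x)
        },
        ppm = , pgm = , pnm = readPNM(path),
        gif = stop("GIF is not supported; convert labels to PNG or TIFF"),
        stop("unsupported image format: .", ext))
    if (length(dim(img)) == 3L && dim(img)[3] == 4L)
        img <- img[, , 1:3]  # drop alpha
    img
}

#' Load an image/label/field-of-view triple
#'
#' The image is returned as `rows x cols x 3` in `[0, 1]` (grayscale inputs
#' are replicated across channels), the label binarised as `pixel > 0`, and
#' the field-of-view mask as ones when the dataset has none.
#'
#' @param spec a [datasetSpec()].
#' @param id image id.
#' @return `list(image, label, fov)`.
#' @export
loadImageLabel <- function(spec, id) {
    img <- readImageFile(file.path(spec$root, sprintf(spec$imagePattern, id)))
    lab <- readImageFile(file.path(spec$root, sprintf(spec$labelPattern, id)))
    if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (length(dim(lab)) == 3L) lab <- lab[, , 1]
    if (!identical(dim(lab), dim(img)[1:2]))
        stop(sprintf("label size (%s) does not match image size (%s) for '%s'",
                     paste(dim(lab), collapse = "x"),
                     paste(dim(img)[1:2], collapse = "x"), id))
    lab <- (lab > 0) + 0
    fov <- matrix(1, nrow(lab), ncol(lab))
    if (!is.null(spec$fovPattern)) {
        fp <- file.path(spec$root, sprintf(spec$fovPattern, id))
        if (file.exists(fp)) {
            fov <- readImageFile(fp)
            if (length(dim(fov)) == 3L) fov <- fov[, , 1]
            if (!identical(dim(fov), dim(lab)))
                stop("field-of-view mask size mismatch for '", id, "'")
            fov <- (fov > 0) + 0
        }
    }
    list(image = img, label = lab, fov = fov)
}

#' Extract square patches from an image/label pair
#'
#' Random mode samples `count` uniformly distributed in-bounds top-left
#' corners (reproducible for a fixed seed); grid mode tiles the image with
#' non-overlapping patches, dropping partial tiles at the borders. Patches
#' are half-open `size x size` windows, 1-based corners.
#'
#' @param image `rows x cols x 3` array.
#' @param label matching binary matrix.
#' @param size patch side in pixels (default 50).
#' @param count number of patches (random mode).
#' @param seed RNG seed (random mode).
#' @param mode `"random"` or `"grid"`.
#' @param id source image id stored with each patch.
#' @return list of patches: `list(image, label, id, corner)`.
#' @export
extractPatches <- function(image, label, size = 50L, count = 100L,
                           seed = NULL, mode = c("random", "grid"),
                           id = "img") {
    mode <- match.arg(mode)
    H <- dim(image)[1]; W <- dim(image)[2]
    size <- as.integer(size)
    if (size > H || size > W)
        stop("patch size exceeds the image dimensions")
    corners <- if (mode == "grid") {
        as.matrix(expand.grid(row = seq(1L, H - size + 1L, by = size),
                              col = seq(1L, W - size + 1L, by = size)))
    } else {
        withSeed(seed, cbind(row = sample.int(H - size + 1L, count, TRUE),
                             col = sample.int(W - size + 1L, count, TRUE)))
    }
    lapply(seq_len(nrow(corners)), function(k) {
        r <- corners[k, 1]; c <- corners[k, 2]
        list(image = image[r:(r + size - 1L), c:(c + size - 1L), , drop = FALSE],
             label = label[r:(r + size - 1L), c:(c + size - 1L)],
             id = id, corner = c(row = unname(r), col = unname(c)))
    })
}

# vectorised HSV -> RGB (h, s, v in [0, 1]); inverse of grDevices::rgb2hsv
hsv2rgbMat <- function(h, s, v) {
    i <- floor(h * 6) %% 6
    f <- h * 6 - floor(h * 6)
    p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
    r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
    g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
    b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
    cbind(r, g, b)
}

#' Sample augmentation parameters from the configured grids
#'
#' Contrast exponents are drawn from `{-0.6, -0.4, ..., 0.8}`, scales from
#' `{0.75, 0.80, ..., 1.05}`, shifts from `{-80, -60, ..., 100}` pixels per
#' axis, and rotation from `rotationSet` (empty by default: rotation
#' disabled).
#'
#' @param seed RNG seed.
#' @param rotationSet numeric vector of candidate angles in degrees.
#' @return list with `hsvGamma`, `scale`, `shift`, `rotationDeg`.
#' @export
augmentParams <- function(seed = NULL, rotationSet = numeric()) {
    withSeed(seed, list(
        hsvGamma = sample(seq(-0.6, 0.8, by = 0.2), 1),
        scale = sample(seq(0.75, 1.05, by = 0.05), 1),
        shift = c(sample(seq(-80, 100, by = 20), 1),
                  sample(seq(-80, 100, by = 20), 1)),
        rotationDeg = if (length(rotationSet)) sample(rotationSet, 1) else 0))
}

#' Augment an image/label pair
#'
#' Contrast: the image is converted to HSV and the saturation and value
#' channels are raised to the power `1 + hsvGamma` (0 is the identity,
#' negative brightens, positive darkens). Geometry: isotropic scaling (content
#' re-centred on the fixed canvas), optional rotation about the centre, and a
#' pixel shift; all geometric operations are applied identically to image and
#' label, the label with nearest-neighbour interpolation and re-binarisation
#' at 0.5, and regions moved off-canvas are zero-filled. Identity parameters
#' return the arrays unchanged.
#'
#' @param image `rows x cols x 3` array in `[0, 1]`.
#' @param label binary matrix.
#' @param hsvGamma contrast exponent offset.
#' @param scale isotropic scale factor.
#' @param shift integer `c(rows, cols)` displacement.
#' @param rotationDeg rotation angle in degrees (0 disables).
#' @return `list(image, label)`.
#' @export
augmentPair <- function(image, label, hsvGamma = 0, scale = 1,
                        shift = c(0L, 0L), rotationDeg = 0) {
    H <- dim(image)[1]; W <- dim(image)[2]
    if (hsvGamma != 0) {
        m <- matrix(aperm(image, c(3, 1, 2)), nrow = 3)
        hsvm <- grDevices::rgb2hsv(m, maxColorValue = 1)
        g <- 1 + hsvGamma
        rgbm <- hsv2rgbMat(hsvm[1, ], hsvm[2, ]^g, hsvm[3, ]^g)
        image <- aperm(array(t(rgbm), c(3, H, W)), c(2, 3, 1))
    }
    if (scale != 1) {
        nh <- max(1L, round(scale * H)); nw <- max(1L, round(scale * W))
        simg <- EBImage::resize(image, nh, nw)
        slab <- EBImage::resize(label, nh, nw, filter = "none")
        image <- array(0, c(H, W, 3)); labNew <- matrix(0, H, W)
        # re-centre the scaled content on the fixed canvas
        ro <- floor((H - nh) / 2); co <- floor((W - nw) / 2)
        sr <- max(1, 1 - ro):min(nh, H - ro)
        sc <- max(1, 1 - co):min(nw, W - co)
        image[sr + ro, sc + co, ] <- simg[sr, sc, ]
        labNew[sr + ro, sc + co] <- slab[sr, sc]
        label <- labNew
    }
    if (rotationDeg != 0) {
        image <- EBImage::rotate(image, rotationDeg, output.dim = c(H, W),
                                 bg.col = 0)
        label <- EBImage::rotate(label, rotationDeg, filter = "none",
                                 output.dim = c(H, W), bg.col = 0)
        image <- array(as.numeric(image), c(H, W, 3))
        label <- matrix(as.numeric(label), H, W)
    }
    if (any(shift != 0)) {
        dr <- as.integer(shift[1]); dc <- as.integer(shift[2])
        img2 <- array(0, c(H, W, 3)); lab2 <- matrix(0, H, W)
        sr <- max(1, 1 + dr):min(H, H + dr)
        sc <- max(1, 1 + dc):min(W, W + dc)
        if (length(sr) > 0 && length(sc) > 0 && sr[1] <= H && sc[1] <= W) {
            img2[sr, sc, ] <- image[sr - dr, sc - dc, , drop = FALSE]
            lab2[sr, sc] <- label[sr - dr, sc - dc]
        }
        image <- img2; label <- lab2
    }
    label <- (label > 0.5) + 0
    image <- pmin(pmax(image, 0), 1)
    list(image = image, label = label)
}

#' Build train/test splits following the published schemes
#'
#' DRIVE: 20 train/validation images and 20 held-out test images, with a
#' 20,000-patch budget split 18,000 train / 2,000 validation. STARE: 20
#' leave-one-out folds, one test image each. HRF: 38 train/validation and 9
#' test images (overridable via `spec$split`), 40,000 patches split
#' 36,000 / 4,000. CHASE_DB1: first 20 images train, remaining 8 test.
#' SYNTH: the split given in `spec$split`.
#'
#' @param spec a [datasetSpec()].
#' @return list of class `splitPlan`: `scheme`, `folds` (each
#'   `list(train, test)`), and `patchBudget` (`c(train =, val =)` or `NULL`).
#' @export
makeSplits <- function(spec) {
    ids <- datasetIds(spec)
    n <- length(ids)
    plan <- switch(spec$name,
        DRIVE = {
            if (n != 40L)
                stop("DRIVE scheme expects 40 images, found ", n)
            # conventional DRIVE naming sorts the 20 test images first
            list(folds = list(list(train = ids[21:40], test = ids[1:20])),
                 patchBudget = c(train = 18000L, val = 2000L))
        },
        STARE = {
            if (n != 20L)
                stop("STARE leave-one-out scheme expects 20 images, found ", n)
            list(folds = lapply(seq_len(n), function(i)
                     list(train = ids[-i], test = ids[i])),
                 patchBudget = NULL)
        },
        HRF = {
            if (!is.null(spec$split)) {
                list(folds = list(list(train = spec$split$train,
                                       test = spec$split$test)),
                     patchBudget = c(train = 36000L, val = 4000L))
            } else {
                if (n < 47L)
                    stop("HRF default scheme needs 47 images (38 + 9); ",
                         "found ", n, " - pass an explicit split")
                list(folds = list(list(train = ids[1:38], test = ids[39:47])),
                     patchBudget = c(train = 36000L, val = 4000L))
            }
        },
        CHASE_DB1 = {
            if (n != 28L)
                stop("CHASE_DB1 scheme expects 28 images, found ", n)
            list(folds = list(list(train = ids[1:20], test = ids[21:28])),
                 patchBudget = NULL)
        },
        SYNTH = {
            if (is.null(spec$split))
                stop("SYNTH datasets need an explicit split in the spec")
            list(folds = list(list(train = spec$split$train,
                                   test = spec$split$test)),
                 patchBudget = NULL)
        })
    for (f in plan$folds) {
        if (length(intersect(f$train, f$test)))
            stop("split is not a partition: train and test overlap")
    }
    structure(c(list(scheme = spec$name, ids = ids), plan),
              class = "splitPlan")
}
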