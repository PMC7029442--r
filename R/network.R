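#' Cascade network configuration
#'
#' The backbone is VGG16 with the three fully connected layers and the last
#' pooling layer removed: 13 convolutional layers grouped into five blocks of
#' (2, 2, 3, 3, 3) convolutions with 2x2 max pooling between consecutive
#' blocks, giving block strides 1, 2, 4, 8, 16. Each block becomes a scale
#' detection block (SDB): every backbone convolution is followed by a dense
#' dilated convolution module, the module outputs are summed, and two 1x1
#' heads emit the block's pair of contour logits (one per cascade direction).
#' A final 1x1 convolution fuses the ten upsampled side logits.
#'
#' @param D number of scale detection blocks (5).
#' @param convsPerBlock integer vector, convolutions per block (sums to 13).
#' @param channelsPerBlock base channel widths before scaling.
#' @param ddcm a [ddcmConfig()]; its `channels` field is ignored (each block
#'   uses its own width).
#' @param widthMultiplier real in (0, 1]: scales every channel count (rounded
#'   up) for CPU-scale experiments; 1 reproduces the full-width network.
#' @param ddcmPlacement `"per_conv"` (one module after every backbone
#'   convolution, the default) or `"per_block"` (a single module after the
#'   block's last convolution).
#' @param seed integer seed for weight initialisation.
#' @return list of class `networkConfig`.
#' @export
networkConfig <- function(D = 5L, convsPerBlock = c(2L, 2L, 3L, 3L, 3L),
                          channelsPerBlock = c(64L, 128L, 256L, 512L, 512L),
                          ddcm = ddcmConfig(), widthMultiplier = 1,
                          ddcmPlacement = c("per_conv", "per_block"),
                          seed = 1L) {
    D <- as.integer(D)
    if (length(convsPerBlock) != D || length(channelsPerBlock) != D)
        stop("convsPerBlock and channelsPerBlock must have length D")
    if (widthMultiplier <= 0 || widthMultiplier > 1)
        stop("widthMultiplier must be in (0, 1]")
    chans <- pmax(1L, as.integer(ceiling(channelsPerBlock * widthMultiplier)))
    structure(list(D = D, convsPerBlock = as.integer(convsPerBlock),
                   channelsPerBlock = as.integer(channelsPerBlock),
                   channels = chans, ddcm = ddcm,
                   widthMultiplier = widthMultiplier,
                   ddcmPlacement = match.arg(ddcmPlacement),
                   seed = as.integer(seed)),
              class = "networkConfig")
}

# number of DDCMs block d carries under the configured placement
nDdcm <- function(cfg, d) {
    if (cfg$ddcmPlacement == "per_conv") cfg$convsPerBlock[d] else 1L
}

#' Build a cascade model
#'
#' Allocates and initialises all weights deterministically from
#' `cfg$seed`: backbone and DDCM kernels with He-scaled gaussians, prediction
#' heads with small gaussians, and the fusion kernel at the uniform value
#' `1 / (2 D)` so the initial fused logit is the mean of the side logits.
#'
#' @param cfg a [networkConfig()].
#' @param backboneWeights optional path to an RDS file with a named list of
#'   `list(w, b)` entries (`conv1_1` .. `conv5_3`) to overwrite the backbone
#'   kernels, e.g. weights converted from an ImageNet-pretrained VGG16.
#' @return a [CascadeModel-class].
#' @export
buildModel <- function(cfg = networkConfig(), backboneWeights = NULL) {
    params <- withSeed(cfg$seed, {
        blocks <- vector("list", cfg$D)
        cin <- 3L
        for (d in seq_len(cfg$D)) {
            ch <- cfg$channels[d]
            m <- cfg$convsPerBlock[d]
            convs <- vector("list", m)
            for (i in seq_len(m)) {
                convs[[i]] <- list(w = initKernel(3L, 3L, cin, ch),
                                   b = numeric(ch))
                cin <- ch
            }
            ddcms <- lapply(seq_len(nDdcm(cfg, d)),
                            function(i) ddcmInit(cfg$ddcm, cin = ch))
            heads <- lapply(1:2, function(i)
                list(w = array(rnorm(ch, sd = 0.01), c(1L, 1L, ch, 1L)),
                     b = numeric(1)))
            blocks[[d]] <- list(convs = convs, ddcms = ddcms,
                                headL2H = heads[[1]], headH2L = heads[[2]])
        }
        fuse <- list(w = array(1 / (2 * cfg$D), c(1L, 1L, 2L * cfg$D, 1L)),
                     b = numeric(1))
        list(blocks = blocks, fuse = fuse)
    })
    model <- new("CascadeModel", config = unclass(cfg), params = params)
    if (!is.null(backboneWeights))
        model <- loadBackboneWeights(model, backboneWeights)
    model
}

#' Load backbone weights from a converted VGG16 parameter file
#'
#' @param model a [CascadeModel-class].
#' @param path RDS file holding a named list with entries `conv<d>_<i> =
#'   list(w = <3 x 3 x cin x cout array>, b = <vector>)`.
#' @return the model with backbone kernels replaced.
#' @export
loadBackboneWeights <- function(model, path) {
    if (!file.exists(path)) stop("backbone weight file not found: ", path)
    wl <- readRDS(path)
    cfg <- model@config
    bad <- character()
    for (d in seq_len(cfg$D)) {
        for (i in seq_len(cfg$convsPerBlock[d])) {
            nm <- sprintf("conv%d_%d", d, i)
            if (is.null(wl[[nm]])) next
            cur <- model@params$blocks[[d]]$convs[[i]]
            if (!identical(dim(wl[[nm]]$w), dim(cur$w)) ||
                length(wl[[nm]]$b) != length(cur$b)) {
                bad <- c(bad, sprintf("%s: have %s, need %s", nm,
                                      paste(dim(wl[[nm]]$w), collapse = "x"),
                                      paste(dim(cur$w), collapse = "x")))
                next
            }
            model@params$blocks[[d]]$convs[[i]] <- wl[[nm]]
        }
    }
    if (length(bad))
        stop("backbone weight shape mismatch:\n  ",
             paste(bad, collapse = "\n  "))
    model
}

# full forward pass; returns side/fused probabilities plus (optionally) all
# caches needed for the backward pass and the native-stride logits
vcForward <- function(model, image, cache = FALSE) {
    cfg <- model@config
    x <- asFeatureMap(image)
    H0 <- dim(x)[1]; W0 <- dim(x)[2]
    minSize <- 2L^(cfg$D - 1L)
    if (H0 < minSize || W0 < minSize)
        stop(sprintf("input must be at least %d x %d", minSize, minSize))
    perConv <- cfg$ddcmPlacement == "per_conv"
    blocksC <- vector("list", cfg$D)
    upL2H <- upH2L <- vector("list", cfg$D)
    natL2H <- natH2L <- vector("list", cfg$D)
    nativeDims <- matrix(0L, cfg$D, 2)
    for (d in seq_len(cfg$D)) {
        bp <- model@params$blocks[[d]]
        m <- cfg$convsPerBlock[d]
        bc <- list(xin = vector("list", m), z = vector("list", m),
                   ddcm = vector("list", nDdcm(cfg, d)))
        r <- NULL
        feats <- vector("list", nDdcm(cfg, d))
        for (i in seq_len(m)) {
            xin <- if (i == 1L) x else r
            z <- cpp_conv2d(xin, bp$convs[[i]]$w, bp$convs[[i]]$b, 1L)
            r <- relu(z)
            if (cache) { bc$xin[[i]] <- xin; bc$z[[i]] <- z }
            if (perConv) {
                dd <- ddcmForward(r, bp$ddcms[[i]], cfg$ddcm, cache = cache)
                if (cache) { feats[[i]] <- dd$out; bc$ddcm[[i]] <- dd$cache }
                else feats[[i]] <- dd
            }
        }
        if (!perConv) {
            dd <- ddcmForward(r, bp$ddcms[[1]], cfg$ddcm, cache = cache)
            if (cache) { feats[[1]] <- dd$out; bc$ddcm[[1]] <- dd$cache }
            else feats[[1]] <- dd
        }
        s <- Reduce(`+`, feats)
        nativeDims[d, ] <- dim(s)[1:2]
        lgL <- cpp_conv2d(s, bp$headL2H$w, bp$headL2H$b, 1L)
        lgH <- cpp_conv2d(s, bp$headH2L$w, bp$headH2L$b, 1L)
        natL2H[[d]] <- lgL; natH2L[[d]] <- lgH
        upL2H[[d]] <- cpp_upsample_bilinear(lgL, H0, W0)[, , 1]
        upH2L[[d]] <- cpp_upsample_bilinear(lgH, H0, W0)[, , 1]
        if (cache) bc$s <- s
        if (d < cfg$D) {
            pl <- cpp_maxpool2(r)
            if (cache) { bc$poolIdx <- pl$idx; bc$rdim <- dim(r) }
            x <- pl$y
        }
        blocksC[[d]] <- bc
    }
    upStack <- array(0, c(H0, W0, 2L * cfg$D))
    for (d in seq_len(cfg$D)) {
        upStack[, , d] <- upL2H[[d]]
        upStack[, , cfg$D + d] <- upH2L[[d]]
    }
    fusedLogit <- cpp_conv2d(upStack, model@params$fuse$w,
                             model@params$fuse$b, 1L)[, , 1]
    out <- list(sideL2H = lapply(upL2H, sigmoid),
                sideH2L = lapply(upH2L, sigmoid),
                fused = sigmoid(fusedLogit),
                nativeDims = nativeDims)
    if (cache)
        c(out, list(upL2H = upL2H, upH2L = upH2L, upStack = upStack,
                    blocks = blocksC, natL2H = natL2H, natH2L = natH2L))
    else out
}

#' Run an image through the cascade
#'
#' @param model a [CascadeModel-class].
#' @param image `rows x cols x 3` array in `[0, 1]` (rows, cols >= 16, the
#'   deepest block stride).
#' @return a [CascadeOutput-class] with the ten side probability maps and the
#'   fused map, all at input resolution.
#' @export
forwardPass <- function(model, image) {
    fw <- vcForward(model, image, cache = FALSE)
    new("CascadeOutput", sideL2H = fw$sideL2H, sideH2L = fw$sideH2L,
        fused = fw$fused)
}

# backward pass: gmaps holds dLoss/dProbability for the 11 output maps
# (lists gL2H, gH2L of length D and matrix gFused); returns nested gradients
# mirroring model@params
vcBackward <- function(model, fw, gmaps) {
    cfg <- model@config
    D <- cfg$D
    perConv <- cfg$ddcmPlacement == "per_conv"
    H0 <- dim(fw$fused)[1]; W0 <- dim(fw$fused)[2]
    gFusedLogit <- gmaps$gFused * fw$fused * (1 - fw$fused)
    fb <- cpp_conv2d_backward(fw$upStack, model@params$fuse$w,
                              array(gFusedLogit, c(H0, W0, 1L)), 1L)
    grads <- list(blocks = vector("list", D),
                  fuse = list(w = fb$gw, b = fb$gb))
    gin <- NULL  # gradient w.r.t. the input of block d + 1
    for (d in rev(seq_len(D))) {
        bp <- model@params$blocks[[d]]
        bc <- fw$blocks[[d]]
        m <- cfg$convsPerBlock[d]
        nd <- fw$nativeDims[d, ]
        gUpL <- fb$gx[, , d] +
            gmaps$gL2H[[d]] * fw$sideL2H[[d]] * (1 - fw$sideL2H[[d]])
        gUpH <- fb$gx[, , D + d] +
            gmaps$gH2L[[d]] * fw$sideH2L[[d]] * (1 - fw$sideH2L[[d]])
        gNatL <- cpp_upsample_bilinear_backward(
            array(gUpL, c(H0, W0, 1L)), nd[1], nd[2])
        gNatH <- cpp_upsample_bilinear_backward(
            array(gUpH, c(H0, W0, 1L)), nd[1], nd[2])
        hbL <- cpp_conv2d_backward(bc$s, bp$headL2H$w, gNatL, 1L)
        hbH <- cpp_conv2d_backward(bc$s, bp$headH2L$w, gNatH, 1L)
        gS <- hbL$gx + hbH$gx
        gb <- list(convs = vector("list", m),
                   ddcms = vector("list", nDdcm(cfg, d)),
                   headL2H = list(w = hbL$gw, b = hbL$gb),
                   headH2L = list(w = hbH$gw, b = hbH$gb))
        # gradient arriving at each post-ReLU activation r_i
        gr <- vector("list", m)
        for (i in seq_len(m)) gr[[i]] <- 0
        if (perConv) {
            for (i in seq_len(m)) {
                db <- ddcmBackward(bc$ddcm[[i]], gS, bp$ddcms[[i]], cfg$ddcm)
                gb$ddcms[[i]] <- db$grads
                gr[[i]] <- gr[[i]] + db$gx
            }
        } else {
            db <- ddcmBackward(bc$ddcm[[1]], gS, bp$ddcms[[1]], cfg$ddcm)
            gb$ddcms[[1]] <- db$grads
            gr[[m]] <- gr[[m]] + db$gx
        }
        if (d < D)  # grad from block d + 1's input, through the pool
            gr[[m]] <- gr[[m]] +
                cpp_maxpool2_backward(bc$poolIdx, gin, bc$rdim[1], bc$rdim[2])
        for (i in rev(seq_len(m))) {
            gz <- gr[[i]] * (bc$z[[i]] > 0)
            cb <- cpp_conv2d_backward(bc$xin[[i]], bp$convs[[i]]$w, gz, 1L)
            gb$convs[[i]] <- list(w = cb$gw, b = cb$gb)
            if (i > 1L) gr[[i - 1L]] <- gr[[i - 1L]] + cb$gx
            else gin <- cb$gx
        }
        grads$blocks[[d]] <- gb
    }
    grads
}

# elementwise walk over two parallel nested parameter lists; matched by name
# where names exist (gradient lists may order leaves differently), else by
# position
paramWalk <- function(a, b, f) {
    if (is.list(a)) {
        out <- a
        nm <- names(a)
        if (is.null(nm)) {
            for (i in seq_along(a)) out[[i]] <- paramWalk(a[[i]], b[[i]], f)
        } else {
            for (n in nm) out[[n]] <- paramWalk(a[[n]], b[[n]], f)
        }
        out
    } else f(a, b)
}

paramMap <- function(a, f) {
    if (is.list(a)) {
        for (nm in seq_along(a)) a[[nm]] <- paramMap(a[[nm]], f)
        a
    } else f(a)
}

#' Save / load model checkpoints
#'
#' Checkpoints hold the full configuration, all weights and any extra state
#' (optimiser velocities, epoch counter), so training can resume exactly.
#'
#' @param model a [CascadeModel-class].
#' @param path file path (RDS).
#' @param extra list of additional state to store.
#' @return `loadCheckpoint` returns `list(model, extra)`.
#' @export
saveCheckpoint <- function(model, path, extra = list()) {
    saveRDS(list(config = model@config, params = model@params, extra = extra),
            path)
    invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
    ck <- readRDS(path)
    list(model = new("CascadeModel", config = ck$config, params = ck$params),
         extra = ck$extra)
}
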