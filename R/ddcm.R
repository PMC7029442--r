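#' Dense dilated convolution module (DDCM) configuration
#'
#' A DDCM is a stack of `K` convolution branches with dilation rates doubling
#' from 1 (`rate_k = 2^(k-1)`). Branch `k` sees the module input plus the
#' outputs of all earlier branches (dense additive skips), applies a 3x3
#' dilated convolution followed by a linear 1x1 convolution, and the module
#' output is the input plus the sum of all branch outputs (residual
#' aggregation). Small rates keep local detail, large rates reach object-level
#' context, so one module enriches features across vessel diameters.
#'
#' @param K number of branches (default 5, the depth at which segmentation
#'   quality saturates in ablation).
#' @param channels number of input = output channels.
#' @param reluOut apply a ReLU to the module output (the branches themselves
#'   are linear).
#' @return a list of class `ddcmConfig` with fields `K`, `rates`, `channels`,
#'   `reluOut`.
#' @seealso [ddcmForward()], [receptiveField()]
#' @export
ddcmConfig <- function(K = 5L, channels = 64L, reluOut = TRUE) {
    K <- as.integer(K)
    if (is.na(K) || K < 1L) stop("'K' must be an integer >= 1")
    structure(list(K = K, rates = as.integer(2^(seq_len(K) - 1L)),
                   channels = as.integer(channels), reluOut = isTRUE(reluOut)),
              class = "ddcmConfig")
}

# He-scaled gaussian kernel init
initKernel <- function(kh, kw, cin, cout, gain = sqrt(2)) {
    array(rnorm(kh * kw * cin * cout, sd = gain / sqrt(kh * kw * cin)),
          c(kh, kw, cin, cout))
}

#' Initialise DDCM weights
#'
#' @param cfg a [ddcmConfig()].
#' @param cin input channel count (defaults to `cfg$channels`).
#' @return named list of arrays: per branch `k`, `k<k>.w3`/`k<k>.b3` (3x3
#'   dilated kernel) and `k<k>.w1`/`k<k>.b1` (1x1 linear mixing).
#' @export
ddcmInit <- function(cfg, cin = cfg$channels) {
    p <- list()
    for (k in seq_len(cfg$K)) {
        p[[sprintf("k%d.w3", k)]] <- initKernel(3L, 3L, cin, cin)
        p[[sprintf("k%d.b3", k)]] <- numeric(cin)
        p[[sprintf("k%d.w1", k)]] <- initKernel(1L, 1L, cin, cin, gain = 1)
        p[[sprintf("k%d.b1", k)]] <- numeric(cin)
    }
    p
}

#' DDCM forward pass
#'
#' @param x input feature map (`H x W x C` array or matrix).
#' @param params weights from [ddcmInit()].
#' @param cfg a [ddcmConfig()].
#' @param cache keep intermediate activations for [ddcmBackward()].
#' @return the output feature map, or (with `cache = TRUE`) a list
#'   `list(out, cache)`.
#' @export
ddcmForward <- function(x, params, cfg, cache = FALSE) {
    x <- asFeatureMap(x)
    if (dim(x)[3] != dim(params[["k1.w3"]])[3])
        stop("input channels do not match DDCM weights")
    s <- x                       # running sum: input + outputs of branches < k
    cc <- if (cache) list(x = x, a = vector("list", cfg$K),
                          u = vector("list", cfg$K)) else NULL
    for (k in seq_len(cfg$K)) {
        a <- s
        u <- cpp_conv2d(a, params[[sprintf("k%d.w3", k)]],
                        params[[sprintf("k%d.b3", k)]], cfg$rates[k])
        bk <- cpp_conv2d(u, params[[sprintf("k%d.w1", k)]],
                         params[[sprintf("k%d.b1", k)]], 1L)
        if (cache) { cc$a[[k]] <- a; cc$u[[k]] <- u }
        s <- s + bk
    }
    out <- if (cfg$reluOut) relu(s) else s
    if (cache) { cc$pre <- s; list(out = out, cache = cc) } else out
}

# reverse-mode gradients through one DDCM; gout matches the module output
ddcmBackward <- function(cache, gout, params, cfg) {
    if (cfg$reluOut) gout <- gout * (cache$pre > 0)
    g <- list()
    gs <- gout                       # gradient w.r.t. running sum s_k
    for (k in rev(seq_len(cfg$K))) {
        n1 <- sprintf("k%d.w1", k); n3 <- sprintf("k%d.w3", k)
        bk1 <- cpp_conv2d_backward(cache$u[[k]], params[[n1]], gs, 1L)
        bk3 <- cpp_conv2d_backward(cache$a[[k]], params[[n3]], bk1$gx,
                                   cfg$rates[k])
        g[[n1]] <- bk1$gw; g[[sprintf("k%d.b1", k)]] <- bk1$gb
        g[[n3]] <- bk3$gw; g[[sprintf("k%d.b3", k)]] <- bk3$gb
        gs <- gs + bk3$gx            # s_{k-1} feeds both branch k and s_k
    }
    list(gx = gs, grads = g)
}

#' Theoretical receptive field of a DDCM
#'
#' The deepest cascade path chains all `K` 3x3 convolutions with rates
#' `2^(k-1)`; each adds `2 * rate` pixels of reach, giving
#' `1 + 2 * (2^K - 1)`. The 1x1 convolutions contribute nothing.
#'
#' @param cfg a [ddcmConfig()].
#' @return integer receptive-field width in pixels.
#' @examples
#' receptiveField(ddcmConfig(K = 5)) # 63
#' @export
receptiveField <- function(cfg) {
    1L + 2L * (2L^cfg$K - 1L)
}
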