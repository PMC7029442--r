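#' Dilated 2-D convolution
#'
#' Computes `out(i, j, o) = sum_{p, q, c} x[i + r (p - p0), j + r (q - q0), c]
#' * w[p, q, c, o] + b[o]` with zero padding `r (k - 1) / 2` per side, so the
#' output keeps the input's spatial size. The dilation rate `r` is the
#' sampling stride inside the kernel: it enlarges the receptive field without
#' adding parameters, and `rate = 1` reduces to standard convolution.
#'
#' @param x numeric array `H x W x Cin` (a matrix is treated as one channel).
#' @param w kernel array `kh x kw x Cin x Cout`.
#' @param b bias vector of length `Cout` (default zeros).
#' @param rate integer dilation rate `>= 1`.
#' @return numeric array `H x W x Cout`.
#' @examples
#' x <- array(rnorm(8 * 8), c(8, 8, 1))
#' w <- array(rnorm(9), c(3, 3, 1, 1))
#' y <- dilatedConv2d(x, w, rate = 2)
#' dim(y)
#' @export
dilatedConv2d <- function(x, w, b = NULL, rate = 1L) {
    x <- asFeatureMap(x)
    if (!is.array(w) || length(dim(w)) != 4L)
        stop("'w' must be a 4-d array (kh, kw, Cin, Cout)")
    rate <- as.integer(rate)
    if (is.na(rate) || rate < 1L) stop("'rate' must be an integer >= 1")
    if (is.null(b)) b <- numeric(dim(w)[4])
    cpp_conv2d(x, w, as.numeric(b), rate)
}

#' Bilinear resampling of feature maps
#'
#' Resamples to a target spatial size (or by an integer factor) with bilinear
#' interpolation at half-pixel centres (no corner alignment), the convention
#' under which constant maps stay constant. Side predictions emitted at a
#' block's native stride are brought back to input resolution with this
#' operation; `factor = 1` is the identity.
#'
#' @param x matrix or `H x W x C` array.
#' @param factor integer upscaling factor (used when `size` is `NULL`).
#' @param size integer `c(rows, cols)` target size.
#' @return resampled map with the same number of channels as `x`.
#' @export
upsampleBilinear <- function(x, factor = NULL, size = NULL) {
    wasMat <- is.matrix(x)
    x <- asFeatureMap(x)
    if (is.null(size)) {
        if (is.null(factor)) stop("give either 'factor' or 'size'")
        size <- dim(x)[1:2] * as.integer(factor)
    }
    y <- cpp_upsample_bilinear(x, as.integer(size[1]), as.integer(size[2]))
    if (wasMat) y[, , 1] else y
}

# coerce matrix -> single-channel array; validate finiteness lazily
asFeatureMap <- function(x) {
    if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
    if (!is.array(x) || length(dim(x)) != 3L)
        stop("feature maps must be matrices or H x W x C arrays")
    storage.mode(x) <- "double"
    x
}

relu <- function(x) {
    x[x < 0] <- 0
    x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# 2x2 max pooling, stride 2 (floor mode); returns y and argmax indices
maxPool2 <- function(x) cpp_maxpool2(asFeatureMap(x))
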