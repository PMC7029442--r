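#' Synthetic fundus scene with per-pixel vessel width annotation
#'
#' A generated test scene standing in for a fundus photograph: an RGB image,
#' the binary vessel label, a width map giving the nominal stroke width (in
#' pixels) of every vessel pixel, and a field-of-view mask. The width map is
#' what makes diameter-specific supervision testable: the ground truth can be
#' decomposed exactly into per-diameter contour maps with
#' [widthPartition()].
#'
#' @slot image numeric array `rows x cols x 3`, values in `[0, 1]`.
#' @slot label numeric matrix `rows x cols` with values in `{0, 1}`.
#' @slot widthMap numeric matrix, `> 0` exactly where `label == 1`.
#' @slot fovMask numeric matrix with values in `{0, 1}`.
#'
#' @seealso [generateScene()], [widthPartition()], [saveScene()]
#' @export
setClass("SyntheticScene",
    representation(image = "array", label = "matrix",
                   widthMap = "matrix", fovMask = "matrix"))

setValidity("SyntheticScene", function(object) {
    d <- dim(object@image)
    msg <- character()
    if (length(d) != 3L || d[3] != 3L)
        msg <- c(msg, "image must be a rows x cols x 3 array")
    if (!identical(dim(object@label), d[1:2]))
        msg <- c(msg, "label dimensions must match image")
    if (!identical(dim(object@widthMap), d[1:2]))
        msg <- c(msg, "widthMap dimensions must match image")
    if (!identical(dim(object@fovMask), d[1:2]))
        msg <- c(msg, "fovMask dimensions must match image")
    if (!all(object@label %in% c(0, 1)))
        msg <- c(msg, "label must be binary")
    if (!identical(unname(object@widthMap > 0), unname(object@label == 1)))
        msg <- c(msg, "widthMap must be positive exactly on vessel pixels")
    if (length(msg)) msg else TRUE
})

#' The eleven output maps of a cascade forward pass
#'
#' Five side predictions per cascade direction (low-to-high and high-to-low,
#' one pair per scale detection block) plus the fused final map, all resampled
#' to the input resolution and passed through a sigmoid.
#'
#' @slot sideL2H list of 5 probability matrices (low-to-high direction).
#' @slot sideH2L list of 5 probability matrices (high-to-low direction).
#' @slot fused probability matrix from the 1x1 fusion convolution.
#'
#' @seealso [forwardPass()], [sideMaps()], [fusedMap()]
#' @export
setClass("CascadeOutput",
    representation(sideL2H = "list", sideH2L = "list", fused = "matrix"))

setValidity("CascadeOutput", function(object) {
    d <- dim(object@fused)
    ok <- vapply(c(object@sideL2H, object@sideH2L),
                 function(m) identical(dim(m), d), logical(1))
    if (length(object@sideL2H) != length(object@sideH2L))
        return("sideL2H and sideH2L must have the same number of stages")
    if (!all(ok)) return("all side maps must match the fused map's dimensions")
    TRUE
})

#' A cascade segmentation model
#'
#' Holds the resolved network configuration and a flat named list of weight
#' arrays. Build with [buildModel()], run with [forwardPass()], fit with
#' [trainModel()].
#'
#' @slot config list, the resolved [networkConfig()].
#' @slot params named list of numeric arrays (kernels and biases).
#'
#' @export
setClass("CascadeModel", representation(config = "list", params = "list"))

#' Complementary supervision targets for one scale stage
#'
#' The two diameter-specific targets of stage `d`: the low-to-high target is
#' the ground truth minus the (frozen) predictions of shallower stages, the
#' high-to-low target the ground truth minus deeper stages' predictions, both
#' clamped to `[0, 1]`.
#'
#' @slot yL2H numeric matrix in `[0, 1]`.
#' @slot yH2L numeric matrix in `[0, 1]`.
#' @slot scale integer stage index in `1..D`.
#'
#' @seealso [buildTargets()]
#' @export
setClass("SupervisionPair",
    representation(yL2H = "matrix", yH2L = "matrix", scale = "integer"))

setValidity("SupervisionPair", function(object) {
    msg <- character()
    if (!identical(dim(object@yL2H), dim(object@yH2L)))
        msg <- c(msg, "targets must share dimensions")
    rng <- range(object@yL2H, object@yH2L)
    if (rng[1] < 0 || rng[2] > 1)
        msg <- c(msg, "targets must lie in [0, 1]")
    if (length(object@scale) != 1L || object@scale < 1L)
        msg <- c(msg, "scale must be a positive integer")
    if (length(msg)) msg else TRUE
})

#' Pixel-level confusion counts
#'
#' @slot tp,fp,tn,fn non-negative pixel counts.
#' @seealso [confusionCounts()], [metricsFromCounts()]
#' @export
setClass("ConfusionCounts",
    representation(tp = "numeric", fp = "numeric",
                   tn = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (length(v) != 4L || any(v < 0) || any(v != round(v)))
        "counts must be single non-negative integers" else TRUE
})

setMethod("show", "SyntheticScene", function(object) {
    d <- dim(object@label)
    cat(sprintf("SyntheticScene %d x %d: %d vessel px (%.1f%%), widths [%s]\n",
                d[1], d[2], sum(object@label),
                100 * mean(object@label),
                if (any(object@label > 0))
                    paste(signif(range(object@widthMap[object@label == 1]), 3),
                          collapse = ", ") else "-"))
})

setMethod("show", "CascadeOutput", function(object) {
    d <- dim(object@fused)
    cat(sprintf("CascadeOutput: %d stages x 2 directions + fused, %d x %d\n",
                length(object@sideL2H), d[1], d[2]))
})

setMethod("show", "CascadeModel", function(object) {
    cfg <- object@config
    cat(sprintf(paste0("CascadeModel: %d scale detection blocks, ",
                       "DDCM K = %d, width multiplier %g, %s parameters\n"),
                cfg$D, cfg$ddcm$K, cfg$widthMultiplier,
                format(nParams(object), big.mark = ",")))
})

setMethod("show", "SupervisionPair", function(object) {
    cat(sprintf("SupervisionPair (stage %d), %d x %d\n", object@scale,
                nrow(object@yL2H), ncol(object@yL2H)))
})

setMethod("show", "ConfusionCounts", function(object) {
    cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d\n",
                object@tp, object@fp, object@tn, object@fn))
})
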