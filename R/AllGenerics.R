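#' Accessors for scenes, outputs and models
#'
#' Small accessor generics: `sceneImage`, `sceneLabel`, `widthMap` and
#' `fovMask` read the slots of a [SyntheticScene-class]; `sideMaps` and
#' `fusedMap` read a [CascadeOutput-class]; `modelConfig` and `nParams` read
#' a [CascadeModel-class].
#'
#' @param x the object.
#' @param direction `"l2h"` or `"h2l"` for `sideMaps`.
#' @return the slot contents; `nParams` the total parameter count.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname accessors
#' @export
setGeneric("sceneLabel", function(x) standardGeneric("sceneLabel"))
#' @rdname accessors
#' @export
setGeneric("widthMap", function(x) standardGeneric("widthMap"))
#' @rdname accessors
#' @export
setGeneric("fovMask", function(x) standardGeneric("fovMask"))
#' @rdname accessors
#' @export
setGeneric("sideMaps", function(x, direction = c("l2h", "h2l"))
    standardGeneric("sideMaps"))
#' @rdname accessors
#' @export
setGeneric("fusedMap", function(x) standardGeneric("fusedMap"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' @rdname accessors
setMethod("sceneImage", "SyntheticScene", function(x) x@image)
#' @rdname accessors
setMethod("sceneLabel", "SyntheticScene", function(x) x@label)
#' @rdname accessors
setMethod("widthMap", "SyntheticScene", function(x) x@widthMap)
#' @rdname accessors
setMethod("fovMask", "SyntheticScene", function(x) x@fovMask)

#' @rdname accessors
setMethod("sideMaps", "CascadeOutput", function(x, direction = c("l2h", "h2l")) {
    direction <- match.arg(direction)
    if (direction == "l2h") x@sideL2H else x@sideH2L
})
#' @rdname accessors
setMethod("fusedMap", "CascadeOutput", function(x) x@fused)

#' @rdname accessors
setMethod("modelConfig", "CascadeModel", function(x) x@config)
#' @rdname accessors
setMethod("nParams", "CascadeModel", function(x)
    sum(rapply(x@params, length, how = "unlist")))
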