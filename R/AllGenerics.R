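#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @export
setGeneric("otuIDs", function(x) standardGeneric("otuIDs"))

#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' @export
setGeneric("emsStats", function(x) standardGeneric("emsStats"))

#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @export
setGeneric("sampleMetadata", function(x) standardGeneric("sampleMetadata"))

#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))

#' @export
setGeneric("fstMatrix", function(x) standardGeneric("fstMatrix"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
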