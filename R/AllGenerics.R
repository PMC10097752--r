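# Generics, accessors and show methods.

#' @rdname ModelBundle-class
#' @param object,x an object.
#' @export
setGeneric("findingNames", function(x) standardGeneric("findingNames"))
#' @rdname ModelBundle-class
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))
#' @rdname ModelBundle-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname CARMatrix-class
#' @param x an object.
#' @export
setGeneric("carValues", function(x) standardGeneric("carValues"))
#' @rdname CARMatrix-class
#' @export
setGeneric("epsilonUsed", function(x) standardGeneric("epsilonUsed"))
#' @rdname LatentFeatures-class
#' @param x an object.
#' @param finding optional finding name to extract a single element.
#' @export
setGeneric("pooledFeatures", function(x, finding = NULL)
  standardGeneric("pooledFeatures"))
#' @rdname LatentFeatures-class
#' @export
setGeneric("featureMaps", function(x, finding = NULL)
  standardGeneric("featureMaps"))
#' @rdname AnnotationPanel-class
#' @param x an object.
#' @export
setGeneric("panelMarks", function(x) standardGeneric("panelMarks"))
#' @rdname AnnotationPanel-class
#' @export
setGeneric("panelLabels", function(x) standardGeneric("panelLabels"))
#' @rdname AnnotationPanel-class
#' @export
setGeneric("readerIds", function(x) standardGeneric("readerIds"))
#' @rdname AnnotationPanel-class
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))
#' @rdname ContingencyTable-class
#' @param x an object.
#' @export
setGeneric("tableCounts", function(x) standardGeneric("tableCounts"))

#' @rdname ModelBundle-class
#' @export
setMethod("findingNames", "ModelBundle", function(x) names(x@findingHeads))
#' @rdname ModelBundle-class
#' @export
setMethod("diseaseNames", "ModelBundle", function(x) names(x@diseaseHeads))
#' @rdname ModelBundle-class
#' @export
setMethod("nChannels", "ModelBundle", function(x) x@channels)
#' @rdname GeneratorSpec-class
#' @param x a \code{GeneratorSpec}.
#' @export
setMethod("findingNames", "GeneratorSpec", function(x) x@findings)
#' @rdname GeneratorSpec-class
#' @export
setMethod("diseaseNames", "GeneratorSpec", function(x) colnames(x@beta))
#' @rdname CARMatrix-class
#' @export
setMethod("carValues", "CARMatrix", function(x) x@values)
#' @rdname CARMatrix-class
#' @export
setMethod("epsilonUsed", "CARMatrix", function(x) x@epsilon)
#' @rdname CARMatrix-class
#' @export
setMethod("findingNames", "CARMatrix", function(x) rownames(x@values))
#' @rdname CARMatrix-class
#' @export
setMethod("diseaseNames", "CARMatrix", function(x) colnames(x@values))
#' @rdname LatentFeatures-class
#' @export
setMethod("pooledFeatures", "LatentFeatures", function(x, finding = NULL) {
  if (is.null(finding)) x@pooled else x@pooled[[finding]]
})
#' @rdname LatentFeatures-class
#' @export
setMethod("featureMaps", "LatentFeatures", function(x, finding = NULL) {
  if (is.null(finding)) x@maps else x@maps[[finding]]
})
#' @rdname AnnotationPanel-class
#' @export
setMethod("panelMarks", "AnnotationPanel", function(x) x@marks)
#' @rdname AnnotationPanel-class
#' @export
setMethod("panelLabels", "AnnotationPanel", function(x) x@labels)
#' @rdname AnnotationPanel-class
#' @export
setMethod("readerIds", "AnnotationPanel",
          function(x) unique(as.character(x@marks$reader_id)))
#' @rdname AnnotationPanel-class
#' @export
setMethod("imageIds", "AnnotationPanel",
          function(x) unique(as.character(x@marks$image_id)))
#' @rdname ContingencyTable-class
#' @export
setMethod("tableCounts", "ContingencyTable", function(x) x@counts)

setMethod("show", "FindingHead", function(object) {
  cat(sprintf("FindingHead '%s': C=%d, |w|=%.4g, b=%.4g\n", object@name,
              length(object@weight), .vnorm(object@weight), object@bias))
})
setMethod("show", "DiseaseHead", function(object) {
  cat(sprintf("DiseaseHead '%s': %d finding blocks x C=%d, c=%.4g\n",
              object@name, length(object@blocks),
              length(object@blocks[[1]]), object@intercept))
})
setMethod("show", "ModelBundle", function(object) {
  cat(sprintf("ModelBundle: %d findings x %d diseases, C=%d (%s weights)\n",
              length(object@findingHeads), length(object@diseaseHeads),
              object@channels,
              if (object@normalized) "unit-norm" else "raw"))
  cat("  findings:", paste(names(object@findingHeads), collapse = ", "), "\n")
  cat("  diseases:", paste(names(object@diseaseHeads), collapse = ", "), "\n")
})
setMethod("show", "CARMatrix", function(object) {
  cat(sprintf("CARMatrix (%d findings x %d diseases), epsilon = %.4g\n",
              nrow(object@values), ncol(object@values), object@epsilon))
  print(signif(object@values, 4))
})
setMethod("show", "AnnotationPanel", function(object) {
  cat(sprintf("AnnotationPanel: %d readings, %d images, %d readers, %d labels\n",
              nrow(object@marks), length(imageIds(object)),
              length(readerIds(object)), length(object@labels)))
})
setMethod("show", "OperatingPoint", function(object) {
  cat(sprintf(
    "OperatingPoint: threshold %.4g (sens %.3f, spec %.3f, hmean %.3f)\n",
    object@threshold, object@sensitivity, object@specificity,
    object@harmonicMean))
})
setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf(
    "GeneratorSpec: n=%d, %dpx, F=%d findings, D=%d diseases, C=%d, noise=%.3g, seed=%d\n",
    object@nImages, object@imageSize, length(object@findings),
    ncol(object@beta), object@channels, object@noise, object@seed))
})
setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable '%s' x '%s' (pooled readings)\n",
              object@finding, object@disease))
  print(object@counts)
})
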