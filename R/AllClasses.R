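#' @import methods
NULL

#' FindingHead: linear classifier for one abnormal finding
#'
#' A finding head scores one abnormal finding (e.g. hemorrhage, drusen) from
#' the global-average-pooled features of that finding's branch: the score is
#' \eqn{\sigma(w^T \bar z + b)}.  The weight direction \eqn{w/\|w\|} is the
#' axis along which counterfactual feature edits are made.
#'
#' @slot name finding identifier.
#' @slot weight numeric weight vector of length C (channel count).
#' @slot bias numeric scalar intercept.
#' @exportClass FindingHead
setClass("FindingHead",
  representation(name = "character", weight = "numeric", bias = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (length(object@bias) != 1L || !is.finite(object@bias))
      msg <- c(msg, "bias must be a finite scalar")
    if (length(object@weight) < 1L || any(!is.finite(object@weight)))
      msg <- c(msg, "weight must be a non-empty finite numeric vector")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname FindingHead-class
#' @param name finding identifier.
#' @param weight numeric weight vector.
#' @param bias numeric intercept.
#' @return a \code{FindingHead}.
#' @export
findingHead <- function(name, weight, bias = 0) {
  new("FindingHead", name = as.character(name),
      weight = as.numeric(weight), bias = as.numeric(bias))
}

#' DiseaseHead: linear classifier for one disease over all finding features
#'
#' A disease head maps the concatenation of all pooled finding features to a
#' diagnosis probability \eqn{\sigma(\sum_f v_{d,f}^T \bar z_f + c_d)}.  The
#' per-finding blocks \eqn{v_{d,f}} carry the finding-disease couplings that
#' the counterfactual attribution ratio reads out.
#'
#' @slot name disease identifier.
#' @slot blocks named list with exactly one length-C numeric vector per
#'   configured finding, in finding order.
#' @slot intercept numeric scalar \eqn{c_d}.
#' @exportClass DiseaseHead
setClass("DiseaseHead",
  representation(name = "character", blocks = "list", intercept = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
      msg <- c(msg, "intercept must be a finite scalar")
    if (length(object@blocks) < 1L) msg <- c(msg, "at least one block required")
    if (is.null(names(object@blocks)) || any(!nzchar(names(object@blocks))))
      msg <- c(msg, "blocks must be named by finding")
    len <- unique(lengths(object@blocks))
    if (length(len) > 1L) msg <- c(msg, "all blocks must share one length")
    if (!all(vapply(object@blocks, function(b) is.numeric(b) && all(is.finite(b)),
                    logical(1))))
      msg <- c(msg, "blocks must be finite numeric vectors")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname DiseaseHead-class
#' @param name disease identifier.
#' @param blocks named list of per-finding weight vectors.
#' @param intercept numeric intercept.
#' @return a \code{DiseaseHead}.
#' @export
diseaseHead <- function(name, blocks, intercept = 0) {
  new("DiseaseHead", name = as.character(name),
      blocks = lapply(blocks, as.numeric), intercept = as.numeric(intercept))
}

#' EncoderSpec: geometry of the toy convolutional encoder
#'
#' Describes the fixed, seeded encoder used at desk scale: a stack of
#' \code{sharedDepth} shared stages (2x2 mean pooling followed by a 1x1
#' channel-mixing convolution and ReLU) and \code{branchDepth} per-finding
#' channel-mixing stages.  The encoder is frozen; only linear heads train.
#'
#' @slot inputSize pixels per side of the (square) input image.
#' @slot sharedDepth number of shared stages before branching.
#' @slot branchDepth per-finding stage count after branching.
#' @slot channels feature channel count C.
#' @exportClass EncoderSpec
setClass("EncoderSpec",
  representation(inputSize = "integer", sharedDepth = "integer",
                 branchDepth = "integer", channels = "integer"),
  validity = function(object) {
    v <- c(object@inputSize, object@sharedDepth, object@branchDepth,
           object@channels)
    if (any(is.na(v)) || any(v < 1L)) "all fields must be positive integers"
    else if (object@inputSize %% 2L^object@sharedDepth != 0L)
      "inputSize must be divisible by 2^sharedDepth"
    else TRUE
  })

#' @rdname EncoderSpec-class
#' @param inputSize,sharedDepth,branchDepth,channels positive integers.
#' @return an \code{EncoderSpec}.
#' @export
encoderSpec <- function(inputSize = 64L, sharedDepth = 3L, branchDepth = 1L,
                        channels = 8L) {
  new("EncoderSpec", inputSize = as.integer(inputSize),
      sharedDepth = as.integer(sharedDepth),
      branchDepth = as.integer(branchDepth), channels = as.integer(channels))
}

#' ModelBundle: the full two-stage model
#'
#' Bundles F finding heads and D disease heads (plus, optionally, an
#' encoder).  By default finding-head weights are rescaled to unit norm at
#' construction (bias kept), the convention under which the closed-form
#' attribution identities hold with coupling \eqn{v_{d,f}^T \hat w_f}; set
#' \code{normalize = FALSE} to keep raw weights, in which case the engine
#' divides the coupling by \eqn{\|w_f\|} internally so the odds-ratio
#' identities still hold exactly.
#'
#' @slot findingHeads named list of \code{FindingHead}.
#' @slot diseaseHeads named list of \code{DiseaseHead}.
#' @slot channels integer channel count C.
#' @slot normalized logical; were finding weights rescaled to unit norm.
#' @slot encoder an encoder object from \code{\link{buildEncoder}} or NULL.
#' @exportClass ModelBundle
setClass("ModelBundle",
  representation(findingHeads = "list", diseaseHeads = "list",
                 channels = "integer", normalized = "logical",
                 encoder = "ANY"),
  validity = function(object) {
    msg <- NULL
    fn <- names(object@findingHeads)
    if (length(fn) == 0L) msg <- c(msg, "at least one finding head required")
    for (fh in object@findingHeads)
      if (length(fh@weight) != object@channels)
        msg <- c(msg, sprintf("finding '%s': weight length != channels", fh@name))
    for (dh in object@diseaseHeads) {
      if (!identical(names(dh@blocks), fn))
        msg <- c(msg, sprintf(
          "disease '%s': blocks must match finding names in order", dh@name))
      if (any(lengths(dh@blocks) != object@channels))
        msg <- c(msg, sprintf("disease '%s': block length != channels", dh@name))
    }
    if (is.null(msg)) TRUE else msg
  })

#' @rdname ModelBundle-class
#' @param findingHeads list of \code{FindingHead} (named or self-naming).
#' @param diseaseHeads list of \code{DiseaseHead}.
#' @param normalize rescale finding weights to unit norm (default TRUE).
#' @param encoder optional encoder object.
#' @return a \code{ModelBundle}.
#' @export
modelBundle <- function(findingHeads, diseaseHeads, normalize = TRUE,
                        encoder = NULL) {
  names(findingHeads) <- vapply(findingHeads, function(h) h@name, character(1))
  names(diseaseHeads) <- vapply(diseaseHeads, function(h) h@name, character(1))
  if (normalize)
    findingHeads <- lapply(findingHeads, normalizeFindingHead)
  new("ModelBundle", findingHeads = findingHeads, diseaseHeads = diseaseHeads,
      channels = length(findingHeads[[1]]@weight), normalized = normalize,
      encoder = encoder)
}

#' Rescale a finding head to unit weight norm
#'
#' Divides the weight vector by its Euclidean norm, keeping the bias.  The
#' finding score changes by a logit rescaling only (rank order preserved);
#' under unit norm the projection coefficient onto the weight direction is
#' exactly \eqn{\sigma^{-1}(\hat y_f) - b_f}.
#'
#' @param head a \code{FindingHead}.
#' @return a unit-norm \code{FindingHead}.
#' @export
normalizeFindingHead <- function(head) {
  nrm <- .vnorm(head@weight)
  if (nrm == 0)
    stop("degenerate finding head '", head@name, "': zero-norm weight",
         call. = FALSE)
  findingHead(head@name, head@weight / nrm, head@bias)
}

#' LatentFeatures: per-finding feature maps and their pooled vectors
#'
#' Holds, for one image, the spatial feature map \eqn{g_f(x)} of every
#' finding branch (a C x H' x W' array) and/or its global-average-pooled
#' vector \eqn{\bar z_f}.  When maps are present the pooled vectors must be
#' their per-channel spatial means.
#'
#' @slot maps named list of C x H' x W' arrays (may be empty).
#' @slot pooled named list of length-C numeric vectors.
#' @exportClass LatentFeatures
setClass("LatentFeatures",
  representation(maps = "list", pooled = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@pooled) == 0L) msg <- c(msg, "pooled must be non-empty")
    for (f in names(object@maps)) {
      if (!f %in% names(object@pooled)) {
        msg <- c(msg, sprintf("map '%s' has no pooled vector", f)); next
      }
      gap <- poolFeatures(object@maps[[f]])
      if (max(abs(gap - object@pooled[[f]])) > 1e-6)
        msg <- c(msg, sprintf(
          "pooled['%s'] is not the spatial mean of its map", f))
    }
    if (is.null(msg)) TRUE else msg
  })

#' @rdname LatentFeatures-class
#' @param maps named list of C x H' x W' arrays, or NULL.
#' @param pooled named list of length-C vectors; computed from \code{maps}
#'   when omitted.
#' @return a \code{LatentFeatures}.
#' @export
latentFeatures <- function(maps = NULL, pooled = NULL) {
  if (is.null(pooled)) {
    if (is.null(maps)) stop("supply maps or pooled", call. = FALSE)
    pooled <- lapply(maps, poolFeatures)
  }
  new("LatentFeatures", maps = if (is.null(maps)) list() else maps,
      pooled = lapply(pooled, as.numeric))
}

#' Decomposition of a pooled feature vector about a finding head
#'
#' Splits \eqn{\bar z_f} into a component along the unit weight direction
#' \eqn{\hat w_f} and an orthogonal remainder:
#' \eqn{\bar z_f = p\,\hat w_f + \bar z_{f,\perp}}.  Under a unit-norm head,
#' \eqn{p = \sigma^{-1}(\hat y_f) - b_f}.
#'
#' @slot parallelCoeff scalar projection coefficient p.
#' @slot direction unit vector \eqn{\hat w_f}.
#' @slot orthogonal the orthogonal remainder.
#' @slot finding finding name.
#' @exportClass Decomposition
setClass("Decomposition",
  representation(parallelCoeff = "numeric", direction = "numeric",
                 orthogonal = "numeric", finding = "character"))

#' EpsilonPolicy: how the counterfactual confidence level is chosen
#'
#' \eqn{\epsilon \in (0, 1/100)} is the probability assigned to a finding in
#' the "confidently absent" counterfactual arm.  \code{fixed} mode uses
#' \code{value} directly; \code{benign_percentile} mode takes the
#' nearest-rank percentile (default 5) of finding predictions on benign
#' validation images, clipped into the permitted interval.
#'
#' @slot mode "fixed" or "benign_percentile".
#' @slot value fixed epsilon, strictly inside (0, 1/100).
#' @slot percentile percentile used in benign_percentile mode.
#' @exportClass EpsilonPolicy
setClass("EpsilonPolicy",
  representation(mode = "character", value = "numeric", percentile = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@mode %in% c("fixed", "benign_percentile"))
      msg <- c(msg, "mode must be 'fixed' or 'benign_percentile'")
    if (object@value <= 0 || object@value >= 0.01)
      msg <- c(msg, "value must lie strictly inside (0, 1/100)")
    if (object@percentile <= 0 || object@percentile >= 100)
      msg <- c(msg, "percentile must lie in (0, 100)")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname EpsilonPolicy-class
#' @param mode "fixed" or "benign_percentile".
#' @param value epsilon used in fixed mode (default 0.005, the midpoint of
#'   the permitted interval).
#' @param percentile percentile for benign_percentile mode (default 5).
#' @return an \code{EpsilonPolicy}.
#' @export
epsilonPolicy <- function(mode = c("fixed", "benign_percentile"),
                          value = 0.005, percentile = 5) {
  new("EpsilonPolicy", mode = match.arg(mode), value = as.numeric(value),
      percentile = as.numeric(percentile))
}

#' CARMatrix: grid of counterfactual attribution ratios
#'
#' An F x D grid of instance-independent counterfactual attribution ratios
#' \eqn{R_{CAR}(f,d)}, with findings as rows and diseases as columns,
#' directly comparable to a pooled expert odds-ratio grid.
#'
#' @slot values numeric F x D matrix, all entries > 0.
#' @slot epsilon the confidence level used.
#' @exportClass CARMatrix
setClass("CARMatrix",
  representation(values = "matrix", epsilon = "numeric"),
  validity = function(object) {
    if (any(object@values <= 0)) "all entries must be positive"
    else if (object@epsilon <= 0 || object@epsilon >= 0.01)
      "epsilon must lie in (0, 1/100)"
    else TRUE
  })

#' AttributionMap: spatial attribution of a finding to a disease
#'
#' The class-activation map of finding f scaled by the finding-disease
#' coupling: \eqn{A(f,d;x) = (v_{d,f}^T \hat w_f)\,(w_f^T g_f(x))} as an
#' H' x W' map.  Its spatial mean equals
#' \eqn{(v_{d,f}^T \hat w_f)(\sigma^{-1}(\hat y_f) - b_f)}.
#'
#' @slot grid numeric H' x W' matrix.
#' @slot finding finding name.
#' @slot disease disease name.
#' @exportClass AttributionMap
setClass("AttributionMap",
  representation(grid = "matrix", finding = "character", disease = "character"))

#' AnnotationPanel: multi-reader binary annotations
#'
#' One row per (image, reader) reading; one binary column per label (finding
#' or disease).  Readers are assumed conditionally independent given the
#' truth, the assumption under which the fusion model is fit.
#'
#' @slot marks data.frame with columns \code{image_id}, \code{reader_id} and
#'   one 0/1 (or NA) column per label.
#' @slot labels character vector of label column names.
#' @exportClass AnnotationPanel
setClass("AnnotationPanel",
  representation(marks = "data.frame", labels = "character"),
  validity = function(object) {
    msg <- NULL
    need <- c("image_id", "reader_id")
    if (!all(need %in% names(object@marks)))
      msg <- c(msg, "marks needs image_id and reader_id columns")
    miss <- setdiff(object@labels, names(object@marks))
    if (length(miss))
      msg <- c(msg, paste("missing label columns:", paste(miss, collapse = ", ")))
    for (l in intersect(object@labels, names(object@marks))) {
      v <- object@marks[[l]]
      if (!all(v %in% c(0, 1, NA)))
        msg <- c(msg, sprintf("label '%s' must be binary (0/1/NA)", l))
    }
    if (is.null(msg)) TRUE else msg
  })

#' @rdname AnnotationPanel-class
#' @param marks data.frame of readings (see slots).
#' @param labels label column names; defaults to every column other than
#'   \code{image_id} and \code{reader_id}.
#' @return an \code{AnnotationPanel}.
#' @export
annotationPanel <- function(marks, labels = NULL) {
  if (is.null(labels))
    labels <- setdiff(names(marks), c("image_id", "reader_id"))
  new("AnnotationPanel", marks = as.data.frame(marks),
      labels = as.character(labels))
}

#' ContingencyTable: pooled 2x2 finding-disease counts
#'
#' Counts of (reader, image) readings in the four joint presence cells.  Row
#' 1 is finding present, row 2 absent; column 1 disease present, column 2
#' absent — so \code{counts[1,1]} is the (f=1, d=1) cell, matching the
#' presence-first indexing of the pooled expert matrix N (not 0-based array
#' indexing).
#'
#' @slot counts 2x2 non-negative integer matrix.
#' @slot finding,disease label names.
#' @exportClass ContingencyTable
setClass("ContingencyTable",
  representation(counts = "matrix", finding = "character",
                 disease = "character"),
  validity = function(object) {
    if (!all(dim(object@counts) == c(2L, 2L))) "counts must be 2x2"
    else if (any(object@counts < 0)) "counts must be non-negative"
    else TRUE
  })

#' OperatingPoint: a chosen decision threshold with its error profile
#'
#' @slot threshold decision threshold (predict positive when score >= it).
#' @slot sensitivity,specificity achieved rates at that threshold.
#' @slot harmonicMean \eqn{2\,se\,sp/(se+sp)}.
#' @exportClass OperatingPoint
setClass("OperatingPoint",
  representation(threshold = "numeric", sensitivity = "numeric",
                 specificity = "numeric", harmonicMean = "numeric"),
  validity = function(object) {
    s <- object@sensitivity + object@specificity
    if (s > 0 &&
        abs(object@harmonicMean -
            2 * object@sensitivity * object@specificity / s) > 1e-8)
      "harmonicMean inconsistent with sensitivity/specificity"
    else TRUE
  })

#' GeneratorSpec: the synthetic study conditions
#'
#' Fully describes the toy cohort: lesion-bearing images (one blob signature
#' per finding), Bernoulli finding prevalences, a logistic finding-to-disease
#' link with known coefficients, per-reader sensitivity/specificity profiles,
#' and the feature-noise level.  Every generator is a pure function of
#' (spec, seed).
#'
#' @slot nImages number of images / feature rows.
#' @slot imageSize pixels per side (>= 64 for image rendering).
#' @slot channels feature channel count C.
#' @slot findings finding names (length F).
#' @slot prevalence named numeric, Bernoulli prevalence per finding, in (0,1).
#' @slot signatures named list per finding: list(count, size, intensity
#'   (length-3 RGB delta), channel).
#' @slot effectSize feature-space displacement magnitude per present finding.
#' @slot noise Gaussian feature noise standard deviation.
#' @slot beta F x D matrix of logistic coefficients (findings x diseases).
#' @slot intercepts length-D logistic intercepts.
#' @slot readerSens,readerSpec per-reader sensitivity/specificity, in (0,1).
#' @slot seed integer seed; fixed seed gives bit-identical output.
#' @exportClass GeneratorSpec
setClass("GeneratorSpec",
  representation(nImages = "integer", imageSize = "integer",
                 channels = "integer", findings = "character",
                 prevalence = "numeric", signatures = "list",
                 effectSize = "numeric", noise = "numeric",
                 beta = "matrix", intercepts = "numeric",
                 readerSens = "numeric", readerSpec = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    F <- length(object@findings)
    if (any(object@prevalence <= 0 | object@prevalence >= 1))
      msg <- c(msg, "prevalences must lie in (0,1)")
    if (any(c(object@readerSens, object@readerSpec) <= 0) ||
        any(c(object@readerSens, object@readerSpec) >= 1))
      msg <- c(msg, "reader profiles must lie in (0,1)")
    if (nrow(object@beta) != F)
      msg <- c(msg, "beta must have one row per finding")
    if (length(object@intercepts) != ncol(object@beta))
      msg <- c(msg, "one intercept per disease required")
    if (object@noise < 0) msg <- c(msg, "noise must be >= 0")
    if (is.null(msg)) TRUE else msg
  })
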