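# Configuration, serialization, preprocessing and report assembly.

#' The fifteen default finding names
#' @return character vector of the abnormal retinal findings covered by the
#'   default configuration.
#' @export
defaultFindingNames <- function() c(
  "hemorrhage", "hard_exudate", "cotton_wool_patch", "drusen", "membrane",
  "macular_hole", "myelinated_nerve_fiber", "chorioretinal_atrophy",
  "vascular_abnormality", "rnfl_defect", "glaucomatous_disc_change",
  "non_glaucomatous_disc_change", "fluid_accumulation",
  "retinal_pigmentary_change", "choroidal_lesion")

#' The eight default disease names
#' @return character vector of the major eye diseases covered by the
#'   default configuration.
#' @export
defaultDiseaseNames <- function() c(
  "dry_AMD", "wet_AMD", "any_DR", "referable_DR", "CRVO",
  "BRVO_hemi_CRVO", "epiretinal_membrane", "glaucoma_suspect")

#' Read a run configuration
#'
#' YAML configuration declaring findings, diseases, the epsilon policy, the
#' operating-point policy, paths, the seed and the (declared-only) training
#' augmentation list.  Missing fields fall back to package defaults; names
#' must be unique and a seed must be present.
#'
#' @param path YAML file path, or NULL for the pure defaults.
#' @return list with components \code{findings}, \code{diseases},
#'   \code{epsilon} (an \code{\link{EpsilonPolicy}}), \code{operatingPoint}
#'   (policy string), \code{seed}, \code{augmentations}, \code{paths}.
#' @export
readRunConfig <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- list(
    findings = raw$findings %||% defaultFindingNames(),
    diseases = raw$diseases %||% defaultDiseaseNames(),
    epsilon = epsilonPolicy(mode = raw$epsilon$mode %||% "fixed",
                            value = raw$epsilon$value %||% 0.005,
                            percentile = raw$epsilon$percentile %||% 5),
    operatingPoint = raw$operating_point %||% "max_harmonic_mean",
    seed = raw$seed %||% 1L,
    augmentations = raw$augmentations %||% character(0),
    paths = raw$paths %||% list())
  if (anyDuplicated(cfg$findings) || anyDuplicated(cfg$diseases))
    stop("finding and disease names must be unique", call. = FALSE)
  if (is.null(cfg$seed)) stop("config must carry a seed", call. = FALSE)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop, square and resize a fundus image
#'
#' Crops rows and columns whose maximum intensity across channels stays
#' below \code{blackThreshold}, pads the remainder to a centered square
#' with black, and bilinearly resizes to \code{targetSize}.  Idempotent on
#' already-processed images.  Content centering is by the crop bounding
#' box (no fovea detector is involved).
#'
#' @param image numeric H x W x 3 array (or H x W matrix) in [0, 1].
#' @param targetSize output side length in pixels.
#' @param blackThreshold background threshold (default 10/255).
#' @return targetSize x targetSize x 3 array.
#' @export
preprocessImage <- function(image, targetSize = 64L,
                            blackThreshold = 10 / 255) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  stopifnot(length(dim(image)) == 3L)
  intens <- apply(image, c(1L, 2L), max)
  rows <- which(apply(intens, 1L, max) >= blackThreshold)
  cols <- which(apply(intens, 2L, max) >= blackThreshold)
  if (length(rows) == 0L || length(cols) == 0L)
    stop("fully black image: nothing to crop to", call. = FALSE)
  img <- image[min(rows):max(rows), min(cols):max(cols), , drop = FALSE]
  d <- dim(img)
  side <- max(d[1], d[2])
  sq <- array(0, c(side, side, 3L))
  r0 <- floor((side - d[1]) / 2); c0 <- floor((side - d[2]) / 2)
  sq[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- img
  out <- EBImage::resize(EBImage::Image(sq, colormode = "Color"),
                         w = targetSize, h = targetSize)
  unclass(EBImage::imageData(out))
}

.fmtNum <- function(x) sprintf("%.17g", x)

#' Serialize / restore a model bundle
#'
#' \code{saveModel} writes a documented JSON header (\code{model.json}:
#' names, F, D, C, normalization flag) plus one CSV weight matrix per head
#' (findings: one row per channel; diseases: one row per finding block).
#' \code{loadModel} restores the bundle; the JSON round-trips exactly and
#' the matrices within float64 resolution (17 significant digits).
#'
#' @param model a \code{\link{ModelBundle}}.
#' @param path directory to write to / read from.
#' @return \code{loadModel} returns a \code{\link{ModelBundle}};
#'   \code{saveModel} returns \code{path} invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ModelBundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(format = "fundusCAR-model", version = 1L,
                 findings = findingNames(model),
                 diseases = diseaseNames(model),
                 F = length(findingNames(model)),
                 D = length(diseaseNames(model)),
                 C = nChannels(model), normalized = model@normalized)
  jsonlite::write_json(header, file.path(path, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (f in findingNames(model)) {
    h <- model@findingHeads[[f]]
    utils::write.csv(
      data.frame(channel = seq_along(h@weight), weight = .fmtNum(h@weight),
                 bias = .fmtNum(rep(h@bias, length(h@weight)))),
      file.path(path, paste0("finding_", f, ".csv")), row.names = FALSE,
      quote = FALSE)
  }
  for (d in diseaseNames(model)) {
    h <- model@diseaseHeads[[d]]
    M <- do.call(rbind, h@blocks)
    df <- data.frame(finding = rownames(M),
                     apply(M, 2L, .fmtNum),
                     intercept = .fmtNum(rep(h@intercept, nrow(M))))
    names(df)[1 + seq_len(ncol(M))] <- paste0("c", seq_len(ncol(M)))
    utils::write.csv(df, file.path(path, paste0("disease_", d, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  hfile <- file.path(path, "model.json")
  if (!file.exists(hfile)) stop("no model.json under ", path, call. = FALSE)
  header <- tryCatch(jsonlite::read_json(hfile, simplifyVector = TRUE),
                     error = function(e)
                       stop("corrupted model header: ", conditionMessage(e),
                            call. = FALSE))
  need <- c("format", "findings", "diseases", "C")
  if (!all(need %in% names(header)) ||
      !identical(header$format, "fundusCAR-model"))
    stop("corrupted model header: missing or foreign format fields",
         call. = FALSE)
  C <- as.integer(header$C)
  fHeads <- lapply(header$findings, function(f) {
    fl <- file.path(path, paste0("finding_", f, ".csv"))
    if (!file.exists(fl)) stop("missing weights for finding '", f, "'",
                               call. = FALSE)
    df <- utils::read.csv(fl)
    findingHead(f, df$weight, df$bias[1])
  })
  dHeads <- lapply(header$diseases, function(d) {
    fl <- file.path(path, paste0("disease_", d, ".csv"))
    if (!file.exists(fl)) stop("missing weights for disease '", d, "'",
                               call. = FALSE)
    df <- utils::read.csv(fl)
    miss <- setdiff(header$findings, df$finding)
    if (length(miss))
      stop("disease '", d, "': missing block for finding '", miss[1], "'",
           call. = FALSE)
    blocks <- lapply(stats::setNames(header$findings, header$findings),
                     function(f) as.numeric(df[df$finding == f,
                                               paste0("c", seq_len(C))]))
    diseaseHead(d, blocks, df$intercept[1])
  })
  # weights are stored as-is; do not renormalize on load
  m <- modelBundle(fHeads, dHeads, normalize = FALSE)
  m@normalized <- isTRUE(header$normalized)
  validObject(m)
  m
}

#' Export a CAR matrix as CSV
#'
#' Finding rows, disease columns.
#'
#' @param car a \code{\link{CARMatrix}}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeCarCsv <- function(car, path) {
  stopifnot(is(car, "CARMatrix"))
  utils::write.csv(data.frame(finding = findingNames(car), carValues(car),
                              check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}

#' Assemble a per-image diagnostic report
#'
#' Deterministic JSON-serializable report for one image: disease
#' probabilities, the per-pair instance I-CAR grid, the top findings above
#' the display threshold for each disease, any interactive overrides (with
#' both original and adjusted probabilities), and provenance (epsilon,
#' seed, package version, optional model hash).
#'
#' @param latents a \code{\link{LatentFeatures}} for the image.
#' @param model a \code{\link{ModelBundle}}.
#' @param eps confidence level in (0, 1).
#' @param overrides optional named finding score overrides in (0, 1).
#' @param threshold display threshold for top findings (default e).
#' @param k maximum top findings per disease (default 3).
#' @param seed seed recorded in provenance.
#' @param modelPath optional saved-model directory; its header hash is
#'   recorded.
#' @return report list; write it with \code{\link{writeReport}}.
#' @export
buildReport <- function(latents, model, eps = 0.005, overrides = NULL,
                        threshold = exp(1), k = 3L, seed = NA_integer_,
                        modelPath = NULL) {
  pooled <- pooledFeatures(latents)
  findingProbs <- vapply(findingNames(model), function(f)
    findingScore(model@findingHeads[[f]], pooled[[f]]), numeric(1))
  diseaseProbs <- vapply(model@diseaseHeads, diseaseScore, numeric(1),
                         pooledAll = pooled)
  ic <- icarMatrix(latents, model, eps)
  top <- lapply(stats::setNames(diseaseNames(model), diseaseNames(model)),
                function(d) as.list(topFindings(ic[, d], threshold, k)))
  rep <- list(
    finding_probabilities = as.list(findingProbs),
    disease_probabilities = as.list(diseaseProbs),
    icar = lapply(stats::setNames(diseaseNames(model), diseaseNames(model)),
                  function(d) as.list(ic[, d])),
    top_findings = top,
    provenance = list(package = "fundusCAR",
                      version = as.character(utils::packageVersion("fundusCAR")),
                      epsilon = eps, seed = seed,
                      threshold = threshold,
                      model_hash = if (is.null(modelPath)) NA_character_
                                   else unname(tools::md5sum(
                                     file.path(modelPath, "model.json")))))
  if (!is.null(overrides)) {
    adj <- interactiveAdjust(latents, model, overrides)
    rep$overrides <- list(set = as.list(unlist(overrides)),
                          original = as.list(adj$original),
                          adjusted = as.list(adj$probabilities))
  }
  rep
}

#' @rdname buildReport
#' @param report a report list from \code{buildReport}.
#' @param path output JSON file.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
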