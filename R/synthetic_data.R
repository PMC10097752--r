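# Synthetic study generator: toy fundus-like images with per-finding blob
# signatures, latent feature cohorts from a known logistic finding->disease
# link, and multi-reader annotation panels with known reader profiles.

#' Default synthetic study conditions
#'
#' Three findings with distinct lesion signatures (dark-red hemorrhage
#' blobs, yellow hard-exudate dots, pale drusen deposits), two diseases
#' driven by a logistic link with strong coefficients (|beta| = 3) on their
#' true findings, C = 8 feature channels, 64 px images, Gaussian feature
#' noise 0.3, and a three-reader panel with sensitivities
#' (0.9, 0.8, 0.7) and specificities (0.95, 0.9, 0.85).
#'
#' @param nImages cohort size (default 2000).
#' @param imageSize pixels per side (>= 64 for rendering).
#' @param channels feature channel count C.
#' @param noise Gaussian feature noise sd.
#' @param seed integer seed.
#' @return a \code{\link{GeneratorSpec}}.
#' @export
toyGeneratorSpec <- function(nImages = 2000L, imageSize = 64L, channels = 8L,
                             noise = 0.3, seed = 1L) {
  findings <- c("hemorrhage", "hard_exudate", "drusen")
  beta <- matrix(c(3, 3, 0,
                   0, 0, 3), nrow = 3L,
                 dimnames = list(findings, c("any_DR", "dry_AMD")))
  new("GeneratorSpec",
      nImages = as.integer(nImages), imageSize = as.integer(imageSize),
      channels = as.integer(channels), findings = findings,
      prevalence = c(hemorrhage = 0.3, hard_exudate = 0.25, drusen = 0.2),
      signatures = list(
        # intensities are chosen to keep every color plane inside [0, 1]
        # on the shaded disc, so lesion colors mix linearly (no clipping
        # cross-talk between the unmixing channels)
        hemorrhage   = list(count = 6L, size = 2.5,
                            intensity = c(0.3, -0.15, -0.12)),
        hard_exudate = list(count = 5L, size = 2.0,
                            intensity = c(0.3, 0.3, -0.08)),
        drusen       = list(count = 4L, size = 3.0,
                            intensity = c(0.2, 0.2, 0.25))),
      effectSize = 2, noise = as.numeric(noise), beta = beta,
      intercepts = c(any_DR = -2.5, dry_AMD = -2),
      readerSens = c(0.9, 0.8, 0.7), readerSpec = c(0.95, 0.9, 0.85),
      seed = as.integer(seed))
}

#' Simulate a feature-level cohort
#'
#' Finding presence is Bernoulli(\eqn{\pi_f}); the pooled feature of
#' finding f is \code{presence * effectSize * u_f} plus isotropic Gaussian
#' noise, where \eqn{u_f} is a fixed seeded unit direction per finding; the
#' disease truth is Bernoulli of the logistic link
#' \eqn{\sigma(\sum_f \beta_{d,f}\,presence_f + \beta_{d,0})}.
#'
#' @param spec a \code{\link{GeneratorSpec}}.
#' @return list with \code{features} (named list of n x C matrices),
#'   \code{findingTruth} (n x F), \code{diseaseTruth} (n x D),
#'   \code{diseaseProb} (n x D link probabilities), \code{directions}
#'   (named list of unit vectors) and the \code{spec} echo.
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "GeneratorSpec"))
  set.seed(spec@seed)
  n <- spec@nImages; C <- spec@channels
  fn <- spec@findings; dn <- colnames(spec@beta)
  directions <- lapply(stats::setNames(fn, fn), function(f) {
    u <- stats::rnorm(C); u / .vnorm(u)
  })
  presence <- vapply(fn, function(f)
    stats::rbinom(n, 1L, spec@prevalence[[f]]), numeric(n))
  colnames(presence) <- fn
  features <- lapply(stats::setNames(fn, fn), function(f)
    outer(presence[, f] * spec@effectSize, directions[[f]]) +
      matrix(stats::rnorm(n * C, sd = spec@noise), n, C))
  eta <- presence %*% spec@beta +
    matrix(spec@intercepts, n, length(dn), byrow = TRUE)
  prob <- .sigmoid(eta)
  disease <- apply(prob, 2L, function(p) stats::rbinom(n, 1L, p))
  colnames(disease) <- dn
  list(features = features, findingTruth = presence, diseaseTruth = disease,
       diseaseProb = prob, directions = directions, spec = spec)
}

# deterministic per-image seed derived from the spec seed
.imageSeed <- function(seed, i) as.integer((seed + i * 7919) %% 2147483647)

.renderOne <- function(spec, i, presence = NULL) {
  S <- spec@imageSize
  set.seed(.imageSeed(spec@seed, i))
  R <- 0.45 * S
  for (sig in spec@signatures)
    if (sig$size >= R)
      stop("blob signature larger than the fundus disc", call. = FALSE)
  if (is.null(presence))
    presence <- vapply(spec@findings, function(f)
      stats::rbinom(1L, 1L, spec@prevalence[[f]]), numeric(1))
  else
    invisible(vapply(spec@findings, function(f)
      stats::rbinom(1L, 1L, spec@prevalence[[f]]), numeric(1)))
  cx <- (S + 1) / 2
  xg <- matrix(seq_len(S), S, S)
  yg <- t(xg)
  r2 <- (xg - cx)^2 + (yg - cx)^2
  disc <- r2 <= R^2
  shade <- (1 - 0.3 * r2 / R^2) * disc
  texture <- matrix(stats::rnorm(S * S, sd = 0.02), S, S) * disc
  baseCol <- c(0.55, 0.35, 0.2)
  img <- array(0, c(S, S, 3L))
  for (ch in 1:3) img[, , ch] <- baseCol[ch] * shade + texture
  for (f in spec@findings) {
    sig <- spec@signatures[[f]]
    # blob parameters are always drawn so that toggling presence does not
    # shift the RNG stream (absent finding => pixel-identical base image)
    rr <- R * 0.85 * sqrt(stats::runif(sig$count))
    th <- stats::runif(sig$count, 0, 2 * pi)
    sz <- sig$size * stats::runif(sig$count, 0.7, 1.3)
    if (presence[[f]] == 1) {
      bx <- cx + rr * cos(th); by <- cx + rr * sin(th)
      for (b in seq_len(sig$count)) {
        bump <- exp(-((xg - bx[b])^2 + (yg - by[b])^2) / (2 * sz[b]^2)) * disc
        for (ch in 1:3)
          img[, , ch] <- img[, , ch] + sig$intensity[ch] * bump
      }
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, presence = presence)
}

#' Render the toy fundus cohort
#'
#' Draws a circular fundus disc on black background; each present finding
#' adds its blob signature at random positions inside the disc.  Output is
#' a pure function of (spec, seed): the same seed yields bit-identical
#' images, and an image with a finding absent is pixel-identical to the
#' lesion-free base for that seed.
#'
#' @param spec a \code{\link{GeneratorSpec}} with \code{imageSize >= 64}.
#' @param presence optional n x F 0/1 matrix forcing finding presence
#'   (e.g. from \code{\link{simulateCohort}}); drawn from the prevalences
#'   when NULL.
#' @param outDir optional directory; when given, images are written as
#'   PNG files \code{img0001.png, ...} plus \code{truth.csv}.
#' @return list with \code{images} (list of H x W x 3 arrays),
#'   \code{truth} (data.frame image_id + per-finding presence) and the
#'   \code{spec} echo.
#' @export
renderToyImages <- function(spec, presence = NULL, outDir = NULL) {
  stopifnot(is(spec, "GeneratorSpec"))
  if (spec@imageSize < 64L) stop("imageSize must be >= 64", call. = FALSE)
  n <- spec@nImages
  images <- vector("list", n)
  pres <- matrix(NA_real_, n, length(spec@findings),
                 dimnames = list(NULL, spec@findings))
  for (i in seq_len(n)) {
    one <- .renderOne(spec, i,
                      presence = if (is.null(presence)) NULL
                                 else presence[i, spec@findings])
    images[[i]] <- one$image
    pres[i, ] <- as.numeric(one$presence[spec@findings])
  }
  truth <- data.frame(image_id = sprintf("img%04d", seq_len(n)), pres,
                      check.names = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      png::writePNG(images[[i]],
                    file.path(outDir, sprintf("img%04d.png", i)))
    utils::write.csv(truth, file.path(outDir, "truth.csv"),
                     row.names = FALSE)
  }
  list(images = images, truth = truth, spec = spec)
}

#' Simulate a multi-reader annotation panel
#'
#' Each reader marks each image independently: positive with probability
#' \code{sens[a]} when the truth is 1 and with probability
#' \code{1 - spec[a]} when it is 0 — exactly the conditional-independence
#' model assumed by the label-fusion posterior.
#'
#' @param truths n x L binary matrix of true labels (colnames are label
#'   names), or a vector for a single label.
#' @param sens,spec per-reader sensitivity/specificity vectors (equal
#'   length = number of readers), entries in (0, 1).
#' @param seed integer seed.
#' @param imageIds optional image identifiers (default img0001, ...).
#' @return an \code{\link{AnnotationPanel}} with one row per
#'   (image, reader).
#' @export
simulateReaderPanel <- function(truths, sens, spec, seed = 1L,
                                imageIds = NULL) {
  # perfect readers (sens = spec = 1) are a legitimate simulation limit
  .assertProb(sens, "sensitivity", open = FALSE)
  .assertProb(spec, "specificity", open = FALSE)
  stopifnot(length(sens) == length(spec))
  if (!is.matrix(truths)) truths <- matrix(truths, ncol = 1L,
                                           dimnames = list(NULL, "label"))
  n <- nrow(truths); A <- length(sens)
  if (is.null(imageIds)) imageIds <- sprintf("img%04d", seq_len(n))
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(A), function(a) {
    p <- ifelse(truths == 1, sens[a], 1 - spec[a])
    mk <- matrix(stats::rbinom(length(p), 1L, p), n, ncol(truths),
                 dimnames = list(NULL, colnames(truths)))
    data.frame(image_id = imageIds, reader_id = sprintf("reader%d", a), mk,
               check.names = FALSE)
  })
  annotationPanel(do.call(rbind, rows), labels = colnames(truths))
}

#' Agreement between model CAR signs and generator coefficients
#'
#' Compares the sign of \eqn{\log R_{CAR}(f,d)} from a trained model with
#' the sign of the generator coefficient \eqn{\beta_{d,f}}, over pairs
#' whose |beta| is at least \code{floor}.  Also reports whether every
#' zero-coefficient pair has smaller |log CAR| than every matched pair.
#'
#' @param spec the \code{\link{GeneratorSpec}} that produced the data.
#' @param model the trained \code{\link{ModelBundle}} (finding and disease
#'   names must match the spec's).
#' @param eps confidence level for the CAR (default 0.005).
#' @param floor minimum |beta| for a pair to count (default 1).
#' @return list with \code{agreement} (fraction in [0,1]), \code{nPairs},
#'   \code{logCAR}, \code{beta} and \code{nullBelowMatched} (logical).
#' @export
groundTruthCar <- function(spec, model, eps = 0.005, floor = 1) {
  stopifnot(is(spec, "GeneratorSpec"), is(model, "ModelBundle"))
  if (!setequal(findingNames(model), spec@findings) ||
      !setequal(diseaseNames(model), colnames(spec@beta)))
    stop("model and spec disagree on finding/disease names", call. = FALSE)
  lc <- log(carValues(carMatrix(model, eps)))
  lc <- lc[spec@findings, colnames(spec@beta), drop = FALSE]
  strong <- abs(spec@beta) >= floor
  agree <- sign(lc[strong]) == sign(spec@beta[strong])
  nullPairs <- spec@beta == 0
  nbm <- if (any(nullPairs) && any(strong))
    max(abs(lc[nullPairs])) < min(abs(lc[strong])) else NA
  list(agreement = mean(agree), nPairs = sum(strong), logCAR = lc,
       beta = spec@beta, nullBelowMatched = nbm)
}
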