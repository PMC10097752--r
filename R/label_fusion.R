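# Multi-reader label fusion: Naive Bayes posterior under a per-reader
# sensitivity/specificity model, EM parameter estimation (binary
# Dawid-Skene), severity recoding, and conservative reference standards.

#' Naive Bayes posterior from independent reader marks
#'
#' Posterior probability that the label is truly present given each
#' reader's binary mark, under conditional independence of readers:
#' \deqn{\Pr(Y=1\mid \hat y_{1..A}) \propto \Pr(Y=1)\prod_a
#'   se_a^{\hat y_a}(1-se_a)^{1-\hat y_a}}
#' and symmetrically with \eqn{1-sp_a, sp_a} for \eqn{Y=0}.
#'
#' @param marks binary vector (one mark per reader), or an n x A matrix for
#'   vectorized evaluation; NA marks are skipped (reader did not read).
#' @param sens,spec per-reader sensitivity and specificity, strictly inside
#'   (0, 1).
#' @param prior prevalence \eqn{\Pr(Y=1)}, strictly inside (0, 1).
#' @return posterior probability (vector of length n for matrix input).
#' @export
naiveBayesPosterior <- function(marks, sens, spec, prior) {
  .assertProb(sens, "sensitivity"); .assertProb(spec, "specificity")
  .assertProb(prior, "prior")
  if (!is.matrix(marks)) marks <- matrix(marks, nrow = 1L)
  if (ncol(marks) != length(sens) || length(sens) != length(spec))
    stop("one sensitivity/specificity per reader column required",
         call. = FALSE)
  l1 <- log(prior); l0 <- log1p(-prior)
  for (a in seq_len(ncol(marks))) {
    m <- marks[, a]
    ok <- !is.na(m)
    c1 <- ifelse(m == 1, log(sens[a]), log1p(-sens[a]))
    c0 <- ifelse(m == 1, log1p(-spec[a]), log(spec[a]))
    l1 <- l1 + ifelse(ok, c1, 0)
    l0 <- l0 + ifelse(ok, c0, 0)
  }
  drop(1 / (1 + exp(l0 - l1)))
}

# observed-data log-likelihood of a marks matrix under (sens, spec, prior)
.dsLoglik <- function(marks, sens, spec, prior) {
  l1 <- log(prior); l0 <- log1p(-prior)
  for (a in seq_len(ncol(marks))) {
    m <- marks[, a]; ok <- !is.na(m)
    l1 <- l1 + ifelse(ok & m == 1, log(sens[a]),
                      ifelse(ok, log1p(-sens[a]), 0))
    l0 <- l0 + ifelse(ok & m == 1, log1p(-spec[a]),
                      ifelse(ok, log(spec[a]), 0))
  }
  mx <- pmax(l1, l0)
  sum(mx + log(exp(l1 - mx) + exp(l0 - mx)))
}

#' Extract the per-image reader-marks matrix of one label
#'
#' Rows are images, columns readers; NA where a reader did not read an
#' image.
#'
#' @param panel an \code{\link{AnnotationPanel}}.
#' @param label label name.
#' @return numeric matrix with image ids as rownames, reader ids as
#'   colnames.
#' @export
marksMatrix <- function(panel, label) {
  stopifnot(is(panel, "AnnotationPanel"))
  if (!label %in% panelLabels(panel))
    stop("label '", label, "' not in panel", call. = FALSE)
  m <- panelMarks(panel)
  imgs <- unique(as.character(m$image_id))
  rds <- unique(as.character(m$reader_id))
  out <- matrix(NA_real_, length(imgs), length(rds),
                dimnames = list(imgs, rds))
  out[cbind(match(as.character(m$image_id), imgs),
            match(as.character(m$reader_id), rds))] <- m[[label]]
  out
}

#' EM estimation of reader profiles and prevalence (binary Dawid-Skene)
#'
#' Alternates an E-step (per-image posterior via
#' \code{\link{naiveBayesPosterior}}) and an M-step (posterior-weighted
#' sensitivity, specificity and prevalence estimates) until the largest
#' parameter change falls below \code{tol}.  Initialization is the
#' majority-vote pseudo-label (deterministic).  The observed-data
#' log-likelihood is non-decreasing across iterations and is returned for
#' inspection.  If EM lands in the label-switched mirror solution (average
#' reader sensitivity + specificity below 1) it is re-anchored by flipping
#' the latent class.
#'
#' @param panel an \code{\link{AnnotationPanel}} (or a plain marks matrix,
#'   images x readers).
#' @param label label name (ignored for matrix input).
#' @param tol convergence tolerance on the parameters (default 1e-6).
#' @param maxIter iteration cap; non-convergence warns and returns the last
#'   iterate.
#' @return list with \code{profiles} (data.frame reader/sensitivity/
#'   specificity), \code{prior}, \code{posteriors} (named per image),
#'   \code{loglik} (trajectory), \code{iterations}, \code{converged},
#'   \code{flipped}.
#' @export
emEstimate <- function(panel, label = NULL, tol = 1e-6, maxIter = 500L) {
  marks <- if (is(panel, "AnnotationPanel")) marksMatrix(panel, label)
           else as.matrix(panel)
  n <- nrow(marks)
  if (n < 50L)
    warning("fewer than 50 images; EM estimates will be unstable",
            call. = FALSE)
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  post <- rowMeans(marks, na.rm = TRUE)        # majority-vote initialization
  sens <- spec <- numeric(ncol(marks))
  prior <- NA_real_
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    # M-step
    priorNew <- clamp(mean(post))
    sensNew <- specNew <- numeric(ncol(marks))
    for (a in seq_len(ncol(marks))) {
      m <- marks[, a]; ok <- !is.na(m)
      sensNew[a] <- clamp(sum(post[ok] * m[ok]) / sum(post[ok]))
      specNew[a] <- clamp(sum((1 - post[ok]) * (1 - m[ok])) /
                            sum(1 - post[ok]))
    }
    delta <- if (it == 1L) Inf
             else max(abs(c(sensNew - sens, specNew - spec, priorNew - prior)))
    sens <- sensNew; spec <- specNew; prior <- priorNew
    # E-step
    post <- naiveBayesPosterior(marks, sens, spec, prior)
    loglik <- c(loglik, .dsLoglik(marks, sens, spec, prior))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", maxIter, " iterations", call. = FALSE)
  flipped <- mean(sens + spec) < 1
  if (flipped) {                               # re-anchor mirror solution
    tmp <- sens; sens <- 1 - spec; spec <- 1 - tmp
    prior <- 1 - prior
    post <- 1 - post
  }
  names(post) <- rownames(marks)
  list(profiles = data.frame(reader = colnames(marks), sensitivity = sens,
                             specificity = spec, row.names = NULL),
       prior = prior, posteriors = post, loglik = loglik, iterations = it,
       converged = converged, flipped = flipped)
}

#' Severity-aware recoding of ordinal annotations to binary marks
#'
#' When labels form a severity ladder (e.g. any-DR below referable-DR), a
#' reader who marks severity level s implicitly asserts every label of
#' severity at most s: the recode emits 1 for those labels and 0 above,
#' with the category "none" asserting nothing.
#'
#' @param orderedLabels label names from least to most severe (excluding
#'   "none").
#' @param annotations character vector of per-reader categories, each
#'   either "none" or one of \code{orderedLabels}.
#' @return readers x labels binary matrix.
#' @examples
#' severityRecode(c("any_DR", "referable_DR"),
#'                c("any_DR", "referable_DR", "none"))
#' @export
severityRecode <- function(orderedLabels, annotations) {
  lv <- c("none", orderedLabels)
  bad <- setdiff(annotations, lv)
  if (length(bad))
    stop("unknown categor", if (length(bad) == 1L) "y: " else "ies: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sev <- match(annotations, lv) - 1L           # none = 0
  out <- outer(sev, seq_along(orderedLabels), ">=") * 1L
  dimnames(out) <- list(names(annotations), orderedLabels)
  out
}

#' Conservative reference standard from reader marks
#'
#' Majority-positive readings are positive, unanimous negatives are
#' negative, and a lone positive is excluded from the reference set.
#' Applies to validation/test reference labels only; training targets use
#' the fused posterior instead.
#'
#' @param marks binary vector of reader marks (default panel size 3).
#' @return one of \code{"positive"}, \code{"negative"}, \code{"excluded"}.
#' @export
referenceStandard <- function(marks) {
  marks <- as.numeric(marks)
  if (any(is.na(marks)) || !all(marks %in% c(0, 1)))
    stop("marks must be binary", call. = FALSE)
  npos <- sum(marks)
  if (2 * npos > length(marks)) "positive"
  else if (npos == 0) "negative"
  else "excluded"
}

#' Fuse a full annotation panel into training targets and reference labels
#'
#' Runs \code{\link{emEstimate}} independently per label (labels are
#' treated as independent), producing the posterior training target and the
#' conservative reference status of every image.
#'
#' @param panel an \code{\link{AnnotationPanel}}.
#' @param labels labels to fuse (default: all panel labels).
#' @param ... passed to \code{\link{emEstimate}}.
#' @return list with \code{targets} (data.frame image_id/label/posterior/
#'   reference_status) and \code{fits} (per-label EM fits).
#' @export
fusePanel <- function(panel, labels = panelLabels(panel), ...) {
  fits <- lapply(stats::setNames(labels, labels), function(l)
    emEstimate(panel, l, ...))
  rows <- lapply(labels, function(l) {
    mm <- marksMatrix(panel, l)
    status <- apply(mm, 1L, function(m) {
      m <- m[!is.na(m)]
      if (length(m) == 0L) NA_character_ else referenceStandard(m)
    })
    data.frame(image_id = rownames(mm), label = l,
               posterior = unname(fits[[l]]$posteriors[rownames(mm)]),
               reference_status = unname(status), row.names = NULL)
  })
  list(targets = do.call(rbind, rows), fits = fits)
}
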