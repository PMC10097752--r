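# Screening-classifier evaluation: AUROC, exact binomial intervals,
# operating-point selection, and the cosine-distance branch-point analysis.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive scores above a random negative, ties
#' counted one half — computed from average ranks, which is exactly the
#' all-pairs enumeration.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), same length.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute AUROC", call. = FALSE)
  r <- rank(scores)                      # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from Beta quantiles: lower
#' \eqn{B_{\alpha/2}(k, n-k+1)} (0 when k = 0), upper
#' \eqn{B_{1-\alpha/2}(k+1, n-k)} (1 when k = n).
#'
#' @param k successes, \code{0 <= k <= n}.
#' @param n trials, \code{n >= 1}.
#' @param alpha two-sided error rate (default 0.05).
#' @return named numeric \code{c(lower, upper)}.
#' @export
clopperPearson <- function(k, n, alpha = 0.05) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("require integers 0 <= k <= n, n >= 1", call. = FALSE)
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

.sensSpecAt <- function(scores, labels, thr) {
  pred <- scores >= thr
  c(sens = sum(pred & labels == 1) / sum(labels == 1),
    spec = sum(!pred & labels == 0) / sum(labels == 0))
}

#' Choose a screening operating point
#'
#' \code{max_harmonic_mean} scans every threshold at the midpoints between
#' consecutive distinct scores (plus the extremes) and returns the
#' maximizer of \eqn{2\,se\,sp/(se+sp)}, ties broken toward higher
#' specificity (the screening convention).  \code{target_sensitivity}
#' returns the largest threshold whose sensitivity is at least
#' \code{target}, the rule used when positives are too scarce to trust the
#' harmonic-mean scan.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1).
#' @param policy "max_harmonic_mean" or "target_sensitivity".
#' @param target required sensitivity for the target policy (default 0.9).
#' @return an \code{\link{OperatingPoint}} (predict positive when score >=
#'   threshold).
#' @export
chooseOperatingPoint <- function(scores, labels,
                                 policy = c("max_harmonic_mean",
                                            "target_sensitivity"),
                                 target = 0.9) {
  policy <- match.arg(policy)
  labels <- as.numeric(labels)
  if (!any(labels == 1) || !any(labels == 0))
    stop("both classes must be present", call. = FALSE)
  s <- sort(unique(scores))
  thresholds <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
                  s[length(s)] + 1)
  ss <- vapply(thresholds, .sensSpecAt, numeric(2), scores = scores,
               labels = labels)
  if (policy == "max_harmonic_mean") {
    hm <- ifelse(ss["sens", ] + ss["spec", ] > 0,
                 2 * ss["sens", ] * ss["spec", ] /
                   (ss["sens", ] + ss["spec", ]), 0)
    best <- which(hm == max(hm))
    pick <- best[which.max(ss["spec", best])]   # tie-break: higher specificity
  } else {
    ok <- which(ss["sens", ] >= target)
    if (length(ok) == 0L) {
      warning("target sensitivity ", target, " unreachable; returning the ",
              "minimum threshold", call. = FALSE)
      pick <- 1L
    } else pick <- ok[which.max(thresholds[ok])]
  }
  se <- unname(ss["sens", pick]); sp <- unname(ss["spec", pick])
  new("OperatingPoint", threshold = thresholds[pick], sensitivity = se,
      specificity = sp,
      harmonicMean = if (se + sp > 0) 2 * se * sp / (se + sp) else 0)
}

#' ROC curve points
#'
#' Sensitivity/specificity at every candidate threshold, for export or
#' plotting.
#'
#' @inheritParams chooseOperatingPoint
#' @return data.frame with threshold, sensitivity, specificity.
#' @export
rocPoints <- function(scores, labels) {
  labels <- as.numeric(labels)
  s <- sort(unique(scores))
  thresholds <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
                  s[length(s)] + 1)
  ss <- t(vapply(thresholds, .sensSpecAt, numeric(2), scores = scores,
                 labels = labels))
  data.frame(threshold = thresholds, sensitivity = ss[, "sens"],
             specificity = ss[, "spec"])
}

#' Mean pairwise cosine distance between findings, per layer
#'
#' For each layer, computes
#' \eqn{d_{cos}(f_i,f_j) = 1 - \frac{1}{|f_i||f_j|}\sum_{I,J}
#' \frac{\Phi(I)^T\Phi(J)}{\|\Phi(I)\|\|\Phi(J)\|}} over all cross pairs of
#' images carrying the two findings, then averages over all unordered
#' finding pairs.  The suggested branch depth is the deepest layer before
#' the mean distance first increases by more than \code{margin} — features
#' up to that layer are still shared across findings.
#'
#' @param sets list (one element per layer, in depth order) of named lists
#'   (one element per finding) of n_images x P feature matrices.
#' @param margin increase required to call the distance rising (default 0).
#' @return list with \code{meanDistance} (named per layer),
#'   \code{pairDistances} (per layer matrix) and \code{branchAfter} (layer
#'   index to branch after, NA when the distance never rises).
#' @export
cosineBranchAnalysis <- function(sets, margin = 0) {
  perLayer <- lapply(sets, function(layer) {
    fn <- names(layer)
    if (length(fn) < 2L) stop("need at least two findings", call. = FALSE)
    normed <- lapply(layer, function(M) {
      M <- as.matrix(M)
      nrm <- sqrt(rowSums(M^2))
      if (any(nrm == 0))
        stop("zero feature vector for image ", which(nrm == 0)[1],
             call. = FALSE)
      M / nrm
    })
    D <- matrix(NA_real_, length(fn), length(fn), dimnames = list(fn, fn))
    for (i in seq_along(fn)) for (j in seq_along(fn)) if (i < j) {
      sim <- tcrossprod(normed[[i]], normed[[j]])
      D[i, j] <- D[j, i] <- 1 - mean(sim)
    }
    D
  })
  meanDist <- vapply(perLayer, function(D) mean(D[upper.tri(D)]), numeric(1))
  if (is.null(names(meanDist)))
    names(meanDist) <- paste0("layer", seq_along(meanDist))
  rising <- which(diff(meanDist) > margin)
  list(meanDistance = meanDist, pairDistances = perLayer,
       branchAfter = if (length(rising)) unname(rising[1]) else NA_integer_)
}
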