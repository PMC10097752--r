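# Counterfactual attribution ratio engine: weight-direction decomposition,
# odds, counterfactual odds, I-CAR / CAR, epsilon selection, attribution
# activation maps, and interactive score overrides.

#' Decompose pooled features about a finding head's weight direction
#'
#' Splits \eqn{\bar z_f} into \eqn{p\,\hat w_f + \bar z_{f,\perp}} where
#' \eqn{\hat w_f = w_f/\|w_f\|} and \eqn{p = \hat w_f^T \bar z_f}.  Under a
#' unit-norm head \eqn{p = \sigma^{-1}(\hat y_f) - b_f}; in general
#' \eqn{p = (\sigma^{-1}(\hat y_f) - b_f)/\|w_f\|}, so the reconstruction
#' and orthogonality identities hold for any weight norm.
#'
#' @param pooled pooled feature vector \eqn{\bar z_f}.
#' @param head a \code{\link{FindingHead}} with nonzero weight norm.
#' @return a \code{\link{Decomposition}}.
#' @export
decomposeFeatures <- function(pooled, head) {
  stopifnot(is(head, "FindingHead"))
  nrm <- .vnorm(head@weight)
  if (nrm == 0)
    stop("degenerate finding head '", head@name, "': zero-norm weight",
         call. = FALSE)
  pooled <- as.numeric(pooled)
  if (length(pooled) != length(head@weight))
    stop("dimension mismatch in decomposeFeatures", call. = FALSE)
  u <- head@weight / nrm
  p <- sum(u * pooled)
  new("Decomposition", parallelCoeff = p, direction = u,
      orthogonal = pooled - p * u, finding = head@name)
}

#' Reassemble a pooled vector from a decomposition
#' @param dec a \code{\link{Decomposition}}.
#' @param parallelCoeff optional replacement projection coefficient.
#' @return numeric pooled vector.
#' @export
recomposeFeatures <- function(dec, parallelCoeff = dec@parallelCoeff)
  parallelCoeff * dec@direction + dec@orthogonal

#' Disease odds
#'
#' \eqn{O(d;x) = \hat y_d / (1 - \hat y_d)}, which for a linear disease head
#' equals \eqn{\exp(\sum_f v_{d,f}^T \bar z_f + c_d)}.
#'
#' @param diseasePred disease probability strictly inside (0, 1).
#' @return positive real odds.
#' @export
odds <- function(diseasePred) {
  if (any(diseasePred <= 0 | diseasePred >= 1))
    stop("odds undefined: prediction must lie strictly inside (0, 1)",
         call. = FALSE)
  diseasePred / (1 - diseasePred)
}

#' Counterfactual latent vector
#'
#' The hypothetical pooled feature vector had finding f been confidently
#' absent: the projection coefficient along \eqn{\hat w_f} is replaced by
#' the value whose finding score is exactly \code{eps}
#' (\eqn{(\sigma^{-1}(\epsilon) - b_f)/\|w_f\|}); the orthogonal component
#' is untouched.
#'
#' @param pooled pooled feature vector \eqn{\bar z_f} (or a
#'   \code{\link{Decomposition}} of it).
#' @param head the matching \code{\link{FindingHead}}.
#' @param eps target finding probability in (0, 1).
#' @return numeric pooled vector \eqn{\bar z_{\setminus f}} with
#'   \code{findingScore(head, .) == eps}.
#' @export
counterfactualLatent <- function(pooled, head, eps) {
  .assertProb(eps, "eps")
  dec <- if (is(pooled, "Decomposition")) pooled
         else decomposeFeatures(pooled, head)
  nrm <- .vnorm(head@weight)
  recomposeFeatures(dec, (logitFn(eps, quiet = TRUE) - head@bias) / nrm)
}

#' Counterfactual disease odds
#'
#' \eqn{C(f,d;x)}: the disease odds after replacing \eqn{\bar z_f} by its
#' counterfactual \eqn{\bar z_{\setminus f}} at confidence \code{eps}, all
#' other finding features untouched.
#'
#' @param pooledAll named list of pooled vectors (or a
#'   \code{\link{LatentFeatures}}).
#' @param diseaseHead a \code{\link{DiseaseHead}}.
#' @param findingHead the \code{\link{FindingHead}} whose finding is
#'   suppressed.
#' @param eps counterfactual confidence in (0, 1).
#' @return positive real counterfactual odds.
#' @export
counterfactualOdds <- function(pooledAll, diseaseHead, findingHead, eps) {
  if (is(pooledAll, "LatentFeatures")) pooledAll <- pooledFeatures(pooledAll)
  f <- findingHead@name
  if (!f %in% names(pooledAll))
    stop("no pooled features for finding '", f, "'", call. = FALSE)
  pooledAll[[f]] <- counterfactualLatent(pooledAll[[f]], findingHead, eps)
  exp(diseaseLinear(diseaseHead, pooledAll))
}

#' Finding-disease coupling
#'
#' \code{coupling} returns the unit-direction coupling
#' \eqn{v_{d,f}^T \hat w_f}; the internal effective coupling additionally
#' divides by \eqn{\|w_f\|} so that closed-form ratios equal their two-pass
#' odds counterparts for any weight norm (the two coincide under the
#' unit-norm default of \code{\link{modelBundle}}).
#'
#' @param findingHead a \code{\link{FindingHead}}.
#' @param diseaseHead a \code{\link{DiseaseHead}} containing a block for
#'   that finding.
#' @return real scalar.
#' @export
coupling <- function(findingHead, diseaseHead) {
  nrm <- .vnorm(findingHead@weight)
  if (nrm == 0)
    stop("degenerate finding head '", findingHead@name, "': zero-norm weight",
         call. = FALSE)
  v <- diseaseHead@blocks[[findingHead@name]]
  if (is.null(v))
    stop("disease '", diseaseHead@name, "' has no block for finding '",
         findingHead@name, "'", call. = FALSE)
  sum(v * findingHead@weight) / nrm
}

.effCoupling <- function(findingHead, diseaseHead)
  coupling(findingHead, diseaseHead) / .vnorm(findingHead@weight)

#' Instance-dependent counterfactual attribution ratio (I-CAR)
#'
#' Closed form
#' \eqn{R_{I\text{-}CAR} = \exp((\sigma^{-1}(\hat y_f) -
#' \sigma^{-1}(\epsilon))\,\kappa)} with coupling
#' \eqn{\kappa = v_{d,f}^T \hat w_f} (unit-norm heads).  Equals the ratio of
#' the disease odds to the counterfactual odds with finding f suppressed to
#' \code{eps}.
#'
#' @param findingPred the finding probability \eqn{\hat y_f}, in (0, 1).
#' @param eps counterfactual confidence in (0, 1).
#' @param coupling the scalar coupling \eqn{v_{d,f}^T \hat w_f}.
#' @return positive real ratio; 1 exactly when \code{coupling} is 0 or
#'   \code{findingPred == eps}.
#' @export
icar <- function(findingPred, eps, coupling) {
  .assertProb(findingPred, "findingPred")
  .assertProb(eps, "eps")
  lo <- logitFn(findingPred, quiet = TRUE) - logitFn(eps, quiet = TRUE)
  if (any(!is.finite(lo)) || any(!is.finite(coupling)))
    stop("non-finite logits or coupling in icar", call. = FALSE)
  exp(lo * coupling)
}

#' Instance I-CAR grid for one image
#'
#' Evaluates the I-CAR of every finding-disease pair on one image's pooled
#' features.
#'
#' @param latents a \code{\link{LatentFeatures}} (or named list of pooled
#'   vectors).
#' @param model a \code{\link{ModelBundle}}.
#' @param eps counterfactual confidence in (0, 1).
#' @return F x D numeric matrix of I-CAR values.
#' @export
icarMatrix <- function(latents, model, eps) {
  if (is(latents, "LatentFeatures")) latents <- pooledFeatures(latents)
  fn <- findingNames(model); dn <- diseaseNames(model)
  out <- matrix(NA_real_, length(fn), length(dn), dimnames = list(fn, dn))
  # effective coupling v.w_hat/||w|| keeps the two-pass odds identity exact
  # for any weight norm; under the unit-norm default it equals v.w_hat.
  for (f in fn) {
    fh <- model@findingHeads[[f]]
    yf <- findingScore(fh, latents[[f]])
    for (d in dn)
      out[f, d] <- icar(yf, eps, .effCoupling(fh, model@diseaseHeads[[d]]))
  }
  out
}

#' Counterfactual attribution ratio of a finding-disease pair
#'
#' The instance-independent CAR compares two hypothetical states in which
#' the finding is surely present (score \eqn{1-\epsilon}) versus confidently
#' absent (score \eqn{\epsilon}):
#' \eqn{R_{CAR} = \exp((\sigma^{-1}(1-\epsilon) -
#' \sigma^{-1}(\epsilon))\,\kappa) = \exp(-2\sigma^{-1}(\epsilon)\,\kappa)}
#' by logit antisymmetry.
#'
#' @param findingHead a \code{\link{FindingHead}}.
#' @param diseaseHead a \code{\link{DiseaseHead}}.
#' @param eps confidence level in (0, 1/100).
#' @return positive real ratio.
#' @export
carRatio <- function(findingHead, diseaseHead, eps) {
  if (eps <= 0 || eps >= 0.01)
    stop("eps must lie strictly inside (0, 1/100)", call. = FALSE)
  exp(-2 * logitFn(eps, quiet = TRUE) * .effCoupling(findingHead, diseaseHead))
}

#' CAR matrix of a model
#'
#' Evaluates \code{\link{carRatio}} over all finding-disease pairs.  The
#' result depends only on the heads (never on an image).
#'
#' @param model a \code{\link{ModelBundle}}.
#' @param eps confidence level in (0, 1/100), or an
#'   \code{\link{EpsilonPolicy}} in fixed mode.
#' @return a \code{\link{CARMatrix}}.
#' @export
carMatrix <- function(model, eps = 0.005) {
  if (is(eps, "EpsilonPolicy")) {
    if (eps@mode != "fixed")
      stop("pass benign predictions through selectEpsilon() first",
           call. = FALSE)
    eps <- eps@value
  }
  fn <- findingNames(model); dn <- diseaseNames(model)
  vals <- matrix(NA_real_, length(fn), length(dn), dimnames = list(fn, dn))
  for (f in fn) for (d in dn)
    vals[f, d] <- carRatio(model@findingHeads[[f]], model@diseaseHeads[[d]], eps)
  new("CARMatrix", values = vals, epsilon = eps)
}

#' Select the counterfactual confidence level
#'
#' Fixed mode returns the policy value.  Benign-percentile mode returns the
#' nearest-rank percentile (default 5th) of finding predictions on benign
#' validation cases, clipped into (0, 1/100) with a warning when outside.
#'
#' @param benignPreds finding probabilities on benign cases (ignored in
#'   fixed mode).
#' @param policy an \code{\link{EpsilonPolicy}}.
#' @return a probability strictly inside (0, 1/100).
#' @export
selectEpsilon <- function(benignPreds = NULL, policy = epsilonPolicy()) {
  stopifnot(is(policy, "EpsilonPolicy"))
  if (policy@mode == "fixed") return(policy@value)
  if (is.null(benignPreds) || length(benignPreds) == 0L)
    stop("no benign predictions supplied; use a fixed-mode EpsilonPolicy",
         call. = FALSE)
  if (length(benignPreds) < 20L)
    warning("fewer than 20 benign predictions; percentile is unstable",
            call. = FALSE)
  s <- sort(as.numeric(benignPreds))
  rank <- max(1L, ceiling(policy@percentile / 100 * length(s)))
  val <- s[rank]
  if (val <= 0 || val >= 0.01) {
    clipped <- min(max(val, 1e-6), 0.01 - 1e-6)
    warning(sprintf(
      "benign percentile %.4g outside (0, 1/100); clipped to %.4g",
      val, clipped), call. = FALSE)
    val <- clipped
  }
  val
}

#' Attribution activation map
#'
#' The class-activation map of finding f scaled by the finding-disease
#' coupling: \eqn{A(f,d;x) = (v_{d,f}^T \hat w_f)\,(w_f^T g_f(x))}, an
#' H' x W' spatial map whose mean equals
#' \eqn{(v_{d,f}^T \hat w_f)(\sigma^{-1}(\hat y_f) - b_f)}.
#'
#' @param latentMap C x H' x W' array \eqn{g_f(x)} (or a
#'   \code{\link{LatentFeatures}} holding one for the finding).
#' @param findingHead,diseaseHead the pair's heads.
#' @return an \code{\link{AttributionMap}}.
#' @export
attributionMap <- function(latentMap, findingHead, diseaseHead) {
  if (is(latentMap, "LatentFeatures"))
    latentMap <- featureMaps(latentMap, findingHead@name)
  if (is.null(latentMap) || length(dim(latentMap)) != 3L)
    stop("latentMap must be a C x H' x W' array", call. = FALSE)
  k <- coupling(findingHead, diseaseHead)   # v . w_hat
  d <- dim(latentMap)
  cam <- matrix(findingHead@weight %*% matrix(latentMap, d[1], d[2] * d[3]),
                d[2], d[3])
  new("AttributionMap", grid = k * cam, finding = findingHead@name,
      disease = diseaseHead@name)
}

#' Bilinearly upsample an attribution map for display
#'
#' @param map an \code{\link{AttributionMap}} (or plain matrix).
#' @param size target side length in pixels.
#' @param normalize scale into [-1, 1] by the maximum absolute value (for
#'   rendering only; raw values are kept in the object).
#' @return numeric size x size matrix.
#' @export
upsampleMap <- function(map, size, normalize = FALSE) {
  g <- if (is(map, "AttributionMap")) map@grid else as.matrix(map)
  out <- EBImage::resize(EBImage::Image(g), w = size, h = size)
  out <- EBImage::imageData(out)
  if (normalize && max(abs(out)) > 0) out <- out / max(abs(out))
  out
}

#' Top findings by attribution
#'
#' Findings whose instance I-CAR exceeds the display threshold (default the
#' natural constant e), sorted descending and truncated to \code{k}
#' (default 3).
#'
#' @param icars named numeric vector of instance I-CAR values per finding.
#' @param threshold display threshold (default \code{exp(1)}).
#' @param k maximum findings returned (default 3).
#' @return named numeric vector (possibly empty), largest first.
#' @export
topFindings <- function(icars, threshold = exp(1), k = 3L) {
  stopifnot(k >= 1L)
  keep <- icars[icars > threshold]
  keep <- keep[order(-keep)]
  utils::head(keep, k)
}

#' Interactive override of finding scores
#'
#' Re-evaluates all disease probabilities after a reader overrides one or
#' more finding scores.  For each overridden finding the projection
#' coefficient along \eqn{\hat w_f} is replaced so the finding score equals
#' the override (orthogonal component untouched); no encoder pass is
#' needed, and the result equals a full forward pass through the disease
#' heads on the modified pooled vectors exactly.
#'
#' @param latents a \code{\link{LatentFeatures}} (or named pooled list).
#' @param model a \code{\link{ModelBundle}}.
#' @param overrides named numeric vector/list, finding name to new score in
#'   (0, 1).
#' @return list with \code{probabilities} (named length-D vector),
#'   \code{pooled} (the modified pooled list) and \code{original} (the
#'   unmodified disease probabilities).
#' @export
interactiveAdjust <- function(latents, model, overrides) {
  pooled <- if (is(latents, "LatentFeatures")) pooledFeatures(latents)
            else latents
  overrides <- unlist(overrides)
  unknown <- setdiff(names(overrides), findingNames(model))
  if (length(unknown))
    stop("override for unknown finding(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  .assertProb(overrides, "override values")
  original <- vapply(model@diseaseHeads, diseaseScore, numeric(1),
                     pooledAll = pooled)
  for (f in names(overrides))
    pooled[[f]] <- counterfactualLatent(pooled[[f]], model@findingHeads[[f]],
                                        overrides[[f]])
  probs <- vapply(model@diseaseHeads, diseaseScore, numeric(1),
                  pooledAll = pooled)
  list(probabilities = probs, pooled = pooled, original = original)
}
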