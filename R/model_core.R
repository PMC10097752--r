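# Two-stage classifier scaffold: pooling, linear heads, and desk-scale
# training of the heads on pooled features.

#' Global average pooling
#'
#' Per-channel spatial mean of a C x H' x W' feature map, the pooling that
#' turns a finding branch's spatial map \eqn{g_f(x)} into \eqn{\bar z_f}.
#'
#' @param maps numeric array of shape C x H' x W' (a C x H' matrix is
#'   accepted as a degenerate W' = 1 map).
#' @return numeric vector of length C.
#' @examples
#' poolFeatures(array(3, c(2, 4, 4)))      # c(3, 3)
#' @export
poolFeatures <- function(maps) {
  if (is.matrix(maps)) maps <- array(maps, c(dim(maps), 1L))
  if (!is.array(maps) || length(dim(maps)) != 3L)
    stop("maps must be a C x H' x W' array", call. = FALSE)
  d <- dim(maps)
  if (d[2] < 1L || d[3] < 1L || d[1] < 1L)
    stop("empty spatial domain: H' x W' must be >= 1", call. = FALSE)
  apply(maps, 1L, mean)
}

#' Finding score
#'
#' \eqn{\hat y_f = \sigma(w_f^T \bar z_f + b_f)} for one finding head.
#' \code{findingLogit} returns the pre-sigmoid linear score.
#'
#' @param head a \code{\link{FindingHead}}.
#' @param pooled pooled feature vector \eqn{\bar z_f} (length C).
#' @return probability in (0, 1); for \code{findingLogit}, a real scalar.
#' @export
findingScore <- function(head, pooled) .sigmoid(findingLogit(head, pooled))

#' @rdname findingScore
#' @export
findingLogit <- function(head, pooled) {
  stopifnot(is(head, "FindingHead"))
  pooled <- as.numeric(pooled)
  if (length(pooled) != length(head@weight))
    stop("dimension mismatch: pooled has length ", length(pooled),
         ", head '", head@name, "' expects ", length(head@weight),
         call. = FALSE)
  sum(head@weight * pooled) + head@bias
}

#' Disease score
#'
#' \eqn{\hat y_d = \sigma(\sum_f v_{d,f}^T \bar z_f + c_d)} over the pooled
#' features of all finding branches.  \code{diseaseLinear} returns the
#' pre-sigmoid linear score.
#'
#' @param head a \code{\link{DiseaseHead}}.
#' @param pooledAll named list of pooled vectors, one per finding block (a
#'   \code{\link{LatentFeatures}} object is also accepted).
#' @return probability in (0, 1); for \code{diseaseLinear}, a real scalar.
#' @export
diseaseScore <- function(head, pooledAll) .sigmoid(diseaseLinear(head, pooledAll))

#' @rdname diseaseScore
#' @export
diseaseLinear <- function(head, pooledAll) {
  stopifnot(is(head, "DiseaseHead"))
  if (is(pooledAll, "LatentFeatures")) pooledAll <- pooledFeatures(pooledAll)
  miss <- setdiff(names(head@blocks), names(pooledAll))
  if (length(miss))
    stop("disease '", head@name, "': missing pooled block(s) for finding(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  s <- head@intercept
  for (f in names(head@blocks)) {
    z <- as.numeric(pooledAll[[f]])
    if (length(z) != length(head@blocks[[f]]))
      stop("disease '", head@name, "': block '", f, "' dimension mismatch",
           call. = FALSE)
    s <- s + sum(head@blocks[[f]] * z)
  }
  s
}

# Deterministic full-batch logistic fit of mean BCE + l2*||w||^2 by
# gradient descent with backtracking line search (monotone loss by
# construction).  Accepts soft targets in [0,1].  Predictors are
# standardized internally and the penalty applied on the standardized
# scale (the glmnet convention; the intercept is unpenalized); the
# returned coefficients are folded back to the raw feature scale.
.bceFit <- function(X, y, l2 = 5e-4, maxIter = 5000L, tol = 1e-7,
                    checkpointEvery = 25L) {
  stopifnot(nrow(X) == length(y))
  .assertProb(y, "labels", open = FALSE)
  if (all(y >= 1 - 1e-12) || all(y <= 1e-12))
    warning("labels are one-class; intercept will dominate", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  X1 <- cbind(sweep(sweep(X, 2L, ctr), 2L, scl, "/"), 1)
  n <- nrow(X1)
  k <- ncol(X1) - 1L
  theta <- numeric(ncol(X1))
  pen <- c(rep(1, k), 0)               # intercept unpenalized
  lossOf <- function(th) {
    p <- .clampProb(.sigmoid(drop(X1 %*% th)), quiet = TRUE)
    -mean(y * log(p) + (1 - y) * log1p(-p)) + l2 * sum(pen * th^2)
  }
  loss <- lossOf(theta)
  history <- loss
  step <- 1
  for (it in seq_len(maxIter)) {
    p <- .sigmoid(drop(X1 %*% theta))
    grad <- drop(crossprod(X1, p - y)) / n + 2 * l2 * pen * theta
    step <- step * 1.5
    repeat {
      cand <- theta - step * grad
      candLoss <- lossOf(cand)
      if (candLoss <= loss || step < 1e-14) break
      step <- step / 2
    }
    if (candLoss > loss) break        # stalled; keep current iterate
    converged <- (loss - candLoss) <= tol * max(1, abs(loss))
    theta <- cand
    loss <- candLoss
    if (it %% checkpointEvery == 0L || converged || it == maxIter)
      history <- c(history, loss)
    if (converged) break
  }
  wStd <- theta[seq_len(k)]
  list(weight = wStd / scl, bias = theta[k + 1L] - sum(wStd * ctr / scl),
       loss = loss, history = history, iterations = it)
}

#' Train disease heads on pooled finding features
#'
#' Fits one L2-regularized logistic head per disease on the concatenated
#' pooled finding features, minimizing mean binary cross-entropy plus
#' \code{l2 * ||w||^2} by deterministic full-batch gradient descent with
#' backtracking line search.  Predictors are standardized internally and
#' the penalty applied to the standardized-scale weights (intercept
#' unpenalized), with coefficients folded back to the raw feature scale.
#' Soft targets (e.g. fused label posteriors) are accepted directly in the
#' cross-entropy.
#'
#' @param features named list with one n x C pooled-feature matrix per
#'   finding, in finding order.
#' @param labels n x D matrix (or data.frame) of targets in [0, 1], one
#'   column per disease.
#' @param l2 L2-regularization coefficient (default 0.0005).
#' @param maxIter,tol optimizer budget and relative-loss-change convergence
#'   tolerance.
#' @return named list of \code{\link{DiseaseHead}}; the per-disease recorded
#'   loss checkpoints are attached as \code{attr(, "history")}.
#' @export
trainDiseaseHeads <- function(features, labels, l2 = 5e-4, maxIter = 5000L,
                              tol = 1e-7) {
  stopifnot(is.list(features), length(features) >= 1L)
  fn <- names(features)
  if (is.null(fn)) stop("features must be a named list (one entry per finding)")
  X <- do.call(cbind, lapply(features, as.matrix))
  labels <- as.matrix(labels)
  if (nrow(X) != nrow(labels)) stop("features and labels disagree on n")
  if (nrow(X) < 1L) stop("at least one image required")
  C <- ncol(as.matrix(features[[1]]))
  heads <- list(); history <- list()
  for (d in colnames(labels)) {
    fit <- .bceFit(X, labels[, d], l2 = l2, maxIter = maxIter, tol = tol)
    blocks <- split(fit$weight, rep(fn, each = C))[fn]
    heads[[d]] <- diseaseHead(d, blocks, fit$bias)
    history[[d]] <- fit$history
  }
  attr(heads, "history") <- history
  heads
}

#' Train finding heads on their own pooled features
#'
#' Convenience fitter for the linear finding heads: per finding, an
#' L2-regularized logistic fit of that finding's pooled branch features
#' against its (possibly soft) target, using the same deterministic
#' optimizer as \code{\link{trainDiseaseHeads}}.  The encoder itself stays
#' frozen.
#'
#' @param features named list with one n x C pooled-feature matrix per
#'   finding.
#' @param labels n x F matrix of targets in [0, 1], columns named by finding.
#' @inheritParams trainDiseaseHeads
#' @return named list of \code{\link{FindingHead}}.
#' @export
trainFindingHeads <- function(features, labels, l2 = 5e-4, maxIter = 5000L,
                              tol = 1e-7) {
  labels <- as.matrix(labels)
  heads <- list()
  for (f in names(features)) {
    if (!f %in% colnames(labels)) stop("no label column for finding '", f, "'")
    fit <- .bceFit(as.matrix(features[[f]]), labels[, f], l2 = l2,
                   maxIter = maxIter, tol = tol)
    heads[[f]] <- findingHead(f, fit$weight, fit$bias)
  }
  heads
}

#' Class-balanced batch sampler
#'
#' Streams index batches in which each slot is filled by a fair coin flip
#' between the positive and negative class, then uniformly within the class,
#' so the expected number of positives and negatives per batch is equal
#' regardless of prevalence.  Every example keeps nonzero sampling
#' probability.
#'
#' @param labels binary vector (0/1).
#' @param batchSize examples per batch (default 6).
#' @param nBatches number of batches to draw.
#' @param seed integer seed.
#' @return list of \code{nBatches} integer index vectors of length
#'   \code{batchSize}.
#' @export
balancedBatches <- function(labels, batchSize = 6L, nBatches = 1L, seed = 1L) {
  labels <- as.numeric(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0L) stop("no positive examples in labels", call. = FALSE)
  if (length(neg) == 0L) stop("no negative examples in labels", call. = FALSE)
  set.seed(as.integer(seed))
  lapply(seq_len(nBatches), function(b) {
    takePos <- stats::runif(batchSize) < 0.5
    idx <- integer(batchSize)
    idx[takePos] <- pos[sample.int(length(pos), sum(takePos), replace = TRUE)]
    idx[!takePos] <- neg[sample.int(length(neg), sum(!takePos), replace = TRUE)]
    idx
  })
}
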