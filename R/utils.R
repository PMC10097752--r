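# Internal numeric helpers shared across modules.

# probabilities are clamped before logit to avoid infinities; clamping is
# reported once per call via a message when it actually occurs.
.PROB_EPS <- 1e-12

.sigmoid <- function(x) 1 / (1 + exp(-x))

.clampProb <- function(p, quiet = FALSE) {
  bad <- p < .PROB_EPS | p > 1 - .PROB_EPS
  if (any(bad)) {
    if (!quiet) message("clamping ", sum(bad), " probabilit",
                        if (sum(bad) == 1L) "y" else "ies",
                        " into [1e-12, 1 - 1e-12] before logit")
    p <- pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)
  }
  p
}

#' Logit (inverse sigmoid)
#'
#' \code{logitFn(p)} returns \eqn{\log(p / (1 - p))}.  Inputs are clamped to
#' \code{[1e-12, 1 - 1e-12]} first; clamping emits a message.
#'
#' @param p numeric vector of probabilities.
#' @param quiet suppress the clamping message.
#' @return numeric vector of logits.
#' @export
logitFn <- function(p, quiet = FALSE) {
  stopifnot(is.numeric(p))
  p <- .clampProb(p, quiet = quiet)
  log(p) - log1p(-p)
}

.assertProb <- function(x, what, open = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  if (open) {
    if (any(x <= 0 | x >= 1))
      stop(what, " must lie strictly inside (0, 1)", call. = FALSE)
  } else if (any(x < 0 | x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

.vnorm <- function(x) sqrt(sum(x^2))
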