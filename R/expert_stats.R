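# Pooled expert odds ratios per finding-disease pair and the CAR-vs-OR
# comparison grid.

#' Pooled 2x2 contingency table over all readings
#'
#' Accumulates every (reader, image) reading of a panel into a single 2x2
#' matrix of joint finding/disease presence counts.  Cell [1,1] is
#' (finding present, disease present) — presence-first indexing, see
#' \code{\linkS4class{ContingencyTable}}.
#'
#' @param panel an \code{\link{AnnotationPanel}} containing both labels.
#' @param finding,disease label names.
#' @return a \code{\link{ContingencyTable}}.
#' @export
pooledContingency <- function(panel, finding, disease) {
  stopifnot(is(panel, "AnnotationPanel"))
  miss <- setdiff(c(finding, disease), panelLabels(panel))
  if (length(miss))
    stop("label(s) not in panel: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- panelMarks(panel)
  f <- m[[finding]]; d <- m[[disease]]
  ok <- !is.na(f) & !is.na(d)
  counts <- matrix(c(sum(f[ok] == 1 & d[ok] == 1),
                     sum(f[ok] == 0 & d[ok] == 1),
                     sum(f[ok] == 1 & d[ok] == 0),
                     sum(f[ok] == 0 & d[ok] == 0)), 2L, 2L,
                   dimnames = list(finding = c("present", "absent"),
                                   disease = c("present", "absent")))
  new("ContingencyTable", counts = counts, finding = finding,
      disease = disease)
}

#' Odds ratio of a pooled contingency table
#'
#' \eqn{OR = N_{11} N_{00} / (N_{10} N_{01})} in presence-first indexing
#' (concordant product over discordant product).  The optional Haldane
#' correction adds 0.5 to every cell first, yielding a finite OR for every
#' table.
#'
#' @param table a \code{\link{ContingencyTable}} or plain 2x2 matrix in the
#'   same cell order.
#' @param correction "none" or "haldane".
#' @return positive real, or \code{Inf} (with a warning) when a discordant
#'   cell is empty and no correction is applied.
#' @export
oddsRatio <- function(table, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  N <- if (is(table, "ContingencyTable")) tableCounts(table)
       else as.matrix(table)
  stopifnot(all(dim(N) == c(2L, 2L)))
  if (correction == "haldane") N <- N + 0.5
  den <- N[1, 2] * N[2, 1]
  if (den == 0) {
    warning("empty discordant cell: odds ratio is infinite ",
            "(consider correction = 'haldane')", call. = FALSE)
    return(Inf)
  }
  N[1, 1] * N[2, 2] / den
}

#' Side-by-side CAR and expert odds-ratio grids
#'
#' Computes the pooled expert odds ratio of every finding-disease pair in
#' the CAR matrix's vocabulary and returns both grids on the log scale,
#' together with a per-disease Spearman rank correlation across findings
#' (a numeric stand-in for the visual grid comparison).
#'
#' @param car a \code{\link{CARMatrix}}.
#' @param panel an \code{\link{AnnotationPanel}} carrying the same finding
#'   and disease labels.
#' @param correction odds-ratio correction (default "haldane" so log-OR is
#'   always finite).
#' @return list with \code{logCAR}, \code{logOR} (F x D matrices) and
#'   \code{rankAgreement} (named per-disease Spearman rho).
#' @export
carOrGrid <- function(car, panel, correction = "haldane") {
  stopifnot(is(car, "CARMatrix"))
  fn <- findingNames(car); dn <- diseaseNames(car)
  miss <- setdiff(c(fn, dn), panelLabels(panel))
  if (length(miss))
    stop("panel lacks label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  orGrid <- matrix(NA_real_, length(fn), length(dn),
                   dimnames = list(fn, dn))
  for (f in fn) for (d in dn)
    orGrid[f, d] <- oddsRatio(pooledContingency(panel, f, d),
                              correction = correction)
  logCAR <- log(carValues(car))
  logOR <- log(orGrid)
  rho <- vapply(dn, function(d)
    stats::cor(logCAR[, d], logOR[, d], method = "spearman"), numeric(1))
  list(logCAR = logCAR, logOR = logOR, rankAgreement = rho)
}
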