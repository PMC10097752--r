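# enumeration oracle: joint probability over Y for an arbitrary mark vector
nbOracle <- function(marks, sens, spec, prior) {
  j1 <- prior * prod(ifelse(marks == 1, sens, 1 - sens))
  j0 <- (1 - prior) * prod(ifelse(marks == 1, 1 - spec, spec))
  j1 / (j1 + j0)
}

test_that("the reader-fusion posterior matches direct enumeration", {
  # worked value: three concordant positives, sens = spec = 0.8, prior 1/2
  got <- naiveBayesPosterior(c(1, 1, 1), rep(0.8, 3), rep(0.8, 3), 0.5)
  expect_equal(got, 0.512 / 0.520, tolerance = 1e-10)
  # uninformative readers return the prior no matter the marks
  for (p in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1)))
    expect_equal(naiveBayesPosterior(p, rep(0.5, 3), rep(0.5, 3), 0.5), 0.5)

  patterns <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  set.seed(61)
  for (i in 1:100) {
    sens <- runif(3, 0.55, 0.99); spec <- runif(3, 0.55, 0.99)
    prior <- runif(1, 0.05, 0.95)
    for (r in seq_len(nrow(patterns))) {
      mk <- patterns[r, ]
      want <- nbOracle(mk, sens, spec, prior)
      expect_lt(abs(naiveBayesPosterior(mk, sens, spec, prior) - want) /
                  want, 1e-10)
    }
  }
  # symmetric under reader permutation when profiles are identical
  expect_equal(naiveBayesPosterior(c(1, 0, 0), rep(0.8, 3), rep(0.9, 3), 0.3),
               naiveBayesPosterior(c(0, 0, 1), rep(0.8, 3), rep(0.9, 3), 0.3))
  expect_error(naiveBayesPosterior(c(1, 1, 1), c(1, 0.8, 0.8),
                                   rep(0.8, 3), 0.5), "strictly inside")
})

test_that("EM recovers reader profiles and the log-likelihood never decreases", {
  sim <- simulatedPanel(n = 2000L)
  fit <- emEstimate(sim$panel, "label")
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik) > -1e-7))
  expect_lt(max(abs(fit$profiles$sensitivity - c(0.9, 0.8, 0.7))), 0.05)
  expect_lt(max(abs(fit$profiles$specificity - c(0.95, 0.9, 0.85))), 0.05)
  expect_lt(abs(fit$prior - 0.3), 0.05)
  # deterministic initialization: repeated runs agree exactly
  fit2 <- emEstimate(sim$panel, "label")
  expect_identical(fit$profiles, fit2$profiles)

  # posterior-thresholded labels beat (or match) the majority vote
  mm <- marksMatrix(sim$panel, "label")
  maj <- as.numeric(rowMeans(mm) > 0.5)
  post <- as.numeric(fit$posteriors > 0.5)
  expect_gte(mean(post == sim$truth), mean(maj == sim$truth))
})

test_that("EM with near-perfect readers collapses to the majority label", {
  set.seed(71)
  truth <- rbinom(500, 1, 0.4)
  pan <- simulateReaderPanel(truth, rep(0.999, 3), rep(0.999, 3), seed = 72L)
  fit <- emEstimate(pan, "label")
  mm <- marksMatrix(pan, "label")
  maj <- as.numeric(rowMeans(mm) > 0.5)
  expect_equal(unname(as.numeric(fit$posteriors > 0.5)), maj)
})

test_that("severity recoding asserts every label at or below the marked severity", {
  # a reader panel grading (any DR, referable DR, no DR)
  got <- severityRecode(c("any_DR", "referable_DR"),
                        c("any_DR", "referable_DR", "none"))
  expect_equal(unname(got[, "any_DR"]), c(1, 1, 0))
  expect_equal(unname(got[, "referable_DR"]), c(0, 1, 0))
  # vein-occlusion ladder: BRVO below CRVO
  gotRvo <- severityRecode(c("BRVO", "CRVO"), c("BRVO", "CRVO", "none"))
  expect_equal(unname(gotRvo[, "BRVO"]), c(1, 1, 0))
  expect_equal(unname(gotRvo[, "CRVO"]), c(0, 1, 0))
  # macular-degeneration ladder: dry below wet
  gotAmd <- severityRecode(c("dry_AMD", "wet_AMD"),
                           c("dry_AMD", "wet_AMD", "none"))
  expect_equal(unname(gotAmd[, "dry_AMD"]), c(1, 1, 0))
  expect_equal(unname(gotAmd[, "wet_AMD"]), c(0, 1, 0))

  expect_equal(sum(severityRecode(c("a", "b"), rep("none", 3))), 0)
  expect_error(severityRecode(c("a", "b"), c("a", "zzz", "none")),
               "unknown categor")
})

test_that("reference standard: majority positive, unanimous negative, lone positive excluded", {
  patterns <- expand.grid(0:1, 0:1, 0:1)
  for (r in seq_len(nrow(patterns))) {
    mk <- as.numeric(patterns[r, ])
    want <- if (sum(mk) >= 2) "positive"
            else if (sum(mk) == 0) "negative" else "excluded"
    expect_identical(referenceStandard(mk), want)
    # permutation invariance in readers
    expect_identical(referenceStandard(rev(mk)), want)
  }
  expect_error(referenceStandard(c(1, NA, 0)), "binary")
})

test_that("panel fusion emits per-image targets and reference status", {
  sim <- simulatedPanel(n = 300L)
  fused <- suppressWarnings(fusePanel(sim$panel))
  tg <- fused$targets
  expect_equal(nrow(tg), 300L)
  expect_true(all(tg$posterior >= 0 & tg$posterior <= 1))
  expect_true(all(tg$reference_status %in%
                    c("positive", "negative", "excluded")))
  mm <- marksMatrix(sim$panel, "label")
  expect_identical(tg$reference_status[match(rownames(mm), tg$image_id)],
                   unname(apply(mm, 1, referenceStandard)))
})
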