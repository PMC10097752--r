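aurocPairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUROC equals the all-pairs Mann-Whitney enumeration", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(91)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    sc <- round(runif(n), 2)           # rounding forces ties
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) %in% c(0, n)) next
    expect_equal(auroc(sc, lb), aurocPairs(sc, lb), tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC is invariant under strictly increasing score transforms", {
  set.seed(92)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.4)
  expect_equal(auroc(exp(sc), lb), auroc(sc, lb))
  expect_equal(auroc(rank(sc), lb), auroc(sc, lb))
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(93)
  sc <- round(rnorm(100), 1); lb <- rbinom(100, 1, 0.35)
  want <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                         direction = "<")))
  expect_equal(auroc(sc, lb), want, tolerance = 1e-10)
})

test_that("Clopper-Pearson intervals match the exact Beta closed forms", {
  ci <- clopperPearson(10, 10)
  expect_equal(unname(ci["lower"]), 0.025^(1 / 10), tolerance = 1e-10)
  expect_equal(unname(ci["upper"]), 1)
  ci0 <- clopperPearson(0, 10)
  expect_equal(unname(ci0["lower"]), 0)
  expect_equal(unname(ci0["upper"]), 1 - 0.025^(1 / 10), tolerance = 1e-10)
  # agrees with the exact binomial test's interval
  for (k in c(1, 3, 7)) {
    bt <- stats::binom.test(k, 12)$conf.int
    expect_equal(unname(clopperPearson(k, 12)), as.numeric(bt),
                 tolerance = 1e-10)
  }
  # interval always contains k/n; width shrinks with n at fixed k/n
  for (n in c(5, 20, 80)) {
    k <- round(0.4 * n)
    ci <- clopperPearson(k, n)
    expect_true(ci["lower"] <= k / n && k / n <= ci["upper"])
  }
  widths <- vapply(c(10, 40, 160, 640), function(n)
    diff(clopperPearson(round(0.3 * n), n)), numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(clopperPearson(11, 10), "0 <= k <= n")
})

opOracle <- function(scores, labels) {
  best <- -Inf; bestPt <- NULL
  for (thr in sort(unique(c(scores - 1e-9, scores + 1e-9)))) {
    se <- mean(scores[labels == 1] >= thr)
    sp <- mean(scores[labels == 0] < thr)
    hm <- if (se + sp > 0) 2 * se * sp / (se + sp) else 0
    if (hm > best + 1e-12) { best <- hm; bestPt <- c(se, sp) }
  }
  list(hm = best, pt = bestPt)
}

test_that("operating-point selection maximizes the harmonic mean", {
  sc <- c(0.9, 0.8, 0.7, 0.4, 0.5, 0.2, 0.1)
  lb <- c(1, 1, 1, 1, 0, 0, 0)
  op <- chooseOperatingPoint(sc, lb)
  expect_equal(op@harmonicMean, 6 / 7, tolerance = 1e-12)
  expect_true(op@threshold > 0.5 && op@threshold <= 0.7)

  sep <- chooseOperatingPoint(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep@sensitivity, 1)
  expect_equal(sep@specificity, 1)

  set.seed(94)
  for (i in 1:15) {
    sc <- round(runif(25), 2); lb <- rbinom(25, 1, 0.4)
    if (sum(lb) %in% c(0, 25)) next
    op <- chooseOperatingPoint(sc, lb)
    expect_equal(op@harmonicMean, opOracle(sc, lb)$hm, tolerance = 1e-9)
    # never dominated: no scanned point beats it in both rates
    rp <- rocPoints(sc, lb)
    dominated <- any(rp$sensitivity > op@sensitivity + 1e-12 &
                       rp$specificity > op@specificity + 1e-12)
    expect_false(dominated)
  }
})

test_that("target-sensitivity policy returns the largest admissible threshold", {
  set.seed(95)
  pos <- sort(runif(10)); neg <- runif(12, 0, 0.6)
  sc <- c(pos, neg); lb <- rep(c(1, 0), c(10, 12))
  op <- chooseOperatingPoint(sc, lb, "target_sensitivity", target = 0.9)
  expect_gte(op@sensitivity, 0.9)
  # rank oracle: threshold admits at least 9 of the 10 positives
  expect_gte(sum(pos >= op@threshold), 9)
  # and the next higher candidate threshold would lose sensitivity
  expect_lt(mean(pos >= op@threshold + 1e-9) - 1e-12, 0.9 + 1e-12)
  expect_warning(chooseOperatingPoint(sc, lb, "target_sensitivity",
                                      target = 1.5), "unreachable")
})

test_that("cosine branch analysis matches a nested-loop oracle and flags the rise", {
  one <- list(a = matrix(c(1, 0), 1), b = matrix(c(1, 0), 1))
  expect_equal(unname(cosineBranchAnalysis(list(one))$meanDistance), 0)
  orth <- list(a = matrix(c(1, 0), 1), b = matrix(c(0, 1), 1))
  expect_equal(unname(cosineBranchAnalysis(list(orth))$meanDistance), 1)

  set.seed(96)
  layer <- list(a = matrix(rnorm(12), 4), b = matrix(rnorm(9), 3),
                c = matrix(rnorm(15), 5))
  got <- cosineBranchAnalysis(list(layer))
  brute <- function(M, N) {
    s <- 0
    for (i in seq_len(nrow(M))) for (j in seq_len(nrow(N)))
      s <- s + sum(M[i, ] * N[j, ]) /
        (sqrt(sum(M[i, ]^2)) * sqrt(sum(N[j, ]^2)))
    1 - s / (nrow(M) * nrow(N))
  }
  pairs <- c(brute(layer$a, layer$b), brute(layer$a, layer$c),
             brute(layer$b, layer$c))
  expect_equal(unname(got$meanDistance), mean(pairs), tolerance = 1e-10)
  # symmetry and bounds
  D <- got$pairDistances[[1]]
  expect_equal(D, t(D))
  expect_true(all(D[upper.tri(D)] >= 0 & D[upper.tri(D)] <= 2))

  # distances (0.3, 0.28, 0.29, 0.4, 0.6): the first rise is between
  # layers 2 and 3, so branch after layer 2; a margin of 0.05 ignores the
  # small 0.28 -> 0.29 bump and moves the branch point to layer 3
  mk <- function(d) {
    u <- c(1, 0); v <- c(1 - d, sqrt(1 - (1 - d)^2))
    list(a = matrix(u, 1), b = matrix(v, 1))
  }
  seqs <- lapply(c(0.3, 0.28, 0.29, 0.4, 0.6), mk)
  expect_equal(cosineBranchAnalysis(seqs)$branchAfter, 2L)
  expect_equal(cosineBranchAnalysis(seqs, margin = 0.05)$branchAfter, 3L)
  expect_true(is.na(cosineBranchAnalysis(lapply(c(0.5, 0.4), mk))$branchAfter))
  expect_error(cosineBranchAnalysis(list(list(a = matrix(0, 1, 2),
                                              b = matrix(1, 1, 2)))),
               "zero feature vector")
})
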