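test_that("feature decomposition reconstructs and is orthogonal", {
  h <- findingHead("f", c(1, 0), 0)
  dec <- decomposeFeatures(c(2, 3), h)
  expect_equal(dec@parallelCoeff * dec@direction, c(2, 0))
  expect_equal(dec@orthogonal, c(0, 3))

  # pooled parallel to w -> zero orthogonal part
  h2 <- findingHead("f", c(3, 4), 1)
  dec2 <- decomposeFeatures(c(3, 4) * 2.5, h2)
  expect_equal(dec2@orthogonal, c(0, 0), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:20) {
    C <- 16L
    h3 <- findingHead("f", rnorm(C), rnorm(1))
    z <- rnorm(C)
    d3 <- decomposeFeatures(z, h3)
    expect_lt(abs(sum(d3@orthogonal * d3@direction)), 1e-8)
    expect_lt(max(abs(recomposeFeatures(d3) - z)), 1e-8)
  }
  expect_error(decomposeFeatures(c(1, 2), findingHead("f", c(0, 0), 0)),
               "degenerate")
})

test_that("odds match the exponential of the disease linear score", {
  expect_equal(odds(0.5), 1)
  expect_equal(odds(0.9), 9, tolerance = 1e-12)
  expect_error(odds(1), "strictly inside")
  expect_error(odds(0), "strictly inside")
  m <- randomModel(5L, 4L, 2L, seed = 8)
  z <- randomPooled(m, seed = 9)
  dh <- m@diseaseHeads[[1]]
  expect_equal(odds(diseaseScore(dh, z)), exp(diseaseLinear(dh, z)),
               tolerance = 1e-8)
})

test_that("counterfactual latent hits the target score and keeps the orthogonal part", {
  m <- randomModel(4L, 8L, 1L, seed = 2)
  z <- randomPooled(m, seed = 3)
  h <- m@findingHeads[[1]]
  eps <- 0.005
  zc <- counterfactualLatent(z[[1]], h, eps)
  expect_equal(findingScore(h, zc), eps, tolerance = 1e-8)
  # suppressing to the current prediction is the identity
  yf <- findingScore(h, z[[1]])
  expect_equal(counterfactualLatent(z[[1]], h, yf), z[[1]],
               tolerance = 1e-10)
  # orthogonal component untouched
  expect_equal(decomposeFeatures(zc, h)@orthogonal,
               decomposeFeatures(z[[1]], h)@orthogonal, tolerance = 1e-10)
})

test_that("closed-form I-CAR equals the two-pass odds ratio", {
  expect_equal(icar(0.005, 0.005, 1.7), 1)
  expect_equal(icar(0.5, 0.9, 0), 1)
  # worked value: logit(0.5) - logit(0.005) = 5.2933, times coupling 0.2
  expect_equal(icar(0.5, 0.005, 0.2), exp(5.293305 * 0.2), tolerance = 1e-6)

  set.seed(31)
  for (i in 1:100) {
    m <- randomModel(15L, 8L, 2L, seed = 1000L + i)
    z <- randomPooled(m, seed = 2000L + i)
    f <- sample(findingNames(m), 1); d <- sample(diseaseNames(m), 1)
    fh <- m@findingHeads[[f]]; dh <- m@diseaseHeads[[d]]
    eps <- runif(1, 1e-4, 0.0099)
    O <- odds(diseaseScore(dh, z))
    Cf <- counterfactualOdds(z, dh, fh, eps)
    closed <- icar(findingScore(fh, z[[f]]), eps, coupling(fh, dh))
    expect_lt(abs(closed - O / Cf) / (O / Cf), 1e-8)
  }
})

test_that("I-CAR is monotone in the finding score with the coupling's sign", {
  ys <- seq(0.05, 0.95, by = 0.05)
  up <- icar(ys, 0.005, 0.7)
  dn <- icar(ys, 0.005, -0.7)
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) < 0))
  expect_equal(icar(ys, 0.005, 0), rep(1, length(ys)))
})

test_that("CAR closed form, reciprocity and the CAR matrix identities hold", {
  fh <- findingHead("f1", c(1, 0), 0.3)
  dPerp <- diseaseHead("d", list(f1 = c(0, 2)), 0)
  expect_equal(carRatio(fh, dPerp, 0.005), 1)
  # coupling 0.2 at eps 0.005: exp((logit(0.995) - logit(0.005)) * 0.2)
  dh <- diseaseHead("d", list(f1 = c(0.2, 0)), 0)
  expect_equal(carRatio(fh, dh, 0.005), exp(10.58661 * 0.2),
               tolerance = 1e-6)
  dneg <- diseaseHead("d", list(f1 = c(-0.2, 0)), 0)
  expect_equal(carRatio(fh, dneg, 0.005) * carRatio(fh, dh, 0.005), 1,
               tolerance = 1e-10)
  expect_error(carRatio(fh, dh, 0.02), "1/100")

  # block-diagonal couplings give exactly-1 off-diagonal entries
  fn <- c("f1", "f2")
  fhs <- list(findingHead("f1", c(1, 0), 0), findingHead("f2", c(0, 1), 0))
  dhs <- list(diseaseHead("d1", list(f1 = c(0.5, 9), f2 = c(0, 2)), 0),
              diseaseHead("d2", list(f1 = c(0, -4), f2 = c(0.3, 5)), 0))
  # blocks orthogonal to the other finding's weight: d1 couples only to f1
  dhs[[1]]@blocks$f2 <- c(0, 0); dhs[[2]]@blocks$f1 <- c(0, 0)
  mb <- modelBundle(fhs, dhs, normalize = FALSE)
  cm <- carMatrix(mb, 0.005)
  expect_equal(carValues(cm)["f1", "d2"], 1)
  expect_equal(carValues(cm)["f2", "d1"], 1)

  # log-entries proportional to the coupling grid; eps rescaling is exact
  m <- randomModel(6L, 8L, 3L, seed = 12)
  K <- outer(findingNames(m), diseaseNames(m),
             Vectorize(function(f, d) coupling(m@findingHeads[[f]],
                                               m@diseaseHeads[[d]])))
  lc <- log(carValues(carMatrix(m, 0.005)))
  expect_equal(lc, K * (-2 * logitFn(0.005)), tolerance = 1e-8,
               ignore_attr = TRUE)
  lc2 <- log(carValues(carMatrix(m, 0.001)))
  expect_equal(lc2, lc * logitFn(0.001) / logitFn(0.005), tolerance = 1e-8)
})

test_that("logit antisymmetry holds across the permitted epsilon range", {
  eps <- c(1e-6, 1e-4, 0.001, 0.005, 0.009, 0.0099)
  expect_true(all(abs(logitFn(1 - eps) + logitFn(eps)) < 1e-10))
})

test_that("epsilon selection follows the policy", {
  expect_equal(selectEpsilon(policy = epsilonPolicy("fixed", 0.005)), 0.005)
  benign <- seq_len(100) * 0.00009       # evenly spaced in (0, 0.009]
  got <- selectEpsilon(benign, epsilonPolicy("benign_percentile"))
  expect_equal(got, sort(benign)[5])     # nearest-rank 5th percentile
  expect_warning(
    out <- selectEpsilon(rep(0.02, 50), epsilonPolicy("benign_percentile")),
    "clipped")
  expect_lt(out, 0.01)
  expect_error(selectEpsilon(NULL, epsilonPolicy("benign_percentile")),
               "fixed")
  expect_warning(selectEpsilon(rep(0.004, 10),
                               epsilonPolicy("benign_percentile")),
                 "fewer than 20")
  expect_error(epsilonPolicy("fixed", 0.02), "0, 1/100")
})

test_that("attribution maps satisfy the pooled-mean identity", {
  C <- 8L
  fh <- findingHead("f1", rnorm(C), 0.4)
  dhPerp <- diseaseHead("d", list(f1 = fh@weight * 0), 0)
  g <- array(rnorm(C * 5 * 5), c(C, 5, 5))
  expect_equal(max(abs(attributionMap(g, fh, dhPerp)@grid)), 0)

  gConst <- array(rep(1:C, 25), c(C, 5, 5))
  dh <- diseaseHead("d", list(f1 = rnorm(C)), 0)
  amc <- attributionMap(gConst, fh, dh)@grid
  expect_lt(diff(range(amc)), 1e-12)

  set.seed(41)
  for (i in 1:10) {
    fh2 <- findingHead("f1", rnorm(C), rnorm(1))
    dh2 <- diseaseHead("d", list(f1 = rnorm(C)), rnorm(1))
    g2 <- array(rnorm(C * 6 * 4), c(C, 6, 4))
    am <- attributionMap(g2, fh2, dh2)
    lhs <- mean(am@grid)
    rhs <- coupling(fh2, dh2) *
      (logitFn(findingScore(fh2, poolFeatures(g2))) - fh2@bias)
    expect_lt(abs(lhs - rhs), 1e-6)
  }
  up <- upsampleMap(attributionMap(g, fh, dh), 20L)
  expect_equal(dim(up), c(20L, 20L))
  upn <- upsampleMap(attributionMap(g, fh, dh), 20L, normalize = TRUE)
  expect_lte(max(abs(upn)), 1)
})

test_that("top findings are threshold-filtered, sorted and truncated", {
  ic <- c(a = 9, b = 3, c = 1.1)
  expect_equal(names(topFindings(ic)), c("a", "b"))
  expect_equal(unname(topFindings(ic)), c(9, 3))
  expect_length(topFindings(c(a = 2.0, b = exp(1))), 0)
  expect_equal(names(topFindings(ic, k = 1L)), "a")
  expect_equal(names(topFindings(c(a = 3, b = 4, c = 5), threshold = 2.5)),
               c("c", "b", "a"))
})

test_that("interactive overrides equal full recomputation and the counterfactual identities", {
  m <- randomModel(6L, 8L, 3L, seed = 15)
  lat <- randomLatents(m, seed = 16)
  eps <- 0.004
  f <- "f2"
  adj <- interactiveAdjust(lat, m, setNames(list(eps), f))
  for (d in diseaseNames(m)) {
    # override-to-eps reproduces the counterfactual odds for every disease
    expect_equal(odds(adj$probabilities[[d]]),
                 counterfactualOdds(lat, m@diseaseHeads[[d]],
                                    m@findingHeads[[f]], eps),
                 tolerance = 1e-10)
    # and equals brute-force recomputation on modified pooled exactly
    expect_identical(adj$probabilities[[d]],
                     diseaseScore(m@diseaseHeads[[d]], adj$pooled))
  }
  # no-op override
  yf <- findingScore(m@findingHeads[[f]], pooledFeatures(lat, f))
  noop <- interactiveAdjust(lat, m, setNames(list(yf), f))
  expect_equal(noop$probabilities, noop$original, tolerance = 1e-10)
  # override to 1 - eps multiplies the counterfactual odds by the CAR
  hi <- interactiveAdjust(lat, m, setNames(list(1 - eps), f))
  for (d in diseaseNames(m)) {
    Cf <- counterfactualOdds(lat, m@diseaseHeads[[d]], m@findingHeads[[f]],
                             eps)
    expect_equal(odds(hi$probabilities[[d]]) / Cf,
                 carRatio(m@findingHeads[[f]], m@diseaseHeads[[d]], eps),
                 tolerance = 1e-8)
  }
  expect_error(interactiveAdjust(lat, m, list(nosuch = 0.5)),
               "unknown finding")
})

test_that("the CAR matrix does not depend on the image", {
  m <- randomModel(4L, 6L, 2L, seed = 18)
  cm <- carMatrix(m, 0.003)
  # ratio of adjusted odds (present surely vs absent) on two different
  # images reproduces the same instance-free matrix
  for (s in c(51L, 52L)) {
    lat <- randomLatents(m, seed = s)
    for (f in findingNames(m)) {
      lo <- interactiveAdjust(lat, m, setNames(list(0.003), f))
      hi <- interactiveAdjust(lat, m, setNames(list(0.997), f))
      for (d in diseaseNames(m))
        expect_equal(odds(hi$probabilities[[d]]) / odds(lo$probabilities[[d]]),
                     carValues(cm)[f, d], tolerance = 1e-8)
    }
  }
})
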