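# Fixtures built in code: random head bundles and latent features.

randomModel <- function(F = 15L, C = 8L, D = 3L, seed = 1L,
                        normalize = TRUE) {
  set.seed(seed)
  fn <- paste0("f", seq_len(F))
  dn <- paste0("d", seq_len(D))
  fh <- lapply(fn, function(f) findingHead(f, rnorm(C), rnorm(1)))
  dh <- lapply(dn, function(d)
    diseaseHead(d, setNames(lapply(fn, function(f) rnorm(C, sd = 0.3)), fn),
                rnorm(1)))
  modelBundle(fh, dh, normalize = normalize)
}

randomPooled <- function(model, seed = 1L) {
  set.seed(seed)
  C <- nChannels(model)
  setNames(lapply(findingNames(model), function(f) rnorm(C)),
           findingNames(model))
}

randomLatents <- function(model, seed = 1L, h = 4L, w = 4L) {
  set.seed(seed)
  C <- nChannels(model)
  maps <- setNames(lapply(findingNames(model), function(f)
    array(rnorm(C * h * w), c(C, h, w))), findingNames(model))
  latentFeatures(maps = maps)
}

# three-reader panel over one label, simulated from known profiles; truth
# and panel use distinct seeds (identical seeds would make reader 1's
# uniform draws coincide with the truth draw).
simulatedPanel <- function(n = 2000L, prevalence = 0.3,
                           sens = c(0.9, 0.8, 0.7),
                           spec = c(0.95, 0.9, 0.85),
                           truthSeed = 100L, panelSeed = 200L) {
  set.seed(truthSeed)
  truth <- rbinom(n, 1L, prevalence)
  list(truth = truth,
       panel = simulateReaderPanel(truth, sens, spec, seed = panelSeed))
}
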