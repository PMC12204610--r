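# The end-to-end recovery pipeline (5000 records with strong planted
# effects -> encode -> train -> held-out evaluation) is expensive, so it
# is computed once and shared by the acceptance tests that probe it.

recoveryPipeline <- function() cached("recoveryPipeline", {
  sim <- makeFixture("recovery")
  pis <- suppressMessages(buildPseudoImages(sim$targets, sim$dnase,
                                            sim$methyl))
  idx <- splitDataset(length(pis), seed = 11L)
  fit <- trainPrimeNet(primeNet(seed = 11L), pis[idx$train], pis[idx$val],
                       trainConfig(max_epochs = 15L,
                                   early_stop_patience = 4L,
                                   learning_rate = 3e-3, seed = 11L))
  test <- pis[idx$test]
  list(sim = sim, images = pis, idx = idx, fit = fit, test = test,
       pred = predictTriples(fit$model, test),
       obs = observedTriples(test))
})
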