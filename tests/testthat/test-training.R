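test_that("orthogonal initialization satisfies W'W = I with zero biases", {
  p <- list("a.W" = matrix(0, 64, 32),        # dense storage (fan-in, out)
            "a.b" = numeric(32),
            "c.W" = array(0, c(3, 8, 16)),    # conv kernel
            "c.b" = numeric(16),
            "sq.W" = matrix(0, 24, 24),
            "wide.W" = array(0, c(5, 2, 1)))  # fan-out 1 < fan-in
  p <- orthogonalInit(p, seed = 9L)
  dev <- orthogonalityDeviation(p)
  expect_lt(dev$weight_dev, 1e-5)
  expect_identical(dev$bias_max, 0)
  expect_identical(p[["a.b"]], numeric(32))
  # a 64x32 dense weight, viewed output x fan-in, is 32 x 64: rows
  # orthonormal
  M <- primenet:::weightAs2d(p[["a.W"]])
  expect_lt(max(abs(tcrossprod(M) - diag(32))), 1e-5)
  # square weight: |det| = 1
  expect_equal(abs(det(p[["sq.W"]])), 1, tolerance = 1e-4)
  # reproducible under the same seed
  expect_identical(orthogonalInit(p, seed = 9L), p)
})

# hand-stepped reference of the two printed update equations
lookaheadReference <- function(phi0, k, alpha, cycles, gradAt, lr) {
  phi <- phi0
  for (t in seq_len(cycles)) {
    theta <- phi
    for (i in seq_len(k)) theta <- theta - lr * gradAt(theta, t, i)
    phi <- phi + alpha * (theta - phi)
  }
  phi
}

test_that("Lookahead matches the hand-stepped scalar quadratic", {
  # loss theta^2, gradient 2 theta, step 0.1, phi0 = theta0 = 1, k = 2,
  # alpha = 0.5: theta1 = 0.8, theta2 = 0.64, phi1 = 0.82
  st <- lookaheadInit(list(w = 1), k = 2L, alpha = 0.5,
                      inner = optimizerSGD(lr = 0.1))
  gradFn <- function(params, batch) list(loss = params$w^2,
                                         grads = list(w = 2 * params$w))
  st <- lookaheadOuterStep(st, gradFn, list(1, 2))
  expect_equal(st$phi$w, 0.82, tolerance = 1e-12)
  expect_equal(st$theta$w, st$phi$w)      # fast weights reset to slow
  expect_equal(st$t, 1L)
})

test_that("Lookahead equals an independent reference on random problems", {
  withr::with_seed(2024, {
    for (trial in 1:100) {
      d <- sample(1:4, 1)
      A <- diag(stats::runif(d, 0.1, 2), nrow = d)  # loss 0.5 w'Aw + g'w
      gv <- stats::rnorm(d)
      k <- sample(1:6, 1)
      alpha <- stats::runif(1, 0.05, 1)
      lr <- stats::runif(1, 0.01, 0.2)
      cycles <- sample(1:3, 1)
      w0 <- stats::rnorm(d)
      gradFn <- function(params, batch)
        list(loss = 0, grads = list(w = A %*% params$w + gv * batch))
      st <- lookaheadInit(list(w = w0), k = k, alpha = alpha,
                          inner = optimizerSGD(lr = lr))
      batchSeq <- stats::rnorm(cycles * k)
      for (t in seq_len(cycles))
        st <- lookaheadOuterStep(st, gradFn,
                                 as.list(batchSeq[(t - 1) * k + seq_len(k)]))
      ref <- lookaheadReference(
        w0, k, alpha, cycles,
        function(w, t, i) A %*% w + gv * batchSeq[(t - 1) * k + i], lr)
      expect_lt(max(abs(st$phi$w - ref)), 1e-10)
    }
  })
})

test_that("Lookahead limits reduce to the inner optimizer / identity", {
  gradFn <- function(params, batch) list(loss = 0,
                                         grads = list(w = 2 * params$w))
  # alpha = 1, k = 1: identical to plain SGD
  st <- lookaheadInit(list(w = 1), k = 1L, alpha = 1,
                      inner = optimizerSGD(lr = 0.1))
  st <- lookaheadOuterStep(st, gradFn, list(1))
  expect_equal(st$phi$w, 1 - 0.1 * 2)
  # alpha -> 0: slow weights barely move
  st2 <- lookaheadInit(list(w = 1), k = 1L, alpha = 1e-9,
                       inner = optimizerSGD(lr = 0.1))
  st2 <- lookaheadOuterStep(st2, gradFn, list(1))
  expect_equal(st2$phi$w, 1, tolerance = 1e-8)
  # short final cycle is allowed and logged
  st3 <- lookaheadInit(list(w = 1), k = 3L, alpha = 0.5,
                       inner = optimizerSGD(lr = 0.1))
  expect_message(lookaheadOuterStep(st3, gradFn, list(1)), "short")
})

test_that("8:1:1 split is disjoint, exhaustive and seeded", {
  sp <- splitDataset(1000L, seed = 5L)
  expect_equal(lengths(sp), c(train = 800L, val = 100L, test = 100L))
  expect_identical(sort(unname(unlist(sp))), 1:1000)
  expect_identical(splitDataset(1000L, seed = 5L), sp)
  expect_false(identical(splitDataset(1000L, seed = 6L), sp))
  expect_error(splitDataset(9L), class = "primenet_validation_error")
  sp2 <- splitDataset(47L)
  expect_equal(lengths(sp2), c(train = 37L, val = 4L, test = 6L))
})

test_that("merge-and-shuffle conserves records and tags provenance", {
  pis <- tinyImages()
  a <- pis[1:20]; b <- pis[21:32]
  m1 <- mergeAndShuffle(list(hek = a, k562 = b), seed = 3L)
  expect_equal(length(m1), 32L)
  expect_setequal(recordIds(m1), recordIds(pis))
  expect_setequal(unique(m1@provenance), c("hek", "k562"))
  expect_identical(m1@provenance[match(recordIds(a), recordIds(m1))],
                   rep("hek", 20))
  m2 <- mergeAndShuffle(list(hek = a, k562 = b), seed = 3L)
  expect_identical(recordIds(m1), recordIds(m2))
  # images follow their record through the permutation
  i <- match(recordIds(pis)[7], recordIds(m1))
  expect_identical(m1@images[, , , i], pis@images[, , , 7])
})

test_that("training reduces the loss on planted signal and is replayable", {
  pis <- tinyImages()
  idx <- splitDataset(length(pis), seed = 1L)
  cfgT <- trainConfig(max_epochs = 5L, batch_size = 16L, seed = 1L,
                      early_stop_patience = 5L)
  fit <- trainPrimeNet(primeNet(smallConfig(), seed = 1L),
                       pis[idx$train], pis[idx$val], cfgT)
  h <- fit$history
  expect_lte(nrow(h), 5L)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)))
  # identical seeds give identical trajectories
  fit2 <- trainPrimeNet(primeNet(smallConfig(), seed = 1L),
                        pis[idx$train], pis[idx$val], cfgT)
  expect_identical(fit2$history, h)
  expect_identical(fit2$model@params, fit$model@params)
  expect_equal(fit$manifest$n_train, length(idx$train))
})

test_that("disabling Lookahead equals alpha = 1, k = 1", {
  pis <- tinyImages()
  idx <- splitDataset(length(pis), seed = 2L)
  base <- trainConfig(max_epochs = 2L, batch_size = 16L, seed = 2L)
  cfgA <- utils::modifyList(base, list(lookahead_enabled = FALSE))
  cfgB <- utils::modifyList(base, list(lookahead_k = 1L,
                                       lookahead_alpha = 1))
  fitA <- trainPrimeNet(primeNet(smallConfig(), seed = 2L),
                        pis[idx$train], pis[idx$val], cfgA)
  fitB <- trainPrimeNet(primeNet(smallConfig(), seed = 2L),
                        pis[idx$train], pis[idx$val], cfgB)
  expect_equal(fitA$history, fitB$history, tolerance = 1e-12)
})

test_that("hyperparameter search logs trials and covers flag states", {
  pis <- tinyImages()
  idx <- splitDataset(length(pis), seed = 4L)
  space <- list(learning_rate = c(1e-3, 3e-3),
                channel_attention_enabled = c(TRUE, FALSE),
                conv_attention_enabled = c(TRUE, FALSE))
  res <- tuneHyperparameters(
    pis[idx$train], pis[idx$val], space, nTrials = 6L, seed = 1L,
    trainCfg = trainConfig(max_epochs = 1L, batch_size = 16L),
    baseConfig = smallConfig())
  expect_equal(nrow(res$trials), 6L)
  expect_equal(res$best_score, max(res$trials$score))
  expect_setequal(unique(res$trials$channel_attention_enabled),
                  c(TRUE, FALSE))
  expect_setequal(unique(res$trials$conv_attention_enabled), c(TRUE, FALSE))
  # reproducible trial sequence under the same seed
  res2 <- tuneHyperparameters(
    pis[idx$train], pis[idx$val], space, nTrials = 6L, seed = 1L,
    trainCfg = trainConfig(max_epochs = 1L, batch_size = 16L),
    baseConfig = smallConfig())
  expect_identical(res$trials, res2$trials)
})
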