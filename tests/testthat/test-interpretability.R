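# A hand-built model whose validly-edited head depends monotonically on
# channel 4 (DNase) of the wild slice at one position: every conv layer
# passes feature channel 1 through unchanged and the trunk reads only
# position `p` of that feature.
monotoneChannel4Model <- function(p = 20L, gain = 6) {
  cfg <- modelConfig(channel_attention_enabled = FALSE,
                     conv_attention_enabled = FALSE,
                     mixconv_out_channels = 2L, compress_channels = 2L,
                     conv_channels = c(2L, 2L), trunk_widths = 4L,
                     branch_widths = 2L)
  m <- primeNet(cfg, seed = 1L)
  prm <- lapply(m@params, function(x) { x[] <- 0; x })
  prm[["mix1.W"]][1, 5, 1] <- 1          # folded channel 5 = wild DNase
  prm[["comp.W"]][1, 1, 1] <- 1
  prm[["conv1.W"]][2, 1, 1] <- 1         # centre-tap identity
  prm[["conv2.W"]][2, 1, 1] <- 1
  prm[["trunk1.W"]][p, 1] <- gain        # flatten index (l = p, c = 1)
  prm[["br1l1.W"]][1, 1] <- 1
  prm[["br1out.W"]][1, 1] <- 1
  m@params <- prm
  m
}

test_that("midpoint path integral is exact for a linear map", {
  withr::with_seed(1, {
    x <- array(stats::runif(128 * 8 * 2), c(128, 8, 2))
    w <- array(stats::rnorm(128 * 8 * 2), c(128, 8, 2))
  })
  wFold <- primenet:::foldImages(array(w, c(dim(w), 1L)))[, 1L, ]
  gradBatchFn <- function(xw) {            # F(x) = <w, x>: constant gradient
    g <- array(0, dim(xw))
    for (s in seq_len(dim(xw)[2])) g[, s, ] <- wFold
    g
  }
  attr <- primenet:::igMidpoint(gradBatchFn, x, array(0, dim(x)), 32L)
  expect_equal(attr, w * x, tolerance = 1e-12)
})

test_that("attributions vanish at the baseline and satisfy completeness", {
  pis <- tinyImages()
  m <- primeNet(smallConfig(), seed = 6L)
  img <- pis@images[, , , 1L]

  ig0 <- integratedGradients(m, img, "valid", baseline = img, steps = 16L)
  expect_true(all(attributionScores(ig0) == 0))

  ig <- integratedGradients(m, pis[1], "valid", steps = 256L)
  f1 <- predictTriples(m, img)[1, "valid"]
  f0 <- predictTriples(m, array(0, dim(img)))[1, "valid"]
  expect_lt(abs(sum(attributionScores(ig)) - (f1 - f0)) /
              max(1e-8, abs(f1 - f0)), 0.01)
  expect_s4_class(ig, "AttributionMap")
  expect_identical(dim(attributionScores(ig)), c(128L, 8L, 2L))
})

test_that("top-sequence selection is a deterministic descending cut", {
  withr::with_seed(7, {
    df <- do.call(rbind, lapply(1:300, function(i) {
      d <- handRecordDf(); d$record_id <- sprintf("s%03d", i); d
    }))
    df$valid <- round(stats::runif(300, 0, 60), 1)   # ties likely
    df$unedited <- 90 - df$valid
    df$erroneous <- 10
  })
  ts <- makeTargetSet(df)
  top <- selectTopSequences(ts, "valid", 200L)
  expect_length(top, 200L)
  obs <- observedTriples(ts)
  expect_gte(min(obs[top, "valid"]), max(obs[setdiff(rownames(obs), top),
                                             "valid"]))
  expect_identical(selectTopSequences(ts, "valid", 200L), top)
  expect_length(selectTopSequences(ts, "valid", 0L), 0L)
  expect_warning(all300 <- selectTopSequences(ts, "valid", 400L),
                 "only 300")
  expect_length(all300, 300L)
  # ties at the cut break by record_id
  df2 <- df[1:5, ]
  df2$record_id <- c("e", "b", "d", "a", "c")
  df2$valid <- c(9, 9, 9, 10, 9)
  df2$unedited <- 90 - df2$valid; df2$erroneous <- 10
  expect_identical(selectTopSequences(makeTargetSet(df2), "valid", 3L),
                   c("a", "b", "c"))
})

test_that("channel optimization drives the planted position and masks rest", {
  p <- 20L
  m <- monotoneChannel4Model(p)
  pis <- tinyImages()
  seeds <- pis[1:6]
  base <- seeds@images
  base[, 5, , ] <- 0.5                       # start channel 4 mid-range
  res <- optimizeEpigeneticChannel(m, base, channel = 4L, head = "valid",
                                   steps = 120L, stepSize = 0.05)
  expect_gt(res$profile[p, "wild"], 0.9)     # ascended toward accessibility
  expect_true(all(res$profile >= 0 & res$profile <= 1))
  # every non-target channel is bit-identical before and after
  expect_identical(res$images[, -5, , ], base[, -5, , ])

  expect_error(optimizeEpigeneticChannel(m, base[, , , 0, drop = FALSE]),
               "empty")
  expect_error(optimizeEpigeneticChannel(m, base, channel = 2L))
})

test_that("attention maps average per stage and sit in (0,1)", {
  pis <- tinyImages()
  m <- primeNet(smallConfig(), seed = 8L)
  maps1 <- extractAttentionMaps(m, pis[1])
  expect_named(maps1, c("ca_in", "ca1", "ca2"))
  expect_true(all(vapply(maps1, length, 1L) == 128L))
  expect_true(all(unlist(maps1) > 0 & unlist(maps1) < 1))
  # average of one image equals the raw forward-pass weights
  X <- primenet:::foldImages(pis@images[, , , 1, drop = FALSE])
  fw <- primenet:::netForward(m@params, m@config, X)
  expect_equal(maps1$ca1, rowMeans(fw$attention$ca1))

  off <- primeNet(smallConfig(conv_attention_enabled = FALSE), seed = 8L)
  expect_error(extractAttentionMaps(off, pis[1]), "disabled")

  # a gate built to attend one stripe concentrates the averaged map there
  gated <- primeNet(smallConfig(), seed = 9L)
  prm <- gated@params
  prm[["ca_in.W"]][] <- 0
  prm[["ca_in.W"]][3, 1, 1] <- 8             # centre tap on the mean map
  prm[["ca_in.b"]][] <- -4
  gated@params <- prm
  stripe <- array(0, c(128, 8, 2, 1))
  stripe[60:70, , , ] <- 1
  maps <- extractAttentionMaps(gated, stripe)
  inside <- mean(maps$ca_in[60:70])
  outside <- mean(maps$ca_in[-(55:75)])
  expect_gt(inside, 0.9)
  expect_lt(outside, 0.1)
})
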