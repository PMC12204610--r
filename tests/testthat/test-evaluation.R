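tripleize <- function(v) cbind(valid = v, unedited = 100 - v, erroneous = 0 * v)

test_that("correlations handle identity, anti-monotone and tied inputs", {
  withr::with_seed(1, v <- stats::runif(20, 0, 100))
  co <- correlations(tripleize(v), tripleize(v))
  expect_equal(co$spearman, c(1, 1, NA_real_))  # constant head undefined
  expect_equal(co$pearson[1:2], c(1, 1))

  dec <- 100 - 0.99 * v                          # strictly decreasing transform
  co2 <- correlations(tripleize(dec), tripleize(v))
  expect_equal(co2$spearman[1], -1)

  # 5-point set with one tie: brute-force average-rank computation
  p <- c(10, 20, 20, 40, 50); o <- c(5, 30, 10, 50, 40)
  rk <- function(x) rank(x, ties.method = "average")
  byHand <- stats::cor(rk(p), rk(o))
  expect_equal(correlations(tripleize(p), tripleize(o))$spearman[1], byHand)

  # invariance under strictly monotone transforms
  withr::with_seed(2, {
    a <- stats::runif(30, 0, 100); b <- stats::runif(30, 0, 100)
    s0 <- correlations(tripleize(a), tripleize(b))$spearman[1]
    expect_equal(correlations(tripleize(100 * (a / 100)^3),
                              tripleize(b))$spearman[1], s0)
  })
})

test_that("binarization is strictly greater than the threshold", {
  expect_identical(binarizeAtThreshold(c(50.1, 50, 49.9, 0, 100)),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(binarizeAtThreshold(rep(0, 5))))
  withr::with_seed(3, v <- round(stats::runif(50, 0, 100), 1))
  lab <- binarizeAtThreshold(v); comp <- binarizeAtThreshold(100 - v)
  at50 <- v == 50
  expect_identical(lab[!at50], !comp[!at50])
})

test_that("ROC follows the rank identity and the hand example", {
  expect_equal(rocPrAuc(1:10, c(rep(FALSE, 5), rep(TRUE, 5)))$auroc, 1)
  # 4-point hand example: label pairs (0.35 vs 0.1, 0.4), (0.8 vs both)
  expect_equal(rocPrAuc(c(0.1, 0.4, 0.35, 0.8),
                        c(FALSE, FALSE, TRUE, TRUE))$auroc, 0.75)
  # shuffled labels at n = 1e4: AUROC near 1/2
  withr::with_seed(4, {
    sc <- stats::runif(1e4)
    lab <- sample(rep(c(TRUE, FALSE), 5e3))
  })
  expect_lt(abs(rocPrAuc(sc, lab)$auroc - 0.5), 0.02)

  # AUROC == U / (n1 n2) on random instances (with ties)
  withr::with_seed(5, {
    for (rep in 1:20) {
      sc <- sample(round(stats::runif(40), 1))
      lab <- stats::runif(40) < 0.4
      if (!any(lab) || all(lab)) next
      mw <- mannWhitneyU(sc[lab], sc[!lab])
      expect_equal(rocPrAuc(sc, lab)$auroc, mw$U / (mw$n1 * mw$n2))
    }
  })
  expect_warning(res <- rocPrAuc(1:4, rep(TRUE, 4)), "single-class")
  expect_true(is.na(res$auroc))
})

test_that("ROC/PR agree with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(6, {
    sc <- stats::runif(200)
    lab <- stats::runif(200) < plogis(4 * sc - 2)
  })
  ours <- rocPrAuc(sc, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours$auroc, ref, tolerance = 1e-12)
})

test_that("Mann-Whitney U statistic and exact p match enumeration", {
  res <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)          # no pair with a > b
  expect_equal(res$p, 1 / 3)      # 2/6 assignments as extreme

  same <- mannWhitneyU(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$U, 9 / 2)     # n1 n2 / 2 by symmetry

  # literal enumeration oracle over all group assignments
  enumP <- function(a, b) {
    n1 <- length(a); v <- c(a, b); n <- length(v)
    r <- rank(v)
    Uof <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
    obs <- Uof(seq_len(n1))
    cen <- n1 * (n - n1) / 2
    combs <- utils::combn(n, n1)
    mean(apply(combs, 2, function(ix) abs(Uof(ix) - cen) >= abs(obs - cen)))
  }
  withr::with_seed(7, {
    for (rep in 1:12) {
      n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
      a <- sample(1:6, n1, replace = TRUE)   # heavy ties on purpose
      b <- sample(1:6, n2, replace = TRUE)
      res <- mannWhitneyU(a, b)
      expect_equal(res$method, "exact")
      expect_equal(res$p, enumP(a, b), tolerance = 1e-12)
    }
  })

  # untied exact case agrees with the distribution-based reference
  withr::with_seed(8, {
    a <- sample(1:1000, 8); b <- sample(2000:3000, 9)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    res <- mannWhitneyU(a, b)
    expect_equal(res$U, unname(ref$statistic))
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  })

  # large samples switch to the tie-corrected normal approximation
  withr::with_seed(9, {
    a <- stats::rnorm(40); b <- stats::rnorm(40, 0.7)
    res <- mannWhitneyU(a, b)
    expect_equal(res$method, "normal")
    ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-6)
  })
})

test_that("epigenetic grouping partitions the annotated records", {
  anns <- list(
    r1 = list(dnase = rep(TRUE, 5), methyl = rep(FALSE, 5)),
    r2 = list(dnase = c(rep(TRUE, 4), FALSE), methyl = c(TRUE, rep(FALSE, 4))),
    r3 = NULL,
    r4 = list(dnase = rep(FALSE, 5), methyl = rep(TRUE, 5)))
  g <- epigeneticGroupSplit(anns)
  expect_equal(nrow(g), 3L)
  expect_equal(attr(g, "excluded"), 1L)
  expect_equal(as.character(g$openness),
               c("completely open", "presence of closure",
                 "presence of closure"))
  expect_equal(as.character(g$methylation),
               c("without methylation", "with methylation",
                 "with methylation"))
  expect_equal(sum(table(g$openness)), 3L)
})

test_that("per-head group comparison reports U and p for each efficiency", {
  withr::with_seed(10, {
    vals <- cbind(c(stats::runif(30, 40, 90), stats::runif(30, 10, 60)),
                  stats::runif(60, 0, 100), stats::runif(60, 0, 100))
    grp <- factor(rep(c("open", "closed"), each = 30))
  })
  vp <- violinPlotData(vals, grp)
  expect_equal(nrow(vp), 180L)
  expect_identical(colnames(vp), c("group", "head", "efficiency"))
  expect_equal(sum(vp$head == "valid"), 60L)
  gc <- groupComparison(vals, grp)
  expect_equal(nrow(gc), 3L)
  expect_identical(gc$head, c("valid", "unedited", "erroneous"))
  expect_true(all(gc$U >= 0 & gc$U <= 900))
  expect_lt(gc$p[1], 0.01)     # planted difference on the first head
  expect_gt(min(gc$p[2:3]), 1e-4 / 3)
})

test_that("the full metrics report combines correlations and AUCs", {
  withr::with_seed(11, {
    obs <- matrix(stats::runif(300, 0, 100), 100, 3)
    pred <- pmax(pmin(obs + matrix(stats::rnorm(300, 0, 8), 100), 100), 0)
  })
  rep_ <- evaluateModel(pred, obs)
  expect_identical(rep_$head, c("valid", "unedited", "erroneous"))
  expect_true(all(rep_$spearman > 0.8))
  expect_true(all(rep_$auroc > 0.8 & rep_$auroc <= 1))
  expect_true(all(rep_$auprc > 0.5 & rep_$auprc <= 1))
  expect_true(all(rep_$threshold == 50))
})
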