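test_that("one-hot encoding follows the A/G/T/C channel map", {
  expect_equal(oneHotEncode("A"), matrix(c(1, 0, 0, 0), 1))
  g <- oneHotEncode("GGG")
  expect_true(all(g[, 2] == 1) && all(g[, c(1, 3, 4)] == 0))
  withr::with_seed(3, {
    seq <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    m <- oneHotEncode(seq)
    expect_true(all(rowSums(m) == 1))
  })
  expect_error(oneHotEncode("ACGN"), "position 3",
               class = "primenet_validation_error")
})

test_that("region channels mark proto+PAM+PBS on 6 and RT on 7", {
  spans <- list(proto = c(0L, 20L), pam = c(20L, 23L), pbs = c(30L, 43L),
                rt = c(30L, 45L))
  m <- encodeRegionChannels(spans, 99L)
  # per-position set-union oracle
  expect_identical(which(m[, 1] == 1) - 1L, c(0:22, 30:42))
  expect_identical(which(m[, 2] == 1) - 1L, 30:44)

  disj <- encodeRegionChannels(list(proto = c(0L, 5L), pam = c(5L, 8L),
                                    pbs = c(10L, 12L), rt = c(20L, 30L)), 40L)
  expect_identical(which(disj[, 1] == 1) - 1L, c(0:7, 10:11))
  expect_identical(which(disj[, 2] == 1) - 1L, 20:29)

  full <- encodeRegionChannels(list(proto = c(0L, 2L), pam = c(2L, 3L),
                                    pbs = c(3L, 4L), rt = c(0L, 10L)), 10L)
  expect_true(all(full[, 2] == 1))

  expect_error(encodeRegionChannels(list(proto = c(0L, 20L), pam = c(20L, 23L),
                                         pbs = c(30L, 43L), rt = c(30L, 100L)),
                                    99L),
               "rt", class = "primenet_validation_error")
})

test_that("epigenetic channels carry the annotation as 0/1", {
  ann <- list(dnase = rep(FALSE, 5), methyl = rep(FALSE, 5))
  expect_true(all(encodeEpigeneticChannels(ann) == 0))
  ann$dnase[4] <- TRUE
  m <- encodeEpigeneticChannels(ann)
  expect_equal(which(m[, 1] == 1), 4L)
  expect_true(all(m[, 2] == 0))
  ann$methyl[] <- TRUE
  expect_true(all(encodeEpigeneticChannels(ann)[, 2] == 1))
})

test_that("annotation transfer follows the edit correspondence", {
  ann <- list(dnase = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
              methyl = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  # substitution: equal lengths, annotation unchanged
  expect_identical(transferAnnotationToEdit(ann, "ACGTAC", "ACCTAC"), ann)
  # 2-nt insertion after position 2: inserted bases FALSE, flanks copied
  tr <- transferAnnotationToEdit(ann, "ACGTAC", "ACGGTTAC")
  expect_identical(tr$dnase, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE,
                               FALSE, TRUE))
  # hand-built: wild prefix ACG (pos 1-3), suffix TAC -> edited positions
  # 4-5 are the insertion
  expect_identical(tr$methyl, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                                TRUE, TRUE))
  # deletion of positions 3-4: vector shortens, flanks copied
  td <- transferAnnotationToEdit(ann, "ACGTAC", "ACAC")
  expect_identical(td$dnase, c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(td$methyl, c(FALSE, TRUE, TRUE, TRUE))
  expect_error(transferAnnotationToEdit(list(dnase = TRUE, methyl = TRUE),
                                        "ACGT", "ACGT"),
               class = "primenet_validation_error")
})

test_that("pseudo-images have the declared shape, padding and symmetry", {
  sim <- tinySim()
  df <- sim$targets@records
  ann <- suppressMessages(buildAnnotations(sim$targets, sim$dnase,
                                           sim$methyl))[[1]]
  img <- buildPseudoImage(df$wild_seq[1], df$edited_seq[1],
                          primenet:::spansOfRow(df, 1), ann)
  expect_identical(dim(img), c(128L, 8L, 2L))
  lw <- nchar(df$wild_seq[1])
  expect_true(all(img[(lw + 1):128, , 1] == 0))   # padding carries no signal
  expect_true(all(img %in% c(0, 1)))

  # wild == edited with identical spans: the two slices coincide
  spans <- primenet:::spansOfRow(df, 1)
  img2 <- buildPseudoImage(df$wild_seq[1], df$wild_seq[1], spans, ann)
  expect_identical(img2[, , 1], img2[, , 2])

  expect_error(buildPseudoImage(strrep("A", 129), strrep("A", 129),
                                spans, NULL),
               "frame", class = "primenet_validation_error")
})

test_that("channel sums are conserved and encoding is injective", {
  sim <- tinySim()
  pis <- tinyImages()
  eff <- pis@effLengths
  for (i in seq_len(length(pis))) {
    for (s in 1:2) {
      base <- pis@images[, 1:4, s, i]
      expect_equal(sum(base), eff[i, s])          # one-hot per position
      expect_true(all(rowSums(base[seq_len(eff[i, s]), , drop = FALSE]) == 1))
    }
  }
  # distinct inputs give distinct images
  keys <- apply(pis@images, 4, function(a) paste(which(a == 1), collapse = ","))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("dataset encoding preserves order and isolates failures", {
  sim <- tinySim()
  pis <- tinyImages()
  expect_identical(recordIds(pis), recordIds(sim$targets))
  expect_equal(length(pis), 32L)
  # deterministic: rebuilding gives bit-identical images
  pis2 <- suppressMessages(buildPseudoImages(sim$targets, sim$dnase,
                                             sim$methyl))
  expect_identical(pis@images, pis2@images)

  # corrupt one record's spans after validation to force an encode failure
  ts <- sim$targets
  ts@records$rt_end[3] <- 200L
  broken <- suppressMessages(buildPseudoImages(ts, sim$dnase, sim$methyl))
  expect_equal(length(broken), 31L)
  expect_match(attr(broken, "failures"), "rec00003")
  expect_identical(recordIds(broken), setdiff(recordIds(ts), "rec00003"))
})
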