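# Synthetic pegRNA-target datasets with planted epigenetic and sequence
# effects, emitting the same formats the real pipeline consumes (sample
# table, two BED tracks) so every module is exercisable offline.

#' Simulation configuration
#'
#' One synthetic chromosome carries non-overlapping 99-nt target windows.
#' Accessibility follows a block model (alternating open/closed runs with
#' geometric lengths, a fraction `acc_coverage` of blocks open);
#' methylation is a Bernoulli draw at each CpG cytosine.  Each record's
#' latent valid-edit score is
#' `s = b0 + beta_acc * accFrac(proto+PAM) - beta_meth * methFrac(proto+PAM)
#'  + beta_gc * GC(PBS) + N(0, noise_sd)`,
#' mapped to an expected triple by a 3-way logistic (softmax over logits
#' `(s, -s, erroneous_logit)`) scaled to 100; observed triples are
#' Dirichlet draws around the expectation with the given concentration.
#'
#' @param n_records number of records.
#' @param seq_length target window length (<= 128), 99.
#' @param proto_len,pam_len protospacer and PAM lengths (20 and 3).
#' @param pbs_range,rt_range sampled PBS / RT template lengths (defaults
#'   centred on a 13-nt PBS and 15-nt RT extension).
#' @param acc_block_mean mean accessibility block length (bp).
#' @param acc_coverage fraction of the genome accessible.
#' @param cpg_meth_prob methylation probability per CpG cytosine.
#' @param cpg_enrich factor favouring G after C during sequence sampling
#'   (1 = uniform ACGT).
#' @param b0,beta_acc,beta_meth,beta_gc,erroneous_logit latent-score
#'   coefficients.
#' @param noise_sd latent Gaussian noise.
#' @param concentration Dirichlet concentration of observed triples.
#' @param indel_frac fraction of records whose edit is a small indel
#'   rather than a substitution.
#' @param minus_strand_frac fraction of records anchored on the minus
#'   strand.
#' @param seed dataset seed.
#' @export
simulationConfig <- function(n_records = 1000L, seq_length = 99L,
                             proto_len = 20L, pam_len = 3L,
                             pbs_range = c(8L, 17L), rt_range = c(10L, 30L),
                             acc_block_mean = 300, acc_coverage = 0.35,
                             cpg_meth_prob = 0.3, cpg_enrich = 1.5,
                             b0 = 0, beta_acc = 2, beta_meth = 1,
                             beta_gc = 1, erroneous_logit = -1,
                             noise_sd = 0.5, concentration = 200,
                             indel_frac = 0.15, minus_strand_frac = 0.15,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$seq_length <= 128L, cfg$acc_coverage >= 0,
            cfg$acc_coverage <= 1, cfg$concentration > 0)
  # canonical layout: protospacer starts at 10, PAM follows, nick after
  # protospacer position 17; PBS ends at the nick, RT starts there
  cfg$proto_start <- 10L
  nick <- cfg$proto_start + 17L
  if (nick + max(cfg$rt_range) > cfg$seq_length ||
      nick - max(cfg$pbs_range) < 0L)
    stop("region layout infeasible for seq_length ", cfg$seq_length)
  cfg
}

# n sequences of length len, sampled base by base with optional CpG
# enrichment (G favoured after C); vectorized across records.
sampleSeqs <- function(n, len, cpg_enrich) {
  base <- c("A", "C", "G", "T")
  m <- matrix("", n, len)
  m[, 1] <- sample(base, n, replace = TRUE)
  wC <- c(1, 1, cpg_enrich, 1); wC <- wC / sum(wC)
  for (i in 2:len) {
    afterC <- m[, i - 1] == "C"
    draw <- sample(base, n, replace = TRUE)
    if (any(afterC))
      draw[afterC] <- sample(base, sum(afterC), replace = TRUE, prob = wC)
    m[, i] <- draw
  }
  apply(m, 1, paste, collapse = "")
}

softmaxTriple <- function(s, erroneous_logit) {
  z <- c(s, -s, erroneous_logit)
  e <- exp(z - max(z))
  100 * e / sum(e)
}

#' Closed-form expected outcome triple
#'
#' Deterministic expectation (no latent noise, no Dirichlet dispersion)
#' from the planted features; used for parameter-recovery checks.
#'
#' @param acc_frac accessible fraction of protospacer+PAM.
#' @param meth_frac methylated fraction of protospacer+PAM.
#' @param gc_pbs GC fraction of the PBS.
#' @param config a [simulationConfig()].
#' @return named numeric triple (valid, unedited, erroneous), summing
#'   to 100.
#' @export
oracleExpectedTriple <- function(acc_frac, meth_frac, gc_pbs, config) {
  s <- config$b0 + config$beta_acc * acc_frac -
    config$beta_meth * meth_frac + config$beta_gc * gc_pbs
  stats::setNames(softmaxTriple(s, config$erroneous_logit), headNames())
}

#' Simulate a full dataset
#'
#' @param config a [simulationConfig()].
#' @return list with `targets` ([TargetSet-class]), `dnase` and `methyl`
#'   (`GRanges` tracks on the synthetic chromosome "chrS"), and `truth`
#'   (data.frame of latent scores, expected triples and planted feature
#'   values per record).
#' @export
simulateDataset <- function(config = simulationConfig()) {
  cfg <- config
  withSeed(cfg$seed, {
    n <- cfg$n_records
    L <- cfg$seq_length
    spacing <- 200L
    starts <- (seq_len(n) - 1L) * spacing
    genomeLen <- n * spacing + 1000L

    # accessibility block model over the synthetic chromosome
    openBase <- logical(genomeLen)   # 1-based genome coordinate view
    pos <- 0L
    repeat {
      len <- max(1L, stats::rgeom(1, 1 / cfg$acc_block_mean) + 1L)
      if (stats::runif(1) < cfg$acc_coverage)
        openBase[(pos + 1L):min(pos + len, genomeLen)] <- TRUE
      pos <- pos + len
      if (pos >= genomeLen) break
    }
    rle_open <- rle(openBase)
    ends <- cumsum(rle_open$lengths)
    ob <- rle_open$values
    dnase <- if (any(ob)) GenomicRanges::GRanges("chrS", IRanges::IRanges(
      start = (ends - rle_open$lengths + 1L)[ob], end = ends[ob]))
      else GenomicRanges::GRanges()

    proto <- c(cfg$proto_start, cfg$proto_start + cfg$proto_len)
    pam <- c(proto[2], proto[2] + cfg$pam_len)
    nick <- cfg$proto_start + 17L
    ppIdx <- (proto[1] + 1L):pam[2]  # protospacer+PAM, 1-based window pos

    wild <- sampleSeqs(n, L, cfg$cpg_enrich)
    strand <- ifelse(stats::runif(n) < cfg$minus_strand_frac, "-", "+")
    pbs_len <- sample(cfg$pbs_range[1]:cfg$pbs_range[2], n, replace = TRUE)
    rt_len <- sample(cfg$rt_range[1]:cfg$rt_range[2], n, replace = TRUE)

    edited <- character(n)
    acc_frac <- meth_frac <- gc_pbs <- numeric(n)
    obs <- matrix(0, n, 3L)
    expected <- matrix(0, n, 3L)
    latent <- numeric(n)
    methPos <- integer(0)

    for (i in seq_len(n)) {
      wchars <- strsplit(wild[i], "", fixed = TRUE)[[1]]
      edit_at <- nick + sample.int(min(4L, rt_len[i]), 1L) - 1L  # 0-based
      u <- stats::runif(1)
      if (u < 1 - cfg$indel_frac) {            # substitution
        wchars2 <- wchars
        wchars2[edit_at + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                                wchars[edit_at + 1L]), 1L)
        edited[i] <- paste(wchars2, collapse = "")
      } else if (u < 1 - cfg$indel_frac / 2) { # 1-2 nt insertion
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:2, 1L),
                            replace = TRUE), collapse = "")
        edited[i] <- paste0(substr(wild[i], 1, edit_at + 1L), ins,
                            substr(wild[i], edit_at + 2L, L))
      } else {                                 # 1-2 nt deletion
        dl <- sample(1:2, 1L)
        edited[i] <- paste0(substr(wild[i], 1, edit_at),
                            substr(wild[i], edit_at + dl + 1L, L))
      }

      # window readout of the accessibility blocks, 5'->3' on the wild seq
      gwin <- starts[i] + seq_len(L)          # 1-based genome positions
      acc <- openBase[gwin]
      if (strand[i] == "-") acc <- rev(acc)

      cpgC <- which(wchars[-L] == "C" & wchars[-1] == "G")
      meth <- rep(FALSE, L)
      if (length(cpgC)) {
        called <- cpgC[stats::runif(length(cpgC)) < cfg$cpg_meth_prob]
        meth[called] <- TRUE
        if (length(called)) {
          gpos <- if (strand[i] == "+") starts[i] + called - 1L
                  else starts[i] + L - called
          methPos <- c(methPos, gpos)
        }
      }

      acc_frac[i] <- mean(acc[ppIdx])
      meth_frac[i] <- mean(meth[ppIdx])
      pbsChars <- wchars[(nick - pbs_len[i] + 1L):nick]
      gc_pbs[i] <- mean(pbsChars %in% c("G", "C"))
      s <- cfg$b0 + cfg$beta_acc * acc_frac[i] -
        cfg$beta_meth * meth_frac[i] + cfg$beta_gc * gc_pbs[i] +
        stats::rnorm(1, 0, cfg$noise_sd)
      latent[i] <- s
      expected[i, ] <- softmaxTriple(s, cfg$erroneous_logit)
      gam <- stats::rgamma(3L, shape = cfg$concentration * expected[i, ] / 100)
      obs[i, ] <- 100 * gam / sum(gam)
    }

    methyl <- if (length(methPos))
      GenomicRanges::reduce(GenomicRanges::sort(GenomicRanges::GRanges(
        "chrS", IRanges::IRanges(methPos + 1L, methPos + 1L))))
      else GenomicRanges::GRanges()

    ids <- sprintf("rec%05d", seq_len(n))
    df <- data.frame(
      record_id = ids, wild_seq = wild, edited_seq = edited,
      proto_start = proto[1], proto_end = proto[2],
      pam_start = pam[1], pam_end = pam[2],
      pbs_start = nick - pbs_len, pbs_end = nick,
      rt_start = nick, rt_end = nick + rt_len,
      chrom = "chrS", gstart = starts, strand = strand,
      valid = obs[, 1], unedited = obs[, 2], erroneous = obs[, 3])
    truth <- data.frame(
      record_id = ids, latent = latent,
      expected_valid = expected[, 1], expected_unedited = expected[, 2],
      expected_erroneous = expected[, 3],
      acc_frac = acc_frac, meth_frac = meth_frac, gc_pbs = gc_pbs)
    list(targets = makeTargetSet(df), dnase = dnase, methyl = methyl,
         truth = truth, config = cfg)
  })
}

#' Canned deterministic fixtures
#'
#' `tiny` (32 records) for unit tests and documentation, `smoke`
#' (300 records) for pipeline smoke runs, `recovery` (5000 records with
#' strong planted effects: beta_acc = 2, low latent noise, tight
#' dispersion) for end-to-end parameter-recovery checks.
#'
#' @param name one of "tiny", "smoke", "recovery".
#' @return as [simulateDataset()].
#' @export
makeFixture <- function(name = c("tiny", "smoke", "recovery")) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = simulationConfig(n_records = 32L, seed = 101L),
    smoke = simulationConfig(n_records = 300L, seed = 102L),
    recovery = simulationConfig(n_records = 5000L, beta_acc = 2,
                                beta_meth = 1.5, beta_gc = 1,
                                noise_sd = 0.25, concentration = 300,
                                seed = 103L))
  simulateDataset(cfg)
}
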