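# Evaluation protocol: per-head correlations, 50%-threshold binarization
# with ROC/PR AUC, and Mann-Whitney U analyses of epigenetic groups.

#' Per-head rank and linear correlations
#'
#' Spearman (average ranks over ties) and Pearson (raw values) between
#' predicted and observed triples.  A head with zero variance in either
#' vector yields NA rather than an error.
#'
#' @param pred,obs numeric matrices (N, 3), columns
#'   valid/unedited/erroneous.
#' @return data.frame with head, spearman, pearson, n.
#' @export
correlations <- function(pred, obs) {
  stopifnot(nrow(pred) == nrow(obs), nrow(pred) >= 3L,
            all(is.finite(pred)), all(is.finite(obs)))
  out <- lapply(1:3, function(j) {
    p <- pred[, j]; o <- obs[, j]
    data.frame(head = headNames()[j],
               spearman = spearmanSafe(p, o),
               pearson = if (stats::sd(p) == 0 || stats::sd(o) == 0) NA_real_
                         else stats::cor(p, o),
               n = length(p))
  })
  do.call(rbind, out)
}

#' Binarize efficiencies at a percent threshold
#'
#' Strictly-greater comparison: a value of exactly 50 is a negative case.
#'
#' @param values percents in \[0, 100\].
#' @param threshold decision threshold, 50 by default.
#' @return logical vector.
#' @export
binarizeAtThreshold <- function(values, threshold = 50) {
  stopifnot(all(values >= 0 & values <= 100))
  values > threshold
}

#' ROC and precision-recall curves with AUC
#'
#' AUROC is computed through the rank (Mann-Whitney) identity
#' U / (n1 * n2); AUPRC by step interpolation of the precision-recall
#' sweep.  Curve points are returned for external plotting.
#'
#' @param scores continuous predictions.
#' @param labels logical (or 0/1) ground-truth classes; both classes must
#'   be present, otherwise AUCs are NA with a warning.
#' @return list with `auroc`, `auprc`, `roc` (data.frame fpr/tpr) and
#'   `pr` (data.frame recall/precision).
#' @export
rocPrAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n2 <- sum(!labels)
  if (n1 == 0L || n2 == 0L) {
    warning("single-class labels: AUC undefined")
    return(list(auroc = NA_real_, auprc = NA_real_, roc = NULL, pr = NULL))
  }
  r <- rank(scores)
  U <- sum(r[labels]) - n1 * (n1 + 1) / 2
  auroc <- U / (n1 * n2)

  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  keep <- c(diff(sc) != 0, TRUE)  # one point per distinct threshold
  tp <- tp[keep]; fp <- fp[keep]
  roc <- data.frame(fpr = c(0, fp / n2), tpr = c(0, tp / n1))
  prec <- tp / (tp + fp); rec <- tp / n1
  pr <- data.frame(recall = c(0, rec), precision = c(1, prec))
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, auprc = auprc, roc = roc, pr = pr)
}

#' Full per-head metrics report
#'
#' Correlations plus ROC/PR AUC after binarizing the *observed* values at
#' the threshold; the continuous predicted efficiency serves as the
#' classifier score (binarizing the score too would degenerate the curve).
#'
#' @param pred,obs numeric (N, 3) matrices.
#' @param threshold percent threshold for the positive class, 50.
#' @return data.frame with head, spearman, pearson, auroc, auprc,
#'   threshold, n.
#' @export
evaluateModel <- function(pred, obs, threshold = 50) {
  co <- correlations(pred, obs)
  auc <- lapply(1:3, function(j) {
    lab <- binarizeAtThreshold(obs[, j], threshold)
    if (all(lab) || !any(lab))
      return(data.frame(auroc = NA_real_, auprc = NA_real_))
    a <- rocPrAuc(pred[, j], lab)
    data.frame(auroc = a$auroc, auprc = a$auprc)
  })
  cbind(co[, c("head", "spearman", "pearson")], do.call(rbind, auc),
        threshold = threshold, n = co$n)
}

#' Group records by epigenetic state
#'
#' Openness: a record is "completely open" iff every position of its wild
#' sequence is DNase accessible, else "presence of closure".  Methylation:
#' "with methylation" iff at least one methylated position, else
#' "without methylation".  Records lacking an annotation are excluded and
#' counted in the `"excluded"` attribute.
#'
#' @param annotations named list of annotations ([buildAnnotations()]).
#' @return data.frame with record_id, openness, methylation (factors).
#' @export
epigeneticGroupSplit <- function(annotations) {
  ok <- !vapply(annotations, is.null, TRUE)
  rows <- lapply(names(annotations)[ok], function(id) {
    a <- annotations[[id]]
    data.frame(record_id = id,
               openness = if (all(a$dnase)) "completely open"
                          else "presence of closure",
               methylation = if (any(a$methyl)) "with methylation"
                             else "without methylation")
  })
  out <- do.call(rbind, rows)
  out$openness <- factor(out$openness,
                         c("completely open", "presence of closure"))
  out$methylation <- factor(out$methylation,
                            c("with methylation", "without methylation"))
  attr(out, "excluded") <- sum(!ok)
  out
}

# Exact permutation distribution of the group-A rank sum under tied ranks,
# via dynamic programming over the multiset of (doubled, integer) ranks.
# Equivalent to enumerating all choose(n, n1) group assignments.
rankSumDistribution <- function(r2, n1) {
  n <- length(r2)
  maxS <- sum(r2)
  # dp[j + 1, s + 1] = number of ways to pick j ranks summing to s
  dp <- matrix(0, n1 + 1L, maxS + 1L)
  dp[1L, 1L] <- 1
  for (item in r2) {
    jmax <- n1
    for (j in jmax:1) {
      nzs <- which(dp[j, ] > 0)
      if (length(nzs))
        dp[j + 1L, nzs + item] <- dp[j + 1L, nzs + item] + dp[j, nzs]
    }
  }
  dp[n1 + 1L, ]
}

#' Mann-Whitney U test
#'
#' U (for group A) counts pairs where a > b plus half the ties.  The
#' two-sided p-value is exact - the full permutation distribution of U,
#' tie-aware, computed by dynamic programming - whenever
#' n1 * n2 <= `exactLimit`; larger samples use the normal approximation
#' with tie and continuity corrections.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exactLimit switch-over product of group sizes, 400.
#' @return list with `U`, `p`, `n1`, `n2`, `method`.
#' @export
mannWhitneyU <- function(a, b, exactLimit = 400) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 * n2 <= exactLimit) {
    # run the DP on the smaller group (U_A + U_B = n1 n2, so the two-sided
    # p is the same either way) to keep the table small
    r2 <- as.integer(round(2 * r))
    small <- if (n1 <= n2) seq_len(n1) else n1 + seq_len(n2)
    nS <- min(n1, n2)
    dist <- rankSumDistribution(r2, nS)
    u2 <- as.integer(round(2 * sum(r[small]))) - nS * (nS + 1L)  # doubled U
    center <- n1 * n2                    # doubled n1 n2 / 2
    devs <- abs(seq_along(dist) - 1L - nS * (nS + 1L) - center)
    p <- sum(dist[devs >= abs(u2 - center)]) / choose(n1 + n2, nS)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(r)
    tiecor <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tiecor))
    mu <- n1 * n2 / 2
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = min(1, p), n1 = n1, n2 = n2, method = method)
}

#' Tidy source data for violin plots
#'
#' Long-format table (group label, head, efficiency) feeding external
#' violin/box plotting of efficiency by epigenetic group.
#'
#' @param values numeric (N, 3) efficiency matrix.
#' @param groups factor of length N.
#' @return data.frame with columns group, head, efficiency.
#' @export
violinPlotData <- function(values, groups) {
  stopifnot(nrow(values) == length(groups))
  do.call(rbind, lapply(1:3, function(j)
    data.frame(group = as.character(groups), head = headNames()[j],
               efficiency = values[, j])))
}

#' Mann-Whitney comparison of epigenetic groups, per head
#'
#' For each of the three efficiencies, tests whether the two groups (e.g.
#' completely open vs presence of closure) differ in distribution.
#'
#' @param values numeric (N, 3) efficiency matrix.
#' @param groups factor of length N with exactly 2 levels.
#' @return data.frame with head, group sizes, U, p.
#' @export
groupComparison <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) == 2L, nrow(values) == length(groups))
  lv <- levels(groups)
  do.call(rbind, lapply(1:3, function(j) {
    res <- mannWhitneyU(values[groups == lv[1], j], values[groups == lv[2], j])
    data.frame(head = headNames()[j], groupA = lv[1], groupB = lv[2],
               nA = res$n1, nB = res$n2, U = res$U, p = res$p,
               method = res$method)
  }))
}
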