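# Gradient-based interpretability: integrated gradients, gradient-ascent
# optimization of the epigenetic channels, and attention-map extraction.

headIndex <- function(head) {
  i <- match(match.arg(head, headNames()), headNames())
  i
}

# Riemann-midpoint path integral shared by every attribution target:
# evaluates the gradient at m points b + (i - 1/2)/m (x - b) in one
# batched call (gradBatchFn maps an (L, m, 16) folded batch to its
# per-input gradients), averages them, and scales by (x - b).  For a
# linear map the constant gradient makes the result w * x exactly.
igMidpoint <- function(gradBatchFn, image, baseline, steps) {
  diffim <- image - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  xw <- foldImages(array(baseline, c(dim(image), 1L))[, , ,
                                                      rep(1L, steps),
                                                      drop = FALSE])
  dirs <- foldImages(array(diffim, c(dim(diffim), 1L)))[, 1L, ]
  for (s in seq_len(steps)) xw[, s, ] <- xw[, s, ] + alphas[s] * dirs
  g <- gradBatchFn(xw)
  gbar <- apply(g, c(1L, 3L), mean)              # (L, 16)
  array(gbar, c(dim(image)[1], 8L, 2L)) * diffim
}

#' Integrated-gradients attribution for one pseudo-image
#'
#' Path integral of the model gradient along the straight line from a
#' baseline to the input, scaled by (input - baseline); approximated by
#' the Riemann midpoint rule with `steps` points, all evaluated in a
#' single batched forward/backward pass.  By the completeness property the
#' attributions sum to F(input) - F(baseline) (to within the integration
#' error; about 1% relative at 256 steps on smooth models).
#'
#' @param model a [PrimeNet-class]
#' @param image one pseudo-image: (L, 8, 2) array (or a length-1
#'   [PseudoImageSet-class]).
#' @param head which output to explain: "valid", "unedited", "erroneous".
#' @param baseline baseline image, all-zeros by default.
#' @param steps number of integration points m (>= 16), 256 by default.
#' @return an [AttributionMap-class]
#' @export
integratedGradients <- function(model, image, head = "valid",
                                baseline = NULL, steps = 256L) {
  if (is(image, "PseudoImageSet")) image <- image@images[, , , 1L]
  stopifnot(length(dim(image)) == 3L, steps >= 16L)
  if (is.null(baseline)) baseline <- array(0, dim(image))
  stopifnot(identical(dim(baseline), dim(image)))
  j <- headIndex(head)
  cfg <- model@config
  gradBatchFn <- function(xw) {
    m <- dim(xw)[2]
    fw <- netForward(model@params, cfg, xw, keepCache = TRUE)
    dOut <- matrix(0, m, 3L); dOut[, j] <- 1
    bw <- netBackward(model@params, cfg, fw$cache, dOut,
                      wantInputGrad = TRUE)
    if (!all(is.finite(bw$dX)))
      stop("non-finite gradients in attribution pass")
    bw$dX
  }
  scores <- igMidpoint(gradBatchFn, image, baseline, steps)
  new("AttributionMap", scores = scores, head = headNames()[j],
      baseline = if (all(baseline == 0)) "zeros" else "custom",
      steps = as.integer(steps))
}

#' Select the top-n records by a head's efficiency
#'
#' Descending sort on the chosen head's observed value, ties broken by
#' record_id so the selection is deterministic.
#'
#' @param x a [TargetSet-class] or [PseudoImageSet-class] with observed
#'   triples.
#' @param head which efficiency to rank by.
#' @param n number of records to keep (200 by default); if more than
#'   available, all are returned with a warning.
#' @return record ids of the selected selection, best first.
#' @export
selectTopSequences <- function(x, head = "valid", n = 200L) {
  j <- headIndex(head)
  obs <- observedTriples(x)
  ids <- rownames(obs)
  keep <- !is.na(obs[, j])
  ids <- ids[keep]; v <- obs[keep, j]
  if (n > length(ids)) {
    warning("requested ", n, " sequences but only ", length(ids),
            " available; returning all")
    n <- length(ids)
  }
  ids[order(-v, ids)][seq_len(n)]
}

#' Gradient-ascent optimization of an epigenetic channel
#'
#' Starting from the supplied seed images (typically the top-n by observed
#' efficiency, see [selectTopSequences()]), iteratively ascends the target
#' head's output with respect to the chosen channel only - the gradients
#' of every other channel are masked to zero, so those channels stay
#' bit-identical - clamping the channel to \[0, 1\] after each step.  The
#' final channel values are averaged across images into one per-position
#' profile for the wild and edited slices.
#'
#' @param model a [PrimeNet-class]
#' @param seedImages a [PseudoImageSet-class] (or (L, 8, 2, N) array).
#' @param channel 0-based pseudo-image channel to optimize: 4 (DNase) or
#'   5 (methylation).
#' @param head output to maximize.
#' @param steps ascent iterations, 200.
#' @param stepSize ascent step, 0.01.
#' @return list with `profile` (L x 2 matrix: wild, edited columns),
#'   `images` (the optimized image array) and the settings used.
#' @export
optimizeEpigeneticChannel <- function(model, seedImages, channel = 4L,
                                      head = "valid", steps = 200L,
                                      stepSize = 0.01) {
  stopifnot(channel %in% c(4L, 5L), stepSize > 0)
  arr <- if (is(seedImages, "PseudoImageSet")) seedImages@images else seedImages
  if (length(dim(arr)) == 3L) arr <- array(arr, c(dim(arr), 1L))
  if (dim(arr)[4] == 0L) stop("empty seed-image set")
  j <- headIndex(head)
  cfg <- model@config
  X <- foldImages(arr)
  n <- dim(X)[2]
  chIdx <- channel + 1L + c(0L, 8L)   # folded indices: wild and edited slice
  dOut <- matrix(0, n, 3L); dOut[, j] <- 1
  for (s in seq_len(steps)) {
    fw <- netForward(model@params, cfg, X, keepCache = TRUE)
    bw <- netBackward(model@params, cfg, fw$cache, dOut, wantInputGrad = TRUE)
    g <- bw$dX[, , chIdx, drop = FALSE]          # gradient masking
    X[, , chIdx] <- pmin(1, pmax(0, X[, , chIdx] + stepSize * g))
  }
  prof <- cbind(wild = rowMeans(array(X[, , chIdx[1]], dim(X)[1:2])),
                edited = rowMeans(array(X[, , chIdx[2]], dim(X)[1:2])))
  d <- dim(arr)
  out <- array(aperm(X, c(1L, 3L, 2L)), c(d[1], 8L, 2L, n))
  list(profile = prof, images = out, channel = channel,
       head = headNames()[j], steps = steps, step_size = stepSize)
}

#' Extract averaged conv-attention maps
#'
#' Runs forward passes with attention capture and averages the spatial
#' weight maps of every conv-attention site (input stage and after each
#' trunk conv layer) over the images, aligned to the 128-position frame.
#'
#' @param model a [PrimeNet-class] with conv-attention enabled.
#' @param images a [PseudoImageSet-class] or (L, 8, 2, N) array.
#' @return named list of length-L numeric vectors (stages ca_in, ca1, ca2).
#' @export
extractAttentionMaps <- function(model, images) {
  if (!model@config$conv_attention_enabled)
    stop("conv-attention is disabled in this model configuration")
  arr <- if (is(images, "PseudoImageSet")) images@images else images
  if (length(dim(arr)) == 3L) arr <- array(arr, c(dim(arr), 1L))
  X <- foldImages(arr)
  fw <- netForward(model@params, model@config, X)
  lapply(fw$attention, rowMeans)
}
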