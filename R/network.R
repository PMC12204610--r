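# The PrimeNet architecture and its gradients.
#
# All feature maps are stored as (L positions, N samples, C channels)
# arrays; the wild/edited axis of the pseudo-image is folded into the
# channel axis before entry (8 x 2 -> 16 channels), so every convolution
# runs along the length axis with zero "same" padding and the seq extent of
# the printed MixConv kernels (1x2, 3x2, 9x2) is consumed as input
# channels.  Convolutions are evaluated as sums of shifted GEMMs, and every
# layer has a hand-written backward pass, which the test suite verifies
# against finite differences.

#' Architecture configuration
#'
#' Defaults follow the printed design: three MixConv kernel scales
#' (length extents 1, 3, 9; each branch spanning both sequences), channel
#' attention after MixConv, 1x1 compression, two further conv layers each
#' followed by spatial conv-attention (kernel 5, sigmoid), and a
#' shared-trunk multibranch head emitting the three efficiencies through a
#' sigmoid scaled to \[0, 100\].  Channel widths and trunk/branch depths
#' are tunable defaults (see [tuneHyperparameters()]), not fixed by the
#' architecture.
#'
#' @param length frame length (positions), 128.
#' @param mixconv_kernels integer length-extents of the MixConv branches.
#' @param mixconv_out_channels output channels per MixConv branch.
#' @param compress_channels channels after the 1x1 compression.
#' @param conv_channels widths of the two trunk conv layers.
#' @param conv_kernel kernel length of the trunk conv layers (odd).
#' @param conv_attention_kernel spatial-attention kernel (odd), 5.
#' @param conv_attention_activation "sigmoid" (independent per-position
#'   weights) or "softmax" (weights summing to 1 over positions).
#' @param channel_attention_enabled,conv_attention_enabled module switches.
#' @param channel_attention_kernel kernel of the channel-axis conv (odd).
#' @param trunk_widths widths of the shared fully-connected trunk.
#' @param branch_widths widths of each head-exclusive branch.
#' @param output_scale scale of the sigmoid output (percent).
#' @return validated config list.
#' @export
modelConfig <- function(length = 128L,
                        mixconv_kernels = c(1L, 3L, 9L),
                        mixconv_out_channels = 16L,
                        compress_channels = 32L,
                        conv_channels = c(32L, 32L),
                        conv_kernel = 3L,
                        conv_attention_kernel = 5L,
                        conv_attention_activation = c("sigmoid", "softmax"),
                        channel_attention_enabled = TRUE,
                        conv_attention_enabled = TRUE,
                        channel_attention_kernel = 3L,
                        trunk_widths = 256L,
                        branch_widths = 64L,
                        output_scale = 100) {
  conv_attention_activation <- match.arg(conv_attention_activation)
  cfg <- list(length = as.integer(length), in_channels = 8L, n_seq = 2L,
              mixconv_kernels = as.integer(mixconv_kernels),
              mixconv_out_channels = as.integer(mixconv_out_channels),
              compress_channels = as.integer(compress_channels),
              conv_channels = as.integer(conv_channels),
              conv_kernel = as.integer(conv_kernel),
              conv_attention_kernel = as.integer(conv_attention_kernel),
              conv_attention_activation = conv_attention_activation,
              channel_attention_enabled = isTRUE(channel_attention_enabled),
              conv_attention_enabled = isTRUE(conv_attention_enabled),
              channel_attention_kernel = as.integer(channel_attention_kernel),
              trunk_widths = as.integer(trunk_widths),
              branch_widths = as.integer(branch_widths),
              output_scale = as.numeric(output_scale))
  if (any(cfg$mixconv_kernels < 1L)) stop("MixConv extents must be >= 1")
  if (any(cfg$mixconv_kernels > cfg$length))
    stop("MixConv kernel extent exceeds frame length")
  if (cfg$conv_attention_kernel %% 2L == 0L)
    stop("conv-attention kernel must be odd")
  if (cfg$conv_kernel %% 2L == 0L) stop("conv kernel must be odd")
  if (cfg$channel_attention_kernel %% 2L == 0L)
    stop("channel-attention kernel must be odd")
  if (length(cfg$conv_channels) != 2L) stop("exactly two trunk conv layers")
  cfg
}

# ---- feature-map primitives -------------------------------------------

asMat <- function(X) { d <- dim(X); dim(X) <- c(d[1] * d[2], d[3]); X }

# 1-D convolution along the length axis ("same" zero padding, odd K):
# y[l] = b + sum_k x[l + k - mid] W_k, evaluated as a single GEMM against
# an im2col matrix (rows = (position, sample), column blocks = kernel
# taps).  The column matrix is cached in the forward result and reused by
# the backward pass, so shifted input copies are built once per layer.

im2col <- function(X, K) {
  d <- dim(X); L <- d[1]; N <- d[2]; Cin <- d[3]
  mid <- (K + 1L) %/% 2L
  if (K == 1L) { Xc <- X; dim(Xc) <- c(L * N, Cin); return(Xc) }
  Xc <- array(0, c(L, N, Cin, K))
  for (k in seq_len(K)) {
    o <- k - mid
    lr <- max(1L, 1L - o):min(L, L - o)
    Xc[lr, , , k] <- X[lr + o, , , drop = FALSE]
  }
  dim(Xc) <- c(L * N, Cin * K)
  Xc
}

# stored W is (K, Cin, Cout); the GEMM wants rows ordered (cin, k)
wAsGemm <- function(W) {
  d <- dim(W)
  array(aperm(W, c(2L, 1L, 3L)), c(d[1] * d[2], d[3]))
}

convForward <- function(X, W, b, withCols = FALSE) {
  d <- dim(X); L <- d[1]; N <- d[2]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  Xc <- im2col(X, K)
  Y <- Xc %*% wAsGemm(W)
  Y <- Y + rep(b, each = L * N)
  dim(Y) <- c(L, N, Cout)
  if (withCols) list(Y = Y, cols = Xc, dimX = d) else Y
}

convBackwardCols <- function(dY, cols, dimX, W) {
  L <- dimX[1]; N <- dimX[2]; Cin <- dimX[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]; mid <- (K + 1L) %/% 2L
  dYm <- dY; dim(dYm) <- c(L * N, Cout)
  dWg <- crossprod(cols, dYm)                       # (Cin*K, Cout)
  dW <- aperm(array(dWg, c(Cin, K, Cout)), c(2L, 1L, 3L))
  G <- tcrossprod(dYm, wAsGemm(W))                  # (L*N, Cin*K)
  if (K == 1L) {
    dX <- G
    dim(dX) <- dimX
  } else {
    dim(G) <- c(L, N * Cin, K)
    dXv <- matrix(0, L, N * Cin)
    for (k in seq_len(K)) {
      o <- k - mid
      lr <- max(1L, 1L - o):min(L, L - o)
      dXv[lr + o, ] <- dXv[lr + o, ] + G[lr, , k]
    }
    dX <- dXv
    dim(dX) <- dimX
  }
  list(dW = dW, db = colSums(dYm), dX = dX)
}

convBackward <- function(dY, X, W) {
  convBackwardCols(dY, im2col(X, dim(W)[1]), dim(X), W)
}

reluForward <- function(X) X * (X > 0)

# Spatial conv-attention: per-position mean and max over channels (2 maps)
# -> conv of the configured kernel -> sigmoid (or softmax over positions)
# -> multiplicative gate broadcast over channels.
convAttentionForward <- function(X, W, b, activation) {
  d <- dim(X); L <- d[1]; N <- d[2]; C <- d[3]
  Xm <- asMat(X)
  mn <- rowMeans(Xm)
  amx <- max.col(Xm, ties.method = "first")
  mx <- Xm[cbind(seq_len(L * N), amx)]
  G <- array(c(mn, mx), c(L, N, 2L))
  zc <- convForward(G, W, b, withCols = TRUE)
  zm <- array(zc$Y, c(L, N))
  if (activation == "sigmoid") {
    a <- sigmoid(zm)
  } else {
    e <- exp(zm - rep(apply(zm, 2L, max), each = L))
    a <- e / rep(colSums(e), each = L)
  }
  Y <- X * as.vector(a)          # recycles the (L, N) map over channels
  list(Y = Y, a = a, cols = zc$cols, dimG = dim(G), amx = amx)
}

convAttentionBackward <- function(dY, X, W, cache, activation) {
  d <- dim(X); L <- d[1]; N <- d[2]; C <- d[3]
  a <- cache$a
  dX <- dY * as.vector(a)
  da <- array(rowSums(asMat(dY * X)), c(L, N))
  if (activation == "sigmoid") {
    dz <- da * a * (1 - a)
  } else {
    dz <- a * (da - rep(colSums(a * da), each = L))
  }
  cb <- convBackwardCols(array(dz, c(L, N, 1L)), cache$cols, cache$dimG, W)
  dmn <- as.vector(cb$dX[, , 1L])
  dmx <- as.vector(cb$dX[, , 2L])
  dX <- dX + (dmn / C)                        # mean path, recycled over C
  idx <- seq_len(L * N) + (cache$amx - 1L) * (L * N)
  dX[idx] <- dX[idx] + dmx
  list(dX = dX, dW = cb$dW, db = cb$db)
}

# Efficient channel attention: global average pool over positions ->
# 1-D conv across the channel axis -> sigmoid -> per-channel gate.
channelAttentionForward <- function(X, w, b, k) {
  d <- dim(X); L <- d[1]; N <- d[2]; C <- d[3]
  Xs <- X; dim(Xs) <- c(L, N * C)
  s <- matrix(colMeans(Xs), N, C)
  mid <- (k + 1L) %/% 2L
  z <- matrix(b, N, C)
  for (j in seq_len(k)) {
    o <- j - mid
    cs <- seq_len(C)[seq_len(C) + o >= 1L & seq_len(C) + o <= C]
    if (length(cs)) z[, cs] <- z[, cs] + w[j] * s[, cs + o, drop = FALSE]
  }
  a <- sigmoid(z)
  Y <- array(as.vector(X) * rep(as.vector(a), each = L), d)
  list(Y = Y, a = a, s = s)
}

channelAttentionBackward <- function(dY, X, w, k, cache) {
  d <- dim(X); L <- d[1]; N <- d[2]; C <- d[3]
  a <- cache$a; s <- cache$s
  av <- rep(as.vector(a), each = L)
  dX <- array(as.vector(dY) * av, d)
  v <- as.vector(dY) * as.vector(X); dim(v) <- c(L, N * C)
  da <- matrix(colSums(v), N, C)
  dz <- da * a * (1 - a)
  mid <- (k + 1L) %/% 2L
  dw <- numeric(k)
  ds <- matrix(0, N, C)
  for (j in seq_len(k)) {
    o <- j - mid
    cs <- seq_len(C)[seq_len(C) + o >= 1L & seq_len(C) + o <= C]
    if (length(cs)) {
      dw[j] <- sum(s[, cs + o, drop = FALSE] * dz[, cs, drop = FALSE])
      ds[, cs + o] <- ds[, cs + o] + w[j] * dz[, cs, drop = FALSE]
    }
  }
  dX <- dX + array(rep(as.vector(ds) / L, each = L), d)
  list(dX = dX, dw = dw, db = sum(dz))
}

flattenForward <- function(X) {
  d <- dim(X)
  t(array(aperm(X, c(1L, 3L, 2L)), c(d[1] * d[3], d[2])))
}

flattenBackward <- function(dH, d) {
  aperm(array(t(dH), c(d[1], d[3], d[2])), c(1L, 3L, 2L))
}

# ---- parameter bookkeeping --------------------------------------------

# Flat named list of parameter arrays; "<name>.W" entries are weights
# (orthogonally initialized), "<name>.b" biases (zero initialized).
paramTemplate <- function(cfg) {
  p <- list()
  cin <- cfg$in_channels * cfg$n_seq
  ak <- cfg$conv_attention_kernel
  if (cfg$conv_attention_enabled) {
    p[["ca_in.W"]] <- array(0, c(ak, 2L, 1L)); p[["ca_in.b"]] <- numeric(1)
  }
  for (i in seq_along(cfg$mixconv_kernels)) {
    p[[sprintf("mix%d.W", i)]] <-
      array(0, c(cfg$mixconv_kernels[i], cin, cfg$mixconv_out_channels))
    p[[sprintf("mix%d.b", i)]] <- numeric(cfg$mixconv_out_channels)
  }
  cmix <- length(cfg$mixconv_kernels) * cfg$mixconv_out_channels
  if (cfg$channel_attention_enabled) {
    p[["catt.W"]] <- numeric(cfg$channel_attention_kernel)
    p[["catt.b"]] <- numeric(1)
  }
  p[["comp.W"]] <- array(0, c(1L, cmix, cfg$compress_channels))
  p[["comp.b"]] <- numeric(cfg$compress_channels)
  cprev <- cfg$compress_channels
  for (i in 1:2) {
    p[[sprintf("conv%d.W", i)]] <-
      array(0, c(cfg$conv_kernel, cprev, cfg$conv_channels[i]))
    p[[sprintf("conv%d.b", i)]] <- numeric(cfg$conv_channels[i])
    if (cfg$conv_attention_enabled) {
      p[[sprintf("ca%d.W", i)]] <- array(0, c(ak, 2L, 1L))
      p[[sprintf("ca%d.b", i)]] <- numeric(1)
    }
    cprev <- cfg$conv_channels[i]
  }
  fprev <- cfg$length * cfg$conv_channels[2]
  for (i in seq_along(cfg$trunk_widths)) {
    p[[sprintf("trunk%d.W", i)]] <- matrix(0, fprev, cfg$trunk_widths[i])
    p[[sprintf("trunk%d.b", i)]] <- numeric(cfg$trunk_widths[i])
    fprev <- cfg$trunk_widths[i]
  }
  for (j in 1:3) {
    bprev <- fprev
    for (i in seq_along(cfg$branch_widths)) {
      p[[sprintf("br%dl%d.W", j, i)]] <- matrix(0, bprev, cfg$branch_widths[i])
      p[[sprintf("br%dl%d.b", j, i)]] <- numeric(cfg$branch_widths[i])
      bprev <- cfg$branch_widths[i]
    }
    p[[sprintf("br%dout.W", j)]] <- matrix(0, bprev, 1L)
    p[[sprintf("br%dout.b", j)]] <- numeric(1)
  }
  p
}

# ---- forward / backward -----------------------------------------------

# X: folded input (L, N, 16).  Returns out (N, 3) plus caches for the
# backward pass and, optionally, the attention maps.
netForward <- function(params, cfg, X, keepCache = FALSE) {
  cache <- list(Xin = X)
  att <- list()
  h <- X
  if (cfg$conv_attention_enabled) {
    cain <- convAttentionForward(h, params[["ca_in.W"]], params[["ca_in.b"]],
                                 cfg$conv_attention_activation)
    cache$ca_in <- cain; att$ca_in <- cain$a
    h <- cain$Y
  }
  cache$mix_in <- h
  branches <- lapply(seq_along(cfg$mixconv_kernels), function(i)
    convForward(h, params[[sprintf("mix%d.W", i)]],
                params[[sprintf("mix%d.b", i)]], withCols = TRUE))
  for (i in seq_along(branches))
    cache[[sprintf("mix%d_cols", i)]] <- branches[[i]][c("cols", "dimX")]
  branches <- lapply(branches, `[[`, "Y")
  d <- dim(branches[[1]])
  M <- array(unlist(branches, use.names = FALSE),
             c(d[1], d[2], sum(vapply(branches, function(b) dim(b)[3], 1L))))
  cache$M <- M
  Mr <- reluForward(M)
  cache$Mr <- Mr
  h <- Mr
  if (cfg$channel_attention_enabled) {
    catt <- channelAttentionForward(h, params[["catt.W"]], params[["catt.b"]],
                                    cfg$channel_attention_kernel)
    cache$catt <- catt
    h <- catt$Y
  }
  zc <- convForward(h, params[["comp.W"]], params[["comp.b"]],
                    withCols = TRUE)
  cache$comp_cols <- zc[c("cols", "dimX")]
  cache$comp_z <- zc$Y
  h <- reluForward(zc$Y)
  for (i in 1:2) {
    zc <- convForward(h, params[[sprintf("conv%d.W", i)]],
                      params[[sprintf("conv%d.b", i)]], withCols = TRUE)
    cache[[sprintf("conv%d_cols", i)]] <- zc[c("cols", "dimX")]
    z <- zc$Y
    cache[[sprintf("conv%d_z", i)]] <- z
    h <- reluForward(z)
    if (cfg$conv_attention_enabled) {
      cai <- convAttentionForward(h, params[[sprintf("ca%d.W", i)]],
                                  params[[sprintf("ca%d.b", i)]],
                                  cfg$conv_attention_activation)
      cache[[sprintf("ca%d", i)]] <- cai
      cache[[sprintf("ca%d_in", i)]] <- h
      att[[sprintf("ca%d", i)]] <- cai$a
      h <- cai$Y
    }
  }
  cache$flat_dim <- dim(h)
  H <- flattenForward(h)
  for (i in seq_along(cfg$trunk_widths)) {
    cache[[sprintf("trunk%d_in", i)]] <- H
    Z <- H %*% params[[sprintf("trunk%d.W", i)]]
    Z <- Z + rep(params[[sprintf("trunk%d.b", i)]], each = nrow(Z))
    cache[[sprintf("trunk%d_z", i)]] <- Z
    H <- reluForward(Z)
  }
  out <- matrix(0, nrow(H), 3L)
  for (j in 1:3) {
    B <- H
    for (i in seq_along(cfg$branch_widths)) {
      cache[[sprintf("br%dl%d_in", j, i)]] <- B
      Z <- B %*% params[[sprintf("br%dl%d.W", j, i)]]
      Z <- Z + rep(params[[sprintf("br%dl%d.b", j, i)]], each = nrow(Z))
      cache[[sprintf("br%dl%d_z", j, i)]] <- Z
      B <- reluForward(Z)
    }
    cache[[sprintf("br%dout_in", j)]] <- B
    zj <- drop(B %*% params[[sprintf("br%dout.W", j)]]) +
      params[[sprintf("br%dout.b", j)]]
    cache[[sprintf("br%dsig", j)]] <- sigmoid(zj)
    out[, j] <- cfg$output_scale * cache[[sprintf("br%dsig", j)]]
  }
  colnames(out) <- headNames()
  list(out = out, cache = if (keepCache) cache else NULL, attention = att)
}

# dOut: (N, 3) gradient w.r.t. the percent-scale outputs.  Returns the
# parameter gradients (same names/shapes as params) and, when requested,
# the gradient w.r.t. the folded input.
netBackward <- function(params, cfg, cache, dOut, wantInputGrad = FALSE) {
  g <- lapply(params, function(p) array(0, dim2(p)))
  nTrunk <- length(cfg$trunk_widths)
  lastTrunk <- if (nTrunk) sprintf("trunk%d_z", nTrunk) else NULL
  Hdim <- if (nTrunk) dim(cache[[lastTrunk]]) else
    c(nrow(dOut), prod(cache$flat_dim[c(1, 3)]))
  dH <- matrix(0, Hdim[1], Hdim[2])
  for (j in 1:3) {
    sg <- cache[[sprintf("br%dsig", j)]]
    dz <- dOut[, j] * cfg$output_scale * sg * (1 - sg)
    Bin <- cache[[sprintf("br%dout_in", j)]]
    g[[sprintf("br%dout.W", j)]] <- crossprod(Bin, dz)
    g[[sprintf("br%dout.b", j)]] <- sum(dz)
    dB <- matrix(dz, ncol = 1L) %*% t(params[[sprintf("br%dout.W", j)]])
    for (i in rev(seq_along(cfg$branch_widths))) {
      dZ <- dB * (cache[[sprintf("br%dl%d_z", j, i)]] > 0)
      Bin <- cache[[sprintf("br%dl%d_in", j, i)]]
      g[[sprintf("br%dl%d.W", j, i)]] <- crossprod(Bin, dZ)
      g[[sprintf("br%dl%d.b", j, i)]] <- colSums(dZ)
      dB <- tcrossprod(dZ, params[[sprintf("br%dl%d.W", j, i)]])
    }
    dH <- dH + dB
  }
  for (i in rev(seq_along(cfg$trunk_widths))) {
    dZ <- dH * (cache[[sprintf("trunk%d_z", i)]] > 0)
    Hin <- cache[[sprintf("trunk%d_in", i)]]
    g[[sprintf("trunk%d.W", i)]] <- crossprod(Hin, dZ)
    g[[sprintf("trunk%d.b", i)]] <- colSums(dZ)
    dH <- tcrossprod(dZ, params[[sprintf("trunk%d.W", i)]])
  }
  dh <- flattenBackward(dH, cache$flat_dim)
  for (i in 2:1) {
    if (cfg$conv_attention_enabled) {
      cab <- convAttentionBackward(dh, cache[[sprintf("ca%d_in", i)]],
                                   params[[sprintf("ca%d.W", i)]],
                                   cache[[sprintf("ca%d", i)]],
                                   cfg$conv_attention_activation)
      g[[sprintf("ca%d.W", i)]] <- cab$dW
      g[[sprintf("ca%d.b", i)]] <- cab$db
      dh <- cab$dX
    }
    dz <- dh * (cache[[sprintf("conv%d_z", i)]] > 0)
    cc <- cache[[sprintf("conv%d_cols", i)]]
    cb <- convBackwardCols(dz, cc$cols, cc$dimX,
                           params[[sprintf("conv%d.W", i)]])
    g[[sprintf("conv%d.W", i)]] <- cb$dW
    g[[sprintf("conv%d.b", i)]] <- cb$db
    dh <- cb$dX
  }
  dz <- dh * (cache$comp_z > 0)
  cb <- convBackwardCols(dz, cache$comp_cols$cols, cache$comp_cols$dimX,
                         params[["comp.W"]])
  g[["comp.W"]] <- cb$dW; g[["comp.b"]] <- cb$db
  dh <- cb$dX
  if (cfg$channel_attention_enabled) {
    cab <- channelAttentionBackward(dh, cache$Mr, params[["catt.W"]],
                                    cfg$channel_attention_kernel, cache$catt)
    g[["catt.W"]] <- cab$dw; g[["catt.b"]] <- cab$db
    dh <- cab$dX
  }
  dM <- dh * (cache$M > 0)
  cmix <- cfg$mixconv_out_channels
  dmixin <- NULL
  for (i in seq_along(cfg$mixconv_kernels)) {
    sel <- ((i - 1L) * cmix + 1L):(i * cmix)
    cc <- cache[[sprintf("mix%d_cols", i)]]
    cb <- convBackwardCols(dM[, , sel, drop = FALSE], cc$cols, cc$dimX,
                           params[[sprintf("mix%d.W", i)]])
    g[[sprintf("mix%d.W", i)]] <- cb$dW
    g[[sprintf("mix%d.b", i)]] <- cb$db
    dmixin <- if (is.null(dmixin)) cb$dX else dmixin + cb$dX
  }
  dX <- NULL
  if (cfg$conv_attention_enabled) {
    cab <- convAttentionBackward(dmixin, cache$Xin, params[["ca_in.W"]],
                                 cache$ca_in, cfg$conv_attention_activation)
    g[["ca_in.W"]] <- cab$dW; g[["ca_in.b"]] <- cab$db
    if (wantInputGrad) dX <- cab$dX
  } else if (wantInputGrad) {
    dX <- dmixin
  }
  list(grads = g, dX = dX)
}

#' Construct an orthogonally initialized PrimeNet
#'
#' Builds the parameter arrays for `config`, applies orthogonal weight
#' initialization with zero biases (see [orthogonalInit()]) under `seed`,
#' and runs a build-time shape audit (a dry forward pass on a 2-sample
#' zero batch) so any stage-shape mismatch fails at build time rather than
#' at call time.
#'
#' @param config see [modelConfig()].
#' @param seed integer initialization seed (recorded in the object and in
#'   checkpoints).
#' @return a [PrimeNet-class]
#' @export
primeNet <- function(config = modelConfig(), seed = 1L) {
  params <- orthogonalInit(paramTemplate(config), seed = seed)
  model <- new("PrimeNet", config = config, params = params,
               seed = as.integer(seed))
  cin <- config$in_channels * config$n_seq
  dry <- netForward(params, config, array(0, c(config$length, 2L, cin)))
  if (!identical(dim(dry$out), c(2L, 3L)))
    stop("shape audit failed: head emitted ", paste(dim(dry$out), collapse = "x"))
  model
}

#' Predict outcome triples
#'
#' Deterministic forward pass; order-preserving over the input batch.
#'
#' @param model a [PrimeNet-class]
#' @param images a [PseudoImageSet-class] or an (L, 8, 2, N) array.
#' @param batchSize forward-pass chunk size.
#' @param zeroChannels optional 0-based pseudo-image channel indices to
#'   zero out before prediction (both sequence slices), for ablations.
#' @return numeric matrix (N, 3) with columns valid/unedited/erroneous,
#'   all values in \[0, output_scale\].
#' @export
predictTriples <- function(model, images, batchSize = 1024L,
                           zeroChannels = NULL) {
  arr <- if (is(images, "PseudoImageSet")) images@images else images
  if (length(dim(arr)) == 3L) arr <- array(arr, c(dim(arr), 1L))
  if (dim(arr)[1] != model@config$length)
    validationError("architecture mismatch: model expects frame length ",
                    model@config$length, ", images have ", dim(arr)[1])
  if (!is.null(zeroChannels)) arr[, zeroChannels + 1L, , ] <- 0
  X <- foldImages(arr)
  n <- dim(X)[2]
  out <- matrix(0, n, 3L, dimnames = list(NULL, headNames()))
  for (s in seq(1L, n, by = batchSize)) {
    e <- min(n, s + batchSize - 1L)
    out[s:e, ] <- netForward(model@params, model@config,
                             X[, s:e, , drop = FALSE])$out
  }
  if (is(images, "PseudoImageSet")) rownames(out) <- images@recordIds
  out
}

#' Maximum deviation from weight orthogonality
#'
#' For every weight array, viewed as its 2-D (output x fan-in) matrix W,
#' computes max |W'W - I| (columns orthonormal when fan-in <= fan-out,
#' rows otherwise) and returns the worst case together with the maximum
#' absolute bias.
#'
#' @param model a [PrimeNet-class] (or a flat parameter list).
#' @return list with `weight_dev` and `bias_max`.
#' @export
orthogonalityDeviation <- function(model) {
  params <- if (is(model, "PrimeNet")) model@params else model
  wd <- 0; bm <- 0
  for (nm in names(params)) {
    p <- params[[nm]]
    if (grepl("\\.W$", nm)) {
      M <- weightAs2d(p)
      G <- if (nrow(M) >= ncol(M)) crossprod(M) else tcrossprod(M)
      wd <- max(wd, max(abs(G - diag(nrow(G)))))
    } else {
      bm <- max(bm, max(abs(p)))
    }
  }
  list(weight_dev = wd, bias_max = bm)
}

# 2-D (output x fan-in) view of a stored weight.
weightAs2d <- function(p) {
  d <- dim(p)
  if (is.null(d)) matrix(p, 1L)                       # channel-attention kernel
  else if (length(d) == 2L) t(p)                      # dense, stored (fan-in, out)
  else t(array(p, c(d[1] * d[2], d[3])))              # conv, (K, Cin, Cout)
}

weightFrom2d <- function(M, template) {
  d <- dim(template)
  if (is.null(d)) as.numeric(M)
  else if (length(d) == 2L) t(M)
  else array(t(M), d)
}
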