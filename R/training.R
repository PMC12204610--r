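# Training scheme: orthogonal initialization, Lookahead-wrapped inner
# optimizer, 8:1:1 splitting, merge-and-shuffle, the training loop and a
# Spearman-objective hyperparameter search.

#' Orthogonal weight initialization
#'
#' Every weight array, viewed as its 2-D (output x fan-in) matrix W, is set
#' to an orthogonal frame: W'W = I when fan-in <= fan-out, WW' = I
#' otherwise (the Gram matrix of the shorter side is the identity).  All
#' biases are set exactly to zero.  Orthogonal frames keep the singular
#' values of every layer at 1, so activations and gradients neither vanish
#' nor explode at the start of training.
#'
#' @param params flat named parameter list (entries `*.W` / `*.b`), e.g.
#'   from a [PrimeNet-class] or its internal template.
#' @param seed integer seed; the draw is reproducible and recorded in
#'   checkpoints.
#' @return the parameter list with weights orthogonalized and biases zero.
#' @export
orthogonalInit <- function(params, seed = 1L) {
  withSeed(seed, {
    for (nm in names(params)) {
      if (grepl("\\.W$", nm)) {
        M2 <- weightAs2d(params[[nm]])
        nr <- nrow(M2); nc <- ncol(M2)
        A <- matrix(stats::rnorm(max(nr, nc) * min(nr, nc)),
                    max(nr, nc), min(nr, nc))
        qrA <- qr(A)
        Q <- qr.Q(qrA)
        Q <- Q * rep(sign(diag(qr.R(qrA))), each = nrow(Q))  # fix QR sign
        W <- if (nr >= nc) Q else t(Q)
        params[[nm]] <- weightFrom2d(W, params[[nm]])
      } else {
        params[[nm]][] <- 0
      }
    }
    params
  })
}

# ---- inner optimizers --------------------------------------------------

#' Inner optimizers for the training loop
#'
#' `optimizerSGD` performs plain gradient descent; `optimizerAdam` the
#' adaptive-moment rule.  Both return the pluggable update-rule interface
#' consumed by [lookaheadInit()] and [trainPrimeNet()]: a list with
#' `init(params)` and `step(state, params, grads)`.
#'
#' @param lr learning rate.
#' @export
optimizerSGD <- function(lr = 0.01) {
  list(name = "sgd", lr = lr,
       init = function(params) list(),
       step = function(state, params, grads) {
         for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
         list(params = params, state = state)
       })
}

#' @rdname optimizerSGD
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical floor.
#' @export
optimizerAdam <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(name = "adam", lr = lr,
       init = function(params)
         list(m = lapply(params, function(p) p * 0),
              v = lapply(params, function(p) p * 0), t = 0L),
       step = function(state, params, grads) {
         state$t <- state$t + 1L
         c1 <- 1 - beta1^state$t
         c2 <- 1 - beta2^state$t
         for (nm in names(params)) {
           state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
           state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
           params[[nm]] <- params[[nm]] -
             lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
         }
         list(params = params, state = state)
       })
}

# ---- Lookahead ---------------------------------------------------------

#' Lookahead optimizer state
#'
#' Lookahead keeps slow weights phi and fast weights theta.  Each outer
#' iteration runs k inner updates of theta by the inner optimizer A
#' (theta_i = theta_{i-1} + A(L, theta_{i-1}, d)), then interpolates the
#' slow weights a fraction alpha toward the final fast weights
#' (phi <- phi + alpha * (theta_k - phi)) and resets theta to the new phi.
#'
#' @param params initial parameter list (becomes both phi and theta).
#' @param k inner steps per outer iteration (>= 1).
#' @param alpha slow-weight step size in (0, 1].
#' @param inner inner optimizer, see [optimizerAdam()].
#' @return Lookahead state list.
#' @export
lookaheadInit <- function(params, k = 5L, alpha = 0.5,
                          inner = optimizerAdam()) {
  stopifnot(k >= 1L, alpha > 0, alpha <= 1)
  list(phi = params, theta = params, k = as.integer(k), alpha = alpha,
       inner = inner, inner_state = inner$init(params), t = 0L)
}

#' One Lookahead outer iteration
#'
#' Advances the fast weights through one inner step per supplied batch
#' (normally exactly k batches; at an epoch boundary a shorter final cycle
#' is allowed and logged), interpolates the slow weights and resets.
#'
#' @param state from [lookaheadInit()].
#' @param gradFn function(params, batch) returning `list(loss, grads)`.
#' @param batches list of mini-batches (length <= k).
#' @return updated state; element `losses` holds the inner-step losses.
#' @export
lookaheadOuterStep <- function(state, gradFn, batches) {
  nb <- length(batches)
  if (nb < state$k)
    logMsg("short Lookahead cycle: ", nb, " of ", state$k, " inner steps")
  losses <- numeric(nb)
  for (i in seq_len(nb)) {
    gr <- gradFn(state$theta, batches[[i]])
    losses[i] <- gr$loss
    upd <- state$inner$step(state$inner_state, state$theta, gr$grads)
    state$theta <- upd$params
    state$inner_state <- upd$state
  }
  for (nm in names(state$phi))
    state$phi[[nm]] <- state$phi[[nm]] +
      state$alpha * (state$theta[[nm]] - state$phi[[nm]])
  state$theta <- state$phi
  state$t <- state$t + 1L
  state$losses <- losses
  state
}

# ---- dataset handling --------------------------------------------------

#' Split a dataset 8:1:1
#'
#' Seeded shuffle followed by a contiguous cut: floor(n * r_train) /
#' floor(n * r_val) samples for train/validation, remainder to test.
#' Partitions are disjoint and exhaustive.
#'
#' @param n number of records (or an object with a `length` method).
#' @param ratios positive weights for (train, val, test); default 8:1:1.
#' @param seed shuffle seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
splitDataset <- function(n, ratios = c(8, 1, 1), seed = 1L) {
  if (!is.numeric(n) || length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (n < 10L) validationError("need at least 10 records to split, got ", n)
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  w <- ratios / sum(ratios)
  idx <- withSeed(seed, sample.int(n))
  ntr <- floor(n * w[1]); nva <- floor(n * w[2])
  list(train = sort(idx[seq_len(ntr)]),
       val = sort(idx[ntr + seq_len(nva)]),
       test = sort(idx[(ntr + nva + 1L):n]))
}

#' Merge training subsets and shuffle
#'
#' Concatenates encoded sets (e.g. the per-cell-line training subsets) and
#' applies one seeded permutation; each sample keeps its provenance tag.
#'
#' @param sets list of [PseudoImageSet-class] objects.
#' @param seed permutation seed.
#' @param tags provenance tag per set (defaults to list names or set index).
#' @return a single [PseudoImageSet-class]
#' @export
mergeAndShuffle <- function(sets, seed = 1L, tags = NULL) {
  stopifnot(length(sets) >= 1L)
  if (is.null(tags)) tags <- if (!is.null(names(sets))) names(sets)
                             else as.character(seq_along(sets))
  imgs <- lapply(sets, function(s) s@images)
  L <- dim(imgs[[1]])[1]
  total <- sum(vapply(sets, length, 1L))
  arr <- array(0, c(L, 8L, 2L, total))
  at <- 0L
  for (s in imgs) { k <- dim(s)[4]; arr[, , , at + seq_len(k)] <- s; at <- at + k }
  eff <- do.call(rbind, lapply(sets, function(s) s@effLengths))
  ids <- unlist(lapply(sets, function(s) s@recordIds), use.names = FALSE)
  obs <- do.call(rbind, lapply(sets, function(s) s@observed))
  prov <- unlist(mapply(function(s, tg) {
    p <- s@provenance; p[!nzchar(p)] <- tg; p
  }, sets, tags, SIMPLIFY = FALSE), use.names = FALSE)
  perm <- withSeed(seed, sample.int(total))
  new("PseudoImageSet", images = arr[, , , perm, drop = FALSE],
      effLengths = eff[perm, , drop = FALSE], recordIds = ids[perm],
      observed = obs[perm, , drop = FALSE], provenance = prov[perm])
}

# ---- training loop -----------------------------------------------------

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs without improvement of the
#'   validly-edited validation Spearman before stopping.
#' @param seed master seed for shuffling (initialization is seeded by
#'   [primeNet()]).
#' @param lookahead_enabled,lookahead_k,lookahead_alpha Lookahead settings.
#' @param verbose print per-epoch progress.
#' @return config list.
#' @export
trainConfig <- function(learning_rate = 1e-3, batch_size = 256L,
                        max_epochs = 50L, early_stop_patience = 10L,
                        seed = 1L, lookahead_enabled = TRUE,
                        lookahead_k = 5L, lookahead_alpha = 0.5,
                        verbose = FALSE) {
  list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs),
       early_stop_patience = as.integer(early_stop_patience),
       seed = as.integer(seed), lookahead_enabled = isTRUE(lookahead_enabled),
       lookahead_k = as.integer(lookahead_k),
       lookahead_alpha = lookahead_alpha, verbose = isTRUE(verbose))
}

spearmanSafe <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Train a PrimeNet model
#'
#' Loss is mean squared error on the percent-scale triple, averaged over
#' the three heads.  The inner Adam optimizer is wrapped in Lookahead when
#' enabled.  After each epoch the validation Spearman of every head is
#' recorded; the returned model carries the parameters of the epoch with
#' the best validly-edited validation Spearman (the same quantity used for
#' early stopping and hyperparameter tuning).
#'
#' @param model a [PrimeNet-class] (typically fresh from [primeNet()]).
#' @param train,val [PseudoImageSet-class] objects with complete observed
#'   triples.
#' @param config see [trainConfig()].
#' @return list with elements `model` (best weights), `history`
#'   (data.frame: epoch, train_loss, val_spearman_valid/unedited/erroneous)
#'   and `manifest` (seeds and settings of the run).
#' @export
trainPrimeNet <- function(model, train, val, config = trainConfig()) {
  cfg <- model@config
  Xtr <- foldImages(train@images)
  Ytr <- train@observed
  if (anyNA(Ytr)) validationError("training set has incomplete observed triples")
  Xva <- foldImages(val@images)
  Yva <- val@observed
  n <- dim(Xtr)[2]

  gradFn <- function(params, batch) {
    xb <- Xtr[, batch, , drop = FALSE]
    yb <- Ytr[batch, , drop = FALSE]
    fw <- netForward(params, cfg, xb, keepCache = TRUE)
    err <- fw$out - yb
    loss <- mean(err^2)
    if (!is.finite(loss))
      stop("non-finite training loss at outer iteration; ",
           "last batch size ", length(batch))
    bw <- netBackward(params, cfg, fw$cache, 2 * err / length(err))
    list(loss = loss, grads = bw$grads)
  }

  inner <- optimizerAdam(lr = config$learning_rate)
  if (config$lookahead_enabled) {
    la <- lookaheadInit(model@params, k = config$lookahead_k,
                        alpha = config$lookahead_alpha, inner = inner)
  } else {
    params <- model@params
    inner_state <- inner$init(params)
  }

  history <- NULL
  best <- list(score = -Inf, params = model@params, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- withSeed(config$seed + epoch, sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    losses <- c()
    if (config$lookahead_enabled) {
      groups <- split(seq_along(batches),
                      ceiling(seq_along(batches) / config$lookahead_k))
      for (gidx in groups) {
        la <- suppressMessages(lookaheadOuterStep(la, gradFn, batches[gidx]))
        losses <- c(losses, la$losses)
      }
      cur <- la$phi
    } else {
      for (b in batches) {
        gr <- gradFn(params, b)
        losses <- c(losses, gr$loss)
        upd <- inner$step(inner_state, params, gr$grads)
        params <- upd$params; inner_state <- upd$state
      }
      cur <- params
    }
    pv <- netForward(cur, cfg, Xva)$out
    sp <- vapply(1:3, function(j) spearmanSafe(pv[, j], Yva[, j]), 0)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(losses),
      val_spearman_valid = sp[1], val_spearman_unedited = sp[2],
      val_spearman_erroneous = sp[3]))
    if (config$verbose)
      logMsg(sprintf("epoch %d: loss %.3f, val rho %.3f/%.3f/%.3f",
                     epoch, mean(losses), sp[1], sp[2], sp[3]))
    if (!is.na(sp[1]) && sp[1] > best$score) {
      best <- list(score = sp[1], params = cur, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  model@params <- best$params
  list(model = model,
       history = history,
       manifest = list(seed = config$seed, init_seed = model@seed,
                       learning_rate = config$learning_rate,
                       batch_size = config$batch_size,
                       lookahead = list(enabled = config$lookahead_enabled,
                                        k = config$lookahead_k,
                                        alpha = config$lookahead_alpha),
                       best_epoch = best$epoch,
                       best_val_spearman_valid = best$score,
                       n_train = n, n_val = dim(Xva)[2]))
}

#' Hyperparameter search maximizing the validly-edited Spearman
#'
#' Random search over a named space of candidate values (the sampler is
#' pluggable; random search keeps the objective contract - the validation
#' Spearman of the validly-edited head - while remaining deterministic
#' under a seed).  Recognized space names: any [modelConfig()] argument
#' (e.g. `compress_channels`, `channel_attention_enabled`,
#' `conv_attention_enabled`, `conv_attention_kernel`,
#' `conv_attention_activation`) plus `learning_rate`.
#'
#' @param train,val [PseudoImageSet-class] objects.
#' @param space named list; each element a vector of candidate values.
#' @param nTrials number of sampled configurations (>= 1).
#' @param seed sampler seed.
#' @param trainCfg training settings applied to every trial.
#' @param baseConfig model-config template the sampled values override.
#' @return list with `best_config`, `best_score`, and `trials`
#'   (data.frame of sampled values and scores, one row per trial).
#' @export
tuneHyperparameters <- function(train, val, space, nTrials = 10L, seed = 1L,
                                trainCfg = trainConfig(max_epochs = 5L,
                                                       early_stop_patience = 5L),
                                baseConfig = modelConfig()) {
  stopifnot(nTrials >= 1L, length(space) >= 1L, !is.null(names(space)))
  draws <- withSeed(seed, lapply(seq_len(nTrials), function(i)
    lapply(space, function(v) v[[sample.int(length(v), 1L)]])))
  trials <- NULL
  best <- list(score = -Inf, config = NULL)
  for (i in seq_len(nTrials)) {
    d <- draws[[i]]
    cfgArgs <- d[setdiff(names(d), "learning_rate")]
    cfg <- do.call(modelConfig, utils::modifyList(
      baseConfig[setdiff(names(baseConfig),
                         c("in_channels", "n_seq"))], cfgArgs))
    tc <- trainCfg
    if (!is.null(d$learning_rate)) tc$learning_rate <- d$learning_rate
    mdl <- primeNet(cfg, seed = seed + i)
    fit <- trainPrimeNet(mdl, train, val, tc)
    score <- max(fit$history$val_spearman_valid, na.rm = TRUE)
    row <- data.frame(trial = i, score = score)
    for (nm in names(d)) row[[nm]] <- d[[nm]]
    trials <- rbind(trials, row)
    if (score > best$score)
      best <- list(score = score, config = cfg,
                   learning_rate = tc$learning_rate)
  }
  if (is.null(trials)) stop("no completed trials")
  list(best_config = best$config, best_score = best$score,
       best_learning_rate = best$learning_rate, trials = trials)
}
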