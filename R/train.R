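# Backpropagation through time, Adam optimisation, and evaluation helpers.

# Batched forward pass. U is an n_input x B x T array; returns hidden
# activity S (n_hidden x B x T) and predictions V (n_out x B x T).
forward_batch <- function(params, U) {
  W_eff <- dale_weights(params)
  d <- dim(U)
  B <- d[2]; T_ <- d[3]
  nh <- params$config$n_hidden
  no <- nrow(params$W_out)
  S <- array(0, c(nh, B, T_))
  V <- array(0, c(no, B, T_))
  s_prev <- matrix(0, nh, B)
  for (t in seq_len(T_)) {
    s_prev <- pmax(params$W_in %*% slice_t(U, t) + W_eff %*% s_prev + params$b_rec, 0)
    S[, , t] <- s_prev
    V[, , t] <- params$W_out %*% s_prev + params$b_out
  }
  list(s = S, v_hat = V)
}

# Loss and analytic gradients over one minibatch via backpropagation
# through the full recurrence. U: n_input x B x T inputs; V: n_out x B x T
# targets. Gradients are with respect to the raw parameters; the sign
# constraint is part of the forward map (chain rule via sign(raw) *
# unit_sign), and the L1 terms contribute their subgradients.
bptt_loss_grads <- function(params, U, V, config = params$config) {
  W_eff <- dale_weights(params)
  Wi <- params$W_in
  Wo <- params$W_out
  d <- dim(U)
  B <- d[2]; T_ <- d[3]
  nh <- config$n_hidden
  la <- config$lambda_act
  S <- vector("list", T_)
  E <- vector("list", T_)
  s_prev <- matrix(0, nh, B)
  loss <- 0
  for (t in seq_len(T_)) {
    s_prev <- pmax(Wi %*% slice_t(U, t) + W_eff %*% s_prev + params$b_rec, 0)
    S[[t]] <- s_prev
    e <- Wo %*% s_prev + params$b_out - slice_t(V, t)
    E[[t]] <- e
    loss <- loss + sum(e * e)
    if (la > 0) loss <- loss + la * sum(s_prev)
  }
  gWi <- matrix(0, nrow(Wi), ncol(Wi))
  gWe <- matrix(0, nh, nh)
  gWo <- matrix(0, nrow(Wo), ncol(Wo))
  gbr <- rep(0, nh)
  gbo <- rep(0, nrow(Wo))
  carry <- matrix(0, nh, B)
  for (t in rev(seq_len(T_))) {
    dV <- 2 * E[[t]]
    gWo <- gWo + tcrossprod(dV, S[[t]])
    gbo <- gbo + rowSums(dV)
    dS <- crossprod(Wo, dV) + carry
    if (la > 0) dS <- dS + la * (S[[t]] > 0)
    dX <- dS * (S[[t]] > 0)
    gWi <- gWi + tcrossprod(dX, slice_t(U, t))
    gbr <- gbr + rowSums(dX)
    s_m1 <- if (t > 1) S[[t - 1]] else matrix(0, nh, B)
    gWe <- gWe + tcrossprod(dX, s_m1)
    carry <- crossprod(W_eff, dX)
  }
  lam <- config$lambda_l1
  loss <- loss + lam * (sum(abs(Wi)) + sum(abs(params$W_rec)) + sum(abs(Wo)))
  gWrec <- gWe * sign(params$W_rec) * rep(params$unit_sign, each = nh) +
    lam * sign(params$W_rec)
  list(
    loss = loss,
    grads = list(
      W_in = gWi + lam * sign(Wi),
      W_rec = gWrec,
      b_rec = gbr,
      W_out = gWo + lam * sign(Wo),
      b_out = gbo
    )
  )
}

# Assemble a batch of clips into input/target arrays according to the
# objective, adding training input noise where configured.
prepare_batch <- function(clips, config, seed) {
  pairs <- lapply(seq_along(clips), function(i) {
    make_targets(clips[[i]], config$objective, config$offset_frames,
                 seed = derive_seed(seed, i))
  })
  noisy_input <- function(i, clip) {
    if (config$objective == "prediction" && is.finite(config$input_snr_db)) {
      add_gaussian_noise_snr(clip, config$input_snr_db,
                             seed = derive_seed(seed, 10000 + i))
    } else {
      clip
    }
  }
  B <- length(clips)
  T_ <- n_frames(pairs[[1]]$input)
  ni <- config$n_input
  U <- array(0, c(ni, B, T_))
  tgt1 <- pairs[[1]]$target
  no <- if (is.list(tgt1) && !inherits(tgt1, "movie_clip")) ni * length(tgt1) else ni
  V <- array(0, c(no, B, T_))
  for (i in seq_len(B)) {
    U[, i, ] <- t(clip_matrix(noisy_input(i, pairs[[i]]$input)))
    tg <- pairs[[i]]$target
    if (inherits(tg, "movie_clip")) {
      V[, i, ] <- t(clip_matrix(tg))
    } else {
      V[, i, ] <- t(do.call(cbind, lapply(tg, clip_matrix)))
    }
  }
  list(U = U, V = V)
}

#' Train the network with Adam
#'
#' Gradient descent on the summed squared-error loss with L1 wiring cost,
#' gradients propagated through the full recurrence and the sign constraint
#' applied at every forward pass. Deterministic given the config seed.
#' Training aborts with a diagnostic if the loss diverges to NaN.
#'
#' @param params A `network_params` object (from [init_network()]).
#' @param corpus Either the list returned by [generate_movie_corpus()] or a
#'   plain list of training clips.
#' @param epochs Number of passes over the training set.
#' @param batch_size Clips per minibatch.
#' @param validation Optional list of validation clips; per-epoch clean
#'   next-frame MSE is recorded.
#' @param verbose Print per-epoch losses.
#' @return A list with `params` (trained), and `history` (a `data.frame`
#'   with per-epoch mean training loss per clip and validation MSE).
#' @export
train_network <- function(params, corpus, epochs = 10, batch_size = 50,
                          validation = NULL, verbose = FALSE) {
  config <- params$config
  clips <- if (!is.null(corpus$train)) corpus$train else corpus
  if (is.null(validation) && !is.null(corpus$validation) &&
      length(corpus$validation) > 0) {
    validation <- corpus$validation
  }
  if (length(clips) == 0) stop("training corpus is empty")
  opt <- list(m = NULL, v = NULL, t = 0, b1 = 0.9, b2 = 0.999, eps = 1e-8)
  pnames <- c("W_in", "W_rec", "b_rec", "W_out", "b_out")
  opt$m <- lapply(pnames, function(p) params[[p]] * 0)
  opt$v <- opt$m
  names(opt$m) <- names(opt$v) <- pnames
  history <- NULL
  for (epoch in seq_len(epochs)) {
    order <- with_seed(derive_seed(config$seed, 555 + epoch),
                       sample.int(length(clips)))
    batches <- split(order, ceiling(seq_along(order) / batch_size))
    epoch_loss <- 0
    for (b in seq_along(batches)) {
      batch <- prepare_batch(clips[batches[[b]]], config,
                             seed = derive_seed(config$seed, epoch * 1000 + b))
      res <- bptt_loss_grads(params, batch$U, batch$V, config)
      if (!is.finite(res$loss)) {
        stop(sprintf(
          "training diverged (loss = %s) at epoch %d batch %d; reduce the learning rate",
          res$loss, epoch, b
        ))
      }
      epoch_loss <- epoch_loss + res$loss
      opt$t <- opt$t + 1
      for (p in pnames) {
        g <- res$grads[[p]]
        opt$m[[p]] <- opt$b1 * opt$m[[p]] + (1 - opt$b1) * g
        opt$v[[p]] <- opt$b2 * opt$v[[p]] + (1 - opt$b2) * g * g
        mhat <- opt$m[[p]] / (1 - opt$b1^opt$t)
        vhat <- opt$v[[p]] / (1 - opt$b2^opt$t)
        params[[p]] <- params[[p]] - config$learning_rate * mhat / (sqrt(vhat) + opt$eps)
      }
    }
    val_mse <- if (!is.null(validation)) predict_mse(params, validation) else NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / length(clips), val_mse = val_mse
    ))
    if (verbose) {
      message(sprintf("epoch %d: train loss/clip %.4f, val MSE %.5f",
                      epoch, epoch_loss / length(clips), val_mse))
    }
  }
  list(params = params, history = history)
}

#' Mean squared prediction error on clean clips
#'
#' Per-pixel, per-step mean squared error of the network's prediction
#' against the true offset frame, evaluated on uncorrupted inputs.
#'
#' @param params A `network_params` object.
#' @param clips List of [movie_clip()] objects.
#' @param W_rec_override Optional replacement recurrent matrix (already
#'   sign-constrained), used by the ablation analyses.
#' @return Scalar MSE.
#' @export
predict_mse <- function(params, clips, W_rec_override = NULL) {
  if (length(clips) == 0) stop("no clips to evaluate")
  config <- params$config
  if (!is.null(W_rec_override)) {
    params$W_rec <- W_rec_override
  }
  pairs <- lapply(clips, make_targets, objective = config$objective,
                  offset_frames = config$offset_frames)
  B <- length(clips)
  T_ <- n_frames(pairs[[1]]$input)
  U <- array(0, c(config$n_input, B, T_))
  no <- nrow(params$W_out)
  V <- array(0, c(no, B, T_))
  for (i in seq_len(B)) {
    U[, i, ] <- t(clip_matrix(pairs[[i]]$input))
    tg <- pairs[[i]]$target
    V[, i, ] <- if (inherits(tg, "movie_clip")) t(clip_matrix(tg)) else
      t(do.call(cbind, lapply(tg, clip_matrix)))
  }
  out <- forward_batch(params, U)
  mean((out$v_hat - V)^2)
}

#' Persistence baseline error
#'
#' MSE of predicting the frame `offset` ahead as a copy of the current
#' frame.
#'
#' @param clips List of [movie_clip()] objects.
#' @param offset Prediction offset in frames.
#' @return Scalar MSE.
#' @export
persistence_mse <- function(clips, offset = 1) {
  errs <- vapply(clips, function(clip) {
    T_ <- n_frames(clip)
    mean((clip$frames[(1 + offset):T_, , , drop = FALSE] -
            clip$frames[1:(T_ - offset), , , drop = FALSE])^2)
  }, numeric(1))
  mean(errs)
}

#' Hyperparameter sweep over L1 strength or prediction offset
#'
#' Trains one model per grid value on the given corpus and reports the
#' clean validation MSE; the selected value is the argmin. The published
#' search spanned lambda in 10^-7..10^-5.5.
#'
#' @param corpus Output of [generate_movie_corpus()].
#' @param base_config A `network_config` supplying all fixed settings.
#' @param lambda_grid Optional vector of `lambda_l1` values.
#' @param offset_grid Optional vector of prediction offsets (used if
#'   `lambda_grid` is `NULL`).
#' @param epochs,batch_size Training settings per grid point.
#' @return A `data.frame` with columns `setting`, `value`, `val_mse`, and an
#'   attribute `selected` giving the argmin row.
#' @export
hyperparameter_sweep <- function(corpus, base_config, lambda_grid = NULL,
                                 offset_grid = NULL, epochs = 3,
                                 batch_size = 25) {
  if (is.null(lambda_grid) && is.null(offset_grid)) stop("empty grid")
  setting <- if (!is.null(lambda_grid)) "lambda_l1" else "offset_frames"
  values <- if (!is.null(lambda_grid)) lambda_grid else offset_grid
  res <- lapply(values, function(v) {
    cfg <- base_config
    cfg[[setting]] <- if (setting == "offset_frames") as.integer(v) else v
    fit <- train_network(init_network(cfg), corpus, epochs = epochs,
                         batch_size = batch_size)
    data.frame(setting = setting, value = v,
               val_mse = predict_mse(fit$params, corpus$validation))
  })
  tab <- do.call(rbind, res)
  attr(tab, "selected") <- tab[which.min(tab$val_mse), ]
  tab
}

# Finite-difference gradient of the full training loss with respect to one
# parameter matrix; used to validate the analytic backward pass.
numeric_gradient <- function(params, U, V, pname, eps = 1e-6,
                             config = params$config) {
  g <- params[[pname]] * 0
  for (i in seq_along(g)) {
    pp <- params; pp[[pname]][i] <- pp[[pname]][i] + eps
    pm <- params; pm[[pname]][i] <- pm[[pname]][i] - eps
    lp <- bptt_loss_grads(pp, U, V, config)$loss
    lm <- bptt_loss_grads(pm, U, V, config)$loss
    g[i] <- (lp - lm) / (2 * eps)
  }
  g
}
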