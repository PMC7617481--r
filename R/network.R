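#' Configuration of the recurrent temporal-prediction network
#'
#' Defaults follow the full-scale architecture: 36x36-pixel input frames
#' (1,296 pixels), 2,592 hidden units of which 10% are inhibitory, L1 wiring
#' penalty `lambda_l1 = 1e-6`, Adam learning rate `1e-4`, next-frame
#' prediction objective with a 1-frame offset, and 6 dB Gaussian input noise
#' during training. Analyses at desk scale use a reduced profile (see
#' [scaled_profile()]).
#'
#' @param n_input Input vector length (pixels per frame; must be a square).
#' @param n_hidden Number of hidden units.
#' @param frac_inhibitory Fraction of hidden units labelled inhibitory.
#' @param lambda_l1 L1 penalty on all weight matrices.
#' @param lambda_act L1 penalty on hidden activity (sparse-autoencoder
#'   objective only).
#' @param learning_rate Adam step size.
#' @param objective One of `"prediction"`, `"denoise"`, `"inpaint"`,
#'   `"sparse_ae"`.
#' @param offset_frames Prediction offset in frames (scalar, or an integer
#'   vector for the prediction-span objective).
#' @param input_snr_db SNR of Gaussian noise added to training inputs
#'   (`Inf` disables; the denoise objective uses its own 3 dB corruption).
#' @param seed Integer seed governing initialisation and batch order.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_input = 1296, n_hidden = 2592,
                           frac_inhibitory = 0.10, lambda_l1 = 1e-6,
                           lambda_act = 0, learning_rate = 1e-4,
                           objective = c("prediction", "denoise", "inpaint",
                                         "sparse_ae"),
                           offset_frames = 1, input_snr_db = 6, seed = 1) {
  objective <- match.arg(objective)
  stopifnot(
    n_input >= 1, n_hidden >= 1,
    frac_inhibitory > 0, frac_inhibitory < 1,
    lambda_l1 >= 0, lambda_act >= 0, learning_rate > 0,
    all(offset_frames >= 0)
  )
  if (objective != "prediction" && !identical(as.numeric(offset_frames), 0)) {
    offset_frames <- 0 # reconstruction objectives target the current frame
  }
  structure(
    list(
      n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
      frac_inhibitory = frac_inhibitory, lambda_l1 = lambda_l1,
      lambda_act = lambda_act, learning_rate = learning_rate,
      objective = objective, offset_frames = as.integer(offset_frames),
      input_snr_db = input_snr_db, seed = as.integer(seed)
    ),
    class = "network_config"
  )
}

#' Desk-scale training profile
#'
#' A reduced configuration used throughout the package's own analyses:
#' 16x16-pixel patches, 512 hidden units, and a corpus of 2,000 synthetic
#' clips. Small enough to train on one CPU in minutes while leaving the
#' architecture, constraint and objective untouched.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [network_config()].
#' @return A `network_config`.
#' @export
scaled_profile <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_input = 256, n_hidden = 512, learning_rate = 1e-3, seed = seed),
    list(...)
  )
  do.call(network_config, args)
}

#' Initialise network parameters
#'
#' Weights are drawn uniformly with scale `1/sqrt(fan_in)` for the input and
#' readout matrices. The recurrent matrix is scaled by `1/fan_in` instead:
#' under the sign constraint every excitatory column contributes with one
#' sign, so the expected total recurrent gain (not its root-mean-square)
#' must stay below one for stable dynamics at initialisation. Unit sign
#' labels assign the first `floor((1 - frac_inhibitory) * n_hidden)` units
#' as excitatory (+1) and the rest inhibitory (-1); with defaults this gives
#' 2,332 excitatory and 260 inhibitory units. The sign constraint holds
#' from the outset.
#'
#' @param config A [network_config()].
#' @return An object of class `network_params` with elements `W_in`
#'   (`n_hidden x n_input`), `W_rec` (`n_hidden x n_hidden`, raw magnitudes
#'   carrying free sign; see [dale_weights()]), `b_rec`, `W_out`
#'   (`n_input x n_hidden`), `b_out`, `unit_sign` (+1/-1 per hidden unit)
#'   and the `config`.
#' @export
init_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  nh <- config$n_hidden
  ni <- config$n_input
  # the prediction-span objective widens the readout: one frame per offset
  no <- ni * if (config$objective == "prediction") length(config$offset_frames) else 1L
  n_exc <- floor(nh * (1 - config$frac_inhibitory) + 1e-9)
  unit_sign <- c(rep(1, n_exc), rep(-1, nh - n_exc))
  params <- with_seed(config$seed, {
    list(
      W_in = matrix(stats::runif(nh * ni, -1, 1) / sqrt(ni), nh, ni),
      W_rec = matrix(stats::runif(nh * nh, -1, 1) / nh, nh, nh),
      b_rec = rep(0, nh),
      W_out = matrix(stats::runif(no * nh, -1, 1) / sqrt(nh), no, nh),
      b_out = rep(0, no)
    )
  })
  params$unit_sign <- unit_sign
  params$config <- config
  class(params) <- "network_params"
  params
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params> %d inputs -> %d hidden (%d exc / %d inh) -> %d outputs; objective %s\n",
    x$config$n_input, x$config$n_hidden, sum(x$unit_sign > 0),
    sum(x$unit_sign < 0), x$config$n_input, x$config$objective
  ))
  invisible(x)
}

#' Apply the sign (Dale) constraint to a recurrent weight matrix
#'
#' Every outgoing weight of an excitatory presynaptic unit is forced
#' non-negative and of an inhibitory unit non-positive:
#' `w <- sign(unit) * |w|`. Rows index postsynaptic units and columns
#' presynaptic units, matching `s[t] = f(W_in u[t] + W_rec s[t-1] + b)`.
#' The map is idempotent.
#'
#' @param W_rec `n_hidden x n_hidden` weight matrix.
#' @param unit_sign Vector of +1 (excitatory) / -1 (inhibitory) per unit.
#' @return The constrained matrix.
#' @export
apply_dale_constraint <- function(W_rec, unit_sign) {
  stopifnot(ncol(W_rec) == length(unit_sign))
  abs(W_rec) * rep(unit_sign, each = nrow(W_rec))
}

#' Effective (sign-constrained) recurrent weights of a network
#'
#' @param params A `network_params` object.
#' @return The constrained recurrent weight matrix used in every forward
#'   pass.
#' @export
dale_weights <- function(params) {
  apply_dale_constraint(params$W_rec, params$unit_sign)
}

#' Run the recurrent network over a clip
#'
#' Exact recurrence `s[t] = max(0, W_in u[t] + W_rec s[t-1] + b_rec)`,
#' `v_hat[t] = W_out s[t] + b_out`, with the sign constraint applied to
#' `W_rec` and `s[0]` equal to `initial_state` (zeros by default). No
#' implicit normalisation.
#'
#' @param params A `network_params` object.
#' @param clip A [movie_clip()] or a `T x n_input` matrix of flattened
#'   frames.
#' @param initial_state Optional `n_hidden` vector for `s[0]`.
#' @return An object of class `network_state` with matrices `s`
#'   (`T x n_hidden`, non-negative) and `v_hat` (`T x n_input`).
#' @export
forward <- function(params, clip, initial_state = NULL) {
  U <- if (inherits(clip, "movie_clip")) clip_matrix(clip) else as.matrix(clip)
  if (anyNA(U) || !all(is.finite(U))) stop("input contains NaN or non-finite values")
  if (ncol(U) != params$config$n_input) {
    stop("flattened frame length does not match `n_input`")
  }
  W_eff <- dale_weights(params)
  nh <- params$config$n_hidden
  T_ <- nrow(U)
  s_prev <- if (is.null(initial_state)) rep(0, nh) else initial_state
  S <- matrix(0, T_, nh)
  for (t in seq_len(T_)) {
    s_prev <- pmax(0, drop(params$W_in %*% U[t, ] + W_eff %*% s_prev) + params$b_rec)
    S[t, ] <- s_prev
  }
  V <- S %*% t(params$W_out) + rep(params$b_out, each = T_)
  structure(list(s = S, v_hat = V), class = "network_state")
}

#' Pair a clip into network input and target
#'
#' For the prediction objective the target at step `t` is the frame
#' `offset_frames` ahead (default 1); the usable clip shortens accordingly.
#' The prediction-span variant takes a vector of offsets and returns one
#' target per offset. The denoise objective corrupts the input at 3 dB SNR,
#' the inpaint objective masks it with 8 random 8x8 patches, and both (like
#' the sparse autoencoder) target the clean current frame.
#'
#' @param clip A [movie_clip()].
#' @param objective Objective name (see [network_config()]).
#' @param offset_frames Integer offset(s) for the prediction objective.
#' @param seed Seed for the stochastic corruptions.
#' @return A list with `input` (a `movie_clip`) and `target` (a `movie_clip`,
#'   or a named list of them for the span objective).
#' @export
make_targets <- function(clip, objective = "prediction", offset_frames = 1,
                         seed = 1) {
  T_ <- n_frames(clip)
  if (objective == "prediction") {
    k_max <- max(offset_frames)
    if (k_max >= T_) stop("offset must be smaller than the clip length")
    take <- function(from, len) {
      movie_clip(clip$frames[from:(from + len - 1), , , drop = FALSE],
                 frame_rate = clip$frame_rate,
                 role = if (from == 1) "input" else "target")
    }
    len <- T_ - k_max
    input <- take(1, len)
    if (length(offset_frames) == 1L) {
      tgt <- if (k_max == 0) {
        movie_clip(clip$frames[1:len, , , drop = FALSE], clip$frame_rate, "target")
      } else {
        take(1 + k_max, len)
      }
      return(list(input = input, target = tgt))
    }
    targets <- lapply(offset_frames, function(k) {
      movie_clip(clip$frames[(1 + k):(k + len), , , drop = FALSE],
                 clip$frame_rate, "target")
    })
    names(targets) <- paste0("offset_", offset_frames)
    return(list(input = input, target = targets))
  }
  target <- movie_clip(clip$frames, clip$frame_rate, "target")
  input <- switch(objective,
    denoise = add_gaussian_noise_snr(clip, 3, seed = seed),
    inpaint = mask_patches(clip, n_patches = 8, patch = 8, seed = seed),
    sparse_ae = clip,
    stop("unknown objective: ", objective)
  )
  list(input = input, target = target)
}

#' Training loss of the network
#'
#' `E = sum_t ||v_hat[t] - target[t]||^2 + lambda_l1 * (|W_in|_1 + |W_rec|_1
#' + |W_out|_1) + lambda_act * sum_t |s[t]|_1`, the squared error summed
#' (not averaged) over time steps and pixels; biases are not regularised and
#' the activity term enters only for the sparse-autoencoder objective.
#'
#' @param params A `network_params` object.
#' @param state A `network_state` from [forward()].
#' @param targets A [movie_clip()] or `T x n_input` matrix of target frames.
#' @param config Optional `network_config` (defaults to the one in
#'   `params`).
#' @return Non-negative scalar loss.
#' @export
network_loss <- function(params, state, targets, config = params$config) {
  Vt <- if (inherits(targets, "movie_clip")) clip_matrix(targets) else as.matrix(targets)
  if (!all(dim(Vt) == dim(state$v_hat))) stop("prediction/target shape mismatch")
  err <- sum((state$v_hat - Vt)^2)
  reg <- config$lambda_l1 * (sum(abs(params$W_in)) + sum(abs(params$W_rec)) +
                               sum(abs(params$W_out)))
  act <- if (config$lambda_act > 0) config$lambda_act * sum(abs(state$s)) else 0
  err + reg + act
}
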