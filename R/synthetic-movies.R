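#' Parameters for the synthetic movie generator
#'
#' The surrogate corpus emulates the statistics the network needs from
#' naturalistic footage: grayscale patches whose spatial content is a
#' bandpass-filtered random texture with a 1/f-like amplitude falloff, and
#' whose temporal structure is advection — `n_layers` texture layers drift
#' at independent clip-specific velocities and are blended by smooth static
#' spatial masks, so motion is locally coherent but heterogeneous across
#' the frame — plus a small in-band generator noise term refreshed every
#' frame.
#'
#' @param n_clips Number of clips to generate (before the train/validation
#'   split).
#' @param clip_length Frames per clip (default 50).
#' @param patch_size Side of the square frame in pixels (default 36).
#' @param bandpass_band Length-2 vector, low/high spatial-frequency cutoffs in
#'   cycles/pixel retained by the retina-like bandpass stage.
#' @param drift_speed_range Length-2 vector, pixels/frame; each clip's drift
#'   speed is drawn uniformly from this interval (direction uniform on the
#'   circle).
#' @param texture_scale Characteristic texture length in pixels; sets the
#'   soft low-frequency knee of the 1/f-like amplitude spectrum.
#' @param n_layers Number of independently drifting texture layers blended
#'   per clip (default 2): motion is coherent within a layer's region but
#'   heterogeneous across the frame, as in natural footage.
#' @param frame_noise Amplitude of the per-frame in-band noise term relative
#'   to the texture amplitude.
#' @param seed Integer seed; the whole corpus is a pure function of
#'   (parameters, seed).
#' @return An object of class `movie_gen_params`.
#' @export
movie_gen_params <- function(n_clips = 100, clip_length = 50, patch_size = 36,
                             bandpass_band = c(0.02, 0.25),
                             drift_speed_range = c(0.5, 2),
                             texture_scale = 6, n_layers = 2,
                             frame_noise = 0.1, seed = 1) {
  stopifnot(
    n_clips >= 1, clip_length >= 2, patch_size >= 4,
    length(bandpass_band) == 2, bandpass_band[1] < bandpass_band[2],
    all(bandpass_band > 0),
    length(drift_speed_range) == 2,
    drift_speed_range[1] <= drift_speed_range[2],
    all(drift_speed_range >= 0), texture_scale > 0, frame_noise >= 0,
    n_layers >= 1
  )
  structure(
    list(
      n_clips = as.integer(n_clips), clip_length = as.integer(clip_length),
      patch_size = as.integer(patch_size), bandpass_band = bandpass_band,
      drift_speed_range = drift_speed_range, texture_scale = texture_scale,
      n_layers = as.integer(n_layers), frame_noise = frame_noise,
      seed = as.integer(seed)
    ),
    class = "movie_gen_params"
  )
}

# FFT frequency grid (cycles/pixel) for an n-pixel axis, matching the
# ordering of stats::fft output.
fft_freqs <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

# Annular amplitude filter: bandpass mask times 1/f-like falloff.
bandpass_amplitude <- function(n, band, texture_scale) {
  f <- fft_freqs(n)
  fr <- sqrt(outer(f^2, f^2, "+"))
  amp <- ifelse(fr >= band[1] & fr <= band[2], 1 / (fr + 1 / texture_scale), 0)
  amp
}

# One clip: `n_layers` filtered textures advected independently (each by
# its own (vx, vy) pixels/frame via Fourier phase shifts), blended with
# smooth static spatial masks so that motion is locally coherent but
# globally heterogeneous, re-bandpassed after blending, plus fresh in-band
# noise each frame. Returns T x H x W.
render_texture_clip <- function(params, velocities) {
  n <- params$patch_size
  T_ <- params$clip_length
  K <- nrow(velocities)
  amp <- bandpass_amplitude(n, params$bandpass_band, params$texture_scale)
  f <- fft_freqs(n)
  specs <- vector("list", K)
  steps <- vector("list", K)
  for (k in seq_len(K)) {
    specs[[k]] <- amp * stats::fft(matrix(stats::rnorm(n * n), n, n))
    steps[[k]] <- exp(-2i * pi * (outer(f, rep(1, n)) * velocities[k, 2] +
                                    outer(rep(1, n), f) * velocities[k, 1]))
  }
  # smooth static blending masks: softmax over low-frequency Gaussian fields
  masks <- if (K == 1) list(matrix(1, n, n)) else {
    lowpass <- ifelse(sqrt(outer(f^2, f^2, "+")) <= 1.5 / n * 2, 1, 0)
    fields <- lapply(seq_len(K), function(k) {
      g <- Re(stats::fft(lowpass * stats::fft(matrix(stats::rnorm(n * n), n, n)),
                         inverse = TRUE)) / (n * n)
      g / max(stats::sd(g), 1e-12)
    })
    z <- lapply(fields, function(g) exp(3 * g))
    tot <- Reduce(`+`, z)
    lapply(z, function(e) e / tot)
  }
  frames <- array(0, c(T_, n, n))
  for (t in seq_len(T_)) {
    blended <- matrix(0, n, n)
    for (k in seq_len(K)) {
      layer <- Re(stats::fft(specs[[k]], inverse = TRUE)) / (n * n)
      blended <- blended + masks[[k]] * layer
      specs[[k]] <- specs[[k]] * steps[[k]]
    }
    # re-apply the bandpass: blending is a spatial product and would
    # otherwise leak power outside the band
    spec_b <- (amp > 0) * stats::fft(blended)
    noise_spec <- amp * stats::fft(matrix(stats::rnorm(n * n), n, n))
    frames[t, , ] <- Re(stats::fft(spec_b + params$frame_noise * noise_spec,
                                   inverse = TRUE)) / (n * n)
  }
  s <- stats::sd(frames)
  if (s > 0) frames <- frames / s
  frames
}

#' Generate a synthetic training/validation movie corpus
#'
#' Produces `n_clips` advected-texture clips and splits them into disjoint
#' training and validation sets (last `val_fraction` of clips held out).
#' Deterministic for a fixed seed.
#'
#' @param params A [movie_gen_params()] object.
#' @param val_fraction Fraction of clips assigned to the validation set.
#' @return A list with elements `train` and `validation`, each a list of
#'   [movie_clip()] objects, plus the `params` used.
#' @export
generate_movie_corpus <- function(params, val_fraction = 0.1) {
  stopifnot(inherits(params, "movie_gen_params"),
            val_fraction >= 0, val_fraction < 1)
  amp <- bandpass_amplitude(params$patch_size, params$bandpass_band,
                            params$texture_scale)
  if (all(amp == 0)) {
    stop("configuration error: no representable spatial frequency falls ",
         "inside `bandpass_band` for this `patch_size`")
  }
  clips <- with_seed(params$seed, {
    lapply(seq_len(params$n_clips), function(i) {
      speed <- stats::runif(params$n_layers, params$drift_speed_range[1],
                            params$drift_speed_range[2])
      angle <- stats::runif(params$n_layers, 0, 2 * pi)
      frames <- render_texture_clip(params,
                                    cbind(speed * cos(angle),
                                          speed * sin(angle)))
      movie_clip(frames, role = "input")
    })
  })
  n_val <- floor(params$n_clips * val_fraction)
  n_train <- params$n_clips - n_val
  list(
    train = clips[seq_len(n_train)],
    validation = if (n_val > 0) clips[n_train + seq_len(n_val)] else list(),
    params = params
  )
}

#' Add Gaussian noise at a target signal-to-noise ratio
#'
#' Corrupts a clip with white Gaussian noise whose variance is set so that
#' `10*log10(var(signal)/var(noise))` equals `snr_db`. Signal power is the
#' variance of the clean clip over all pixels and frames. `snr_db = Inf` is
#' the no-noise sentinel and returns the clip unchanged.
#'
#' @param clip A [movie_clip()].
#' @param snr_db Target SNR in decibels (`Inf` for no noise).
#' @param seed Integer seed for the noise draw.
#' @return A new `movie_clip`; the input is not modified.
#' @export
add_gaussian_noise_snr <- function(clip, snr_db, seed = 1) {
  stopifnot(inherits(clip, "movie_clip"))
  if (is.infinite(snr_db) && snr_db > 0) return(clip)
  sp <- stats::var(as.vector(clip$frames))
  if (sp == 0) stop("SNR undefined: clip has zero signal power")
  noise_sd <- sqrt(sp / 10^(snr_db / 10))
  noisy <- with_seed(seed, clip$frames + stats::rnorm(length(clip$frames), sd = noise_sd))
  movie_clip(noisy, frame_rate = clip$frame_rate, role = clip$role)
}

#' Make a drifting sinusoidal grating clip
#'
#' Full-field sinusoid of amplitude 1 (pixel values span -1..1). The wave
#' vector points along the motion `direction`; the stripe `orientation` is
#' perpendicular to it. Give either `orientation` (stripes, axial, mod pi) or
#' `direction` (motion, mod 2*pi); if only `orientation` is supplied the
#' motion direction is `orientation + pi/2`.
#'
#' @param orientation Stripe orientation in radians (optional).
#' @param direction Motion direction in radians (optional).
#' @param sf Spatial frequency, cycles/pixel (must be <= 0.5).
#' @param tf Temporal (drift) frequency, cycles/frame (must be <= 0.5;
#'   0 gives a static grating).
#' @param phase Spatial phase in radians.
#' @param size Frame side in pixels.
#' @param n_frames Number of frames.
#' @return A [movie_clip()].
#' @export
make_grating <- function(orientation = NULL, direction = NULL, sf = 0.1,
                         tf = 0.05, phase = 0, size = 36, n_frames = 50) {
  if (is.null(direction)) {
    if (is.null(orientation)) stop("give `orientation` or `direction`")
    direction <- orientation + pi / 2
  }
  if (sf > 0.5 || sf < 0) stop("`sf` beyond the Nyquist limit (0.5 cycles/pixel)")
  if (tf > 0.5 || tf < 0) stop("`tf` beyond the Nyquist limit (0.5 cycles/frame)")
  xy <- seq_len(size)
  spatial <- 2 * pi * sf * (outer(rep(1, size), xy) * cos(direction) +
                              outer(xy, rep(1, size)) * sin(direction))
  frames <- array(0, c(n_frames, size, size))
  for (t in seq_len(n_frames)) {
    frames[t, , ] <- sin(spatial - 2 * pi * tf * (t - 1) + phase)
  }
  movie_clip(frames, role = "input")
}

# Integer-shift a binary mask on a torus by (dx, dy) pixels.
shift_mask <- function(mask, dx, dy) {
  n <- nrow(mask)
  ix <- ((seq_len(n) - 1 - dy) %% n) + 1
  iy <- ((seq_len(n) - 1 - dx) %% n) + 1
  mask[ix, iy]
}

#' Make area-matched moving bar and random-dot stimuli
#'
#' For each bar length `L` a bar of `L x width` lit pixels is paired with a
#' random-dot stimulus of exactly the same total lit area (square dots of
#' side `width`, plus one partial rectangle if needed), both translating at
#' the same integer-rounded speed along `direction` (toroidal wrap keeps the
#' lit area constant across frames).
#'
#' @param lengths Integer vector of bar lengths in pixels.
#' @param width Bar width (and dot side) in pixels.
#' @param direction Motion direction, radians.
#' @param speed Pixels per frame.
#' @param size Frame side in pixels.
#' @param n_frames Frames per clip.
#' @param seed Seed for dot placement.
#' @return A [stimulus_set()] with one bar and one dot clip per length; the
#'   labels table records class, length, lit area, direction and speed.
#' @export
make_bar_dot_stimuli <- function(lengths, width = 2, direction = 0, speed = 1,
                                 size = 36, n_frames = 50, seed = 1) {
  stopifnot(all(lengths >= 1), width >= 1)
  if (any(lengths > size) || width > size) stop("stimulus area exceeds the frame")
  build_clip <- function(mask) {
    frames <- array(0, c(n_frames, size, size))
    for (t in seq_len(n_frames)) {
      d <- round(speed * (t - 1))
      frames[t, , ] <- shift_mask(mask, round(d * cos(direction)),
                                  round(d * sin(direction)))
    }
    movie_clip(frames, role = "input")
  }
  place_dots <- function(n_px) {
    # square dots of side `width`, then one partial rectangle; >=1 px gap
    mask <- matrix(0, size, size)
    sides <- c(rep(width, n_px %/% (width * width)))
    rem <- n_px %% (width * width)
    with_seed(derive_seed(seed, n_px), {
      occupied <- matrix(FALSE, size, size)
      put <- function(h, w) {
        for (attempt in 1:500) {
          r <- sample.int(size - h + 1, 1)
          c <- sample.int(size - w + 1, 1)
          rr <- max(1, r - 1):min(size, r + h)
          cc <- max(1, c - 1):min(size, c + w)
          if (!any(occupied[rr, cc])) {
            mask[r:(r + h - 1), c:(c + w - 1)] <<- 1
            occupied[rr, cc] <<- TRUE
            return(TRUE)
          }
        }
        FALSE
      }
      for (s in sides) {
        if (!put(s, s)) stop("could not place dots without overlap; frame too small")
      }
      if (rem > 0) {
        h <- min(width, rem)
        w <- ceiling(rem / h)
        # trim to the exact remainder using an h x w block minus extras
        if (h * w != rem) {
          # use a 1 x rem strip for exactness
          h <- 1; w <- rem
        }
        if (!put(h, w)) stop("could not place dots without overlap; frame too small")
      }
    })
    mask
  }
  clips <- list()
  labels <- NULL
  for (L in lengths) {
    area <- L * width
    bar <- matrix(0, size, size)
    r0 <- floor((size - L) / 2)
    c0 <- floor((size - width) / 2)
    bar[r0 + seq_len(L), c0 + seq_len(width)] <- 1
    dot <- place_dots(area)
    stopifnot(sum(bar) == area, sum(dot) == area)
    clips <- c(clips, list(build_clip(bar), build_clip(dot)))
    labels <- rbind(labels, data.frame(
      stimulus_class = c("bar", "dots"), length = L, area = area,
      direction = direction, speed = speed
    ))
  }
  stimulus_set(clips, labels)
}

#' Make oddball and omission grating sequences with matched controls
#'
#' Two pattern elements A and B (static full-field gratings; for the
#' omission paradigm B is a blank frame) alternate one frame per element.
#' For each (pair, deviant position) the generator emits three sequences:
#' the violating sequence (the expected element at the deviant position is
#' replaced by the other element, or by a blank under omission), the
#' standard-completion control (pure alternation), and the shifted control
#' (alternation starting from B, so its frame at the deviant position equals
#' the deviant frame without violating any pattern).
#'
#' @param orientation_pairs Two-column matrix of A/B stripe orientations in
#'   radians; default all ordered pairs over 0/45/90/135 degrees.
#' @param paradigm `"oddball"` (B replaces expected A and vice versa) or
#'   `"omission"` (the deviant frame is blank).
#' @param deviant_positions Integer vector of deviant frame indices
#'   (default 5:25).
#' @param n_frames Sequence length in frames (default 25).
#' @param sf,size Grating spatial frequency and frame side.
#' @return A [stimulus_set()]; labels record pair, paradigm, sequence type
#'   (`violating`, `standard`, `shifted`) and deviant position.
#' @export
make_oddball_sequences <- function(orientation_pairs = NULL,
                                   paradigm = c("oddball", "omission"),
                                   deviant_positions = 5:25, n_frames = 25,
                                   sf = 0.1, size = 36) {
  paradigm <- match.arg(paradigm)
  if (is.null(orientation_pairs)) {
    oris <- deg2rad(c(0, 45, 90, 135))
    if (paradigm == "oddball") {
      grid <- expand.grid(a = oris, b = oris)
      grid <- grid[grid$a != grid$b, ]
      orientation_pairs <- as.matrix(grid)
    } else {
      orientation_pairs <- cbind(a = oris, b = NA_real_)
    }
  }
  if (any(deviant_positions < 1 | deviant_positions > n_frames)) {
    stop("deviant position outside the sequence")
  }
  grating_frame <- function(ori) {
    make_grating(orientation = ori, sf = sf, tf = 0, size = size,
                 n_frames = 2)$frames[1, , ]
  }
  blank <- matrix(0, size, size)
  clips <- list()
  labels <- NULL
  for (p_i in seq_len(nrow(orientation_pairs))) {
    a_ori <- unname(orientation_pairs[p_i, 1])
    A <- grating_frame(a_ori)
    B <- if (paradigm == "omission") blank else
      grating_frame(unname(orientation_pairs[p_i, 2]))
    elem <- function(k) if (k %% 2 == 1) A else B       # standard: A,B,A,B,...
    elem_shift <- function(k) if (k %% 2 == 1) B else A # shifted:  B,A,B,A,...
    seq_frames <- function(pick, deviant_at = NA) {
      frames <- array(0, c(n_frames, size, size))
      for (k in seq_len(n_frames)) frames[k, , ] <- pick(k)
      if (!is.na(deviant_at)) {
        frames[deviant_at, , ] <- if (paradigm == "omission") blank else elem_shift(deviant_at)
      }
      frames
    }
    for (p in deviant_positions) {
      clips <- c(clips, list(
        movie_clip(seq_frames(elem, deviant_at = p)),
        movie_clip(seq_frames(elem)),
        movie_clip(seq_frames(elem_shift))
      ))
      labels <- rbind(labels, data.frame(
        stimulus_class = "oddball", pair = p_i,
        orientation_a = a_ori,
        orientation_b = unname(orientation_pairs[p_i, 2]),
        paradigm = paradigm,
        sequence_type = c("violating", "standard", "shifted"),
        deviant_position = p
      ))
    }
  }
  stimulus_set(clips, labels)
}

#' Mask random square patches in every frame
#'
#' Implements the inpainting-style corruption: per frame, `n_patches`
#' square regions of side `patch` at seeded uniform positions are set to the
#' mask value 0 (the data mean). Overlap between patches is allowed.
#'
#' @param clip A [movie_clip()].
#' @param n_patches Patches per frame (default 8).
#' @param patch Patch side in pixels (default 8).
#' @param seed Integer seed for patch placement.
#' @return A new masked `movie_clip`; the input is untouched.
#' @export
mask_patches <- function(clip, n_patches = 8, patch = 8, seed = 1) {
  stopifnot(inherits(clip, "movie_clip"), n_patches >= 0, patch >= 1)
  d <- dim(clip$frames)
  if (patch > min(d[2:3])) stop("`patch` larger than the frame")
  if (n_patches == 0) return(clip)
  frames <- clip$frames
  with_seed(seed, {
    for (t in seq_len(d[1])) {
      for (k in seq_len(n_patches)) {
        r <- sample.int(d[2] - patch + 1, 1)
        c <- sample.int(d[3] - patch + 1, 1)
        frames[t, r:(r + patch - 1), c:(c + patch - 1)] <- 0
      }
    }
  })
  movie_clip(frames, frame_rate = clip$frame_rate, role = clip$role)
}

#' Simulate repeated-trial reference neurons from hidden activity
#'
#' Synthetic stand-in for extracellularly recorded visual neurons: each
#' neuron's signal rate is a rectified sigmoid of a random linear readout of
#' the supplied hidden activity (the readout is constructed inside the span
#' of the leading principal components, mirroring neurons driven by dominant
#' population features), and each trial adds independent Gaussian noise
#' before rectification.
#'
#' @param hidden_activity `T x n_units` matrix of model hidden activity.
#' @param n_neurons Number of reference neurons.
#' @param noise_level Trial noise standard deviation relative to the signal
#'   standard deviation (0 gives identical trials).
#' @param n_trials Number of repeated trials (must be >= 2).
#' @param seed Integer seed.
#' @param n_components Number of leading principal components spanned by the
#'   ground-truth readouts.
#' @return A list of class `reference_neuron_set`: `rates`
#'   (`n_neurons x n_trials x T`, non-negative), `ground_truth_filters`
#'   (`n_units x n_neurons`), `signal` (`n_neurons x T` noiseless rates), and
#'   `noise_to_signal_power` per neuron (from the across-trial decomposition).
#' @export
simulate_reference_neurons <- function(hidden_activity, n_neurons = 20,
                                       noise_level = 0.2, n_trials = 10,
                                       seed = 1, n_components = 50) {
  stopifnot(is.matrix(hidden_activity), all(is.finite(hidden_activity)))
  if (n_trials < 2) stop("n_trials must be >= 2 (noise ceiling undefined otherwise)")
  T_ <- nrow(hidden_activity)
  k <- min(n_components, ncol(hidden_activity), T_ - 1)
  pc <- stats::prcomp(hidden_activity, center = TRUE, rank. = k)
  out <- with_seed(seed, {
    w <- matrix(stats::rnorm(k * n_neurons), k, n_neurons)
    x <- scale(pc$x[, seq_len(k), drop = FALSE] %*% w)
    signal <- pmax(1 / (1 + exp((0.3 - x) / 0.4)) - 0.1, 0)
    rates <- array(0, c(n_neurons, n_trials, T_))
    for (n in seq_len(n_neurons)) {
      s_sd <- stats::sd(signal[, n])
      if (s_sd == 0) s_sd <- 1
      for (tr in seq_len(n_trials)) {
        rates[n, tr, ] <- pmax(0, signal[, n] +
                                 noise_level * s_sd * stats::rnorm(T_))
      }
    }
    list(rates = rates, w = w, signal = t(signal))
  })
  filters <- pc$rotation[, seq_len(k), drop = FALSE] %*% out$w
  nsr <- vapply(seq_len(n_neurons), function(n) {
    dec <- signal_noise_power(out$rates[n, , ])
    if (dec$signal_power <= 0) Inf else dec$noise_power / dec$signal_power
  }, numeric(1))
  structure(
    list(rates = out$rates, ground_truth_filters = filters,
         signal = out$signal, noise_to_signal_power = nsr),
    class = "reference_neuron_set"
  )
}

#' @export
print.reference_neuron_set <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf(
    "<reference_neuron_set> %d neurons x %d trials x %d bins; median N/S power %.3g\n",
    d[1], d[2], d[3], stats::median(x$noise_to_signal_power)
  ))
  invisible(x)
}

#' Desk-scale corpus conditions
#'
#' The movie-generator settings used by the package's own desk-scale
#' experiments: 2,000 clips of 50 frames at 16x16 pixels, with the
#' bandpass band rescaled so the cycles-per-patch range matches the
#' full-scale 36-pixel configuration (0.72-9 cycles per patch, i.e.
#' 0.045-0.45 cycles/pixel at 16 pixels).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [movie_gen_params()].
#' @return A `movie_gen_params` object.
#' @export
scaled_corpus_params <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_clips = 2000, patch_size = 16, clip_length = 50,
         bandpass_band = c(0.045, 0.45), seed = seed),
    list(...)
  )
  do.call(movie_gen_params, args)
}
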