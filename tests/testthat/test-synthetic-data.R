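# Stimulus and surrogate-data generators.

test_that("movie corpus is deterministic and splits disjointly", {
  mp <- movie_gen_params(n_clips = 5, patch_size = 12, clip_length = 10,
                         seed = 1)
  c1 <- generate_movie_corpus(mp)
  c2 <- generate_movie_corpus(mp)
  expect_identical(c1$train, c2$train)
  expect_identical(c1$validation, c2$validation)
  expect_length(c1$train, 5)   # floor(5 * 0.1) = 0 held out
  c3 <- generate_movie_corpus(movie_gen_params(n_clips = 20, patch_size = 12,
                                               clip_length = 10, seed = 2))
  expect_length(c3$train, 18)
  expect_length(c3$validation, 2)
})

test_that("zero drift leaves only generator noise between frames", {
  drifting <- generate_movie_corpus(
    movie_gen_params(n_clips = 2, patch_size = 16, clip_length = 20,
                     seed = 7))$train[[1]]
  static <- generate_movie_corpus(
    movie_gen_params(n_clips = 2, patch_size = 16, clip_length = 20,
                     drift_speed_range = c(0, 0), seed = 7))$train[[1]]
  msd <- function(clip) {
    T_ <- n_frames(clip)
    mean((clip$frames[-1, , ] - clip$frames[-T_, , ])^2)
  }
  expect_lt(msd(static), msd(drifting))
  # static frame-to-frame differences carry no systematic structure: the
  # mean frame difference is near zero
  expect_lt(abs(mean(static$frames[2, , ] - static$frames[1, , ])), 0.05)
})

test_that("clip spectra respect the bandpass band", {
  mp <- movie_gen_params(n_clips = 2, patch_size = 36, clip_length = 10,
                         seed = 3)
  clip <- generate_movie_corpus(mp)$train[[1]]
  f <- lateralpred:::fft_freqs(36)
  frad <- sqrt(outer(f^2, f^2, "+"))
  inband <- frad >= mp$bandpass_band[1] & frad <= mp$bandpass_band[2]
  for (t in c(1, 5, 10)) {
    spec <- Mod(stats::fft(clip$frames[t, , ]))^2
    expect_gt(sum(spec[inband]) / sum(spec), 0.99)
  }
  expect_lt(abs(mean(clip$frames)), 1e-8) # DC excluded -> zero mean
})

test_that("an unrepresentable bandpass band is a configuration error", {
  expect_error(
    generate_movie_corpus(movie_gen_params(n_clips = 1, patch_size = 8,
                                           clip_length = 4,
                                           bandpass_band = c(0.001, 0.01))),
    "configuration error"
  )
})

test_that("noise injection hits the requested SNR", {
  clip <- generate_movie_corpus(movie_gen_params(n_clips = 1, patch_size = 36,
                                                 clip_length = 50,
                                                 seed = 4))$train[[1]]
  expect_identical(add_gaussian_noise_snr(clip, Inf), clip)
  ratio_for <- function(db, seed = 2) {
    noisy <- add_gaussian_noise_snr(clip, db, seed = seed)
    stats::var(as.vector(noisy$frames - clip$frames)) /
      stats::var(as.vector(clip$frames))
  }
  expect_gt(ratio_for(0), 0.95)
  expect_lt(ratio_for(0), 1.05)
  expect_equal(ratio_for(6), 10^(-0.6), tolerance = 0.05)
  # attained SNR within 0.2 dB on a default-size clip
  for (db in c(0, 3, 6)) {
    expect_lt(abs(-10 * log10(ratio_for(db)) - db), 0.2)
  }
  zero <- movie_clip(array(0, c(3, 4, 4)))
  expect_error(add_gaussian_noise_snr(zero, 6), "zero signal power")
})

test_that("gratings drift, saturate at amplitude 1, and respect symmetry", {
  g0 <- make_grating(direction = 0.4, sf = 0.2, tf = 0, size = 24,
                     n_frames = 5)
  for (t in 2:5) expect_equal(g0$frames[t, , ], g0$frames[1, , ])
  g <- make_grating(direction = 0.4, sf = 0.2, tf = 0.1, size = 64,
                    n_frames = 30)
  expect_equal(max(g$frames), 1, tolerance = 1e-3)
  expect_equal(min(g$frames), -1, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(g$frames[1, , ], g$frames[2, , ])))
  # flipping the motion direction by pi negates the static pattern, and a
  # pi phase shift restores it: the stripe pattern is axial
  ga <- make_grating(direction = 1, sf = 0.15, tf = 0, size = 16, n_frames = 2)
  gb <- make_grating(direction = 1 + pi, sf = 0.15, tf = 0, size = 16,
                     n_frames = 2)
  gc <- make_grating(direction = 1 + pi, sf = 0.15, tf = 0, phase = pi,
                     size = 16, n_frames = 2)
  expect_equal(gb$frames, -ga$frames, tolerance = 1e-12)
  expect_equal(gc$frames, ga$frames, tolerance = 1e-12)
  expect_error(make_grating(direction = 0, sf = 0.6), "Nyquist")
  expect_error(make_grating(direction = 0, sf = 0.1, tf = 0.7), "Nyquist")
})

test_that("bar and dot stimuli are exactly area matched", {
  ss <- make_bar_dot_stimuli(lengths = c(3, 6, 9), width = 2, speed = 1,
                             size = 24, n_frames = 8, seed = 2)
  expect_equal(nrow(ss$labels), 6)
  for (L in c(3, 6, 9)) {
    rows <- which(ss$labels$length == L)
    areas <- vapply(rows, function(i) sum(ss$clips[[i]]$frames[1, , ] > 0),
                    numeric(1))
    expect_equal(areas[1], areas[2])
    expect_equal(areas[1], L * 2)
  }
  # every frame preserves the lit area (toroidal translation)
  for (i in seq_along(ss$clips)) {
    per_frame <- apply(ss$clips[[i]]$frames > 0, 1, sum)
    expect_true(all(per_frame == per_frame[1]))
  }
})

test_that("dot stimuli are disconnected; zero speed is static", {
  ss <- make_bar_dot_stimuli(lengths = 8, width = 2, speed = 0, size = 24,
                             n_frames = 5, seed = 3)
  dots <- ss$clips[[which(ss$labels$stimulus_class == "dots")]]
  # flood-fill component count oracle (4-connectivity)
  n_components <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    k <- 0L
    for (start in which(mask)) {
      if (lab[start] != 0L) next
      k <- k + 1L
      queue <- start
      while (length(queue) > 0) {
        cur <- queue[1]; queue <- queue[-1]
        if (lab[cur] != 0L || !mask[cur]) next
        lab[cur] <- k
        r <- (cur - 1) %% nrow(mask) + 1
        c <- (cur - 1) %/% nrow(mask) + 1
        nb <- c(if (r > 1) cur - 1, if (r < nrow(mask)) cur + 1,
                if (c > 1) cur - nrow(mask), if (c < ncol(mask)) cur + nrow(mask))
        queue <- c(queue, nb[mask[nb] & lab[nb] == 0L])
      }
    }
    max(lab)
  }
  expect_gte(n_components(dots$frames[1, , ] > 0), 2)
  for (t in 2:5) expect_equal(dots$frames[t, , ], dots$frames[1, , ])
  expect_error(make_bar_dot_stimuli(lengths = 30, width = 2, size = 24),
               "exceeds the frame")
})

test_that("oddball sequences violate the pattern only at the deviant", {
  ss <- make_oddball_sequences(
    orientation_pairs = cbind(0, pi / 4), paradigm = "oddball",
    deviant_positions = c(5, 12), n_frames = 25, size = 12
  )
  lab <- ss$labels
  grab <- function(type, p) {
    ss$clips[[which(lab$sequence_type == type & lab$deviant_position == p)]]
  }
  v <- grab("violating", 5); s <- grab("standard", 5); h <- grab("shifted", 5)
  # frames 1..4 alternate A,B,A,B and frame 5 is the B-type deviant
  expect_equal(v$frames[1:4, , ], s$frames[1:4, , ])
  expect_equal(v$frames[5, , ], s$frames[2, , ])       # B where A expected
  expect_false(isTRUE(all.equal(v$frames[5, , ], s$frames[5, , ])))
  # violating and shifted share the frame at the deviant position
  expect_equal(v$frames[5, , ], h$frames[5, , ])
  # outside the deviant, violating equals standard everywhere
  expect_equal(v$frames[6:25, , ], s$frames[6:25, , ])
  expect_error(make_oddball_sequences(orientation_pairs = cbind(0, 1),
                                      deviant_positions = 30, n_frames = 25),
               "outside the sequence")
})

test_that("omission deviants are blank frames", {
  ss <- make_oddball_sequences(paradigm = "omission",
                               deviant_positions = 7, n_frames = 25,
                               size = 10)
  lab <- ss$labels
  v <- ss$clips[[which(lab$sequence_type == "violating" & lab$pair == 1)]]
  expect_true(all(v$frames[7, , ] == 0))
  expect_false(all(v$frames[1, , ] == 0)) # grating where A expected
})

test_that("patch masking is bounded, seeded, and identity at zero", {
  clip <- rand_clip(T = 4, side = 20, seed = 9)
  expect_identical(mask_patches(clip, n_patches = 0), clip)
  m1 <- mask_patches(clip, n_patches = 8, patch = 8, seed = 5)
  m2 <- mask_patches(clip, n_patches = 8, patch = 8, seed = 5)
  expect_identical(m1, m2)
  changed <- apply(m1$frames != clip$frames, 1, sum)
  expect_true(all(changed <= 8 * 64))
  expect_true(all(changed > 0))
  expect_error(mask_patches(clip, patch = 30), "larger than the frame")
})

test_that("reference neurons have controlled noise structure", {
  set.seed(2)
  act <- matrix(stats::rnorm(200 * 30)^2, 200, 30)
  expect_error(simulate_reference_neurons(act, n_trials = 1), "n_trials")
  clean <- simulate_reference_neurons(act, n_neurons = 5, noise_level = 0,
                                      n_trials = 3, seed = 1)
  expect_equal(clean$rates[, 1, ], clean$rates[, 2, ])
  expect_true(all(clean$noise_to_signal_power < 1e-10))
  expect_true(all(clean$rates >= 0))
  # mean noise-to-signal ratio grows strictly with the noise level
  levels <- c(0.1, 0.3, 0.6)
  nsr <- vapply(levels, function(nl) {
    mean(simulate_reference_neurons(act, n_neurons = 8, noise_level = nl,
                                    n_trials = 8, seed = 4)$noise_to_signal_power)
  }, numeric(1))
  expect_true(all(diff(nsr) > 0))
  r1 <- simulate_reference_neurons(act, n_neurons = 3, noise_level = 0.2,
                                   n_trials = 4, seed = 7)
  r2 <- simulate_reference_neurons(act, n_neurons = 3, noise_level = 0.2,
                                   n_trials = 4, seed = 7)
  expect_identical(r1$rates, r2$rates)
})
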