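# Shared fixtures. Everything is generated in code; the expensive trained
# scaled model is built once per test run and cached for all tests that
# probe the trained network.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_input = 4, n_hidden = 6, frac_inhibitory = 1 / 3, seed = 42),
    list(...)
  )
  do.call(network_config, args)
}

tiny_net <- function(...) init_network(tiny_config(...))

rand_clip <- function(T = 6, side = 2, seed = 1) {
  set.seed(seed)
  movie_clip(array(stats::rnorm(T * side * side), c(T, side, side)))
}

small_corpus <- function(n = 12, side = 8, T = 20, seed = 3, ...) {
  generate_movie_corpus(movie_gen_params(n_clips = n, patch_size = side,
                                         clip_length = T, seed = seed, ...))
}

# A linear-rectified network whose hidden units have known Gabor input
# filters (no recurrence): ground truth for estimator-recovery tests.
planted_gabor_net <- function(side = 16, thetas = c(0, pi / 4, pi / 2),
                              sf = 0.15, sigma = 2.5, seed = 5) {
  nh <- length(thetas)
  cfg <- network_config(n_input = side^2, n_hidden = max(nh, 2),
                        frac_inhibitory = 1 / max(nh, 2), seed = seed)
  p <- init_network(cfg)
  p$W_rec[] <- 0
  p$b_rec[] <- 0
  p$W_out[] <- 0
  filters <- matrix(0, max(nh, 2), side^2)
  xg <- outer(rep(1, side), seq_len(side))
  yg <- outer(seq_len(side), rep(1, side))
  ctr <- (side + 1) / 2
  for (i in seq_len(nh)) {
    th <- thetas[i] - pi / 2 # wave vector angle for stripe orientation th
    xr <- (xg - ctr) * cos(th) + (yg - ctr) * sin(th)
    yr <- -(xg - ctr) * sin(th) + (yg - ctr) * cos(th)
    g <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * sf * xr)
    filters[i, ] <- as.vector(g)
  }
  p$W_in <- filters
  list(params = p, filters = filters[seq_len(nh), , drop = FALSE])
}

# ---- cached scaled trained model (the package's study condition) --------
# 16x16 patches, 512 hidden units, 2,000 synthetic clips; built once.
.trained_cache <- new.env(parent = emptyenv())

scaled_study <- function() {
  if (!exists("study", envir = .trained_cache)) {
    corpus <- generate_movie_corpus(scaled_corpus_params(seed = 11))
    cfg <- scaled_profile(seed = 11)
    init <- init_network(cfg)
    fit <- train_network(init, corpus, epochs = 30, batch_size = 50)
    assign("study", list(corpus = corpus, init = init, params = fit$params,
                         history = fit$history),
           envir = .trained_cache)
  }
  get("study", envir = .trained_cache)
}

# Downstream physiology of the trained model, computed once: grating
# tuning plus the thresholded connectivity graph over all units (the
# tuning-gated analyses select their unit subsets themselves).
scaled_physiology <- function() {
  if (!exists("phys", envir = .trained_cache)) {
    st <- scaled_study()
    battery <- grating_battery(st$params)
    tuning <- classify_selectivity(tuning_profiles(battery))
    graph <- threshold_connections(dale_weights(st$params),
                                   st$params$unit_sign)
    assign("phys", list(tuning = tuning, graph = graph),
           envir = .trained_cache)
  }
  get("phys", envir = .trained_cache)
}

# Hand construction of a connectivity_graph for toy analyses.
toy_graph <- function(adjacency, weight, population,
                      centers = NULL, units = seq_len(ncol(adjacency))) {
  g <- list(adjacency = adjacency, weight = weight, units = units,
            population = population, percentile = NA, threshold = NA)
  if (!is.null(centers)) {
    cx <- centers[, 1]; cy <- centers[, 2]
    d <- sqrt(outer(cy, cy, "-")^2 + outer(cx, cx, "-")^2)
    g$rf_distance <- d
    rc <- matrix("excluded", nrow(d), ncol(d))
    rc[which(d < 2.5)] <- "short"
    rc[which(d > 5 & d <= 9.17)] <- "long"
    g$range_class <- rc
  }
  structure(g, class = "connectivity_graph")
}
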