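# Ablations, silhouette clustering, bar/dot deficits, prediction-error
# units.

make_toy_ablation_setup <- function() {
  set.seed(21)
  n <- 20
  W <- apply_dale_constraint(matrix(rnorm(n * n), n, n),
                             rep(c(1, -1), c(16, 4)))
  g <- threshold_connections(W, rep(c(1, -1), c(16, 4)), percentile = 70)
  po <- runif(n, 0, pi)
  tun <- data.frame(unit = 1:n, preferred_orientation = po,
                    preferred_direction = runif(n, 0, 2 * pi),
                    OSI = 0.9, DSI = 0.9)
  list(W = W, g = g, tun = tun)
}

test_that("ablation touches exactly the selected edges", {
  s <- make_toy_ablation_setup()
  edges <- select_ablation_edges(s$g, s$tun, "co_tuned")
  expect_gt(nrow(edges), 0)
  med <- median_ee_weight(s$g)
  abl1 <- ablate(s$g, edges, n_ablate = 1, n_repeats = 3, seed = 5)
  W1 <- apply_ablation(s$W, abl1, 1)
  diff_idx <- which(W1 != s$W)
  expect_lte(length(diff_idx), 1) # exactly one entry (unless already median)
  expect_true(all(W1[diff_idx] == med))
  # zero ablations leave the weights identical
  abl0 <- ablate(s$g, edges, n_ablate = 0, n_repeats = 2, seed = 5)
  expect_identical(apply_ablation(s$W, abl0, 1), s$W)
  # seeded draws reproduce
  abl2 <- ablate(s$g, edges, n_ablate = 3, n_repeats = 4, seed = 9)
  abl3 <- ablate(s$g, edges, n_ablate = 3, n_repeats = 4, seed = 9)
  expect_identical(abl2$edge_sets, abl3$edge_sets)
  expect_error(ablate(s$g, edges[0, , drop = FALSE], 1), "empty")
  expect_error(ablate(s$g, edges, nrow(edges) + 1), "exceeds")
  # only E->E edges are eligible
  expect_true(all(s$g$population[edges[, 1]] == "E"))
  expect_true(all(s$g$population[edges[, 2]] == "E"))
})

test_that("the tuning windows partition edges into ablation classes", {
  s <- make_toy_ablation_setup()
  co <- select_ablation_edges(s$g, s$tun, "co_tuned")
  orth <- select_ablation_edges(s$g, s$tun, "orthogonal")
  po <- s$tun$preferred_orientation
  if (nrow(co) > 0) {
    d <- lateralpred:::fold_angle_diff(po[co[, 2]] - po[co[, 1]], pi)
    expect_true(all(d < pi / 8))
  }
  if (nrow(orth) > 0) {
    d <- lateralpred:::fold_angle_diff(po[orth[, 2]] - po[orth[, 1]], pi)
    expect_true(all(d > 3 * pi / 8))
  }
  # the two orientation classes never overlap
  expect_equal(nrow(merge(as.data.frame(co), as.data.frame(orth))), 0)
})

test_that("the error curve anchors at the unablated model", {
  corpus <- small_corpus(n = 10, side = 6, T = 10, seed = 23)
  cfg <- network_config(n_input = 36, n_hidden = 16, frac_inhibitory = 0.25,
                        learning_rate = 1e-3, seed = 4)
  fit <- train_network(init_network(cfg), corpus, epochs = 2, batch_size = 4)
  W <- dale_weights(fit$params)
  g <- threshold_connections(W, fit$params$unit_sign, percentile = 60)
  po <- seq(0, pi, length.out = 17)[1:16]
  tun <- data.frame(unit = 1:16, preferred_orientation = po,
                    preferred_direction = po * 2, OSI = 0.9, DSI = 0.9)
  curve <- ablation_error_curve(fit$params, corpus$validation, g, tun,
                                classes = c("co_tuned", "orthogonal"),
                                n_grid = c(0, 2), n_repeats = 3, seed = 1)
  base <- attr(curve, "baseline_mse")
  expect_equal(curve$mse[curve$n_ablate == 0], rep(base, 2))
  # replacing an edge with its own weight is a null ablation
  edges <- select_ablation_edges(g, tun, "co_tuned")
  e1 <- edges[1, , drop = FALSE]
  abl <- ablate(g, e1, 1, n_repeats = 1, seed = 2,
                replacement = W[g$units[e1[1, 1]], g$units[e1[1, 2]]])
  expect_equal(predict_mse(fit$params, corpus$validation,
                           W_rec_override = apply_ablation(W, abl, 1)),
               base)
})

test_that("silhouette scores match the direct per-point formula", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  labels <- rep(1:2, each = 10)
  got <- lateralpred:::mean_silhouette(pts, labels)
  # direct (b - a) / max(a, b) recomputation
  D <- as.matrix(stats::dist(pts))
  sil <- vapply(seq_len(20), function(i) {
    a <- mean(D[i, labels == labels[i] & seq_len(20) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(got, mean(sil), tolerance = 1e-12)
  expect_gt(got, 0.8) # two tight, well-separated clusters
  # random labels give a near-zero score; always within [-1, 1]
  set.seed(32)
  rnd <- replicate(20, {
    p <- matrix(rnorm(60), 30, 2)
    lateralpred:::mean_silhouette(p, sample(rep(1:3, each = 10)))
  })
  expect_true(all(rnd >= -1 & rnd <= 1))
  expect_lt(abs(mean(rnd)), 0.1)
})

test_that("silhouette analysis separates orientation classes when clean", {
  net <- planted_gabor_net(side = 12,
                           thetas = seq(0, pi, length.out = 9)[1:8],
                           seed = 6)
  res <- silhouette_analysis(net$params, base_orientations = c(0, pi / 2),
                             snr_db = Inf, n_reps = 3, n_frames = 10,
                             seed = 3)
  expect_true(all(res$scores >= -1 & res$scores <= 1))
  noisy <- silhouette_analysis(net$params, base_orientations = c(0, pi / 2),
                               snr_db = -9.5, n_reps = 3, n_frames = 10,
                               seed = 3)
  expect_true(all(noisy$scores >= -1 & noisy$scores <= 1))
  expect_lt(noisy$mean_silhouette, res$mean_silhouette)
})

test_that("bar/dot deficits are zero without ablation", {
  corpus_cfg <- network_config(n_input = 144, n_hidden = 16,
                               frac_inhibitory = 0.25, learning_rate = 1e-3,
                               seed = 8)
  p <- init_network(corpus_cfg)
  stim <- make_bar_dot_stimuli(lengths = c(4, 8), width = 2, size = 12,
                               n_frames = 10, seed = 2)
  res <- bar_dot_deficit(p, NULL, stim)
  expect_true(all(res$table$deficit_pct == 0))
  expect_equal(nrow(res$table), 4)
})

test_that("prediction-error units are detected by their history dependence", {
  # hand-built circuit on 1x2 frames: A = (1, 0), B = (0, 1)
  size <- 2 # frames are 1 x 2... use 2x1? movie frames H x W; use H=1, W=2
  A <- matrix(c(1, 0), 1, 2)
  B <- matrix(c(0, 1), 1, 2)
  mk <- function(elems, deviant_at = NA, deviant = NULL) {
    fr <- array(0, c(25, 1, 2))
    for (k in 1:25) fr[k, , ] <- elems[[(k - 1) %% 2 + 1]]
    if (!is.na(deviant_at)) fr[deviant_at, , ] <- deviant
    movie_clip(fr)
  }
  clips <- list(); lab <- NULL
  for (p_dev in 5:14) {
    dev <- if (p_dev %% 2 == 1) B else A # swap the expected element
    clips <- c(clips, list(mk(list(A, B), p_dev, dev), mk(list(A, B)),
                           mk(list(B, A))))
    lab <- rbind(lab, data.frame(
      stimulus_class = "oddball", pair = 1, paradigm = "oddball",
      sequence_type = c("violating", "standard", "shifted"),
      deviant_position = p_dev
    ))
  }
  ss <- stimulus_set(clips, lab)
  cfg <- network_config(n_input = 2, n_hidden = 4, frac_inhibitory = 0.25,
                        seed = 1)
  p <- init_network(cfg)
  p$W_in[] <- 0; p$W_rec[] <- 0; p$b_rec[] <- 0; p$unit_sign <- rep(1, 4)
  # unit 1: B detector (feedforward); unit 2: pure PE, needs B now AND B on
  # the previous frame (only the violating sequence has B after B, at the
  # 5 odd deviant positions); unit 3: responds 3 to a B-after-B deviant
  # and exactly 1 to the shifted control's B-after-A; unit 4: silent
  p$W_in[1, 2] <- 1
  p$W_in[2, 2] <- 1; p$W_rec[2, 1] <- 1; p$b_rec[2] <- -1.5
  p$W_in[3, 2] <- 10; p$W_rec[3, 1] <- 2; p$b_rec[3] <- -9
  res_strict <- detect_prediction_error_units(p, ss, "strict")
  expect_equal(res_strict$class, c("mixed", "pure_PE", "mixed", "none"))
  res_loose <- detect_prediction_error_units(p, ss, "loose")
  expect_equal(res_loose$class[2], "pure_PE")
  # unit 3's deviant response is exactly 3x the control: fails the strict
  # exceedance of the loose criterion
  expect_equal(res_loose$class[3], "mixed")
})
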