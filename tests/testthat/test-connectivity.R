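# Thresholded graphs, tuning-difference profiles, trend test, visual-space
# normalisation, shuffle controls, and the connectivity score.

test_that("percentile thresholding matches a sort-and-count oracle", {
  set.seed(5)
  n <- 40
  W <- matrix(rnorm(n * n), n, n)
  sign <- rep(c(1, -1), c(30, 10))
  We <- apply_dale_constraint(W, sign)
  g <- threshold_connections(We, sign, percentile = 95)
  aw <- abs(We)[row(We) != col(We)]
  thr <- sort(aw)[ceiling(0.95 * (length(aw) - 1)) ] # bracket the quantile
  oracle <- sum(abs(We) > stats::quantile(aw, 0.95) & row(We) != col(We))
  expect_equal(sum(g$adjacency), oracle)
  # ~5% of ordered pairs under distinct weights
  expect_equal(sum(g$adjacency) / (n * (n - 1)), 0.05, tolerance = 0.01)
  # raising the percentile never adds edges
  g99 <- threshold_connections(We, sign, percentile = 99)
  expect_true(all(g$adjacency[g99$adjacency]))
  expect_lt(sum(g99$adjacency), sum(g$adjacency))
  # all-equal weights: nothing strictly exceeds the threshold
  g_eq <- threshold_connections(matrix(1, 5, 5), rep(1, 5))
  expect_equal(sum(g_eq$adjacency), 0)
})

test_that("range classes follow the receptive-field distance cut-offs", {
  centers <- cbind(c(0, 1, 7, 20), c(0, 0, 0, 0))
  W <- matrix(1, 4, 4) + diag(4)
  g <- threshold_connections(W, rep(1, 4), percentile = 10,
                             centers = centers)
  expect_equal(g$range_class[2, 1], "short")    # distance 1
  expect_equal(g$range_class[3, 1], "long")     # distance 7
  expect_equal(g$range_class[4, 1], "excluded") # distance 20 > 9.17
  expect_equal(g$range_class[3, 2], "long")     # distance 6
  expect_equal(g$rf_distance[2, 1], 1)
})

test_that("connection probability by tuning difference is per-bin counts", {
  # 6 excitatory units; orientations chosen to land in known bins
  po <- c(0, 0, pi / 4, pi / 4, pi / 2, pi / 2)
  tuning <- data.frame(
    unit = 1:6, preferred_orientation = po, preferred_direction = po * 2,
    OSI = 0.9, DSI = 0.9,
    class = factor(rep("orientation_selective", 6),
                   levels = c("orientation_selective", "direction_selective",
                              "non_selective"))
  )
  adj <- matrix(FALSE, 6, 6)
  adj[2, 1] <- TRUE # delta 0
  adj[3, 1] <- TRUE # delta 45
  adj[5, 1] <- TRUE # delta 90
  g <- toy_graph(adj, matrix(0.5, 6, 6), rep("E", 6))
  prof <- probability_by_tuning_difference(g, tuning, "orientation",
                                           range = "all")
  # candidates per bin: delta 0 pairs (within groups): 3 groups * 2 = 6;
  # delta 45: 0-45 and 45-90 cross pairs = 16; delta 90: 0-90 pairs = 8
  expect_equal(prof$candidates, c(6, 16, 8))
  expect_equal(prof$connected, c(1, 1, 1))
  expect_equal(prof$probability, c(1 / 6, 1 / 16, 1 / 8))
  # arithmetic case from hand counts
  hand <- data.frame(connected = c(2, 1, 1), candidates = c(4, 4, 4))
  expect_equal(hand$connected / hand$candidates, c(0.5, 0.25, 0.25))
})

test_that("the trend statistic matches closed forms and permutations", {
  # equal proportions: no trend
  flat <- data.frame(connected = c(10, 10, 10), candidates = c(40, 40, 40))
  r <- cochran_armitage_trend(flat)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  # two-bin case equals the two-proportion z statistic
  two <- data.frame(connected = c(12, 5), candidates = c(30, 30))
  r2 <- cochran_armitage_trend(two)
  p1 <- 12 / 30; p2 <- 5 / 30; pb <- 17 / 60
  z_two_prop <- (p2 - p1) / sqrt(pb * (1 - pb) * (1 / 30 + 1 / 30))
  expect_equal(r2$statistic, z_two_prop, tolerance = 1e-10)
  # agrees with the chi-squared trend test
  pt <- suppressWarnings(stats::prop.trend.test(c(12, 5), c(30, 30)))
  expect_equal(r2$statistic^2, unname(pt$statistic), tolerance = 1e-10)
  # permutation oracle on a small monotone table
  tab <- data.frame(connected = c(8, 4, 1), candidates = c(20, 20, 20))
  robs <- cochran_armitage_trend(tab)
  outcomes <- rep(rep(c(1, 0), 3), c(8, 12, 4, 16, 1, 19))
  bins <- rep(0:2, each = 20)
  set.seed(99)
  zs <- replicate(20000, {
    o <- sample(outcomes)
    x <- tapply(o, bins, sum)
    cochran_armitage_trend(data.frame(connected = as.vector(x),
                                      candidates = c(20, 20, 20)))$statistic
  })
  p_perm <- mean(abs(zs) >= abs(robs$statistic) - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / 20000)
  expect_lt(abs(p_perm - robs$p_value), max(4 * se, 0.01))
  # degenerate margins
  expect_warning(
    r0 <- cochran_armitage_trend(data.frame(connected = c(0, 0),
                                            candidates = c(5, 5))),
    "degenerate"
  )
  expect_equal(r0$p_value, 1)
})

test_that("visual-space normalisation satisfies the worked examples", {
  expect_equal(drop(normalize_visual_space(c(3, 5), c(3, 4), pi / 2)),
               c(0, 1), tolerance = 1e-12)
  # theta = pi/2: the rotation is the identity
  set.seed(2)
  pts <- matrix(rnorm(10), 5, 2)
  expect_equal(normalize_visual_space(pts, c(0, 0), pi / 2), pts,
               tolerance = 1e-12)
  expect_equal(drop(normalize_visual_space(c(1, 0), c(0, 0), 0)),
               c(0, -1), tolerance = 1e-12)
})

test_that("normalisation is a rigid motion and axially symmetric", {
  set.seed(7)
  pts <- matrix(rnorm(40), 20, 2)
  post <- c(0.3, -1)
  theta <- 0.8
  out <- normalize_visual_space(pts, post, theta)
  expect_equal(as.vector(stats::dist(out)), as.vector(stats::dist(pts)),
               tolerance = 1e-12)
  # inverse transform recovers the inputs
  a <- theta - pi / 2
  Rinv <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  back <- out %*% t(Rinv) + matrix(post, 20, 2, byrow = TRUE)
  expect_equal(back, pts, tolerance = 1e-12)
  # sector labels are invariant under theta -> theta + pi
  out2 <- normalize_visual_space(pts, post, theta + pi)
  expect_equal(abs(out2), abs(out), tolerance = 1e-12)
  sec <- function(m) abs(m[, 2]) > abs(m[, 1])
  expect_equal(sec(out2), sec(out))
})

test_that("co-axial and co-orthogonal sectors split the candidate pairs", {
  # post unit at centre, orientation pi/2 (vertical axis); pre units at
  # distance 6 along and across the axis, plus one exact diagonal
  centers <- rbind(c(8, 8), c(8, 14), c(8, 2), c(14, 8), c(2, 8),
                   c(8 + 6 / sqrt(2), 8 + 6 / sqrt(2)))
  n <- nrow(centers)
  tuning <- data.frame(
    unit = 1:n,
    preferred_orientation = rep(pi / 2, n),
    preferred_direction = rep(pi / 2, n), OSI = 0.9, DSI = 0.9,
    class = factor(rep("orientation_selective", n),
                   levels = c("orientation_selective", "direction_selective",
                              "non_selective"))
  )
  adj <- matrix(FALSE, n, n)
  adj[1, 2] <- TRUE # co-axial pre connected
  adj[1, 4] <- TRUE # co-orthogonal pre connected
  fits <- data.frame(unit = 1:n, center_x = centers[, 1],
                     center_y = centers[, 2])
  g <- toy_graph(adj, matrix(0.1, n, n), rep("E", n), centers = centers)
  res <- coaxial_coorthogonal_analysis(g, fits, tuning, n_perm = 50,
                                       seed = 1, side = 16,
                                       central_bounds = 16)
  # orientation pi/2 maps the vertical axis onto itself: pre units above or
  # below their post are co-axial, left/right co-orthogonal, diagonals are
  # boundary or fall outside the long-range band; the long-range ordered
  # pairs split 4 per sector (unit 1 with 2,3 axially, with 4,5 across)
  expect_equal(sum(res$coaxial$candidates), 4)
  expect_equal(sum(res$coorthogonal$candidates), 4)
  expect_equal(sum(res$coaxial$connected), 1)
  expect_equal(sum(res$coorthogonal$connected), 1)
})

test_that("presynaptic density sectors resolve opposite versus ahead", {
  # post unit 1 prefers direction 0 (+x); all pre units sit at x < post
  centers <- rbind(c(10, 10), c(3, 10), c(4, 9), c(2, 11), c(16, 10))
  n <- 5
  tuning <- data.frame(unit = 1:n, preferred_orientation = 0,
                       preferred_direction = 0, OSI = 0.9,
                       DSI = c(0.9, 0, 0, 0, 0))
  adj <- matrix(FALSE, n, n)
  adj[1, 2:4] <- TRUE
  g <- toy_graph(adj, matrix(0.1, n, n), c("E", "E", "E", "I", "E"),
                 centers = centers)
  fits <- data.frame(unit = 1:n, center_x = centers[, 1],
                     center_y = centers[, 2])
  res <- presynaptic_density_sectors(g, fits, tuning, post_class = "ds")
  dE <- res$densities[res$densities$pre_population == "E", ]
  expect_equal(dE$opposite, 1) # all excitatory pre behind the unit
  expect_equal(dE$ahead, 0)
  dI <- res$densities[res$densities$pre_population == "I", ]
  expect_equal(dI$opposite, 1)
  # mirror-symmetric ensemble: equal halves
  adj2 <- matrix(FALSE, n, n)
  adj2[1, c(2, 5)] <- TRUE # pre at x = 3 and x = 16 around post x = 10...
  centers2 <- rbind(c(10, 10), c(3, 10), c(4, 9), c(2, 11), c(17, 10))
  g2 <- toy_graph(adj2, matrix(0.1, n, n), rep("E", 5), centers = centers2)
  fits2 <- data.frame(unit = 1:n, center_x = centers2[, 1],
                      center_y = centers2[, 2])
  res2 <- presynaptic_density_sectors(g2, fits2, tuning, post_class = "ds")
  d2 <- res2$densities[res2$densities$pre_population == "E", ]
  expect_equal(d2$opposite, 0.5)
  expect_equal(d2$ahead, 0.5)
})

test_that("correlation bins reproduce a pair-enumeration oracle", {
  set.seed(11)
  n <- 10
  corr <- matrix(runif(n * n, -0.1, 0.9), n, n)
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  W <- matrix(runif(n * n), n, n)
  sign <- rep(1, n)
  g <- threshold_connections(apply_dale_constraint(W, sign), sign,
                             percentile = 80)
  breaks <- seq(-0.2, 1, 0.2)
  out <- correlation_vs_connectivity(corr, g, breaks = breaks)
  # enumeration oracle over ordered pairs
  for (b in seq_len(nrow(out))) {
    cnt <- 0L; conn <- 0L
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      v <- corr[i, j]
      lo <- out$bin_lo[b]; hi <- out$bin_hi[b]
      inbin <- if (b == 1) v >= lo & v <= hi else v > lo & v <= hi
      if (inbin) {
        cnt <- cnt + 1L
        if (g$adjacency[j, i]) conn <- conn + 1L
      }
    }
    expect_equal(out$n_pairs[b], cnt)
    expect_equal(out$n_connected[b], conn)
  }
  # connection iff correlation > 0.5 gives a step in probability
  adj <- corr > 0.5 & row(corr) != col(corr)
  gs <- toy_graph(adj, matrix(1, n, n), rep("E", n))
  step <- correlation_vs_connectivity(corr, gs, breaks = breaks)
  lowbins <- step$bin_hi <= 0.4
  expect_true(all(step$p_connected[lowbins & step$n_pairs > 0] == 0))
  expect_true(all(step$p_connected[step$bin_lo >= 0.6 & step$n_pairs > 0] == 1))
  # equal weights -> constant mean strength across occupied bins
  ms <- step$mean_strength[!is.na(step$mean_strength)]
  expect_true(all(ms == ms[1]))
})

test_that("weight shuffles preserve the multiset and the mean rate", {
  set.seed(13)
  n <- 30
  W <- apply_dale_constraint(matrix(rnorm(n * n), n, n), rep(1, n))
  units <- 1:20
  null <- shuffle_control(W, units, downstream_op = function(Wk) {
    sort(Wk[units, units][row(diag(20)) != col(diag(20))])
  }, n_shuffles = 5, seed = 3)
  target <- sort(W[units, units][row(diag(20)) != col(diag(20))])
  for (k in 1:5) expect_equal(unname(null$values[k, ]), target)
  # reproducible
  null2 <- shuffle_control(W, units, function(Wk) Wk[2, 1], n_shuffles = 10,
                           seed = 7)
  null3 <- shuffle_control(W, units, function(Wk) Wk[2, 1], n_shuffles = 10,
                           seed = 7)
  expect_identical(null2$values, null3$values)
  # law of large numbers: mean per-bin connection probability over
  # shuffles approaches the subset's overall connection rate
  sign <- rep(1, n)
  g <- threshold_connections(W, sign, units = units, percentile = 90)
  rate <- sum(g$adjacency) / (20 * 19)
  thr <- g$threshold
  po <- runif(n, 0, pi)
  tun <- data.frame(unit = 1:n, preferred_orientation = po,
                    preferred_direction = po, OSI = 0.9, DSI = 0.9,
                    class = factor(rep("orientation_selective", n),
                                   levels = c("orientation_selective",
                                              "direction_selective",
                                              "non_selective")))
  null4 <- shuffle_control(W, units, function(Wk) {
    gk <- threshold_connections(Wk, sign, units = units, percentile = 90)
    probability_by_tuning_difference(gk, tun, "orientation",
                                     range = "all")$probability
  }, n_shuffles = 200, seed = 5)
  expect_equal(unname(null4$mean), rep(rate, 3), tolerance = 0.25)
})

test_that("the connectivity score averages per-profile correlations", {
  profs <- list(c(0.5, 0.3, 0.1), c(0.2, 0.25, 0.4), c(0.9, 0.5, 0.4))
  expect_equal(connectivity_score(profs, profs), 1)
  negated <- lapply(profs, function(p) -p + mean(p) * 2)
  expect_equal(connectivity_score(profs, negated), -1)
  refs <- list(c(0.4, 0.2, 0.05), c(0.5, 0.1, 0.3), c(1, 0.6, 0.2))
  manual <- mean(mapply(stats::cor, profs, refs))
  expect_equal(connectivity_score(profs, refs), manual)
  expect_error(connectivity_score(profs, refs[1:2]), "length")
})
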