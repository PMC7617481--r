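# Thresholded functional-connectivity graph, tuning-difference motifs,
# visual-space normalisation, trend tests, shuffle controls, and the
# connectivity score.

#' Threshold recurrent weights into a directed connectivity graph
#'
#' A directed edge pre -> post exists when the absolute recurrent weight
#' `|W[post, pre]|` strictly exceeds the given percentile of absolute
#' weights pooled over all ordered pairs of the included units
#' (self-connections excluded; zero weights included in the pool). The
#' percentile uses the linear-interpolation convention. With default 95 the
#' edge fraction is ~5% of ordered pairs when weights are distinct.
#'
#' @param W_rec Sign-constrained recurrent matrix (rows postsynaptic,
#'   columns presynaptic), e.g. [dale_weights()].
#' @param unit_sign +1/-1 population label per unit.
#' @param units Indices of included units (default all).
#' @param percentile Threshold percentile (published default 95; robust over
#'   92.5-99).
#' @param centers Optional `n_units x 2` matrix of fitted RF centres
#'   (columns x, y) over the *original* unit indexing; enables RF distances
#'   and range classes.
#' @return An object of class `connectivity_graph`: `adjacency` (logical,
#'   `[post, pre]`, over `units`), `weight`, `units`, `population`
#'   (`"E"`/`"I"` per included unit), `threshold`, and (with centres)
#'   `rf_distance` plus `range_class` (`short` < 2.5 px, `long` in
#'   (5, 9.17] px, otherwise `excluded`).
#' @export
threshold_connections <- function(W_rec, unit_sign, units = NULL,
                                  percentile = 95, centers = NULL) {
  n_all <- ncol(W_rec)
  if (is.null(units)) units <- seq_len(n_all)
  W <- W_rec[units, units, drop = FALSE]
  aw <- abs(W)
  off <- row(aw) != col(aw)
  thr <- stats::quantile(aw[off], probs = percentile / 100, names = FALSE)
  adjacency <- aw > thr & off
  g <- list(
    adjacency = adjacency, weight = W, units = units,
    population = ifelse(unit_sign[units] > 0, "E", "I"),
    percentile = percentile, threshold = thr
  )
  if (!is.null(centers)) {
    cx <- centers[units, 1]
    cy <- centers[units, 2]
    d <- sqrt(outer(cy, cy, "-")^2 + outer(cx, cx, "-")^2)
    g$rf_distance <- d
    rc <- matrix("excluded", nrow(d), ncol(d))
    rc[which(d < 2.5)] <- "short"
    rc[which(d > 5 & d <= 9.17)] <- "long"
    rc[which(is.na(d))] <- NA_character_
    g$range_class <- rc
  }
  structure(g, class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  n <- length(x$units)
  cat(sprintf(
    "<connectivity_graph> %d units (%d E / %d I), %d edges (%.2f%% of ordered pairs, threshold %.4g)\n",
    n, sum(x$population == "E"), sum(x$population == "I"), sum(x$adjacency),
    100 * sum(x$adjacency) / (n * (n - 1)), x$threshold
  ))
  invisible(x)
}

#' Edge list of a connectivity graph
#'
#' @param graph A `connectivity_graph`.
#' @return A `data.frame` with columns `pre`, `post` (original unit
#'   indices), `weight`, `pre_population`, `post_population`, and (when
#'   centres were supplied) `rf_distance` and `range_class`.
#' @export
graph_edges <- function(graph) {
  idx <- which(graph$adjacency, arr.ind = TRUE)
  out <- data.frame(
    pre = graph$units[idx[, 2]], post = graph$units[idx[, 1]],
    weight = graph$weight[idx],
    pre_population = graph$population[idx[, 2]],
    post_population = graph$population[idx[, 1]]
  )
  if (!is.null(graph$rf_distance)) {
    out$rf_distance <- graph$rf_distance[idx]
    out$range_class <- graph$range_class[idx]
  }
  out
}

# Local index (within graph$units) of a set of original unit ids.
graph_index <- function(graph, ids) match(ids, graph$units)

# Candidate ordered pairs (local indices) for a population pair code such
# as "EE" (pre population first), optionally restricted by range class.
candidate_pairs <- function(graph, pre_units, post_units, pair = "EE",
                            range = "all") {
  pre_pop <- substr(pair, 1, 1)
  post_pop <- substr(pair, 2, 2)
  pre_ok <- pre_units[graph$population[pre_units] == pre_pop]
  post_ok <- post_units[graph$population[post_units] == post_pop]
  pairs <- expand.grid(pre = pre_ok, post = post_ok)
  pairs <- pairs[pairs$pre != pairs$post, ]
  if (range != "all") {
    if (is.null(graph$range_class)) stop("graph has no RF distances")
    rc <- graph$range_class[cbind(pairs$post, pairs$pre)]
    pairs <- pairs[!is.na(rc) & rc == range, ]
  }
  pairs
}

#' Connection probability versus tuning difference
#'
#' Bins candidate ordered pairs of selective units by their difference in
#' preferred orientation (folded to 0-90 degrees) or direction (folded to
#' 0-180 degrees) and reports the fraction connected per bin. Published
#' orientation bins are 0-22.5, 22.5-67.5, 67.5-90 degrees; direction bins
#' continue in 45-degree steps to 180.
#'
#' @param graph A `connectivity_graph` built with RF centres when `range`
#'   filtering is requested.
#' @param tuning Classified tuning profiles ([classify_selectivity()], Ko
#'   scheme) over the original unit indexing.
#' @param feature `"orientation"` or `"direction"`.
#' @param pair Two-letter population code, pre then post (`"EE"`, `"EI"`,
#'   `"IE"`, `"II"`).
#' @param bins Bin edges in degrees.
#' @param range `"short"`, `"long"` or `"all"`.
#' @return An object of class `connectivity_profile`: a `data.frame` with
#'   `bin_lo`, `bin_hi`, `connected`, `candidates`, `probability`
#'   (`NA` where a bin has no candidates).
#' @export
probability_by_tuning_difference <- function(graph, tuning,
                                             feature = c("orientation", "direction"),
                                             pair = "EE",
                                             bins = NULL, range = "short") {
  feature <- match.arg(feature)
  if (is.null(bins)) {
    bins <- if (feature == "orientation") c(0, 22.5, 67.5, 90) else
      c(0, 22.5, 67.5, 112.5, 157.5, 180)
  }
  sel_units <- if (feature == "orientation") {
    tuning$unit[tuning$class %in% c("orientation_selective", "direction_selective")]
  } else {
    tuning$unit[tuning$class == "direction_selective"]
  }
  sel_local <- graph_index(graph, intersect(sel_units, graph$units))
  pairs <- candidate_pairs(graph, sel_local, sel_local, pair = pair,
                           range = range)
  if (feature == "orientation") {
    pref <- tuning$preferred_orientation[match(graph$units, tuning$unit)]
    delta <- rad2deg(fold_angle_diff(pref[pairs$pre] - pref[pairs$post], pi))
  } else {
    pref <- tuning$preferred_direction[match(graph$units, tuning$unit)]
    delta <- rad2deg(fold_angle_diff(pref[pairs$pre] - pref[pairs$post], 2 * pi))
  }
  conn <- graph$adjacency[cbind(pairs$post, pairs$pre)]
  bin_profile(delta, conn, bins, feature = feature, pair = pair, range = range)
}

# Shared binning for connectivity profiles.
bin_profile <- function(delta, connected, bins, ...) {
  bi <- cut(delta, breaks = bins, include.lowest = TRUE, right = TRUE)
  connected_counts <- tapply(connected, bi, sum)
  candidate_counts <- tapply(connected, bi, length)
  connected_counts[is.na(connected_counts)] <- 0
  candidate_counts[is.na(candidate_counts)] <- 0
  out <- data.frame(
    bin_lo = bins[-length(bins)], bin_hi = bins[-1],
    connected = as.integer(connected_counts),
    candidates = as.integer(candidate_counts)
  )
  out$probability <- ifelse(out$candidates > 0, out$connected / out$candidates,
                            NA_real_)
  attr(out, "meta") <- list(...)
  class(out) <- c("connectivity_profile", "data.frame")
  out
}

#' Cochran-Armitage trend test on a connectivity profile
#'
#' Tests for a linear trend in the per-bin connection proportion across
#' ordered bins using integer scores. The statistic is the standard
#' trend z (its square is the chi-squared trend statistic); the p value is
#' two-sided. Degenerate margins (no successes, no failures, or a single
#' informative bin) return `statistic = 0`, `p = 1` with a warning.
#'
#' @param profile A `connectivity_profile`, or anything with `connected`
#'   and `candidates` columns.
#' @param scores Bin scores (default `0, 1, 2, ...`).
#' @return A list with `statistic` (z), `p_value`, and `df = 1`.
#' @export
cochran_armitage_trend <- function(profile, scores = NULL) {
  x <- profile$connected
  n <- profile$candidates
  keep <- n > 0
  x <- x[keep]; n <- n[keep]
  if (length(x) < 2) stop("need at least 2 ordered bins with candidates")
  if (is.null(scores)) scores <- seq_along(x) - 1 else scores <- scores[keep]
  N <- sum(n)
  p_bar <- sum(x) / N
  s_bar <- sum(n * scores) / N
  denom <- p_bar * (1 - p_bar) * sum(n * (scores - s_bar)^2)
  if (denom <= 0) {
    warning("degenerate margins; trend undefined")
    return(list(statistic = 0, p_value = 1, df = 1))
  }
  z <- sum(x * (scores - s_bar)) / sqrt(denom)
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)), df = 1)
}

#' Normalise visual space around a postsynaptic unit
#'
#' Translates receptive-field centres so the postsynaptic centre sits at
#' the origin, then rotates by the postsynaptic preferred orientation minus
#' 90 degrees, `R(theta - pi/2)`. After the rotation the preferred
#' orientation axis lies along the vertical (y) axis; distances are
#' preserved exactly.
#'
#' @param pre_centers `n x 2` matrix (columns x, y) of presynaptic centres.
#' @param post_center Length-2 vector, postsynaptic centre.
#' @param theta Postsynaptic preferred orientation in radians.
#' @return `n x 2` matrix of normalised coordinates.
#' @export
normalize_visual_space <- function(pre_centers, post_center, theta) {
  pre_centers <- matrix(pre_centers, ncol = 2)
  a <- theta - pi / 2
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  shifted <- sweep(pre_centers, 2, post_center)
  shifted %*% t(R)
}

# Rotation used for direction-based sectors: maps the postsynaptic
# preferred direction phi onto the +x axis.
normalize_direction_space <- function(pre_centers, post_center, phi) {
  pre_centers <- matrix(pre_centers, ncol = 2)
  R <- matrix(c(cos(-phi), sin(-phi), -sin(-phi), cos(-phi)), 2, 2)
  shifted <- sweep(pre_centers, 2, post_center)
  shifted %*% t(R)
}

# Central square region mask for RF centres (postsynaptic units only), to
# avoid edge effects: centres must fall inside the central `bounds` x
# `bounds` pixel box of a `side` x `side` frame.
in_central_bounds <- function(centers, side, bounds = 16) {
  lo <- (side - bounds) / 2
  hi <- lo + bounds
  centers[, 1] >= lo & centers[, 1] <= hi &
    centers[, 2] >= lo & centers[, 2] <= hi
}

#' Co-axial versus co-orthogonal long-range connectivity
#'
#' Restricts to long-range candidate pairs (RF distance in (5, 9.17]
#' pixels) whose postsynaptic unit is orientation-selective and whose RF
#' centre lies within the central 16x16-pixel bounds. After visual-space
#' normalisation, a presynaptic centre is co-axial when `|y| > |x|` (the
#' quadrants containing the postsynaptic orientation axis), co-orthogonal
#' when `|x| > |y|`, and excluded on the boundary. Connection-probability
#' profiles versus orientation difference are computed per sector, and a
#' permutation test (sector labels shuffled among candidate pairs) compares
#' the similarly-tuned (first-bin) probabilities between sectors.
#'
#' @param graph A `connectivity_graph` with RF centres.
#' @param fits Gabor fit table (for centres) over original unit indexing.
#' @param tuning Classified tuning profiles (Ko scheme).
#' @param bins Orientation-difference bin edges in degrees.
#' @param pair Population pair (default `"EE"`).
#' @param central_bounds Side of the central region in pixels.
#' @param n_perm Label permutations for the sector comparison.
#' @param seed Permutation seed.
#' @param side Frame side in pixels (inferred from the fit centres if
#'   omitted).
#' @return A list of class `coaxial_analysis`: `coaxial`, `coorthogonal`
#'   (connectivity profiles), `delta_first_bin` (observed co-axial minus
#'   co-orthogonal first-bin probability), and `perm_p`.
#' @export
coaxial_coorthogonal_analysis <- function(graph, fits, tuning,
                                          bins = c(0, 22.5, 67.5, 90),
                                          pair = "EE", central_bounds = 16,
                                          n_perm = 1000, seed = 1,
                                          side = NULL) {
  if (is.null(side)) {
    side <- ceiling(max(fits$center_x, fits$center_y, na.rm = TRUE))
  }
  centers <- as.matrix(fits[match(graph$units, fits$unit),
                            c("center_x", "center_y")])
  pref_or <- tuning$preferred_orientation[match(graph$units, tuning$unit)]
  sel <- tuning$unit[tuning$class %in% c("orientation_selective",
                                         "direction_selective")]
  sel_local <- graph_index(graph, intersect(sel, graph$units))
  central <- which(in_central_bounds(centers, side, central_bounds))
  post_ok <- intersect(sel_local, central)
  pairs <- candidate_pairs(graph, sel_local, post_ok, pair = pair,
                           range = "long")
  if (nrow(pairs) == 0) stop("no long-range candidate pairs available")
  # vectorised normalize_visual_space over all candidate pairs
  a <- pref_or[pairs$post] - pi / 2
  dx <- centers[pairs$pre, 1] - centers[pairs$post, 1]
  dy <- centers[pairs$pre, 2] - centers[pairs$post, 2]
  norm <- cbind(cos(a) * dx - sin(a) * dy, sin(a) * dx + cos(a) * dy)
  sector <- ifelse(abs(norm[, 2]) > abs(norm[, 1]), "coaxial",
                   ifelse(abs(norm[, 1]) > abs(norm[, 2]), "coorthogonal",
                          "boundary"))
  delta <- rad2deg(fold_angle_diff(pref_or[pairs$pre] - pref_or[pairs$post], pi))
  conn <- graph$adjacency[cbind(pairs$post, pairs$pre)]
  use <- sector != "boundary"
  prof <- function(mask) bin_profile(delta[mask], conn[mask], bins)
  coax <- prof(use & sector == "coaxial")
  coor <- prof(use & sector == "coorthogonal")
  first_bin_delta <- function(sec_labels) {
    m1 <- sec_labels == "coaxial" & delta <= bins[2]
    m2 <- sec_labels == "coorthogonal" & delta <= bins[2]
    mean(conn[m1 & use]) - mean(conn[m2 & use])
  }
  obs <- first_bin_delta(sector)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      first_bin_delta(replace(sector, which(use), sample(sector[use])))
    }, numeric(1))
  })
  perm_p <- (1 + sum(abs(null) >= abs(obs), na.rm = TRUE)) / (n_perm + 1)
  structure(list(coaxial = coax, coorthogonal = coor,
                 delta_first_bin = obs, perm_p = perm_p),
            class = "coaxial_analysis")
}

#' Presynaptic ensemble density opposite versus ahead of preferred motion
#'
#' For every direction-selective postsynaptic excitatory unit (DSI above or
#' below the threshold, per `post_class`), the connected presynaptic
#' centres are rotated so the postsynaptic preferred direction points along
#' +x; the density is the fraction of the ensemble in the opposite
#' (`x < 0`) versus ahead (`x > 0`) half-plane, split by presynaptic
#' population. One-sample t statistics compare each population's opposite
#' density to the equal-density reference 0.5.
#'
#' @param graph A `connectivity_graph` with RF centres.
#' @param fits Gabor fit table.
#' @param tuning Tuning profiles with `DSI` and `preferred_direction`.
#' @param post_class `"ds"` (DSI > threshold) or `"weak"` (DSI <=
#'   threshold).
#' @param dsi_threshold Direction-selectivity threshold (default 0.8).
#' @return A list of class `density_sectors`: `densities` (per postsynaptic
#'   unit and presynaptic population: `opposite`, `ahead`, `n_pre`),
#'   `tests` (per population: t statistic and p against 0.5), and the
#'   number of empty ensembles skipped.
#' @export
presynaptic_density_sectors <- function(graph, fits, tuning,
                                        post_class = c("ds", "weak"),
                                        dsi_threshold = 0.8) {
  post_class <- match.arg(post_class)
  centers <- as.matrix(fits[match(graph$units, fits$unit),
                            c("center_x", "center_y")])
  dsi <- tuning$DSI[match(graph$units, tuning$unit)]
  pdir <- tuning$preferred_direction[match(graph$units, tuning$unit)]
  is_post <- graph$population == "E" & !is.na(dsi) &
    (if (post_class == "ds") dsi > dsi_threshold else dsi <= dsi_threshold)
  rows <- list()
  skipped <- 0L
  for (j in which(is_post)) {
    pres <- which(graph$adjacency[j, ])
    pres <- pres[!is.na(centers[pres, 1])]
    if (length(pres) == 0) {
      skipped <- skipped + 1L
      next
    }
    nc <- normalize_direction_space(centers[pres, , drop = FALSE],
                                    centers[j, ], pdir[j])
    for (pop in c("E", "I")) {
      sel <- graph$population[pres] == pop
      if (!any(sel)) next
      x <- nc[sel, 1]
      x <- x[x != 0]
      if (length(x) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        post = graph$units[j], pre_population = pop,
        opposite = mean(x < 0), ahead = mean(x > 0), n_pre = length(x)
      )
    }
  }
  densities <- do.call(rbind, rows)
  tests <- lapply(c(E = "E", I = "I"), function(pop) {
    d <- densities$opposite[densities$pre_population == pop]
    if (length(d) < 2 || stats::sd(d) == 0) {
      return(list(t = NA_real_, p = NA_real_, mean_opposite = mean(d)))
    }
    tt <- stats::t.test(d, mu = 0.5)
    list(t = unname(tt$statistic), p = tt$p.value, mean_opposite = mean(d))
  })
  structure(list(densities = densities, tests = tests, skipped = skipped),
            class = "density_sectors")
}

#' Connection probability and input strength versus response correlation
#'
#' Over ordered pairs of included units, bins the pairwise natural-movie
#' response correlation and reports per bin the fraction of connected
#' pairs and the mean absolute weight among connected pairs, plus a
#' histogram of correlations among connected pairs.
#'
#' @param corr A correlation matrix over original unit indices (e.g.
#'   `response_correlations()$correlation`).
#' @param graph A `connectivity_graph`.
#' @param breaks Correlation bin edges.
#' @return A `data.frame` with `bin_lo`, `bin_hi`, `n_pairs`, `n_connected`,
#'   `p_connected`, `mean_strength`; attribute `connected_correlations`
#'   holds the correlation values of connected pairs.
#' @export
correlation_vs_connectivity <- function(corr, graph,
                                        breaks = seq(-0.2, 1, by = 0.1)) {
  n <- length(graph$units)
  cc <- corr[graph$units, graph$units]
  off <- row(cc) != col(cc)
  vals <- cc[off]
  conn <- graph$adjacency[off]
  w <- abs(graph$weight)[off]
  keep <- !is.na(vals)
  vals <- vals[keep]; conn <- conn[keep]; w <- w[keep]
  bi <- cut(vals, breaks = breaks, include.lowest = TRUE)
  agg <- function(f, v) tapply(v, bi, f)
  n_pairs <- agg(length, vals)
  n_conn <- agg(sum, conn)
  mean_strength <- vapply(levels(bi), function(l) {
    sel <- bi == l & conn
    if (any(sel, na.rm = TRUE)) mean(w[which(sel)]) else NA_real_
  }, numeric(1))
  out <- data.frame(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    n_pairs = as.integer(ifelse(is.na(n_pairs), 0, n_pairs)),
    n_connected = as.integer(ifelse(is.na(n_conn), 0, n_conn)),
    mean_strength = mean_strength
  )
  out$p_connected <- ifelse(out$n_pairs > 0, out$n_connected / out$n_pairs,
                            NA_real_)
  attr(out, "connected_correlations") <- vals[conn]
  out
}

#' Shuffle-control null for connectivity analyses
#'
#' Randomly permutes the recurrent weights among the ordered pairs of the
#' selected unit subset (preserving the weight multiset exactly) and
#' recomputes an arbitrary downstream profile per shuffle. Shuffled weights
#' are used only for connectivity analyses, never for unit responses.
#'
#' @param W_rec Sign-constrained recurrent matrix.
#' @param units Unit subset selected by the same criteria as the real
#'   analysis.
#' @param downstream_op Function taking a shuffled full-size `W_rec` and
#'   returning a numeric vector (e.g. per-bin probabilities).
#' @param n_shuffles Number of shuffles (published default 1,000).
#' @param seed Integer seed.
#' @return A list of class `shuffle_null`: `values` (`n_shuffles x k`
#'   matrix), `mean`, `q025`, `q975`.
#' @export
shuffle_control <- function(W_rec, units, downstream_op, n_shuffles = 1000,
                            seed = 1) {
  sub <- W_rec[units, units, drop = FALSE]
  off_idx <- which(row(sub) != col(sub))
  vals <- with_seed(seed, {
    lapply(seq_len(n_shuffles), function(k) {
      sh <- sub
      sh[off_idx] <- sub[off_idx][sample.int(length(off_idx))]
      Wk <- W_rec
      Wk[units, units] <- sh
      downstream_op(Wk)
    })
  })
  values <- do.call(rbind, vals)
  structure(
    list(values = values,
         mean = colMeans(values, na.rm = TRUE),
         q025 = apply(values, 2, stats::quantile, 0.025, na.rm = TRUE),
         q975 = apply(values, 2, stats::quantile, 0.975, na.rm = TRUE)),
    class = "shuffle_null"
  )
}

#' Model connectivity score
#'
#' Mean Pearson correlation between matched model and reference
#' connectivity profiles (bin-for-bin). Reference profiles are supplied as
#' numeric vectors, e.g. read from a fixture table.
#'
#' @param model_profiles List of numeric vectors (or
#'   `connectivity_profile` objects, whose `probability` column is used).
#' @param reference_profiles List of numeric vectors of matching lengths.
#' @return Scalar mean correlation.
#' @export
connectivity_score <- function(model_profiles, reference_profiles) {
  if (length(model_profiles) != length(reference_profiles)) {
    stop("profile lists differ in length")
  }
  rs <- mapply(function(m, r) {
    if (inherits(m, "connectivity_profile")) m <- m$probability
    if (inherits(r, "connectivity_profile")) r <- r$probability
    if (length(m) != length(r)) stop("profile bin counts differ")
    stats::cor(m, r, use = "complete.obs")
  }, model_profiles, reference_profiles)
  mean(rs)
}
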