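# Ablation experiments, representation-clustering (silhouette) analysis,
# bar/dot ablation deficits, and prediction-error unit detection.

#' Median connected excitatory-to-excitatory weight
#'
#' The ablation replacement value: the median recurrent weight over
#' connected E -> E edges of the graph.
#'
#' @param graph A `connectivity_graph`.
#' @return Scalar weight.
#' @export
median_ee_weight <- function(graph) {
  ee <- graph$adjacency &
    outer(graph$population == "E", graph$population == "E", "&")
  if (!any(ee)) stop("graph has no connected E->E edges")
  stats::median(graph$weight[ee])
}

#' Select connected edges by tuning relationship
#'
#' Partitions connected E->E edges by the tuning relationship between the
#' presynaptic and postsynaptic unit: `co_tuned` (orientation difference
#' < 22.5 degrees), `orthogonal` (> 67.5 degrees), or `co_anti_tuned`
#' (direction difference < 22.5 or > 157.5 degrees), matching the
#' orientation/direction bin conventions.
#'
#' @param graph A `connectivity_graph`.
#' @param tuning Tuning profiles over original unit indices.
#' @param target_class One of `"co_tuned"`, `"orthogonal"`,
#'   `"co_anti_tuned"`.
#' @param pair Population pair (default `"EE"`).
#' @return Two-column matrix of (post, pre) local indices into the graph.
#' @export
select_ablation_edges <- function(graph, tuning,
                                  target_class = c("co_tuned", "orthogonal",
                                                   "co_anti_tuned"),
                                  pair = "EE") {
  target_class <- match.arg(target_class)
  idx <- which(graph$adjacency, arr.ind = TRUE) # [post, pre]
  pre_pop <- graph$population[idx[, 2]]
  post_pop <- graph$population[idx[, 1]]
  keep <- pre_pop == substr(pair, 1, 1) & post_pop == substr(pair, 2, 2)
  idx <- idx[keep, , drop = FALSE]
  po <- tuning$preferred_orientation[match(graph$units, tuning$unit)]
  pd <- tuning$preferred_direction[match(graph$units, tuning$unit)]
  d_or <- rad2deg(fold_angle_diff(po[idx[, 2]] - po[idx[, 1]], pi))
  d_dir <- rad2deg(fold_angle_diff(pd[idx[, 2]] - pd[idx[, 1]], 2 * pi))
  sel <- switch(target_class,
    co_tuned = d_or < 22.5,
    orthogonal = d_or > 67.5,
    co_anti_tuned = d_dir < 22.5 | d_dir > 157.5
  )
  idx[which(sel), , drop = FALSE]
}

#' Draw random ablation sets over a class of connections
#'
#' Each repeat picks `n_ablate` edges uniformly without replacement from
#' the candidate class; applying a repeat sets exactly those recurrent
#' weights to the replacement value (by default the median connected E->E
#' weight). The original weights are never modified in place.
#'
#' @param graph A `connectivity_graph`.
#' @param edges Candidate edge matrix from [select_ablation_edges()].
#' @param n_ablate Edges ablated per repeat.
#' @param n_repeats Number of independent repeats (published default
#'   1,000).
#' @param replacement Replacement weight (default [median_ee_weight()]).
#' @param seed Integer seed.
#' @return An object of class `ablation_set`: list of per-repeat edge
#'   matrices plus the replacement value.
#' @export
ablate <- function(graph, edges, n_ablate, n_repeats = 1000,
                   replacement = NULL, seed = 1) {
  if (nrow(edges) == 0) stop("ablation class is empty")
  if (n_ablate > nrow(edges)) {
    stop("n_ablate exceeds the available connections of this class")
  }
  if (is.null(replacement)) replacement <- median_ee_weight(graph)
  sets <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(k) {
      edges[sample.int(nrow(edges), n_ablate), , drop = FALSE]
    })
  })
  structure(list(edge_sets = sets, replacement = replacement,
                 units = graph$units, n_ablate = n_ablate),
            class = "ablation_set")
}

#' Apply one ablation repeat to a recurrent weight matrix
#'
#' @param W_rec Full sign-constrained recurrent matrix (original unit
#'   indexing).
#' @param ablation An `ablation_set`.
#' @param repeat_i Which repeat to apply.
#' @return A modified copy of `W_rec`.
#' @export
apply_ablation <- function(W_rec, ablation, repeat_i = 1) {
  ed <- ablation$edge_sets[[repeat_i]]
  if (nrow(ed) > 0) {
    W_rec[cbind(ablation$units[ed[, 1]], ablation$units[ed[, 2]])] <-
      ablation$replacement
  }
  W_rec
}

#' Prediction-error increase as a function of ablation size
#'
#' For each tuning class and each number of ablated connections, reports
#' the mean clean next-frame MSE over ablation repeats. `n = 0` reproduces
#' the unablated model error exactly.
#'
#' @param params A trained `network_params`.
#' @param clips Validation clips.
#' @param graph A `connectivity_graph`.
#' @param tuning Tuning profiles.
#' @param classes Character vector of ablation classes.
#' @param n_grid Integer vector of ablation counts.
#' @param n_repeats Repeats per (class, n).
#' @param seed Integer seed.
#' @return A `data.frame` with `class`, `n_ablate`, `mse`, `se`; attribute
#'   `baseline_mse` holds the unablated error.
#' @export
ablation_error_curve <- function(params, clips, graph, tuning,
                                 classes = c("co_tuned", "orthogonal"),
                                 n_grid = c(0, 25, 50, 100), n_repeats = 20,
                                 seed = 1) {
  W0 <- dale_weights(params)
  baseline <- predict_mse(params, clips)
  rows <- list()
  for (cls in classes) {
    edges <- select_ablation_edges(graph, tuning, cls)
    for (n in n_grid) {
      if (n == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, n_ablate = 0L, mse = baseline, se = 0
        )
        next
      }
      n_use <- min(n, nrow(edges))
      abl <- ablate(graph, edges, n_use, n_repeats = n_repeats,
                    seed = derive_seed(seed, n))
      mses <- vapply(seq_len(n_repeats), function(k) {
        predict_mse(params, clips,
                    W_rec_override = apply_ablation(W0, abl, k))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, n_ablate = n_use, mse = mean(mses),
        se = stats::sd(mses) / sqrt(n_repeats)
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline_mse") <- baseline
  out
}

# Mean silhouette width recomputed directly from its definition; cluster::
# silhouette serves as the packaged route, this is kept for the oracle in
# documentation examples.
mean_silhouette <- function(points, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(points))
  mean(sil[, "sil_width"])
}

#' Silhouette score of orientation-class representations
#'
#' Presents three classes of gratings whose orientations are offset by 0,
#' 11.25 and 22.5 degrees from a base orientation, each with several noisy
#' repetitions at the requested SNR, and computes the silhouette score of
#' the time-averaged hidden-activity points labelled by class (in the full
#' hidden space). The analysis repeats over base orientations spanning the
#' full circle and averages. Ablated and intact networks can be compared
#' via `W_rec_override`.
#'
#' @param params A `network_params`.
#' @param base_orientations Base stripe orientations in radians (default 8
#'   spanning the circle).
#' @param offsets_deg Class offsets in degrees (default 0, 11.25, 22.5).
#' @param snr_db Stimulus SNR in dB (published conditions: 0 and -9.5).
#' @param n_reps Noisy repetitions per class.
#' @param sf,tf,n_frames Grating parameters.
#' @param W_rec_override Optional ablated recurrent matrix.
#' @param seed Integer seed.
#' @return A list of class `clustering_result`: `scores` per base
#'   orientation, `mean_silhouette`, and the condition metadata.
#' @export
silhouette_analysis <- function(params, base_orientations = seq(0, 2 * pi,
                                                                length.out = 9)[-9],
                                offsets_deg = c(0, 11.25, 22.5), snr_db = 0,
                                n_reps = 10, sf = 0.15, tf = 0.1,
                                n_frames = 30, W_rec_override = NULL,
                                seed = 1) {
  if (n_reps < 2) stop("each class needs at least 2 points")
  if (!is.null(W_rec_override)) params$W_rec <- W_rec_override
  side <- as.integer(sqrt(params$config$n_input))
  scores <- vapply(seq_along(base_orientations), function(bi) {
    base <- base_orientations[bi]
    labels <- rep(seq_along(offsets_deg), each = n_reps)
    B <- length(labels)
    U <- array(0, c(params$config$n_input, B, n_frames))
    b <- 0
    for (ci in seq_along(offsets_deg)) {
      g <- make_grating(orientation = base + deg2rad(offsets_deg[ci]),
                        sf = sf, tf = tf, size = side, n_frames = n_frames)
      for (r in seq_len(n_reps)) {
        b <- b + 1
        gn <- add_gaussian_noise_snr(g, snr_db,
                                     seed = derive_seed(seed, bi * 1000 + b))
        U[, b, ] <- t(clip_matrix(gn))
      }
    }
    out <- forward_batch(params, U)
    pts <- t(apply(out$s, c(1, 2), mean)) # B x n_hidden time-averaged
    mean_silhouette(pts, labels)
  }, numeric(1))
  structure(
    list(scores = scores, mean_silhouette = mean(scores),
         base_orientations = base_orientations, snr_db = snr_db,
         ablated = !is.null(W_rec_override)),
    class = "clustering_result"
  )
}

#' Ablation deficit on bar versus random-dot stimuli
#'
#' For every stimulus in an area-matched bar/dot set, the deficit is the
#' percentage increase of next-frame MSE in the ablated relative to the
#' intact network, averaged over ablation repeats; per stimulus type the
#' Pearson correlation of deficit with lit area is reported.
#'
#' @param params A trained `network_params`.
#' @param ablation An `ablation_set` (or `NULL` for a control run, giving
#'   zero deficits).
#' @param stimuli A [stimulus_set()] from [make_bar_dot_stimuli()].
#' @param n_repeats Ablation repeats averaged per stimulus.
#' @return A list of class `bar_dot_deficit`: `table` (per stimulus:
#'   class, area, control and ablated MSE, `deficit_pct`) and
#'   `correlations` (per class, deficit vs area).
#' @export
bar_dot_deficit <- function(params, ablation, stimuli, n_repeats = NULL) {
  W0 <- dale_weights(params)
  n_rep <- if (is.null(ablation)) 1 else
    min(if (is.null(n_repeats)) length(ablation$edge_sets) else n_repeats,
        length(ablation$edge_sets))
  rows <- lapply(seq_along(stimuli$clips), function(i) {
    clip <- stimuli$clips[[i]]
    ctrl <- predict_mse(params, list(clip))
    abl_mse <- if (is.null(ablation)) ctrl else {
      mean(vapply(seq_len(n_rep), function(k) {
        predict_mse(params, list(clip),
                    W_rec_override = apply_ablation(W0, ablation, k))
      }, numeric(1)))
    }
    cbind(stimuli$labels[i, c("stimulus_class", "area")],
          data.frame(mse_control = ctrl, mse_ablated = abl_mse,
                     deficit_pct = 100 * (abl_mse - ctrl) / ctrl))
  })
  tab <- do.call(rbind, rows)
  correlations <- vapply(split(tab, tab$stimulus_class), function(d) {
    if (stats::sd(d$deficit_pct) == 0 || stats::sd(d$area) == 0) NA_real_
    else stats::cor(d$area, d$deficit_pct)
  }, numeric(1))
  structure(list(table = tab, correlations = correlations),
            class = "bar_dot_deficit")
}

#' Detect prediction-error-like units from oddball sequences
#'
#' For each unit and each stimulus condition (orientation pair or omission
#' grating), compares the unit's activity on the deviant frame of the
#' violating sequence against its activity on the same frame of the two
#' controls (standard completion and shifted). Under the `strict`
#' criterion a unit is `pure_PE` when, for some condition, it responds
#' (activity > `eps`) on the deviant frame at 5 or more deviant positions
#' while both controls stay silent (<= `eps`) there. Under `loose` the
#' deviant response must strictly exceed three times the larger control
#' response at 5 or more positions. Units responding to both standard and
#' violating stimuli are `mixed`; all others `none`.
#'
#' @param params A `network_params`.
#' @param stimuli A [stimulus_set()] from [make_oddball_sequences()].
#' @param criteria `"strict"` or `"loose"`.
#' @param eps Activity at or below this counts as no response (rectified
#'   units can be exactly zero).
#' @param min_positions Deviant positions required (default 5).
#' @return A `data.frame` with `unit` and `class`
#'   (`pure_PE` / `mixed` / `none`); attribute `counts` tabulates classes.
#' @export
detect_prediction_error_units <- function(params, stimuli,
                                          criteria = c("strict", "loose"),
                                          eps = 1e-8, min_positions = 5) {
  criteria <- match.arg(criteria)
  lab <- stimuli$labels
  nh <- params$config$n_hidden
  conds <- unique(lab$pair)
  pure <- rep(FALSE, nh)
  responds_viol <- rep(FALSE, nh)
  responds_std <- rep(FALSE, nh)
  for (cond in conds) {
    rows <- which(lab$pair == cond)
    positions <- unique(lab$deviant_position[rows])
    # one batched forward pass over every sequence of this condition
    T_ <- n_frames(stimuli$clips[[rows[1]]])
    U <- array(0, c(params$config$n_input, length(rows), T_))
    for (i in seq_along(rows)) {
      U[, i, ] <- t(clip_matrix(stimuli$clips[[rows[i]]]))
    }
    S <- forward_batch(params, U)$s
    ok_count <- rep(0L, nh)
    for (p in positions) {
      i_v <- which(lab$sequence_type[rows] == "violating" &
                     lab$deviant_position[rows] == p)
      i_s <- which(lab$sequence_type[rows] == "standard" &
                     lab$deviant_position[rows] == p)
      i_h <- which(lab$sequence_type[rows] == "shifted" &
                     lab$deviant_position[rows] == p)
      rv <- S[, i_v[1], p]
      rs <- S[, i_s[1], p]
      rh <- S[, i_h[1], p]
      responds_viol <- responds_viol | rv > eps
      responds_std <- responds_std | rs > eps
      hit <- if (criteria == "strict") {
        rv > eps & rs <= eps & rh <= eps
      } else {
        rv > 3 * pmax(rs, rh) & rv > eps
      }
      ok_count <- ok_count + hit
    }
    pure <- pure | ok_count >= min_positions
  }
  cls <- ifelse(pure, "pure_PE",
                ifelse(responds_viol & responds_std, "mixed", "none"))
  out <- data.frame(unit = seq_len(nh), class = cls)
  attr(out, "counts") <- table(factor(cls, c("pure_PE", "mixed", "none")))
  out
}
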