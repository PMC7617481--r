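# Grating-derived selectivity: preferred parameters, OSI/DSI, simple/complex
# modulation ratio, and natural-movie response correlations.

#' Default grating parameter grid
#'
#' Six log-spaced spatial frequencies over 0.03-0.5 cycles/pixel, five
#' log-spaced temporal frequencies over 0.02-0.25 cycles/frame, and 16
#' equally spaced motion directions over 0-360 degrees.
#'
#' @return A list with `sf`, `tf` and `directions` (radians).
#' @export
grating_grid <- function() {
  list(
    sf = exp(seq(log(0.03), log(0.5), length.out = 6)),
    tf = exp(seq(log(0.02), log(0.25), length.out = 5)),
    directions = seq(0, 2 * pi, length.out = 17)[-17]
  )
}

#' Record responses to a battery of drifting gratings
#'
#' Presents every (tf, sf, direction) combination as a drifting sinusoid of
#' amplitude 1 and records each unit's mean response over the stimulus
#' frames, discarding the first `discard` frames as onset transient. The
#' preferred condition is the argmax of the mean response; exact ties are
#' broken by the first index and flagged.
#'
#' @param params A `network_params` object.
#' @param grid A list as returned by [grating_grid()].
#' @param n_frames Frames per grating presentation (default 50).
#' @param discard Onset frames excluded from the mean (default 10).
#' @param phase Spatial phase of all gratings.
#' @return An object of class `grating_battery`: `responses` (array
#'   `units x tf x sf x direction`), the `grid`, and per-unit `preferred`
#'   indices with a `tie` flag.
#' @export
grating_battery <- function(params, grid = grating_grid(), n_frames = 50,
                            discard = 10, phase = 0) {
  side <- as.integer(sqrt(params$config$n_input))
  conds <- expand.grid(tf_i = seq_along(grid$tf), sf_i = seq_along(grid$sf),
                       dir_i = seq_along(grid$directions))
  B <- nrow(conds)
  U <- array(0, c(params$config$n_input, B, n_frames))
  for (b in seq_len(B)) {
    g <- make_grating(direction = grid$directions[conds$dir_i[b]],
                      sf = grid$sf[conds$sf_i[b]], tf = grid$tf[conds$tf_i[b]],
                      phase = phase, size = side, n_frames = n_frames)
    U[, b, ] <- t(clip_matrix(g))
  }
  out <- forward_batch(params, U)
  use <- (discard + 1):n_frames
  mean_resp <- apply(out$s[, , use, drop = FALSE], c(1, 2), mean)
  nh <- params$config$n_hidden
  responses <- array(0, c(nh, length(grid$tf), length(grid$sf),
                          length(grid$directions)))
  for (b in seq_len(B)) {
    responses[, conds$tf_i[b], conds$sf_i[b], conds$dir_i[b]] <- mean_resp[, b]
  }
  pref_idx <- apply(mean_resp, 1, which.max)
  tie <- apply(mean_resp, 1, function(r) sum(r == max(r)) > 1)
  preferred <- data.frame(
    unit = seq_len(nh),
    tf = grid$tf[conds$tf_i[pref_idx]],
    sf = grid$sf[conds$sf_i[pref_idx]],
    direction = grid$directions[conds$dir_i[pref_idx]],
    tie = tie
  )
  structure(list(responses = responses, grid = grid, preferred = preferred,
                 n_frames = n_frames, discard = discard),
            class = "grating_battery")
}

#' Orientation and direction selectivity indices
#'
#' `OSI = (R_pref - R_orth) / (R_pref + R_orth)` and
#' `DSI = (R_pref - R_opp) / (R_pref + R_opp)`; both lie in `[0, 1]` for
#' non-negative responses. A zero denominator yields `NA` (flagged
#' undefined).
#'
#' @param r_pref,r_other Non-negative mean responses at the preferred and
#'   the orthogonal (OSI) or opposite (DSI) condition; vectorised.
#' @return Numeric vector of indices.
#' @export
compute_osi_dsi <- function(r_pref, r_other) {
  stopifnot(all(r_pref >= 0, na.rm = TRUE), all(r_other >= 0, na.rm = TRUE))
  den <- r_pref + r_other
  ifelse(den > 0, (r_pref - r_other) / den, NA_real_)
}

#' Tuning profile of every unit from a grating battery
#'
#' At each unit's preferred (tf, sf): the direction tuning curve gives the
#' preferred direction, `R_prefDir` and `R_oppDir` (+180 degrees); orientation
#' responses average the two directions sharing an orientation axis, giving
#' the preferred orientation, `R_prefOr` and `R_orthOr` (+90 degrees).
#'
#' @param battery A `grating_battery`.
#' @return A `data.frame` with one row per unit: preferred parameters
#'   (radians; orientation in `[0, pi)`), component responses, `OSI`, `DSI`,
#'   and the tie flag.
#' @export
tuning_profiles <- function(battery) {
  grid <- battery$grid
  nd <- length(grid$directions)
  stopifnot(nd %% 4 == 0)
  half <- nd / 2
  nh <- dim(battery$responses)[1]
  out <- vector("list", nh)
  for (u in seq_len(nh)) {
    resp_u <- array(battery$responses[u, , , ],
                    c(length(grid$tf), length(grid$sf), nd)) # tf x sf x dir
    flat <- array(resp_u, c(length(grid$tf) * length(grid$sf), nd))
    cond_best <- arrayInd(which.max(resp_u), dim(resp_u))
    dir_curve <- resp_u[cond_best[1], cond_best[2], ]
    pd_i <- which.max(dir_curve)
    opp_i <- ((pd_i - 1 + half) %% nd) + 1
    ori_curve <- (dir_curve[seq_len(half)] + dir_curve[seq_len(half) + half]) / 2
    po_i <- which.max(ori_curve)
    orth_i <- ((po_i - 1 + half %/% 2) %% half) + 1
    out[[u]] <- data.frame(
      unit = u,
      preferred_tf = grid$tf[cond_best[1]],
      preferred_sf = grid$sf[cond_best[2]],
      preferred_direction = grid$directions[pd_i],
      # stripe orientation is perpendicular to the motion direction
      preferred_orientation = (grid$directions[po_i] - pi / 2) %% pi,
      R_pref_dir = dir_curve[pd_i], R_opp_dir = dir_curve[opp_i],
      R_pref_or = ori_curve[po_i], R_orth_or = ori_curve[orth_i],
      tie = battery$preferred$tie[u]
    )
  }
  prof <- do.call(rbind, out)
  prof$OSI <- compute_osi_dsi(prof$R_pref_or, prof$R_orth_or)
  prof$DSI <- compute_osi_dsi(prof$R_pref_dir, prof$R_opp_dir)
  prof
}

#' Classify units by grating selectivity
#'
#' Two published threshold schemes, both with strict inequalities:
#' `"ko"` labels a unit direction-selective when `OSI > 0.4` and
#' `DSI > 0.3`, orientation-selective when `OSI > 0.4` only, and
#' non-selective otherwise; `"rossi"` uses the stricter single criterion
#' `DSI > 0.8` (direction-selective) versus `DSI <= 0.8`
#' (weakly-selective). Undefined indices (tied or zero-response units)
#' classify as non-selective.
#'
#' @param profiles A `data.frame` from [tuning_profiles()].
#' @param scheme `"ko"` or `"rossi"`.
#' @param osi_threshold,dsi_threshold Override the scheme thresholds.
#' @return `profiles` with an added factor column `class`.
#' @export
classify_selectivity <- function(profiles, scheme = c("ko", "rossi"),
                                 osi_threshold = NULL, dsi_threshold = NULL) {
  scheme <- match.arg(scheme)
  osi <- ifelse(is.na(profiles$OSI), 0, profiles$OSI)
  dsi <- ifelse(is.na(profiles$DSI), 0, profiles$DSI)
  if (scheme == "ko") {
    osi_t <- if (is.null(osi_threshold)) 0.4 else osi_threshold
    dsi_t <- if (is.null(dsi_threshold)) 0.3 else dsi_threshold
    cls <- ifelse(osi > osi_t & dsi > dsi_t, "direction_selective",
                  ifelse(osi > osi_t, "orientation_selective", "non_selective"))
    levels <- c("orientation_selective", "direction_selective", "non_selective")
  } else {
    dsi_t <- if (is.null(dsi_threshold)) 0.8 else dsi_threshold
    cls <- ifelse(dsi > dsi_t, "direction_selective", "weakly_selective")
    levels <- c("direction_selective", "weakly_selective")
  }
  profiles$class <- factor(cls, levels = levels)
  profiles
}

#' Modulation ratio (F1/F0) of a response trace
#'
#' `F0` is the trace mean and `F1` the amplitude of a least-squares sinusoid
#' at the (known) stimulus temporal frequency with free phase. Units with
#' `F > 1` are simple-cell-like, `F < 1` complex-cell-like. The ratio is
#' undefined when the sinusoid fit correlates with the trace below 0.9 or
#' when `F0` is not positive.
#'
#' @param trace Response time course to the preferred drifting grating.
#' @param tf Stimulus temporal frequency in cycles/frame.
#' @return A list of class `modulation_result`: `F0`, `F1`, `F`,
#'   `sinusoid_fit_r`, `class` (`"simple_like"`, `"complex_like"` or
#'   `"undefined"`).
#' @export
modulation_ratio <- function(trace, tf) {
  stopifnot(length(trace) >= 2 / tf)
  t_ <- seq_along(trace) - 1
  F0 <- mean(trace)
  X <- cbind(sin(2 * pi * tf * t_), cos(2 * pi * tf * t_))
  fit <- stats::lm.fit(cbind(1, X), trace)
  F1 <- sqrt(sum(fit$coefficients[2:3]^2))
  pred <- cbind(1, X) %*% fit$coefficients
  r <- if (stats::sd(pred) == 0 || stats::sd(trace) == 0) NA_real_ else
    stats::cor(drop(pred), trace)
  if (is.na(r) || r < 0.9 || F0 <= 0) {
    cls <- "undefined"
    Fr <- NA_real_
  } else {
    Fr <- F1 / F0
    cls <- if (Fr > 1) "simple_like" else "complex_like"
  }
  structure(list(F0 = F0, F1 = F1, F = Fr, sinusoid_fit_r = r, class = cls),
            class = "modulation_result")
}

#' Modulation ratios for all units at their preferred gratings
#'
#' Presents each unit's preferred (tf, sf, direction) grating and computes
#' [modulation_ratio()] on the unit's post-onset response trace. Units
#' sharing a preferred condition share one presentation.
#'
#' @param params A `network_params` object.
#' @param profiles Output of [tuning_profiles()].
#' @param n_frames,discard Presentation length and onset frames dropped.
#' @return A `data.frame`: unit, `F0`, `F1`, `F`, `sinusoid_fit_r`, `class`.
#' @export
modulation_ratio_set <- function(params, profiles, n_frames = 100,
                                 discard = 10) {
  side <- as.integer(sqrt(params$config$n_input))
  key <- paste(profiles$preferred_tf, profiles$preferred_sf,
               profiles$preferred_direction)
  ukey <- unique(key)
  U <- array(0, c(params$config$n_input, length(ukey), n_frames))
  for (i in seq_along(ukey)) {
    row <- profiles[match(ukey[i], key), ]
    g <- make_grating(direction = row$preferred_direction,
                      sf = row$preferred_sf, tf = row$preferred_tf,
                      size = side, n_frames = n_frames)
    U[, i, ] <- t(clip_matrix(g))
  }
  out <- forward_batch(params, U)
  use <- (discard + 1):n_frames
  rows <- lapply(seq_len(nrow(profiles)), function(u) {
    b <- match(key[u], ukey)
    m <- modulation_ratio(out$s[u, b, use], profiles$preferred_tf[u])
    data.frame(unit = profiles$unit[u], F0 = m$F0, F1 = m$F1, F = m$F,
               sinusoid_fit_r = m$sinusoid_fit_r, class = m$class)
  })
  do.call(rbind, rows)
}

#' Pairwise natural-movie response correlations
#'
#' For each clip, the Pearson correlation of every pair of units' response
#' time courses; the reported matrix averages over clips. A pair is skipped
#' on clips where either unit has zero response variance, and the number of
#' contributing clips is returned alongside.
#'
#' @param params A `network_params` object.
#' @param clips List of [movie_clip()] objects (typically 100 validation
#'   clips).
#' @return A list of class `response_correlations`: `correlation` (symmetric
#'   `n_units x n_units`, unit diagonal) and `n_clips_used` per pair.
#' @export
response_correlations <- function(params, clips) {
  nh <- params$config$n_hidden
  acc <- matrix(0, nh, nh)
  cnt <- matrix(0L, nh, nh)
  for (clip in clips) {
    S <- forward(params, clip)$s
    sds <- apply(S, 2, stats::sd)
    ok <- sds > 0
    if (sum(ok) >= 2) {
      cc <- stats::cor(S[, ok, drop = FALSE])
      acc[ok, ok] <- acc[ok, ok] + cc
      cnt[ok, ok] <- cnt[ok, ok] + 1L
    }
  }
  corr <- ifelse(cnt > 0, acc / cnt, NA_real_)
  diag(corr) <- 1
  structure(list(correlation = corr, n_clips_used = cnt),
            class = "response_correlations")
}
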