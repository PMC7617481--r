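# Receptive-field estimation by response-weighted averaging, Gabor
# parameterisation, and the inclusion criteria applied before any
# connectivity analysis.

#' Response-weighted-average receptive fields
#'
#' Presents `n_noise_frames` of white Gaussian noise (mean 0, sd 1) as one
#' continuous sequence (recurrent state carried across frames, not reset)
#' and estimates each unit's receptive field as the response-weighted
#' average of the stimulus, `RF = sum_t r_t x_t / sum_t r_t`. The
#' spatiotemporal variant stacks the past `n_lags` frames (lag 0 = current).
#' Units with zero total response have undefined fields and are flagged.
#'
#' @param params A `network_params` object.
#' @param n_noise_frames Number of noise frames (default 25,000).
#' @param n_lags Number of past lags in the spatiotemporal map (default 7).
#' @param seed Integer seed for the noise sequence.
#' @param chunk Frames processed per block (memory control; no effect on the
#'   result).
#' @return An object of class `rf_set`: `map` (`n_units x H x W`, lag-0
#'   field), `st_map` (`n_units x n_lags x H x W`), `undefined` (logical per
#'   unit), and the frame geometry.
#' @export
response_weighted_average <- function(params, n_noise_frames = 25000,
                                      n_lags = 7, seed = 1, chunk = 5000) {
  ni <- params$config$n_input
  nh <- params$config$n_hidden
  side <- as.integer(sqrt(ni))
  stopifnot(side * side == ni, n_lags >= 1)
  num <- array(0, c(nh, n_lags, ni)) # sum_t r_t x_{t-l}
  den <- rep(0, nh)
  state <- rep(0, nh)
  W_eff <- dale_weights(params)
  prev_tail <- NULL # last n_lags-1 frames of the previous chunk
  done <- 0
  with_seed(seed, {
    while (done < n_noise_frames) {
      n_t <- min(chunk, n_noise_frames - done)
      X <- matrix(stats::rnorm(n_t * ni), n_t, ni)
      S <- matrix(0, n_t, nh)
      for (t in seq_len(n_t)) {
        state <- pmax(0, drop(params$W_in %*% X[t, ] + W_eff %*% state) +
                        params$b_rec)
        S[t, ] <- state
      }
      Xfull <- rbind(prev_tail, X)
      off <- nrow(Xfull) - n_t # rows of history before this chunk
      for (l in seq_len(n_lags) - 1L) {
        rows <- seq_len(n_t) + off - l
        ok <- rows >= 1
        if (!any(ok)) next
        num[, l + 1L, ] <- num[, l + 1L, ] +
          crossprod(S[ok, , drop = FALSE], Xfull[rows[ok], , drop = FALSE])
      }
      den <- den + colSums(S)
      keep <- min(n_lags - 1L, nrow(Xfull))
      prev_tail <- if (keep > 0) {
        Xfull[(nrow(Xfull) - keep + 1L):nrow(Xfull), , drop = FALSE]
      } else {
        NULL
      }
      done <- done + n_t
    }
  })
  undefined <- den == 0
  den_safe <- ifelse(undefined, NA_real_, den)
  st <- num / rep(den_safe, times = n_lags * ni)
  st_map <- array(st, c(nh, n_lags, side, side))
  map <- array(st_map[, 1L, , ], c(nh, side, side))
  structure(
    list(map = map, st_map = st_map, undefined = undefined,
         side = side, n_lags = n_lags, n_frames = n_noise_frames),
    class = "rf_set"
  )
}

#' @export
print.rf_set <- function(x, ...) {
  cat(sprintf("<rf_set> %d units, %dx%d px, %d lags (from %d noise frames)\n",
              dim(x$map)[1], x$side, x$side, x$n_lags, x$n_frames))
  invisible(x)
}

#' Temporal power profile and centre of mass of a spatiotemporal field
#'
#' Per lag, the mean squared field value over space, normalised to sum to
#' one; the temporal centre of mass is the power-weighted mean lag (lag 0 =
#' current frame).
#'
#' @param st_map A `n_lags x H x W` array (one unit's spatiotemporal map).
#' @return A list with `temporal_power` (sums to 1) and `center_of_mass`.
#' @export
temporal_summary <- function(st_map) {
  stopifnot(length(dim(st_map)) == 3L)
  pw <- apply(st_map^2, 1, mean)
  if (sum(pw) == 0) stop("all-zero spatiotemporal map: temporal power undefined")
  pw <- pw / sum(pw)
  lags <- seq_along(pw) - 1
  list(temporal_power = pw, center_of_mass = sum(lags * pw))
}

# Gabor surface over pixel coordinates. theta is the wave-vector angle; the
# stripe orientation is theta + pi/2 (axial). sigma values enter as
# absolute values so the optimiser can roam freely.
gabor_surface <- function(xg, yg, cx, cy, theta, sigma_x, sigma_y, sf, phase, amp) {
  xr <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  yr <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  amp * exp(-(xr^2 / (2 * abs(sigma_x)^2) + yr^2 / (2 * abs(sigma_y)^2))) *
    cos(2 * pi * sf * xr + phase)
}

#' Fit a Gabor function to a receptive-field map
#'
#' Nonlinear least squares (Levenberg-Marquardt) over centre, envelope
#' sigmas, carrier angle, spatial frequency, phase and amplitude.
#' Initialisation takes the centre from the squared-map centroid and the
#' carrier angle/frequency from the dominant Fourier component; five
#' jittered restarts guard against local minima. `fit_r` is the Pearson
#' correlation between the fitted surface and the map, and `rf_size` the
#' geometric mean of the fitted envelope sigmas. A failed fit (including an
#' all-zero map) returns `fit_r = NA` and `included = FALSE`.
#'
#' @param map `H x W` numeric matrix.
#' @param n_starts Number of jittered restarts.
#' @param seed Seed for the restart jitter.
#' @return A one-row `data.frame` of class `gabor_fit`: `center_x`,
#'   `center_y` (pixels, column/row), `sigma_major`, `sigma_minor`,
#'   `orientation` (stripe orientation, radians in `[0, pi)`),
#'   `spatial_frequency` (cycles/pixel), `phase`, `amplitude`, `fit_r`,
#'   `rf_size`.
#' @export
fit_gabor <- function(map, n_starts = 5, seed = 1) {
  stopifnot(is.matrix(map))
  failed <- data.frame(
    center_x = NA_real_, center_y = NA_real_, sigma_major = NA_real_,
    sigma_minor = NA_real_, orientation = NA_real_,
    spatial_frequency = NA_real_, phase = NA_real_, amplitude = NA_real_,
    fit_r = NA_real_, rf_size = NA_real_
  )
  if (anyNA(map) || all(map == 0) || stats::sd(map) == 0) return(failed)
  H <- nrow(map); W <- ncol(map)
  xg <- outer(rep(1, H), seq_len(W)) # x = column
  yg <- outer(seq_len(H), rep(1, W)) # y = row
  w2 <- map^2 / sum(map^2)
  cx0 <- sum(xg * w2); cy0 <- sum(yg * w2)
  # dominant spatial frequency from the FFT peak (excluding DC)
  spec <- Mod(stats::fft(map))
  fy <- fft_freqs(H); fx <- fft_freqs(W)
  spec[1, 1] <- 0
  pk <- arrayInd(which.max(spec), dim(spec))
  f_vec <- c(fx[pk[2]], fy[pk[1]])
  sf0 <- max(sqrt(sum(f_vec^2)), 0.02)
  theta0 <- atan2(f_vec[2], f_vec[1])
  amp0 <- max(abs(map))
  sig0 <- max(1.5, sqrt(1 / (4 * pi * sf0)))
  dat <- data.frame(z = as.vector(map), x = as.vector(xg), y = as.vector(yg))
  best <- NULL
  best_rss <- Inf
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      jitter <- if (k == 1) rep(0, 4) else stats::rnorm(4, sd = c(0.5, 0.5, 0.4, 0.3))
      list(cx = cx0 + jitter[1], cy = cy0 + jitter[2],
           theta = theta0 + jitter[3], phase = jitter[4])
    })
  })
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ gabor_surface(x, y, cx, cy, theta, sx, sy, sf, ph, A),
        data = dat,
        start = list(cx = st$cx, cy = st$cy, theta = st$theta, sx = sig0,
                     sy = sig0, sf = sf0, ph = st$phase, A = amp0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- fit
      }
    }
  }
  if (is.null(best)) return(failed)
  co <- as.list(stats::coef(best))
  pred <- stats::fitted(best)
  r <- suppressWarnings(stats::cor(pred, dat$z))
  sx <- abs(co$sx); sy <- abs(co$sy)
  data.frame(
    center_x = co$cx, center_y = co$cy,
    sigma_major = max(sx, sy), sigma_minor = min(sx, sy),
    orientation = (co$theta + pi / 2) %% pi,
    spatial_frequency = abs(co$sf), phase = co$ph, amplitude = co$A,
    fit_r = r, rf_size = sqrt(sx * sy)
  )
}

#' Fit Gabors to every receptive field in an `rf_set`
#'
#' @param rfs An `rf_set` from [response_weighted_average()].
#' @param n_starts,seed Passed to [fit_gabor()].
#' @return A `data.frame` with one row per unit (column `unit` plus the
#'   [fit_gabor()] fields).
#' @export
fit_gabor_set <- function(rfs, n_starts = 5, seed = 1) {
  n <- dim(rfs$map)[1]
  rows <- lapply(seq_len(n), function(u) {
    if (rfs$undefined[u]) {
      f <- fit_gabor(matrix(0, 1, 1))
    } else {
      f <- fit_gabor(matrix(rfs$map[u, , ], rfs$side, rfs$side),
                     n_starts = n_starts, seed = derive_seed(seed, u))
    }
    cbind(unit = u, f)
  })
  do.call(rbind, rows)
}

#' Apply the receptive-field inclusion criteria
#'
#' A unit is excluded when its fitted field is smaller than `min_size`
#' pixels or when the Gabor fit correlation falls below `min_r` (failed fits
#' count as excluded by the fit criterion).
#'
#' @param fits A `data.frame` from [fit_gabor_set()].
#' @param min_size Minimum `rf_size` in pixels (default 0.5).
#' @param min_r Minimum Gabor fit correlation (default 0.7).
#' @return `fits` with a logical `included` column; the attribute
#'   `exclusion_summary` reports the fraction excluded by size, by fit, and
#'   by their union.
#' @export
apply_inclusion_criteria <- function(fits, min_size = 0.5, min_r = 0.7) {
  bad_size <- is.na(fits$rf_size) | fits$rf_size < min_size
  bad_fit <- is.na(fits$fit_r) | fits$fit_r < min_r
  fits$included <- !(bad_size | bad_fit)
  attr(fits, "exclusion_summary") <- c(
    frac_size = mean(bad_size),
    frac_fit = mean(bad_fit),
    frac_total = mean(bad_size | bad_fit)
  )
  fits
}
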