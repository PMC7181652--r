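#' Summed probability distribution of a radiocarbon date set
#'
#' Calibrates every determination to unit mass on a common calendar grid and
#' adds the densities elementwise. The total mass therefore equals the number
#' of dates unless `normalize_total = TRUE`, in which case the sum is divided
#' by it.
#'
#' @param dates A tibble of determinations with columns `c14_age`,
#'   `c14_error` and optionally `lab_id`, `delta_r`, `delta_r_error` (see
#'   [read_c14_dates()]).
#' @param curve A [cal_curve()].
#' @param grid_step Grid spacing in calendar years (default 1).
#' @param normalize_total Divide the summed density by the number of dates.
#' @param grid_range Optional `c(old, young)` cal BP window to which the
#'   returned grid is cut after summation (densities are unchanged, the grid
#'   is just windowed).
#' @return A tibble of class `spd` with columns `cal_bp` (ascending) and
#'   `density` (probability mass per grid cell), and attributes `n_dates`,
#'   `normalized_total`, `grid_step`.
#' @export
sum_spd <- function(dates, curve, grid_step = 1, normalize_total = FALSE,
                    grid_range = NULL) {
  stopifnot(inherits(curve, "cal_curve"))
  validate_dates(dates)
  grid <- calib_grid(curve, grid_step)
  r <- dates$c14_age - (dates$delta_r %||% rep(0, nrow(dates)))
  v_date <- dates$c14_error^2 + (dates$delta_r_error %||% rep(0, nrow(dates)))^2
  at <- curve_at(curve, grid)
  dens <- calib_matrix_density(r, v_date, at$mu, at$sigma,
                               lab_id = dates$lab_id)
  total <- rowSums(dens)
  if (normalize_total) total <- total / nrow(dates)
  out <- tibble::tibble(cal_bp = grid, density = total)
  if (!is.null(grid_range)) {
    check_window(grid_range, "grid_range")
    out <- dplyr::filter(out, .data$cal_bp >= grid_range[2],
                         .data$cal_bp <= grid_range[1])
  }
  structure(out, class = c("spd", class(out)),
            n_dates = nrow(dates), normalized_total = normalize_total,
            grid_step = grid_step)
}

# Column j = normalized calibration mass of date j on the shared grid.
# Same likelihood as calibrate(); kept as a matrix op for the Monte-Carlo
# null, where hundreds of thousands of calibrations are needed.
calib_matrix_density <- function(r, v_date, mu, sigma_c, lab_id = NULL) {
  v <- outer(sigma_c^2, v_date, "+")
  z <- outer(mu, r, "-")
  d <- exp(-(z * z) / (2 * v))
  cs <- colSums(d)
  if (any(cs == 0)) {
    bad <- which(cs == 0)[1]
    id <- if (!is.null(lab_id)) lab_id[bad] else sprintf("#%d", bad)
    abort(sprintf("calibration failure for date %s: inconsistent with curve everywhere", id))
  }
  sweep(d, 2, cs, "/")
}

#' Monte-Carlo null envelope for an SPD under uniform calendar deposition
#'
#' Implements the uniform-calendar null: per simulation, `n_dates` calendar
#' years are drawn uniformly over `window`, each is back-calibrated with a
#' lab error resampled (with replacement) from `error_pool`, the simulated
#' determinations are calibrated and summed, and the envelope records the
#' pointwise mean and the central `band_mass` percentile band over all
#' simulations.
#'
#' @param n_dates Number of dates per simulated set.
#' @param error_pool Numeric vector of lab errors (14C yr) to resample.
#' @param window `c(old, young)` cal BP; calendar years are drawn uniformly
#'   on it and the envelope is reported on its grid.
#' @param curve A [cal_curve()]; the window must lie inside its span.
#' @param n_sims Number of simulated date sets.
#' @param band_mass Central band coverage (default 0.95).
#' @param seed Integer seed; the envelope is fully reproducible from it.
#' @param grid_step Grid spacing in calendar years (default 1).
#' @return A tibble of class `spd_null` with columns `cal_bp`, `mean`,
#'   `lower`, `upper`, and attributes `n_sims`, `band_mass`, `window`,
#'   `seed`, `n_dates`, `grid_step`.
#' @export
simulate_null <- function(n_dates, error_pool, window, curve, n_sims,
                          band_mass = 0.95, seed = 1L, grid_step = 1) {
  stopifnot(inherits(curve, "cal_curve"))
  check_window(window)
  if (length(error_pool) == 0 || any(error_pool <= 0)) {
    abort("error_pool must be a non-empty vector of positive lab errors")
  }
  if (n_sims < 1) abort("n_sims must be >= 1")
  rng <- range(curve$cal_bp)
  if (window[2] < rng[1] || window[1] > rng[2]) {
    abort(sprintf("window [%s, %s] outside curve span [%s, %s]",
                  window[1], window[2], rng[1], rng[2]))
  }
  # extend the calibration grid beyond the window so per-date mass is not
  # clipped; 8 sd of total error translated through the shallowest curve slope
  slopes <- diff(curve$c14_bp) / diff(curve$cal_bp)
  min_slope <- max(min(slopes), 0.05)
  margin <- ceiling(8 * sqrt(max(error_pool)^2 + max(curve$sigma)^2) / min_slope)
  ext <- c(min(window[1] + margin, floor(rng[2] / grid_step) * grid_step),
           max(window[2] - margin, ceiling(rng[1] / grid_step) * grid_step))
  grid <- seq(ext[2], ext[1], by = grid_step)
  at <- curve_at(curve, grid)
  in_win <- grid >= window[2] & grid <= window[1]
  sims <- withr::with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      ages <- runif(n_dates, window[2], window[1])
      slab <- sample(error_pool, n_dates, replace = TRUE)
      c14 <- uncalibrate(ages, curve, slab)
      d <- calib_matrix_density(c14, slab^2, at$mu, at$sigma)
      rowSums(d)[in_win]
    }, numeric(sum(in_win)))
  })
  alpha <- (1 - band_mass) / 2
  qs <- apply(sims, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  out <- tibble::tibble(cal_bp = grid[in_win],
                        mean = rowMeans(sims),
                        lower = qs[1, ],
                        upper = qs[2, ])
  structure(out, class = c("spd_null", class(out)),
            n_sims = n_sims, band_mass = band_mass, window = window,
            seed = seed, n_dates = n_dates, grid_step = grid_step)
}

#' Intervals where an SPD escapes its null envelope
#'
#' Finds maximal runs of grid cells where the observed SPD density lies above
#' the envelope's upper bound (sign `"+"`) or below its lower bound (sign
#' `"-"`), discarding runs spanning less than `min_duration` calendar years.
#' Runs touching the outer `edge_margin` years of the null window are flagged
#' (`edge = TRUE`): the uniform null is biased there by calibration
#' spill-over.
#'
#' @param spd An `spd` tibble from [sum_spd()].
#' @param env An `spd_null` tibble from [simulate_null()] on the same grid.
#' @param min_duration Minimum run length in calendar years (default 50).
#' @param edge_margin Edge-flag margin in calendar years (default 100).
#' @return A tibble with columns `cal_bp_old`, `cal_bp_young`, `sign`,
#'   `duration`, `edge`, ordered old to young. Zero rows when the SPD stays
#'   inside the band.
#' @export
spd_deviations <- function(spd, env, min_duration = 50, edge_margin = 100) {
  if (nrow(spd) != nrow(env) || any(spd$cal_bp != env$cal_bp)) {
    abort("grid mismatch: spd and envelope must share an identical cal_bp grid")
  }
  step <- attr(spd, "grid_step") %||% min(diff(spd$cal_bp))
  state <- ifelse(spd$density > env$upper, 1L,
                  ifelse(spd$density < env$lower, -1L, 0L))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values != 0L
  win <- attr(env, "window") %||% range(env$cal_bp)[c(2, 1)]
  out <- purrr::map_dfr(which(keep), function(i) {
    lo <- spd$cal_bp[starts[i]]
    hi <- spd$cal_bp[ends[i]]
    tibble::tibble(
      cal_bp_old = hi, cal_bp_young = lo,
      sign = if (runs$values[i] > 0) "+" else "-",
      duration = hi - lo,
      edge = lo <= (min(win) + edge_margin) || hi >= (max(win) - edge_margin)
    )
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(cal_bp_old = numeric(), cal_bp_young = numeric(),
                          sign = character(), duration = numeric(),
                          edge = logical()))
  }
  out <- dplyr::filter(out, .data$duration >= min_duration)
  dplyr::arrange(out, dplyr::desc(.data$cal_bp_old))
}
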