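#' Calibrate a radiocarbon determination
#'
#' Converts a conventional 14C age `r +/- sigma_lab` into a probability mass
#' function over calendar age. On a uniform grid of calendar ages theta the
#' unnormalized density is
#' `exp(-(r - dR - mu(theta))^2 / (2 * (sigma_lab^2 + sigma_dR^2 + sigma_c(theta)^2)))`,
#' where `mu`, `sigma_c` are the interpolated curve mean and error and `dR`
#' is an optional reservoir offset (marine convention). The density is
#' normalized to total mass 1, trimmed to the smallest contiguous grid span
#' holding at least `1 - trim_mass` of the mass, and renormalized.
#'
#' @param c14_age Measured 14C age (14C yr BP).
#' @param c14_error One-sigma lab error (14C yr), `> 0`.
#' @param curve A [cal_curve()].
#' @param delta_r,delta_r_error Reservoir offset and its one-sigma error
#'   (14C yr); defaults 0.
#' @param grid_step Grid spacing in calendar years (default 1).
#' @param trim_mass Total tail mass removed by trimming (default 1e-5).
#'
#' @return A tibble of class `cal_density` with columns `cal_bp` (ascending)
#'   and `mass` (sums to 1), and attributes `grid_step`, `c14_age`,
#'   `c14_error`.
#' @export
#' @examples
#' crv <- cal_curve(c(4000, 6000), c(4000, 6000), c(1e-6, 1e-6))
#' d <- calibrate(4500, 20, crv)
#' sum(d$mass)
calibrate <- function(c14_age, c14_error, curve, delta_r = 0,
                      delta_r_error = 0, grid_step = 1, trim_mass = 1e-5) {
  stopifnot(inherits(curve, "cal_curve"))
  if (length(c14_age) != 1) abort("calibrate() takes a single determination")
  if (!is.finite(c14_error) || c14_error <= 0) abort("c14_error must be > 0")
  if (delta_r_error < 0) abort("delta_r_error must be >= 0")
  grid <- calib_grid(curve, grid_step)
  mass <- calib_mass(c14_age, c14_error, curve, grid,
                     delta_r = delta_r, delta_r_error = delta_r_error)
  tr <- trim_density(grid, mass, trim_mass)
  out <- tibble::tibble(cal_bp = tr$grid, mass = tr$mass)
  structure(out, class = c("cal_density", class(out)),
            grid_step = grid_step, c14_age = c14_age, c14_error = c14_error)
}

calib_grid <- function(curve, grid_step) {
  lo <- ceiling(min(curve$cal_bp) / grid_step) * grid_step
  hi <- floor(max(curve$cal_bp) / grid_step) * grid_step
  seq(lo, hi, by = grid_step)
}

# Unnormalized-then-normalized calibration mass on a supplied grid.
calib_mass <- function(c14_age, c14_error, curve, grid,
                       delta_r = 0, delta_r_error = 0) {
  at <- curve_at(curve, grid)
  v <- c14_error^2 + delta_r_error^2 + at$sigma^2
  dens <- exp(-(c14_age - delta_r - at$mu)^2 / (2 * v))
  if (max(dens) < 1e-300) {
    abort(sprintf(
      "calibration failure: 14C age %s inconsistent with curve everywhere",
      format(c14_age)))
  }
  dens / sum(dens)
}

# Smallest contiguous window holding >= 1 - trim_mass, then renormalize.
trim_density <- function(grid, mass, trim_mass) {
  if (trim_mass <= 0) return(list(grid = grid, mass = mass))
  target <- 1 - trim_mass
  cs <- cumsum(mass)
  # for each right end j, leftmost i with sum(mass[i..j]) >= target is
  # the first i where cs[j] - cs[i-1] >= target, i.e. cs[i-1] <= cs[j]-target
  i_minus_1 <- findInterval(cs - target, cs)       # rows where feasible
  feasible <- which(cs - target >= 0)
  if (length(feasible) == 0) return(list(grid = grid, mass = mass))
  widths <- feasible - i_minus_1[feasible]
  j <- feasible[which.min(widths)]
  i <- i_minus_1[j] + 1
  m <- mass[i:j]
  list(grid = grid[i:j], mass = m / sum(m))
}

#' Simulate a radiocarbon determination from a known calendar age
#'
#' Back-calibration ("uncalibration"): the step that turns calendar years
#' sampled under a null or a synthetic occupation model into measurable 14C
#' ages. Returns `mu(cal_bp)` plus Gaussian noise with standard deviation
#' `sqrt(sigma_c(cal_bp)^2 + sigma_lab^2)`.
#'
#' @param cal_bp Calendar age(s) within the curve span (cal BP).
#' @param curve A [cal_curve()].
#' @param sigma_lab Lab error(s) (14C yr), `> 0`; recycled against `cal_bp`.
#' @param seed Optional integer; when given, draws are made in a local RNG
#'   scope so repeated calls with the same seed return identical values and
#'   the caller's RNG state is untouched.
#' @return Numeric vector of simulated 14C ages (14C yr BP).
#' @export
uncalibrate <- function(cal_bp, curve, sigma_lab, seed = NULL) {
  if (any(!is.finite(sigma_lab) | sigma_lab <= 0)) abort("sigma_lab must be > 0")
  at <- curve_at(curve, cal_bp)   # range-checks cal_bp
  sd_tot <- sqrt(at$sigma^2 + sigma_lab^2)
  draw <- function() at$mu + rnorm(length(cal_bp), 0, sd_tot)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Highest-posterior-density intervals of a calibrated density
#'
#' Ranks grid cells by descending mass, takes the smallest set whose total
#' mass reaches `mass`, and merges contiguous cells into closed intervals.
#'
#' @param d A `cal_density` tibble from [calibrate()].
#' @param mass Target coverage in (0, 1); default 0.954 (two-sigma
#'   convention).
#' @return A tibble with columns `cal_bp_min`, `cal_bp_max`, `mass`
#'   (interval coverage), ordered young to old.
#' @export
hpd_interval <- function(d, mass = 0.954) {
  if (!(mass > 0 && mass < 1)) abort("mass must be in (0, 1)")
  ord <- order(d$mass, decreasing = TRUE)
  cum <- cumsum(d$mass[ord])
  k <- which(cum >= mass)[1]
  if (is.na(k)) k <- length(ord)
  sel <- sort(ord[seq_len(k)])
  step <- attr(d, "grid_step") %||% min(diff(d$cal_bp))
  brk <- c(0, which(diff(d$cal_bp[sel]) > step * 1.5), length(sel))
  purrr::map_dfr(seq_len(length(brk) - 1), function(g) {
    cells <- sel[(brk[g] + 1):brk[g + 1]]
    tibble::tibble(cal_bp_min = d$cal_bp[cells[1]],
                   cal_bp_max = d$cal_bp[cells[length(cells)]],
                   mass = sum(d$mass[cells]))
  })
}

#' Point summaries of a calibrated density
#'
#' @param d A `cal_density` tibble.
#' @return `cal_median()`: the grid age at which the cumulative mass first
#'   reaches 0.5. `cal_mode()`: the grid age of maximum mass.
#' @export
cal_median <- function(d) {
  d$cal_bp[which(cumsum(d$mass) >= 0.5)[1]]
}

#' @rdname cal_median
#' @export
cal_mode <- function(d) {
  d$cal_bp[which.max(d$mass)]
}
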