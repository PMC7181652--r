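#' Piecewise-linear age-depth model
#'
#' Builds a piecewise-linear interpolant of age versus depth through dated
#' control points (typically medians of calibrated densities, see
#' [cal_median()]). Depth and age must both increase strictly downcore; any
#' reversal is reported with the offending pairs.
#'
#' @param points Data frame with columns `depth_cm`, `cal_bp` and optionally
#'   `sigma` (age uncertainty, carried as metadata).
#' @return An object of class `age_depth`.
#' @export
#' @examples
#' adm <- age_depth_model(data.frame(depth_cm = c(0, 100), cal_bp = c(4000, 8000)))
#' age_at_depth(adm, 50)
age_depth_model <- function(points) {
  df <- as.data.frame(points)
  need <- c("depth_cm", "cal_bp")
  if (!all(need %in% names(df))) abort("control points need columns depth_cm, cal_bp")
  df <- df[order(df$depth_cm), , drop = FALSE]
  if (nrow(df) < 2) abort("an age-depth model needs >= 2 control points")
  if (any(diff(df$depth_cm) <= 0)) abort("control-point depths must be strictly increasing")
  rev_idx <- which(diff(df$cal_bp) <= 0)
  if (length(rev_idx)) {
    pairs <- paste(sprintf("(%g cm: %g BP) >= (%g cm: %g BP)",
                           df$depth_cm[rev_idx], df$cal_bp[rev_idx],
                           df$depth_cm[rev_idx + 1], df$cal_bp[rev_idx + 1]),
                   collapse = "; ")
    abort(sprintf("age reversal(s) in control points: %s", pairs))
  }
  structure(list(depth_cm = df$depth_cm, cal_bp = df$cal_bp,
                 sigma = df$sigma %||% rep(NA_real_, nrow(df))),
            class = "age_depth")
}

#' @export
print.age_depth <- function(x, ...) {
  cat(sprintf("piecewise-linear age-depth model: %d control points, %g-%g cm, %g-%g cal BP\n",
              length(x$depth_cm), min(x$depth_cm), max(x$depth_cm),
              min(x$cal_bp), max(x$cal_bp)))
  invisible(x)
}

adm_segment <- function(adm, depth_cm) {
  rng <- range(adm$depth_cm)
  if (any(depth_cm < rng[1] | depth_cm > rng[2])) {
    abort(sprintf("depth outside modelled span [%g, %g] cm (extrapolation refused)",
                  rng[1], rng[2]))
  }
  # at an interior knot the younger (shallower) segment applies
  pmax(1L, findInterval(depth_cm, adm$depth_cm, left.open = TRUE))
}

#' Evaluate an age-depth model
#'
#' `age_at_depth()` interpolates age linearly; `sar_at_depth()` returns the
#' local sediment accumulation rate, the slope d(depth)/d(age) of the
#' containing segment (at a knot, the younger segment's slope applies).
#' Depths outside the modelled span are refused.
#'
#' @param adm An [age_depth_model()].
#' @param depth_cm Numeric vector of depths (cm).
#' @return Numeric vector: ages in cal BP, or SAR in cm/yr.
#' @export
age_at_depth <- function(adm, depth_cm) {
  adm_segment(adm, depth_cm)   # range check
  approx(adm$depth_cm, adm$cal_bp, xout = depth_cm)$y
}

#' @rdname age_at_depth
#' @export
sar_at_depth <- function(adm, depth_cm) {
  seg <- adm_segment(adm, depth_cm)
  slopes <- diff(adm$depth_cm) / diff(adm$cal_bp)
  slopes[seg]
}

#' Proxy flux (accumulation rate) from concentrations and an age-depth model
#'
#' Flux at each sample is its concentration multiplied by the local sediment
#' accumulation rate: `flux_i = concentration_i * sar(depth_i)`, in
#' (concentration unit) x cm/yr.
#'
#' @param record Core table: data frame with `depth_cm` plus one column per
#'   proxy (non-negative concentrations). A `site` attribute or column is
#'   carried through.
#' @param adm An [age_depth_model()] spanning all sample depths.
#' @param proxy Name of the proxy column to use.
#' @return A tibble of class `flux_series` with columns `depth_cm`, `cal_bp`,
#'   `concentration`, `sar`, `flux`, and attributes `site`, `proxy`.
#' @export
compute_flux <- function(record, adm, proxy) {
  df <- as.data.frame(record)
  if (!"depth_cm" %in% names(df)) abort("core record needs a depth_cm column")
  if (!proxy %in% names(df)) {
    abort(sprintf("proxy '%s' not present in core record (has: %s)",
                  proxy, paste(setdiff(names(df), "depth_cm"), collapse = ", ")))
  }
  conc <- df[[proxy]]
  if (any(conc < 0, na.rm = TRUE)) abort("concentrations must be >= 0")
  rng <- range(adm$depth_cm)
  bad <- which(df$depth_cm < rng[1] | df$depth_cm > rng[2])
  if (length(bad)) {
    abort(sprintf("sample depth(s) outside age model span: rows %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  sar <- sar_at_depth(adm, df$depth_cm)
  out <- tibble::tibble(depth_cm = df$depth_cm,
                        cal_bp = age_at_depth(adm, df$depth_cm),
                        concentration = conc, sar = sar, flux = conc * sar)
  site <- attr(record, "site") %||%
    (if ("site" %in% names(df)) as.character(df$site[1]) else NA_character_)
  structure(out, class = c("flux_series", class(out)), site = site, proxy = proxy)
}

#' Multi-site z-score composite with lowess smoothing
#'
#' Restricts each site's flux series to the analysis window, standardizes it
#' (mean 0, sd 1 within the window, per site), pools all (age, z) points, and
#' fits a lowess smoother (tricube weights, local linear fits, 3 robustifying
#' iterations) with `span` as the fraction of pooled points, evaluated on a
#' 10-year grid.
#'
#' @param series A list of `flux_series` tibbles (see [compute_flux()]);
#'   names or `site` attributes label the sites.
#' @param window `c(old, young)` analysis window in cal BP (default
#'   `c(8000, 4000)`).
#' @param span Lowess span as a fraction of pooled points (default 0.1).
#' @param grid_step Evaluation grid spacing in years (default 10).
#' @return An object of class `composite_series`: list with `points` (tibble
#'   site, cal_bp, z), `smooth` (tibble cal_bp, value), `span`, `window`.
#' @export
composite_zscores <- function(series, window = c(8000, 4000), span = 0.1,
                              grid_step = 10) {
  check_window(window)
  if (inherits(series, "flux_series")) series <- list(series)
  if (length(series) < 1) abort("need at least one flux series")
  site_names <- purrr::imap_chr(series, function(s, i) {
    attr(s, "site") %||% (if (is.character(i)) i else sprintf("site_%s", i))
  })
  points <- purrr::map2_dfr(series, site_names, function(s, nm) {
    w <- dplyr::filter(s, .data$cal_bp >= window[2], .data$cal_bp <= window[1])
    if (nrow(w) < 3) {
      abort(sprintf("site %s has < 3 samples inside the window", nm))
    }
    sdv <- sd(w$flux)
    if (!is.finite(sdv) || sdv == 0) {
      abort(sprintf("site %s: zero flux variance in window, cannot standardize", nm))
    }
    tibble::tibble(site = nm, cal_bp = w$cal_bp,
                   z = (w$flux - mean(w$flux)) / sdv)
  })
  points <- dplyr::arrange(points, .data$cal_bp)
  lw <- lowess(points$cal_bp, points$z, f = span, iter = 3)
  grid <- seq(ceiling(min(points$cal_bp) / grid_step) * grid_step,
              floor(max(points$cal_bp) / grid_step) * grid_step,
              by = grid_step)
  smooth <- tibble::tibble(cal_bp = grid,
                           value = approx(lw$x, lw$y, xout = grid, ties = mean)$y)
  structure(list(points = points, smooth = smooth, span = span,
                 window = window),
            class = "composite_series")
}

#' @export
print.composite_series <- function(x, ...) {
  cat(sprintf("composite z-score series: %d sites, %d points, window %g-%g cal BP, span %g\n",
              length(unique(x$points$site)), nrow(x$points),
              x$window[1], x$window[2], x$span))
  invisible(x)
}

#' Delimit production phases from a smoothed composite
#'
#' Maximal runs of the smoothed composite exceeding `threshold_sd` z-score
#' units, discarding runs shorter than `min_duration` years. The threshold
#' is an operational convention of this package (recorded in the output
#' attributes), not a published constant.
#'
#' @param cs A [composite_zscores()] result.
#' @param threshold_sd Z-score threshold (default 0.5).
#' @param min_duration Minimum phase duration in years (default 100).
#' @return A tibble with columns `cal_bp_old`, `cal_bp_young`, `duration`,
#'   `peak_z`, ordered old to young; attributes record the convention.
#' @export
detect_production_phases <- function(cs, threshold_sd = 0.5, min_duration = 100) {
  stopifnot(inherits(cs, "composite_series"))
  sm <- cs$smooth
  above <- !is.na(sm$value) & sm$value > threshold_sd
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- purrr::map_dfr(which(runs$values), function(i) {
    seg <- starts[i]:ends[i]
    tibble::tibble(cal_bp_old = sm$cal_bp[ends[i]],
                   cal_bp_young = sm$cal_bp[starts[i]],
                   duration = sm$cal_bp[ends[i]] - sm$cal_bp[starts[i]],
                   peak_z = max(sm$value[seg]))
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(cal_bp_old = numeric(), cal_bp_young = numeric(),
                          duration = numeric(), peak_z = numeric())
  } else {
    out <- dplyr::arrange(dplyr::filter(out, .data$duration >= min_duration),
                          dplyr::desc(.data$cal_bp_old))
  }
  structure(out, threshold_sd = threshold_sd, min_duration = min_duration)
}

#' Read core tables and control points from CSV
#'
#' Core dialect: `depth_cm` then proxy columns. Control-point dialect:
#' `depth_cm, cal_bp[, sigma]`.
#'
#' @param path CSV path.
#' @param site Optional site label attached as an attribute.
#' @return A tibble (`read_core()`) or an [age_depth_model()]
#'   (`read_control_points()` returns the raw tibble; pass it to
#'   [age_depth_model()]).
#' @export
read_core <- function(path, site = NULL) {
  df <- tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE,
                                          comment = "#"))
  if (!"depth_cm" %in% names(df)) abort("core CSV needs a depth_cm column")
  structure(df, site = site %||% basename(path))
}

#' @rdname read_core
#' @export
read_control_points <- function(path) {
  tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE, comment = "#"))
}
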