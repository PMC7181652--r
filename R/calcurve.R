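#' Construct a calibration curve
#'
#' A calibration curve maps calendar age (cal BP, BP = before AD 1950) to the
#' conventional radiocarbon age mu(theta) with its own one-sigma uncertainty
#' sigma_c(theta). Between tabulated knots both the mean and the error are
#' interpolated linearly.
#'
#' @param cal_bp Numeric vector of calendar ages (cal BP). Any order; stored
#'   ascending.
#' @param c14_bp Numeric vector of conventional 14C ages (14C yr BP).
#' @param sigma Numeric vector of curve errors (14C yr), all `> 0`.
#' @param name Curve label.
#' @param kind `"atmospheric"` or `"marine"`. Marine curves carry the
#'   convention that a per-date reservoir offset (delta R) is subtracted from
#'   the determination before calibration.
#'
#' @return A tibble of class `cal_curve` with columns `cal_bp`, `c14_bp`,
#'   `sigma`, sorted ascending in `cal_bp`.
#' @export
#' @examples
#' cal_curve(c(1000, 2000), c(1050, 2040), c(10, 12))
cal_curve <- function(cal_bp, c14_bp, sigma, name = "synthetic",
                      kind = c("atmospheric", "marine")) {
  kind <- match.arg(kind)
  if (length(cal_bp) < 2) abort("a calibration curve needs at least 2 knots")
  if (length(c14_bp) != length(cal_bp) || length(sigma) != length(cal_bp)) {
    abort("cal_bp, c14_bp and sigma must have equal length")
  }
  if (anyNA(cal_bp) || anyNA(c14_bp) || anyNA(sigma)) {
    abort("calibration curve knots must not contain NA")
  }
  if (any(sigma <= 0)) abort("curve sigma must be > 0 at every knot")
  ord <- order(cal_bp)
  cal_bp <- cal_bp[ord]
  if (any(diff(cal_bp) <= 0)) {
    abort("cal_bp must be strictly increasing after sorting (duplicate calendar ages)")
  }
  out <- tibble::tibble(cal_bp = as.numeric(cal_bp),
                        c14_bp = as.numeric(c14_bp[ord]),
                        sigma = as.numeric(sigma[ord]))
  structure(out, class = c("cal_curve", class(out)),
            curve_name = name, kind = kind)
}

#' Read a calibration curve from a text file
#'
#' Accepts the common tabulated-curve dialect: lines starting with `#` and
#' blank lines are ignored, fields are separated by commas or whitespace
#' (auto-detected per line), and the three leading columns are read as
#' (cal BP, 14C age BP, curve error). Rows may appear in any order (IntCal
#' files run old to young); the result is always sorted ascending in cal BP.
#'
#' @param path Path to the curve file.
#' @inheritParams cal_curve
#' @return A [cal_curve()] tibble.
#' @export
read_calcurve <- function(path, name = basename(path),
                          kind = c("atmospheric", "marine")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("curve file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2) abort(sprintf("curve file %s: need at least 2 data rows", path))
  parse_row <- function(line, lineno) {
    line <- sub("#.*$", "", line)
    fields <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
    if (length(fields) < 3) {
      abort(sprintf("curve file %s, line %d: expected >= 3 fields, got %d",
                    path, lineno, length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals)) {
      abort(sprintf("curve file %s, line %d: non-numeric field in first 3 columns",
                    path, lineno))
    }
    vals
  }
  mat <- t(vapply(seq_along(idx),
                  function(i) parse_row(lines[idx[i]], idx[i]),
                  numeric(3)))
  cal_curve(mat[, 1], mat[, 2], mat[, 3], name = name, kind = kind)
}

#' Write a calibration curve to a text file
#'
#' Writes the dialect [read_calcurve()] reads (comma-separated, `#` header),
#' round-tripping the knot values exactly (full double precision).
#'
#' @param curve A [cal_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calcurve <- function(curve, path) {
  stopifnot(inherits(curve, "cal_curve"))
  header <- sprintf("# %s (%s): cal BP, 14C age BP, curve error",
                    attr(curve, "curve_name"), attr(curve, "kind"))
  body <- sprintf("%.17g,%.17g,%.17g", curve$cal_bp, curve$c14_bp, curve$sigma)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Evaluate a calibration curve at calendar ages
#'
#' Linear interpolation of both the 14C-age mean and the curve error; exact
#' at knots. Ages outside the tabulated span are refused.
#'
#' @param curve A [cal_curve()].
#' @param cal_bp Numeric vector of calendar ages (cal BP).
#' @return A tibble with columns `cal_bp`, `mu` (14C yr BP) and `sigma`
#'   (14C yr).
#' @export
curve_at <- function(curve, cal_bp) {
  stopifnot(inherits(curve, "cal_curve"))
  rng <- range(curve$cal_bp)
  if (any(cal_bp < rng[1] | cal_bp > rng[2])) {
    abort(sprintf("cal_bp outside curve span [%s, %s]", rng[1], rng[2]))
  }
  tibble::tibble(
    cal_bp = as.numeric(cal_bp),
    mu = approx(curve$cal_bp, curve$c14_bp, xout = cal_bp)$y,
    sigma = approx(curve$cal_bp, curve$sigma, xout = cal_bp)$y
  )
}

#' Read a radiocarbon date list from CSV
#'
#' Expected header: `lab_id,c14_age,c14_error` with optional `delta_r`,
#' `delta_r_error`, `material` columns. Missing reservoir columns default
#' to 0.
#'
#' @param path CSV path.
#' @return A tibble with one row per determination.
#' @export
read_c14_dates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("lab_id", "c14_age", "c14_error")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("date list %s lacks column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (!"delta_r" %in% names(df)) df$delta_r <- 0
  if (!"delta_r_error" %in% names(df)) df$delta_r_error <- 0
  if (!"material" %in% names(df)) df$material <- NA_character_
  validate_dates(df)
  tibble::as_tibble(df)
}

validate_dates <- function(dates) {
  if (nrow(dates) == 0) abort("date set is empty")
  if (any(!is.finite(dates$c14_age))) abort("c14_age must be finite")
  if (any(!is.finite(dates$c14_error) | dates$c14_error <= 0)) {
    abort("all c14_error values must be > 0")
  }
  dr_err <- dates$delta_r_error %||% rep(0, nrow(dates))
  if (any(dr_err < 0)) abort("delta_r_error must be >= 0")
  invisible(dates)
}
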