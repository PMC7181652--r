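#' Cultural period table for Southern Scandinavia
#'
#' The default table spans the Mesolithic Kongemose (8400-7400 cal BP) and
#' Ertebolle (7400-5900 cal BP) cultures and the earlier (5900-5000) and
#' later (5000-4000) Neolithic. Periods must be contiguous, non-overlapping
#' and ordered old to young.
#'
#' @param labels Character vector of period labels.
#' @param old_bp,young_bp Numeric bounds (cal BP), `old_bp > young_bp`.
#' @return A tibble of class `period_table` with columns `label`, `old_bp`,
#'   `young_bp`.
#' @export
period_table <- function(labels, old_bp, young_bp) {
  if (length(labels) != length(old_bp) || length(labels) != length(young_bp)) {
    abort("labels, old_bp and young_bp must have equal length")
  }
  if (any(old_bp <= young_bp)) abort("each period needs old_bp > young_bp")
  ord <- order(old_bp, decreasing = TRUE)
  labels <- labels[ord]; old_bp <- old_bp[ord]; young_bp <- young_bp[ord]
  if (length(labels) > 1 && any(young_bp[-length(labels)] != old_bp[-1])) {
    abort("periods must be contiguous: each young bound must equal the next old bound")
  }
  out <- tibble::tibble(label = labels, old_bp = old_bp, young_bp = young_bp)
  structure(out, class = c("period_table", class(out)))
}

#' @rdname period_table
#' @export
default_period_table <- function() {
  period_table(
    labels = c("Kongemose", "Ertebolle", "earlier Neolithic", "later Neolithic"),
    old_bp = c(8400, 7400, 5900, 5000),
    young_bp = c(7400, 5900, 5000, 4000)
  )
}

# Mesolithic/Neolithic grouping used for the pooled isotope summaries
period_epoch <- function(label) {
  dplyr::case_match(label,
    c("Kongemose", "Ertebolle") ~ "Mesolithic",
    c("earlier Neolithic", "later Neolithic") ~ "Neolithic",
    .default = NA_character_)
}

#' Assign a calendar age to a cultural period
#'
#' Boundary convention: a period covers `old_bp >= age > young_bp`, so an
#' age exactly on a boundary belongs to the younger period (e.g. 5900 cal BP
#' is earlier Neolithic, not Ertebolle). The youngest period's young bound is
#' additionally inclusive so the table span is fully covered.
#'
#' @param age Numeric vector of ages (cal BP).
#' @param table A [period_table()] (default [default_period_table()]).
#' @return Character vector of period labels.
#' @export
assign_period <- function(age, table = default_period_table()) {
  stopifnot(inherits(table, "period_table"))
  span <- c(max(table$old_bp), min(table$young_bp))
  if (any(age > span[1] | age < span[2], na.rm = TRUE)) {
    abort(sprintf("age(s) outside period-table span [%g, %g] cal BP",
                  span[1], span[2]))
  }
  vapply(age, function(a) {
    if (is.na(a)) return(NA_character_)
    hit <- which(table$old_bp >= a & a > table$young_bp)
    if (length(hit) == 0 && a == span[2]) hit <- nrow(table)
    table$label[hit[1]]
  }, character(1))
}

#' Box-plot summaries of isotope values by period
#'
#' Summaries per period label and isotope: n, mean, median, quartiles
#' (linear-interpolation "inclusive" quantiles, R type 7), minimum and
#' maximum, computed over the samples that carry that isotope. Samples with
#' a `period` column use it; otherwise periods are assigned from `age_calbp`.
#' Humans and dogs are summarized separately unless `pool_taxa = TRUE`.
#'
#' @param samples Tibble with columns `id`, `taxon`, optional `period`,
#'   optional `age_calbp`, and isotope columns among `d13c`, `d15n`, `d2h`
#'   (per-mil; empty cells allowed).
#' @param table A [period_table()].
#' @param pool_taxa Pool humans and dogs into one group.
#' @return A tibble with columns `period`, (`taxon`,) `isotope`, `n`,
#'   `mean`, `median`, `q1`, `q3`, `min`, `max`.
#' @export
summarize_by_period <- function(samples, table = default_period_table(),
                                pool_taxa = FALSE) {
  df <- tibble::as_tibble(samples)
  isos <- intersect(c("d13c", "d15n", "d2h"), names(df))
  if (length(isos) == 0) abort("no isotope columns (d13c, d15n, d2h) found")
  if (!"period" %in% names(df) || anyNA(df$period)) {
    if (!"age_calbp" %in% names(df)) {
      abort("samples need a period column or age_calbp to assign one")
    }
    miss <- if ("period" %in% names(df)) is.na(df$period) else rep(TRUE, nrow(df))
    df$period <- ifelse(miss, assign_period(df$age_calbp, table), df$period %||% NA)
  }
  long <- tidyr::pivot_longer(df, dplyr::all_of(isos),
                              names_to = "isotope", values_to = "delta")
  long <- dplyr::filter(long, !is.na(.data$delta), !is.na(.data$period))
  grp <- if (pool_taxa || !"taxon" %in% names(long)) {
    dplyr::group_by(long, .data$period, .data$isotope)
  } else {
    dplyr::group_by(long, .data$period, .data$taxon, .data$isotope)
  }
  out <- dplyr::summarise(grp,
    n = dplyr::n(),
    mean = mean(.data$delta),
    median = median(.data$delta),
    q1 = quantile(.data$delta, 0.25, names = FALSE, type = 7),
    q3 = quantile(.data$delta, 0.75, names = FALSE, type = 7),
    min = min(.data$delta),
    max = max(.data$delta),
    .groups = "drop")
  ord <- match(out$period, table$label)
  dplyr::arrange(out, ord, .data$isotope)
}

#' Two-endmember mixing configuration
#'
#' Marine and terrestrial endmember delta values per isotope. The defaults
#' are package conventions for exploration and simulation, not published
#' constants: d13C marine -12 / terrestrial -21 per mil, d2H marine +70 /
#' terrestrial -10 per mil. d15N is trophic-enriched and excluded from
#' mixing by default; pass endmembers explicitly to include it.
#'
#' @param d13c,d15n,d2h Named numeric vectors `c(marine = , terrestrial = )`
#'   or `NULL` to exclude the isotope.
#' @return A named list of class `mixing_config`.
#' @export
mixing_config <- function(d13c = c(marine = -12, terrestrial = -21),
                          d15n = NULL,
                          d2h = c(marine = 70, terrestrial = -10)) {
  cfg <- purrr::compact(list(d13c = d13c, d15n = d15n, d2h = d2h))
  purrr::iwalk(cfg, function(v, nm) {
    if (!all(c("marine", "terrestrial") %in% names(v))) {
      abort(sprintf("%s endmembers must be named c(marine=, terrestrial=)", nm))
    }
    if (v[["marine"]] == v[["terrestrial"]]) {
      abort(sprintf("%s endmembers must be distinct", nm))
    }
  })
  structure(cfg, class = "mixing_config")
}

#' Marine-resource fraction from a delta value
#'
#' Linear two-endmember mixing:
#' `f = (delta - terrestrial) / (marine - terrestrial)`, clipped to `[0, 1]`
#' with clipping flagged.
#'
#' @param delta Numeric vector of delta values (per mil).
#' @param config A [mixing_config()].
#' @param isotope Which isotope's endmembers to use (`"d13c"`, `"d15n"`,
#'   `"d2h"`).
#' @return A tibble with columns `delta`, `fraction` (in `[0, 1]`),
#'   `clipped`.
#' @export
#' @examples
#' mixing_fraction(-13, mixing_config(), "d13c")  # 8/9
mixing_fraction <- function(delta, config = mixing_config(), isotope) {
  stopifnot(inherits(config, "mixing_config"))
  if (!isotope %in% names(config)) {
    abort(sprintf("no endmembers configured for isotope '%s'", isotope))
  }
  em <- config[[isotope]]
  f_raw <- (delta - em[["terrestrial"]]) / (em[["marine"]] - em[["terrestrial"]])
  tibble::tibble(delta = as.numeric(delta),
                 fraction = pmin(1, pmax(0, f_raw)),
                 clipped = f_raw < 0 | f_raw > 1)
}

#' Read an isotope sample table from CSV
#'
#' Expected header: `id,taxon,period,age_calbp,d13c,d15n,d2h`; empty cells
#' allowed.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_isotopes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!any(c("d13c", "d15n", "d2h") %in% names(df))) {
    abort(sprintf("isotope table %s has no isotope columns", path))
  }
  tibble::as_tibble(df)
}
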