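#' Synthetic calibration curve
#'
#' Builds a wiggly, strictly monotone curve
#' `mu(theta) = theta + wiggle_amp * sin(2*pi*theta / wiggle_period) + noise`
#' with constant curve error `sigma`. The smooth noise term is a cubic spline
#' through seeded Gaussian anchors spaced every 20 knot steps. Parameter
#' combinations that cannot be monotone (`2*pi*wiggle_amp/wiggle_period >=
#' 1`) are refused up front; the generated knots are checked again after
#' noise is added.
#'
#' @param span `c(old, young)` calendar span in cal BP.
#' @param wiggle_amp Sine amplitude (14C yr); 0 for a noise-free identity
#'   curve.
#' @param wiggle_period Sine period (yr).
#' @param sigma Constant curve error (14C yr), `> 0`.
#' @param noise_sd Standard deviation of the smooth noise anchors (14C yr).
#' @param knot_step Knot spacing (yr, default 5).
#' @param seed Integer seed (only needed when `noise_sd > 0`).
#' @return A [cal_curve()] tibble; the truth parameters are attached as the
#'   `truth` attribute.
#' @export
make_calcurve <- function(span = c(12000, 0), wiggle_amp = 30,
                          wiggle_period = 500, sigma = 15, noise_sd = 0,
                          knot_step = 5, seed = 1L) {
  check_window(span, "span")
  if (sigma <= 0) abort("sigma must be > 0")
  if (wiggle_amp < 0 || wiggle_period <= 0) abort("invalid wiggle parameters")
  if (wiggle_amp > 0 && 2 * pi * wiggle_amp / wiggle_period >= 1) {
    abort("non-monotone parameterization: need 2*pi*wiggle_amp/wiggle_period < 1")
  }
  theta <- seq(span[2], span[1], by = knot_step)
  mu <- theta + wiggle_amp * sin(2 * pi * theta / wiggle_period)
  if (noise_sd > 0) {
    anchor_x <- seq(span[2], span[1], length.out = max(4, ceiling(length(theta) / 20)))
    anchor_y <- withr::with_seed(seed, rnorm(length(anchor_x), 0, noise_sd))
    mu <- mu + stats::spline(anchor_x, anchor_y, xout = theta)$y
  }
  if (any(diff(mu) <= 0)) {
    abort("generated curve is not strictly monotone; reduce wiggle_amp or noise_sd")
  }
  crv <- cal_curve(theta, mu, rep(sigma, length(theta)), name = "synthetic", kind = "atmospheric")
  attr(crv, "truth") <- list(span = span, wiggle_amp = wiggle_amp,
                             wiggle_period = wiggle_period, sigma = sigma,
                             noise_sd = noise_sd, knot_step = knot_step,
                             seed = seed)
  crv
}

# TRUE where age falls inside any c(old, young) window row
in_windows <- function(age, windows) {
  hit <- rep(FALSE, length(age))
  for (i in seq_len(nrow(windows))) {
    hit <- hit | (age <= windows$old[i] & age >= windows$young[i])
  }
  hit
}

#' Sample a synthetic radiocarbon date archive from an occupation model
#'
#' Calendar ages are drawn from a normalized piecewise-constant intensity
#' (boxcar occupation pulses over a background), each is back-calibrated via
#' [uncalibrate()] with a lab error resampled from `error_pool`, and the true
#' ages are recorded in the `truth` attribute.
#'
#' @param intensity Tibble with columns `old`, `young` (cal BP) and `rate`
#'   (relative deposition rate, `> 0`); windows must lie inside the curve
#'   span.
#' @param n Number of dates, `>= 1`.
#' @param error_pool Numeric vector of lab errors (14C yr) to resample
#'   (typical shell-date archives run ~40-80 14C yr).
#' @param curve A [cal_curve()].
#' @param seed Integer seed.
#' @return A date tibble (columns `lab_id`, `c14_age`, `c14_error`,
#'   `delta_r`, `delta_r_error`, `material`) with a `truth` attribute
#'   holding the sampled true calendar ages and the generator parameters.
#' @export
sample_dates <- function(intensity, n, error_pool, curve, seed = 1L) {
  intensity <- tibble::as_tibble(intensity)
  if (nrow(intensity) == 0) abort("intensity must have at least one window")
  if (!all(c("old", "young", "rate") %in% names(intensity))) {
    abort("intensity needs columns old, young, rate")
  }
  if (any(intensity$rate <= 0)) abort("intensity rates must be > 0")
  if (any(intensity$old <= intensity$young)) abort("windows must have old > young")
  if (n < 1) abort("n must be >= 1")
  rng <- range(curve$cal_bp)
  if (any(intensity$young < rng[1] | intensity$old > rng[2])) {
    abort("intensity windows outside curve span")
  }
  if (length(error_pool) == 0 || any(error_pool <= 0)) {
    abort("error_pool must be a non-empty vector of positive errors")
  }
  w <- intensity$rate * (intensity$old - intensity$young)
  res <- withr::with_seed(seed, {
    win <- sample.int(nrow(intensity), n, replace = TRUE, prob = w)
    age <- runif(n, intensity$young[win], intensity$old[win])
    slab <- sample(error_pool, n, replace = TRUE)
    list(age = age, slab = slab, c14 = uncalibrate(age, curve, slab))
  })
  out <- tibble::tibble(
    lab_id = sprintf("SYN-%04d", seq_len(n)),
    c14_age = res$c14, c14_error = res$slab,
    delta_r = 0, delta_r_error = 0, material = "synthetic shell")
  attr(out, "truth") <- list(true_age = res$age, intensity = intensity,
                             seed = seed)
  out
}

#' Synthetic Gaussian-niche training set
#'
#' Emulates a modern species-environment training set along a salinity-like
#' gradient: sample environmental values are uniform on `gradient`, taxon
#' optima are uniform on the gradient and tolerances uniform on
#' `tolerance_range`, and expected abundance follows the unimodal niche
#' model `y_ik = max_abundance * exp(-(x_i - u_k)^2 / (2 t_k^2))`, with
#' optional Poisson counts. Rows that come out all zero are redrawn.
#'
#' @param n_samples,n_taxa Dimensions (default 150 x 40).
#' @param gradient `c(lo, hi)` environmental range (default 0-30, a
#'   brackish-marine salinity gradient).
#' @param max_abundance Niche-peak expected abundance (default 100).
#' @param tolerance_range `c(lo, hi)` niche tolerances (default 2-5 salinity
#'   units).
#' @param count_model `"poisson"` (counts) or `"none"` (expected values).
#' @param seed Integer seed.
#' @return A list with `abundances` (tibble), `env` (numeric), and `truth`
#'   (optima, tolerances, parameters, seed).
#' @export
make_training_set <- function(n_samples = 150, n_taxa = 40,
                              gradient = c(0, 30), max_abundance = 100,
                              tolerance_range = c(2, 5),
                              count_model = c("poisson", "none"), seed = 1L) {
  count_model <- match.arg(count_model)
  if (n_taxa < 2) abort("n_taxa must be >= 2")
  if (gradient[1] >= gradient[2]) abort("gradient must be c(lo, hi) with lo < hi")
  res <- withr::with_seed(seed, {
    env <- runif(n_samples, gradient[1], gradient[2])
    opt <- runif(n_taxa, gradient[1], gradient[2])
    tol <- runif(n_taxa, tolerance_range[1], tolerance_range[2])
    mu <- max_abundance * exp(-outer(env, opt, "-")^2 / (2 * rep(tol, each = n_samples)^2))
    Y <- if (count_model == "poisson") {
      matrix(rpois(length(mu), mu), n_samples, n_taxa)
    } else mu
    for (i in which(rowSums(Y) == 0)) {
      tries <- 0
      while (sum(Y[i, ]) == 0) {
        if (tries >= 50) {   # hopeless expected row: redraw the sample too
          env[i] <- runif(1, gradient[1], gradient[2])
          mu[i, ] <- max_abundance * exp(-(env[i] - opt)^2 / (2 * tol^2))
          tries <- 0
        }
        Y[i, ] <- if (count_model == "poisson") rpois(n_taxa, mu[i, ]) else mu[i, ]
        tries <- tries + 1
      }
    }
    list(env = env, opt = opt, tol = tol, Y = Y)
  })
  colnames(res$Y) <- sprintf("taxon_%02d", seq_len(n_taxa))
  list(abundances = tibble::as_tibble(res$Y),
       env = res$env,
       truth = list(optima = res$opt, tolerances = res$tol,
                    gradient = gradient, max_abundance = max_abundance,
                    count_model = count_model, seed = seed))
}

#' Sample fossil assemblages from a recorded niche truth
#'
#' Draws new assemblages at given environmental values from the Gaussian
#' niche model recorded in a [make_training_set()] `truth`, so fossil
#' samples with known true salinity can be pushed through a fitted transfer
#' function.
#'
#' @param env Numeric vector of true environmental values.
#' @param truth The `truth` element of a [make_training_set()] result.
#' @param count_model `"poisson"` or `"none"`.
#' @param seed Integer seed.
#' @return A tibble of assemblages (taxa as in the training set).
#' @export
sample_assemblages <- function(env, truth, count_model = c("poisson", "none"),
                               seed = 1L) {
  count_model <- match.arg(count_model)
  mu <- truth$max_abundance *
    exp(-outer(env, truth$optima, "-")^2 / (2 * rep(truth$tolerances, each = length(env))^2))
  Y <- if (count_model == "poisson") {
    withr::with_seed(seed, matrix(rpois(length(mu), mu), nrow(mu), ncol(mu)))
  } else mu
  colnames(Y) <- sprintf("taxon_%02d", seq_along(truth$optima))
  tibble::as_tibble(Y)
}

#' Synthetic sediment core with boxcar production pulses
#'
#' Generates a constant-sedimentation core over an age window with a proxy
#' whose true flux is `base_flux` outside and `base_flux * pulse_multiplier`
#' inside the pulse windows, perturbed by multiplicative lognormal noise
#' (mean 1). Concentrations are flux divided by the sediment accumulation
#' rate; control points are exact, so [compute_flux()] against the implied
#' age-depth model recovers the noisy flux exactly and, with `noise_sd = 0`,
#' the boxcar itself.
#'
#' @param pulses Tibble with columns `old`, `young`: pulse windows in cal BP
#'   (default the two production pulses at 7600-7100 and 6400-5900).
#' @param base_flux Background flux (proxy units per cm^2 per yr).
#' @param pulse_multiplier Flux multiplier inside pulses (default 3).
#' @param sar Sediment accumulation rate (cm/yr, default 0.05).
#' @param noise_sd Lognormal sdlog of the multiplicative noise (default 0.3).
#' @param window `c(old, young)` cored age span (default `c(8000, 4000)`).
#' @param step_yr Sampling resolution in years (default 20).
#' @param proxy Proxy column name (default `"pigment_flux_proxy"`).
#' @param site Site label.
#' @param seed Integer seed.
#' @return A list with `core` (tibble `depth_cm` + proxy column, `site`
#'   attribute), `control` (tibble of exact control points), and `truth`
#'   (true flux series and parameters).
#' @export
make_core <- function(pulses = tibble::tibble(old = c(7600, 6400),
                                              young = c(7100, 5900)),
                      base_flux = 100, pulse_multiplier = 3, sar = 0.05,
                      noise_sd = 0.3, window = c(8000, 4000), step_yr = 20,
                      proxy = "pigment_flux_proxy", site = "synthetic_site",
                      seed = 1L) {
  check_window(window)
  if (sar <= 0) abort("sar must be > 0")
  age <- seq(window[2], window[1], by = step_yr)
  depth <- (age - window[2]) * sar
  flux_true <- base_flux * ifelse(in_windows(age, tibble::as_tibble(pulses)),
                                  pulse_multiplier, 1)
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, exp(rnorm(length(age), -noise_sd^2 / 2, noise_sd)))
  } else rep(1, length(age))
  conc <- flux_true * noise / sar
  core <- tibble::tibble(depth_cm = depth, !!proxy := conc)
  attr(core, "site") <- site
  mid <- ceiling(length(age) / 2)
  control <- tibble::tibble(depth_cm = depth[c(1, mid, length(age))],
                            cal_bp = age[c(1, mid, length(age))],
                            sigma = 0)
  list(core = core, control = control,
       truth = list(age = age, flux_true = flux_true, flux_noisy = flux_true * noise,
                    pulses = tibble::as_tibble(pulses), sar = sar,
                    base_flux = base_flux, pulse_multiplier = pulse_multiplier,
                    noise_sd = noise_sd, seed = seed, site = site))
}

#' Synthetic isotope samples from a two-endmember diet model
#'
#' For each period, delta values are generated as
#' `terrestrial + f * (marine - terrestrial) + N(0, noise_sd)` per isotope
#' configured in `config`, with the period's midpoint age attached.
#' `period_fractions` maps each period label to its marine fraction: either
#' a single number applied to every isotope, or a named vector giving a
#' fraction per isotope (real compilations imply different effective
#' fractions per tracer).
#'
#' @param period_fractions Named list/vector: period label -> marine
#'   fraction(s) in `[0, 1]`.
#' @param n_per_period Samples per period: single number or named vector.
#' @param config A [mixing_config()].
#' @param noise_sd Gaussian noise sd (per mil): single number or named per
#'   isotope (default 0.5).
#' @param table A [period_table()].
#' @param taxon Taxon label for the generated samples.
#' @param seed Integer seed.
#' @return A list with `samples` (tibble `id, taxon, period, age_calbp` +
#'   isotope columns) and `truth` (the configured fractions and parameters).
#' @export
make_isotope_samples <- function(period_fractions, n_per_period,
                                 config = mixing_config(), noise_sd = 0.5,
                                 table = default_period_table(),
                                 taxon = "human", seed = 1L) {
  labels <- names(period_fractions)
  if (is.null(labels)) abort("period_fractions must be named by period label")
  if (!all(labels %in% table$label)) {
    abort("period_fractions labels must appear in the period table")
  }
  fr_of <- function(lab, iso) {
    f <- period_fractions[[lab]]
    f <- if (length(f) > 1 || !is.null(names(f))) f[[iso]] else f
    if (is.na(f) || f < 0 || f > 1) abort("marine fractions must be in [0, 1]")
    f
  }
  n_of <- function(lab) {
    if (length(n_per_period) == 1 && is.null(names(n_per_period))) {
      n_per_period
    } else n_per_period[[lab]]
  }
  sd_of <- function(iso) {
    if (length(noise_sd) == 1 && is.null(names(noise_sd))) noise_sd else noise_sd[[iso]]
  }
  samples <- withr::with_seed(seed, {
    purrr::map_dfr(labels, function(lab) {
      n <- n_of(lab)
      row <- table[table$label == lab, ]
      out <- tibble::tibble(
        id = sprintf("%s-%03d", gsub("\\s+", "_", lab), seq_len(n)),
        taxon = taxon, period = lab,
        age_calbp = (row$old_bp + row$young_bp) / 2)
      for (iso in names(config)) {
        em <- config[[iso]]
        f <- fr_of(lab, iso)
        mu <- em[["terrestrial"]] + f * (em[["marine"]] - em[["terrestrial"]])
        out[[iso]] <- mu + rnorm(n, 0, sd_of(iso))
      }
      out
    })
  })
  list(samples = samples,
       truth = list(period_fractions = period_fractions,
                    n_per_period = n_per_period, config = config,
                    noise_sd = noise_sd, seed = seed))
}

#' Synthetic human collagen isotope compilation (study-scale stand-in)
#'
#' A synthetic stand-in for a Mesolithic-Neolithic human collagen
#' compilation, generated at the documented group sizes (Kongemose n = 14,
#' Ertebolle n = 12, earlier Neolithic n = 42, later Neolithic n = 18; d2H
#' measured on a subset of 4 Mesolithic and 8 Neolithic individuals) around
#' the canonical period signatures: d13C -13 (Mesolithic) / -20 per mil
#' (Neolithic), d15N 13 / 9.5 per mil, d2H +66 / -5 per mil. Within-period
#' spread is 0.8 per mil for d13C and d15N and 8 per mil for d2H. All values
#' are simulated; the table carries an `epoch` column with the
#' Mesolithic/Neolithic grouping.
#'
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `taxon`, `period`, `epoch`,
#'   `age_calbp`, `d13c`, `d15n`, `d2h` and a `truth` attribute.
#' @export
make_isotope_compilation <- function(seed = 1L) {
  table <- default_period_table()
  sizes <- c("Kongemose" = 14, "Ertebolle" = 12,
             "earlier Neolithic" = 42, "later Neolithic" = 18)
  sig <- list(Mesolithic = c(d13c = -13, d15n = 13, d2h = 66),
              Neolithic = c(d13c = -20, d15n = 9.5, d2h = -5))
  spread <- c(d13c = 0.8, d15n = 0.8, d2h = 8)
  d2h_n <- c("Kongemose" = 2, "Ertebolle" = 2,
             "earlier Neolithic" = 5, "later Neolithic" = 3)
  out <- withr::with_seed(seed, {
    purrr::map_dfr(names(sizes), function(lab) {
      n <- sizes[[lab]]
      ep <- period_epoch(lab)
      row <- table[table$label == lab, ]
      tb <- tibble::tibble(
        id = sprintf("%s-%03d", gsub("\\s+", "_", lab), seq_len(n)),
        taxon = "human", period = lab, epoch = ep,
        age_calbp = (row$old_bp + row$young_bp) / 2,
        d13c = rnorm(n, sig[[ep]][["d13c"]], spread[["d13c"]]),
        d15n = rnorm(n, sig[[ep]][["d15n"]], spread[["d15n"]]),
        d2h = NA_real_)
      tb$d2h[seq_len(d2h_n[[lab]])] <- rnorm(d2h_n[[lab]],
                                             sig[[ep]][["d2h"]],
                                             spread[["d2h"]])
      tb
    })
  })
  attr(out, "truth") <- list(sizes = sizes, signatures = sig, spread = spread,
                             d2h_n = d2h_n, seed = seed, synthetic = TRUE)
  out
}
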