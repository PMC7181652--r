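two_pt <- function() {
  age_depth_model(data.frame(depth_cm = c(0, 100), cal_bp = c(4000, 8000)))
}

test_that("piecewise-linear age model: midpoint age and constant SAR", {
  adm <- two_pt()
  expect_equal(age_at_depth(adm, 50), 6000)
  expect_equal(sar_at_depth(adm, c(0, 50, 100)), rep(100 / 4000, 3))
})

test_that("age reversals and extrapolation are refused", {
  expect_error(age_depth_model(data.frame(depth_cm = c(0, 50, 100),
                                          cal_bp = c(4000, 7000, 6500))),
               "reversal")
  adm <- two_pt()
  expect_error(age_at_depth(adm, 101), "extrapolation")
  expect_error(sar_at_depth(adm, -1), "extrapolation")
  expect_error(age_depth_model(data.frame(depth_cm = 0, cal_bp = 4000)), ">= 2")
})

test_that("interpolation matches the segment-wise formula at random depths", {
  pts <- data.frame(depth_cm = c(0, 40, 100), cal_bp = c(4000, 5000, 8000))
  adm <- age_depth_model(pts)
  withr::with_seed(12, {
    d <- runif(50, 0, 100)
    seg <- pmax(1, findInterval(d, pts$depth_cm, left.open = TRUE))
    w <- (d - pts$depth_cm[seg]) / (pts$depth_cm[seg + 1] - pts$depth_cm[seg])
    oracle_age <- (1 - w) * pts$cal_bp[seg] + w * pts$cal_bp[seg + 1]
    expect_equal(age_at_depth(adm, d), oracle_age, tolerance = 1e-10)
    oracle_sar <- (diff(pts$depth_cm) / diff(pts$cal_bp))[seg]
    expect_equal(sar_at_depth(adm, d), oracle_sar, tolerance = 1e-12)
  })
  # at an interior knot the younger (shallower) segment's slope applies
  expect_equal(sar_at_depth(adm, 40), 40 / 1000)
})

test_that("age models are bit-identical for identical inputs", {
  pts <- data.frame(depth_cm = c(0, 40, 100), cal_bp = c(4000, 5000, 8000))
  expect_identical(age_depth_model(pts), age_depth_model(pts))
})

test_that("flux is concentration times SAR, with linear scaling", {
  core <- tibble::tibble(depth_cm = c(25, 50), shells = c(200, 0))
  adm <- age_depth_model(data.frame(depth_cm = c(0, 100), cal_bp = c(4000, 6000)))
  fl <- compute_flux(core, adm, "shells")
  expect_equal(fl$flux, c(200 * 0.05, 0))
  doubled <- compute_flux(dplyr::mutate(core, shells = shells * 2), adm, "shells")
  expect_equal(doubled$flux, 2 * fl$flux)
  # doubling SAR (same depths, half the age span) doubles flux
  adm2 <- age_depth_model(data.frame(depth_cm = c(0, 100), cal_bp = c(4000, 5000)))
  expect_equal(compute_flux(core, adm2, "shells")$flux, 2 * fl$flux)
  expect_error(compute_flux(core, adm, "pigment"), "not present")
  expect_error(compute_flux(tibble::tibble(depth_cm = 500, shells = 1), adm, "shells"),
               "outside")
})

test_that("a noiseless synthetic core round-trips through compute_flux exactly", {
  sim <- make_core(noise_sd = 0, seed = 3)
  fl <- compute_flux(sim$core, age_depth_model(sim$control), "pigment_flux_proxy")
  expect_equal(fl$flux, sim$truth$flux_true, tolerance = 1e-9)
  expect_equal(fl$cal_bp, sim$truth$age, tolerance = 1e-9)
  flat <- make_core(pulse_multiplier = 1, noise_sd = 0, seed = 3)
  fl2 <- compute_flux(flat$core, age_depth_model(flat$control), "pigment_flux_proxy")
  expect_equal(diff(range(fl2$flux)), 0)
})

fake_flux <- function(cal_bp, flux, site = "X") {
  structure(tibble::tibble(depth_cm = seq_along(cal_bp), cal_bp = cal_bp,
                           concentration = NA_real_, sar = NA_real_, flux = flux),
            class = c("flux_series", "tbl_df", "tbl", "data.frame"),
            site = site, proxy = "test")
}

test_that("single-site composite standardizes and smooths noise toward zero", {
  withr::with_seed(41, {
    ages <- seq(4000, 8000, length.out = 200)
    fl <- fake_flux(ages, 100 + rnorm(200, 0, 5))
    cs <- composite_zscores(fl, window = c(8000, 4000), span = 0.3)
    expect_equal(mean(cs$points$z), 0, tolerance = 1e-9)
    expect_equal(sd(cs$points$z), 1, tolerance = 1e-9)
    expect_lt(abs(mean(cs$smooth$value, na.rm = TRUE)), 0.05)
  })
})

test_that("z-standardization is idempotent", {
  withr::with_seed(4, {
    ages <- seq(4000, 8000, length.out = 100)
    fl <- fake_flux(ages, rlnorm(100, 4, 0.4))
    cs1 <- composite_zscores(fl, span = 0.2)
    fl2 <- fake_flux(ages, cs1$points$z)
    cs2 <- composite_zscores(fl2, span = 0.2)
    expect_equal(cs2$points$z, cs1$points$z, tolerance = 1e-12)
  })
})

test_that("two sites that are exact negatives after standardization cancel", {
  withr::with_seed(15, {
    ages <- seq(4000, 8000, length.out = 150)
    x <- 50 + 10 * sin(ages / 300) + rnorm(150, 0, 2)
    a <- fake_flux(ages, x, site = "A")
    b <- fake_flux(ages, 200 - x, site = "B")   # affine negative
    cs <- composite_zscores(list(a, b))
    expect_true(all(abs(cs$smooth$value) < 0.05, na.rm = TRUE))
  })
})

test_that("zero-variance and too-short series are refused by site name", {
  ages <- seq(4000, 8000, length.out = 50)
  expect_error(composite_zscores(fake_flux(ages, rep(3, 50), site = "KIL")),
               "KIL")
  expect_error(composite_zscores(fake_flux(c(5000, 6000), c(1, 2), site = "HF")),
               "HF")
})

test_that("increasing the lowess span never adds variance to the smooth", {
  sims <- lapply(1:3, function(i) make_core(noise_sd = 0.5, seed = 50 + i,
                                            site = paste0("s", i)))
  fluxes <- lapply(sims, function(s)
    compute_flux(s$core, age_depth_model(s$control), "pigment_flux_proxy"))
  vars <- vapply(c(0.1, 0.3, 0.6), function(sp) {
    stats::var(composite_zscores(fluxes, span = sp)$smooth$value, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(vars) <= 1e-12))
})

test_that("three pulsed sites yield smooth maxima inside both pulse windows", {
  sims <- lapply(1:3, function(i) make_core(noise_sd = 0.5, seed = 60 + i,
                                            site = paste0("s", i)))
  fluxes <- lapply(sims, function(s)
    compute_flux(s$core, age_depth_model(s$control), "pigment_flux_proxy"))
  cs <- composite_zscores(fluxes)
  phases <- detect_production_phases(cs)
  expect_gte(nrow(phases), 2)
  expect_true(any(overlaps(phases$cal_bp_old, phases$cal_bp_young, 7600, 7100)))
  expect_true(any(overlaps(phases$cal_bp_old, phases$cal_bp_young, 6400, 5900)))
})

fake_composite <- function(grid, value, span = 0.1, window = c(8000, 4000)) {
  structure(list(points = tibble::tibble(site = "X", cal_bp = grid, z = value),
                 smooth = tibble::tibble(cal_bp = grid, value = value),
                 span = span, window = window),
            class = "composite_series")
}

test_that("phase detection: flat smooth is empty, a constructed pulse is exact", {
  grid <- seq(4000, 8000, by = 10)
  expect_equal(nrow(detect_production_phases(fake_composite(grid, rep(0, length(grid))))), 0)
  v <- ifelse(grid >= 5900 & grid <= 6400, 0.9, 0)
  ph <- detect_production_phases(fake_composite(grid, v))
  expect_equal(nrow(ph), 1)
  expect_equal(ph$cal_bp_old, 6400)
  expect_equal(ph$cal_bp_young, 5900)
  # shorter than min_duration -> discarded
  v2 <- ifelse(grid >= 6000 & grid <= 6050, 0.9, 0)
  expect_equal(nrow(detect_production_phases(fake_composite(grid, v2))), 0)
})
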