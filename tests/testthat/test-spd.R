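make_dates <- function(c14, err, lab = sprintf("D%02d", seq_along(c14))) {
  tibble::tibble(lab_id = lab, c14_age = c14, c14_error = err,
                 delta_r = 0, delta_r_error = 0)
}

test_that("the SPD of one date is that date's calibrated density", {
  crv <- identity_curve(sigma = 10)
  spd <- sum_spd(make_dates(5000, 40), crv)
  d <- calibrate(5000, 40, crv, trim_mass = 0)
  expect_equal(sum(spd$density), 1, tolerance = 1e-9)
  expect_equal(spd$density[match(d$cal_bp, spd$cal_bp)], d$mass, tolerance = 1e-12)
})

test_that("SPD is additive: a duplicated date doubles the density", {
  crv <- identity_curve(sigma = 10)
  one <- sum_spd(make_dates(5000, 40), crv)
  two <- sum_spd(make_dates(c(5000, 5000), c(40, 40)), crv)
  expect_equal(two$density, 2 * one$density, tolerance = 1e-12)
  expect_equal(sum(two$density), 2, tolerance = 1e-9)
  norm <- sum_spd(make_dates(c(5000, 5000), c(40, 40)), crv, normalize_total = TRUE)
  expect_equal(norm$density, one$density, tolerance = 1e-12)
})

test_that("the matrix SPD path equals a per-date calibration loop", {
  crv <- make_calcurve(span = c(10000, 2000), wiggle_amp = 30, wiggle_period = 500,
                       sigma = 15, seed = 4)
  dates <- withr::with_seed(8, make_dates(runif(50, 4000, 8000), runif(50, 40, 80)))
  spd <- sum_spd(dates, crv)
  loop <- Reduce(`+`, lapply(seq_len(nrow(dates)), function(i) {
    calibrate(dates$c14_age[i], dates$c14_error[i], crv, trim_mass = 0)$mass
  }))
  expect_equal(spd$density, loop, tolerance = 1e-12)
  expect_equal(sum(spd$density), nrow(dates), tolerance = 1e-6)
})

test_that("calibration failures propagate the lab id", {
  crv <- cal_curve(c(4000, 6000), c(4000, 6000), c(10, 10))
  expect_error(sum_spd(make_dates(c(5000, 90000), c(40, 40)), crv), "D02")
})

test_that("the uniform null has flat mean density n_dates per window year", {
  crv <- identity_curve(sigma = 1e-6)
  env <- simulate_null(50, error_pool = 1, window = c(8100, 3500), curve = crv,
                       n_sims = 200, seed = 10)
  interior <- env$cal_bp > 3800 & env$cal_bp < 7800
  expect_equal(nrow(env), 4601)
  # analytic limit: 50/4600 per year; per-sim interior means are averages of
  # ~binomial date counts, giving the Monte-Carlo SE of the grand mean
  m <- mean(env$mean[interior])
  expected <- 50 / 4600
  p <- 4001 / 4600
  mc_se <- sqrt(50 * p * (1 - p)) / 4001 / sqrt(200)
  expect_lt(abs(m - expected), 3 * mc_se)
})

test_that("the null mean surface is flat with a realistic error pool", {
  crv <- identity_curve(sigma = 15)
  env <- simulate_null(50, error_pool = seq(40, 80, by = 5),
                       window = c(8100, 3500), curve = crv,
                       n_sims = 500, seed = 11)
  interior <- env$cal_bp > 3800 & env$cal_bp < 7800
  expect_lt(sd(env$mean[interior]) / mean(env$mean[interior]), 0.05)
})

test_that("the null envelope is reproducible from its seed", {
  crv <- identity_curve(sigma = 15)
  a <- simulate_null(20, c(40, 60, 80), c(8100, 3500), crv, n_sims = 20, seed = 5)
  b <- simulate_null(20, c(40, 60, 80), c(8100, 3500), crv, n_sims = 20, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_null(20, c(40, 60, 80), c(8100, 3500), crv, n_sims = 20, seed = 6)
  expect_false(identical(a$mean, c2$mean))
})

test_that("widening band_mass never shrinks the envelope", {
  crv <- identity_curve(sigma = 15)
  narrow <- simulate_null(20, c(40, 60), c(8100, 3500), crv, n_sims = 50,
                          band_mass = 0.80, seed = 5)
  wide <- simulate_null(20, c(40, 60), c(8100, 3500), crv, n_sims = 50,
                        band_mass = 0.95, seed = 5)
  expect_true(all(wide$lower <= narrow$lower + 1e-12))
  expect_true(all(wide$upper >= narrow$upper - 1e-12))
  expect_true(all(narrow$lower <= narrow$mean & narrow$mean <= narrow$upper))
})

test_that("the null window must lie inside the curve span", {
  crv <- cal_curve(c(4000, 6000), c(4000, 6000), c(10, 10))
  expect_error(simulate_null(10, 40, c(8100, 3500), crv, n_sims = 5, seed = 1),
               "span")
})

fake_env <- function(grid, lower, upper, window = c(max(grid), min(grid))) {
  structure(tibble::tibble(cal_bp = grid, mean = (lower + upper) / 2,
                           lower = lower, upper = upper),
            class = c("spd_null", "tbl_df", "tbl", "data.frame"),
            window = window)
}

fake_spd <- function(grid, density) {
  structure(tibble::tibble(cal_bp = grid, density = density),
            class = c("spd", "tbl_df", "tbl", "data.frame"), grid_step = 1)
}

test_that("deviation scan: null case, constructed exceedance, edge flag", {
  grid <- 3500:8100
  env <- fake_env(grid, rep(0.2, length(grid)), rep(0.8, length(grid)),
                  window = c(8100, 3500))
  inside <- fake_spd(grid, rep(0.5, length(grid)))
  expect_equal(nrow(spd_deviations(inside, env)), 0)

  dens <- rep(0.5, length(grid))
  dens[grid >= 6500 & grid <= 7000] <- 0.81
  dev <- spd_deviations(fake_spd(grid, dens), env)
  expect_equal(nrow(dev), 1)
  expect_equal(dev$cal_bp_old, 7000)
  expect_equal(dev$cal_bp_young, 6500)
  expect_equal(dev$sign, "+")
  expect_false(dev$edge)

  dens2 <- rep(0.5, length(grid))
  dens2[grid <= 3650] <- 0.1    # touches the young edge
  dev2 <- spd_deviations(fake_spd(grid, dens2), env)
  expect_equal(dev2$sign, "-")
  expect_true(dev2$edge)

  expect_error(spd_deviations(fake_spd(3500:8000, dens[1:4501]), env), "grid mismatch")
})

test_that("deviation intervals match a brute-force run-length scan", {
  grid <- 5000:6000
  withr::with_seed(21, {
    dens <- runif(length(grid), 0, 1)
    env <- fake_env(grid, rep(0.25, length(grid)), rep(0.75, length(grid)))
    dev <- spd_deviations(fake_spd(grid, dens), env, min_duration = 5)
    # oracle: explicit state walk
    state <- ifelse(dens > 0.75, 1L, ifelse(dens < 0.25, -1L, 0L))
    runs <- list(); cur <- state[1]; start <- 1
    for (i in 2:length(state)) {
      if (state[i] != cur) {
        if (cur != 0L) runs[[length(runs) + 1]] <- c(start, i - 1, cur)
        cur <- state[i]; start <- i
      }
    }
    if (cur != 0L) runs[[length(runs) + 1]] <- c(start, length(state), cur)
    keep <- Filter(function(r) grid[r[2]] - grid[r[1]] >= 5, runs)
    expect_equal(nrow(dev), length(keep))
    oracle_old <- sort(vapply(keep, function(r) grid[r[2]], numeric(1)),
                       decreasing = TRUE)
    expect_equal(dev$cal_bp_old, oracle_old)
  })
})
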