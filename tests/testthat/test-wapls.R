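test_that("a one-taxon-per-sample training set is learned exactly by component 1", {
  Y <- diag(5) * 10
  colnames(Y) <- paste0("t", 1:5)
  env <- c(3, 8, 15, 22, 29)
  fit <- wapls(Y, env, n_components = 1)
  expect_lt(fit$apparent$rmse[1], 1e-10)
  expect_equal(as.vector(fit$fitted[, 1]), env, tolerance = 1e-10)
})

test_that("component 1 equals classical WA with (weighted) inverse deshrinking", {
  ts <- make_training_set(n_samples = 80, n_taxa = 25, seed = 13)
  fit <- wapls(ts$abundances, ts$env, n_components = 2)
  # independent oracle: direct WA formulas + lm() deshrinking
  Y <- as.matrix(ts$abundances)
  u <- colSums(Y * ts$env) / colSums(Y)          # taxon optima (WA)
  init <- as.vector(Y %*% u) / rowSums(Y)        # initial WA estimates
  desh <- stats::lm(ts$env ~ init, weights = rowSums(Y) / sum(Y))
  expect_equal(as.vector(fit$fitted[, 1]), unname(stats::fitted(desh)),
               tolerance = 1e-8)
})

test_that("WA-PLS uses relative composition: global rescaling changes nothing", {
  ts <- make_training_set(n_samples = 60, n_taxa = 20, seed = 5)
  f1 <- wapls(ts$abundances, ts$env, n_components = 2)
  f2 <- wapls(as.matrix(ts$abundances) * 7.3, ts$env, n_components = 2)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-10)
  expect_equal(f1$apparent, f2$apparent, tolerance = 1e-10)
  expect_equal(predict(f2, ts$abundances[1:5, ]), predict(f1, ts$abundances[1:5, ]),
               tolerance = 1e-10)
})

test_that("apparent RMSE never increases with component count", {
  for (s in 1:5) {
    ts <- make_training_set(n_samples = 60, n_taxa = 20, seed = s)
    fit <- wapls(ts$abundances, ts$env, n_components = 4)
    expect_true(all(diff(fit$apparent$rmse) <= 1e-12))
  }
})

test_that("in-sample prediction from stored coefficients reproduces fitted values", {
  ts <- make_training_set(n_samples = 70, n_taxa = 22, seed = 9)
  fit <- wapls(ts$abundances, ts$env, n_components = 3)
  for (k in 1:3) {
    expect_equal(predict(fit, ts$abundances, k = k), as.vector(fit$fitted[, k]),
                 tolerance = 1e-10)
  }
})

test_that("fossil columns are aligned by name; unknown taxa warn and drop", {
  ts <- make_training_set(n_samples = 70, n_taxa = 22, seed = 9)
  fit <- wapls(ts$abundances, ts$env, n_components = 2)
  fossil <- ts$abundances[1:10, ]
  shuffled <- fossil[, sample(ncol(fossil))]
  expect_equal(predict(fit, shuffled), predict(fit, fossil))
  extra <- dplyr::mutate(fossil, mystery_taxon = 5)
  expect_warning(p <- predict(fit, extra), "mystery_taxon")
  alien <- tibble::tibble(unknown_a = c(1, 0), unknown_b = c(0, 2))
  expect_error(suppressWarnings(predict(fit, alien)), "overlap")
})

test_that("degenerate components raise a rank error naming the component", {
  Y <- matrix(1, 10, 4, dimnames = list(NULL, paste0("t", 1:4)))
  expect_error(wapls(Y, 1:10, n_components = 1), "component 1")
})

test_that("bootstrap validation is seeded, optimistic-corrected and learnable", {
  # perfectly learnable: one taxon per distinct sample, duplicated 10x
  Y <- diag(5)[rep(1:5, each = 10), ] * 20
  colnames(Y) <- paste0("t", 1:5)
  env <- rep(c(4, 9, 14, 19, 24), each = 10)
  fit <- wapls(Y, env, n_components = 1)
  cv <- wapls_boot(fit, n_boot = 50, seed = 2)
  expect_lt(cv$rmsep_boot[1], 1e-6)

  ts <- make_training_set(n_samples = 60, n_taxa = 20, seed = 31)
  fit2 <- wapls(ts$abundances, ts$env, n_components = 2)
  cv_a <- wapls_boot(fit2, n_boot = 40, seed = 7)
  cv_b <- wapls_boot(fit2, n_boot = 40, seed = 7)
  expect_identical(as.data.frame(cv_a), as.data.frame(cv_b))
})

test_that("bootstrap RMSEP is never better than the apparent RMSE", {
  for (s in 1:20) {
    ts <- make_training_set(n_samples = 50, n_taxa = 15, seed = 100 + s)
    fit <- wapls(ts$abundances, ts$env, n_components = 2)
    cv <- wapls_boot(fit, n_boot = 40, seed = s)
    expect_true(all(cv$rmsep_boot >= fit$apparent$rmse - 1e-12))
  }
})

test_that("recovered taxon optima track the generating niche optima", {
  ts <- make_training_set(seed = 17)
  fit <- wapls(ts$abundances, ts$env, n_components = 2)
  opt <- taxon_optima(fit)
  expect_gte(cor(opt$optimum, ts$truth$optima), 0.95)
})

test_that("tidy and glance summarize the fit broom-style", {
  ts <- make_training_set(n_samples = 40, n_taxa = 12, seed = 3)
  fit <- wapls(ts$abundances, ts$env, n_components = 2, transform = "sqrt")
  td <- tidy(fit)
  expect_equal(nrow(td), 12 * 2)
  expect_named(td, c("taxon", "component", "score", "beta"))
  gl <- glance(fit)
  expect_equal(gl$n_components, 2)
  expect_equal(gl$transform, "sqrt")
  expect_equal(gl$r2, fit$apparent$r2[2])
})

test_that("reconstruction back-transforms, propagates error and subtracts modern", {
  ts <- make_training_set(seed = 17)
  fit <- wapls(ts$abundances, ts$env, n_components = 2, transform = "sqrt")
  cv <- wapls_boot(fit, n_boot = 30, seed = 4)
  fossil <- ts$abundances[1:8, ]
  rec <- reconstruct_salinity(fit, cv, fossil, modern_reference = 12)
  est_t <- predict(fit, fossil)
  expect_equal(rec$estimate_t, est_t)
  expect_equal(rec$estimate, est_t^2)
  expect_equal(rec$se, 2 * abs(est_t) * cv$rmsep_boot[2])
  expect_equal(rec$deviation, est_t^2 - 12)
  expect_error(reconstruct_salinity(fit, cv, fossil, modern_reference = NULL),
               "modern_reference")
})

test_that("fossils drawn at a known salinity reconstruct the expected deviation", {
  ts <- make_training_set(seed = 23)
  fit <- wapls(ts$abundances, ts$env, n_components = 2, transform = "sqrt")
  cv <- wapls_boot(fit, n_boot = 50, seed = 6)
  fossil <- sample_assemblages(rep(20, 30), ts$truth, seed = 8)
  rec <- reconstruct_salinity(fit, cv, fossil, modern_reference = 15)
  # truth: salinity 20, modern 15 -> deviation +5; the model error is common
  # to every fossil sample, so the reconstruction SE does not shrink with n
  expect_lt(abs(mean(rec$deviation) - 5), 2 * mean(rec$se))
})

test_that("training-set and fossil CSV dialects round-trip", {
  ts <- make_training_set(n_samples = 10, n_taxa = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                                        salinity = ts$env), ts$abundances)
  readr::write_csv(df, f)
  back <- read_training_set(f)
  expect_equal(back$env, ts$env)
  expect_equal(as.data.frame(back$abundances), as.data.frame(ts$abundances))
})
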