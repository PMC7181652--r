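#' Fit a weighted-averaging partial least squares (WA-PLS) transfer function
#'
#' WA-PLS predicts an environmental variable (here typically salinity) from
#' species assemblage counts. Components are built iteratively: the residual
#' target starts as the (optionally transformed) environmental variable;
#' taxon scores are abundance-weighted averages of the target over samples;
#' sample scores are abundance-weighted averages of the taxon scores,
#' orthogonalized against earlier components and standardized with sample
#' weights proportional to assemblage row totals; the environmental variable
#' is then regressed on the components by weighted least squares (the
#' inverse-deshrinking step), and the residuals become the next target.
#' The whole score chain is folded back into taxon-level coefficients, so a
#' fitted model predicts from relative abundances alone.
#'
#' @param abundances Matrix or data frame (samples x taxa) of non-negative
#'   abundances; every row and column must have a positive sum. Column names
#'   are taxon names.
#' @param env Numeric vector, one environmental value per sample, on the
#'   untransformed scale.
#' @param n_components Number of components to extract (default 2, the model
#'   class used for diatom-inferred salinity).
#' @param transform `"none"` or `"sqrt"`: transformation applied to `env`
#'   before fitting. With `"sqrt"`, predictions and cross-validation errors
#'   are in square-root units and [reconstruct_salinity()] back-transforms by
#'   squaring.
#'
#' @return An object of class `wapls`: a list with elements
#'   `taxon_coefficients` (taxa x components matrix of folded score
#'   coefficients), `coefficients` (per component count, intercept + component
#'   weights), `fitted` (samples x components apparent predictions,
#'   transformed scale), `apparent` (tibble: component, rmse, r2; rmse
#'   weighted by relative row totals), plus the training data needed for
#'   cross-validation.
#' @seealso [predict.wapls()], [wapls_boot()], [reconstruct_salinity()]
#' @export
wapls <- function(abundances, env, n_components = 2,
                  transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  Y <- as.matrix(abundances)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("taxon_", seq_len(ncol(Y)))
  storage.mode(Y) <- "double"
  n <- nrow(Y); m <- ncol(Y)
  if (length(env) != n) abort("length(env) must equal nrow(abundances)")
  if (any(Y < 0) || anyNA(Y)) abort("abundances must be non-negative and complete")
  if (any(rowSums(Y) <= 0)) abort("every sample (row) must have a positive total")
  if (any(colSums(Y) <= 0)) abort("every taxon (column) must have a positive total")
  if (n_components < 1 || n_components > min(n, m)) {
    abort("n_components must be between 1 and min(n_samples, n_taxa)")
  }
  xt <- if (transform == "sqrt") {
    if (any(env < 0)) abort("sqrt transform needs non-negative env values")
    sqrt(env)
  } else as.numeric(env)

  W <- Y / sum(Y)
  r <- rowSums(W)                 # sample weights (relative row totals)
  cs <- colSums(W)
  Wrow <- W / r                   # rows sum to 1
  K <- n_components
  Tm <- matrix(0, n, K)
  U <- matrix(0, m, K, dimnames = list(colnames(Y), NULL))   # raw WA scores
  B <- matrix(0, m, K, dimnames = list(colnames(Y), NULL))   # folded coefs
  fitted <- matrix(0, n, K)
  coefs <- vector("list", K)
  e <- xt - sum(r * xt)
  for (a in seq_len(K)) {
    u <- as.vector(crossprod(W, e)) / cs
    U[, a] <- u
    t_a <- as.vector(Wrow %*% u)
    v <- u
    if (a > 1) {
      for (b in seq_len(a - 1)) {
        al <- sum(r * t_a * Tm[, b])
        t_a <- t_a - al * Tm[, b]
        v <- v - al * B[, b]
      }
    }
    sn <- sqrt(sum(r * t_a^2))
    if (!is.finite(sn) || sn < 1e-12) {
      abort(sprintf("degenerate WA-PLS component %d: sample scores have zero variance", a))
    }
    Tm[, a] <- t_a / sn
    B[, a] <- v / sn
    fit <- lm.wfit(cbind(`(Intercept)` = 1, Tm[, seq_len(a), drop = FALSE]),
                   xt, r)
    fitted[, a] <- xt - fit$residuals
    coefs[[a]] <- fit$coefficients
    e <- fit$residuals
  }
  apparent <- tibble::tibble(
    component = seq_len(K),
    rmse = vapply(seq_len(K), function(a) sqrt(sum(r * (xt - fitted[, a])^2)),
                  numeric(1)),
    r2 = vapply(seq_len(K), function(a) cor(fitted[, a], xt)^2, numeric(1))
  )
  structure(list(
    taxon_coefficients = B, taxon_scores = U, coefficients = coefs,
    sample_scores = Tm, fitted = fitted, apparent = apparent,
    taxon_names = colnames(Y), n_components = K, transform = transform,
    abundances = Y, env = as.numeric(env), env_t = xt, weights = r
  ), class = "wapls")
}

#' @export
print.wapls <- function(x, ...) {
  cat(sprintf("WA-PLS transfer function: %d samples, %d taxa, %d component(s)\n",
              nrow(x$abundances), length(x$taxon_names), x$n_components))
  cat(sprintf("env transform: %s\n", x$transform))
  print(x$apparent)
  invisible(x)
}

# score matrix (n x K) for row-normalized new data, replaying the folded chain
wapls_scores <- function(object, Wrow) {
  Wrow %*% object$taxon_coefficients
}

align_fossil <- function(object, newdata, quiet = FALSE) {
  df <- as.data.frame(newdata)
  reserved <- intersect(c("sample_id", "depth", "depth_cm", "age", "cal_bp"),
                        names(df))
  ids <- if ("sample_id" %in% names(df)) as.character(df$sample_id) else NULL
  df <- df[setdiff(names(df), reserved)]
  unknown <- setdiff(names(df), object$taxon_names)
  if (length(unknown) && !quiet) {
    warn(sprintf("dropping %d fossil taxa absent from training: %s",
                 length(unknown), paste(head(unknown, 5), collapse = ", ")))
  }
  shared <- intersect(object$taxon_names, names(df))
  if (length(shared) == 0) abort("no fossil taxa overlap the training set")
  Y0 <- matrix(0, nrow(df), length(object$taxon_names),
               dimnames = list(NULL, object$taxon_names))
  Y0[, shared] <- as.matrix(df[shared])
  rs <- rowSums(Y0)
  if (any(rs <= 0)) {
    abort(sprintf("fossil row(s) %s contain only unknown taxa or zero counts",
                  paste(which(rs <= 0), collapse = ", ")))
  }
  list(Wrow = Y0 / rs, ids = ids)
}

#' Predict environmental values from a fitted WA-PLS model
#'
#' Fossil columns are matched to training taxa by name; taxa absent from
#' training are dropped with a warning and rows are renormalized over the
#' remaining taxa. Predictions are on the transformed scale of the fit.
#'
#' @param object A [wapls()] fit.
#' @param newdata Data frame or matrix of fossil assemblages with taxon-named
#'   columns (`sample_id`/`depth`-style bookkeeping columns are ignored).
#' @param k Number of components to use (default: the fitted number).
#' @param quiet Suppress the dropped-taxa warning.
#' @param ... Unused.
#' @return Numeric vector of estimates (transformed env units).
#' @export
predict.wapls <- function(object, newdata, k = object$n_components,
                          quiet = FALSE, ...) {
  if (k < 1 || k > object$n_components) abort("k must be in 1..n_components")
  al <- align_fossil(object, newdata, quiet = quiet)
  sc <- wapls_scores(object, al$Wrow)
  b <- object$coefficients[[k]]
  as.vector(b[1] + sc[, seq_len(k), drop = FALSE] %*% b[-1])
}

# predictions for all component counts at once (n x K), used by the bootstrap
predict_all_wapls <- function(object, newdata, quiet = TRUE) {
  al <- align_fossil(object, newdata, quiet = quiet)
  sc <- wapls_scores(object, al$Wrow)
  K <- object$n_components
  out <- matrix(0, nrow(sc), K)
  for (k in seq_len(K)) {
    b <- object$coefficients[[k]]
    out[, k] <- b[1] + sc[, seq_len(k), drop = FALSE] %*% b[-1]
  }
  out
}

#' Deshrunk taxon optima from the first WA-PLS component
#'
#' Applies the component-1 deshrinking regression to the folded taxon
#' coefficients, yielding each taxon's effective optimum on the (transformed)
#' environmental scale. On synthetic Gaussian-niche data these recover the
#' generating niche optima.
#'
#' @param model A [wapls()] fit.
#' @return A tibble with columns `taxon`, `optimum` (transformed env units).
#' @export
taxon_optima <- function(model) {
  b <- model$coefficients[[1]]
  tibble::tibble(taxon = model$taxon_names,
                 optimum = as.numeric(b[1] + b[2] * model$taxon_coefficients[, 1]))
}

#' @describeIn wapls Broom-style per-taxon tidy output: folded score
#'   coefficient and raw WA taxon score per component.
#' @param x A `wapls` fit (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy wapls
#' @export
tidy.wapls <- function(x, ...) {
  tibble::tibble(
    taxon = rep(x$taxon_names, x$n_components),
    component = rep(seq_len(x$n_components), each = length(x$taxon_names)),
    score = as.vector(x$taxon_scores),
    beta = as.vector(x$taxon_coefficients)
  )
}

#' @describeIn wapls One-row model summary at the full component count.
#' @method glance wapls
#' @export
glance.wapls <- function(x, ...) {
  k <- x$n_components
  tibble::tibble(n_samples = nrow(x$abundances),
                 n_taxa = length(x$taxon_names),
                 n_components = k,
                 rmse = x$apparent$rmse[k],
                 r2 = x$apparent$r2[k],
                 transform = x$transform)
}

#' Bootstrap cross-validation of a WA-PLS model
#'
#' Per cycle, samples are resampled with replacement, the model is refitted
#' on the bootstrap set (taxa absent from it are dropped for that cycle), and
#' the out-of-bag samples are predicted. `rmsep_boot` per component is the
#' root mean square of all out-of-bag errors pooled over cycles; `r2_boot`
#' is the squared correlation between per-sample averaged out-of-bag
#' predictions and the observed values. The `s1` (within-sample bootstrap
#' spread) / `s2` (bias of averaged predictions) decomposition is also
#' reported. Cycles whose bootstrap sample holds fewer than two distinct
#' environmental values are redrawn (at most 10 times each).
#'
#' @param model A [wapls()] fit.
#' @param n_boot Number of bootstrap cycles (default 1000).
#' @param seed Integer seed; results are reproducible from it.
#' @return A tibble of class `wapls_cv` with columns `component`,
#'   `rmsep_boot`, `r2_boot`, `s1`, `s2`, and attributes `n_boot`, `seed`,
#'   `n_redraws`, `transform`.
#' @export
wapls_boot <- function(model, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(model, "wapls"))
  if (n_boot < 1) abort("n_boot must be >= 1")
  Y <- model$abundances
  xt <- model$env_t
  n <- nrow(Y)
  K <- model$n_components
  err_ss <- numeric(K); err_n <- numeric(K)
  pred_sum <- matrix(0, n, K); pred_ss <- matrix(0, n, K)
  pred_cnt <- matrix(0, n, K)
  n_redraws <- 0L
  withr::with_seed(seed, {
    for (cycle in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- 0L
      while (length(unique(xt[idx])) < 2 && tries < 10L) {
        idx <- sample.int(n, n, replace = TRUE)
        tries <- tries + 1L
        n_redraws <- n_redraws + 1L
      }
      oob <- setdiff(seq_len(n), idx)
      Yb <- Y[idx, , drop = FALSE]
      keep <- colSums(Yb) > 0
      # an OOB assemblage composed only of taxa absent from the bootstrap
      # sample cannot be predicted this cycle
      oob <- oob[rowSums(Y[oob, keep, drop = FALSE]) > 0]
      if (length(oob) == 0) next
      kb <- min(K, length(idx) - 1, sum(keep))
      fit <- wapls(Yb[, keep, drop = FALSE], model$env[idx],
                   n_components = kb, transform = model$transform)
      p <- predict_all_wapls(fit, Y[oob, , drop = FALSE])
      for (k in seq_len(K)) {
        kk <- min(k, kb)
        ek <- p[, kk] - xt[oob]
        err_ss[k] <- err_ss[k] + sum(ek^2)
        err_n[k] <- err_n[k] + length(oob)
        pred_sum[oob, k] <- pred_sum[oob, k] + p[, kk]
        pred_ss[oob, k] <- pred_ss[oob, k] + p[, kk]^2
        pred_cnt[oob, k] <- pred_cnt[oob, k] + 1
      }
    }
  })
  mean_pred <- pred_sum / pred_cnt
  out <- tibble::tibble(
    component = seq_len(K),
    rmsep_boot = sqrt(err_ss / err_n),
    r2_boot = vapply(seq_len(K), function(k) {
      ok <- pred_cnt[, k] > 0
      cor(mean_pred[ok, k], xt[ok])^2
    }, numeric(1)),
    s1 = vapply(seq_len(K), function(k) {
      ok <- pred_cnt[, k] > 1
      v <- (pred_ss[ok, k] - pred_cnt[ok, k] * mean_pred[ok, k]^2) /
        (pred_cnt[ok, k] - 1)
      sqrt(mean(pmax(v, 0)))
    }, numeric(1)),
    s2 = vapply(seq_len(K), function(k) {
      ok <- pred_cnt[, k] > 0
      sqrt(mean((mean_pred[ok, k] - xt[ok])^2))
    }, numeric(1))
  )
  structure(out, class = c("wapls_cv", class(out)),
            n_boot = n_boot, seed = seed, n_redraws = n_redraws,
            transform = model$transform)
}

#' Reconstruct salinity as deviations from a modern reference
#'
#' Applies a fitted WA-PLS model to fossil assemblages, back-transforms the
#' estimates to the untransformed salinity scale (squaring, when the model
#' was fitted on square-root units), attaches the bootstrap RMSEP as a
#' per-sample standard error (delta-method propagated through the
#' back-transform), and expresses estimates as deviations from a modern
#' reference salinity.
#'
#' @param model A [wapls()] fit.
#' @param cv A [wapls_boot()] result for the same model (supplies RMSEP);
#'   may be `NULL`, in which case `se` is `NA`.
#' @param fossil Fossil assemblage table (taxon-named columns; optional
#'   `sample_id`/`depth` columns are carried through).
#' @param modern_reference Modern salinity on the untransformed scale.
#' @param k Component count to use (default: the fitted number).
#' @return A tibble with columns (`sample_id`, `depth` if present,)
#'   `estimate_t` (transformed scale), `estimate`, `se`, `deviation`
#'   (`estimate - modern_reference`).
#' @export
reconstruct_salinity <- function(model, cv, fossil, modern_reference,
                                 k = model$n_components) {
  if (missing(modern_reference) || is.null(modern_reference) ||
      !is.finite(modern_reference)) {
    abort("modern_reference (untransformed salinity) is required")
  }
  est_t <- predict(model, fossil, k = k)
  se_t <- if (is.null(cv)) NA_real_ else cv$rmsep_boot[k]
  if (model$transform == "sqrt") {
    estimate <- est_t^2
    se <- 2 * abs(est_t) * se_t
  } else {
    estimate <- est_t
    se <- rep(se_t, length(est_t))
  }
  out <- tibble::tibble(estimate_t = est_t, estimate = estimate, se = se,
                        deviation = estimate - modern_reference)
  fdf <- as.data.frame(fossil)
  for (col in intersect(c("depth", "depth_cm", "sample_id"), names(fdf))) {
    out <- dplyr::bind_cols(tibble::tibble(!!col := fdf[[col]]), out)
  }
  out
}

#' Read a training set or fossil matrix from CSV
#'
#' Training-set dialect: first column `sample_id`, second the environmental
#' variable, remaining columns taxa. Fossil dialect: `sample_id`, `depth`,
#' then taxa.
#'
#' @param path CSV path.
#' @return For `read_training_set()`: a list with `abundances` (tibble),
#'   `env` (numeric), `sample_id`. For `read_fossil_matrix()`: a tibble.
#' @export
read_training_set <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (ncol(df) < 3) abort("training CSV needs sample_id, env and >=1 taxon column")
  list(sample_id = as.character(df[[1]]),
       env = as.numeric(df[[2]]),
       abundances = tibble::as_tibble(df[-(1:2)]))
}

#' @rdname read_training_set
#' @export
read_fossil_matrix <- function(path) {
  tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE, comment = "#"))
}
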