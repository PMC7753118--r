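#' Configuration for elastic-net stability selection
#'
#' Collects the tuning constants of the penalized-regression layer. Defaults
#' follow the analysis design: 5-fold cross-validated penalty selection inside
#' each of 5,000 bootstrap resamples, a 75% variable-inclusion-probability
#' cutoff and percentile 95% confidence intervals. The L1/L2 mixing fraction
#' `alpha` defaults to the equal mix 0.5.
#'
#' @param alpha L1 mixing fraction in `(0, 1]` (1 = lasso).
#' @param lambda_grid_size Number of penalty values on the geometric grid.
#' @param lambda_min_ratio Smallest grid value as a fraction of `lambda_max`.
#' @param n_folds Cross-validation folds for per-resample penalty selection.
#' @param n_bootstrap Number of bootstrap resamples `B`.
#' @param vip_threshold Selection cutoff on the variable inclusion probability.
#' @param ci_level Level of the percentile bootstrap confidence intervals.
#' @param convergence_tol Coordinate-descent stopping tolerance (max absolute
#'   coefficient change per sweep).
#' @param max_sweeps Sweep budget before the solver reports non-convergence.
#' @param seed Integer seed governing all resampling.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.5, lambda_grid_size = 100,
                        lambda_min_ratio = 1e-4, n_folds = 5,
                        n_bootstrap = 5000, vip_threshold = 0.75,
                        ci_level = 0.95, convergence_tol = 1e-7,
                        max_sweeps = 100000, seed = 1L) {
  assert_that(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  assert_that(lambda_min_ratio > 0 && lambda_min_ratio < 1,
              "lambda_min_ratio must lie in (0, 1)")
  assert_that(n_folds >= 2, "n_folds must be at least 2")
  assert_that(vip_threshold > 0 && vip_threshold < 1,
              "vip_threshold must lie in (0, 1)")
  assert_that(ci_level > 0 && ci_level < 1, "ci_level must lie in (0, 1)")
  structure(list(alpha = alpha, lambda_grid_size = lambda_grid_size,
                 lambda_min_ratio = lambda_min_ratio, n_folds = n_folds,
                 n_bootstrap = n_bootstrap, vip_threshold = vip_threshold,
                 ci_level = ci_level, convergence_tol = convergence_tol,
                 max_sweeps = max_sweeps, seed = as.integer(seed)),
            class = "enet_config")
}

#' Min-max normalization of a design matrix
#'
#' Maps each column to `[0, 1]` via `(x - min) / (max - min)` and returns the
#' per-column transform so the mapping can be inverted or applied to new data.
#'
#' @param x Numeric matrix (or data frame) with named columns; every column
#'   must have positive range.
#' @return List with `x` (the normalized matrix), `min` and `range` (named
#'   per-column vectors).
#' @examples
#' minmax_normalize(cbind(a = c(0, 5, 10)))$x
#' @export
minmax_normalize <- function(x) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  mins <- apply(x, 2, min)
  rng <- apply(x, 2, max) - mins
  flat <- rng <= 0
  if (any(flat))
    stop("constant column(s) cannot be min-max normalized: ",
         paste(colnames(x)[flat], collapse = ", "), call. = FALSE)
  scaled <- sweep(sweep(x, 2, mins, "-"), 2, rng, "/")
  list(x = scaled, min = mins, range = rng)
}

# Residual of y after an OLS fit on the intercept plus unpenalized columns.
unpenalized_residual <- function(X, y, pf, skip = rep(FALSE, ncol(X))) {
  free <- which(pf == 0 & !skip)
  Z <- cbind(rep(1, length(y)), X[, free, drop = FALSE])
  lm.fit(Z, y)$residuals
}

#' Smallest penalty that zeroes every penalized coefficient
#'
#' The top of the regularization path: with unpenalized columns (penalty
#' factor 0) already fitted by least squares, all penalized coefficients are
#' exactly zero whenever `lambda >= lambda_max`. Without unpenalized columns
#' this is `max_j |x_j' (y - mean(y))| / (n * alpha * pf_j)`.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param alpha L1 mixing fraction.
#' @param penalty_factors Per-column non-negative penalty weights (default 1).
#' @return The scalar `lambda_max`.
#' @export
lambda_max <- function(X, y, alpha, penalty_factors = rep(1, ncol(X))) {
  X <- as.matrix(X)
  n <- nrow(X)
  pf <- penalty_factors
  pen <- which(pf > 0)
  assert_that(length(pen) > 0, "no penalized columns: lambda_max undefined")
  r0 <- unpenalized_residual(X, y, pf)
  # inflate by one part in 1e12 so the all-zero solution is exact at the
  # reported boundary regardless of floating-point summation order
  max(abs(crossprod(X[, pen, drop = FALSE], r0)) / (n * alpha * pf[pen])) *
    (1 + 1e-12)
}

lambda_grid <- function(lmax, config) {
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$lambda_grid_size))
}

#' Elastic-net fit by cyclic coordinate descent
#'
#' Minimizes the penalized least-squares objective
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i'\beta)^2 +
#'       \lambda \sum_j pf_j \left(\alpha|\beta_j| +
#'       \frac{1-\alpha}{2}\beta_j^2\right)}
#' with an unpenalized intercept, by cyclic coordinate descent with
#' soft-threshold updates. `lambda` may be a decreasing vector, in which case
#' the path is computed with warm starts and the fit at the last value is
#' returned along with the full path.
#'
#' @param X Numeric design matrix (named columns recommended).
#' @param y Numeric response.
#' @param lambda Penalty value(s), non-negative.
#' @param config An [enet_config()] (supplies `alpha`, tolerance, sweep cap).
#' @param penalty_factors Per-column non-negative weights; 0 leaves a column
#'   unpenalized. Default 1 for every column.
#' @param skip Logical per-column flags; flagged columns are frozen at zero
#'   (used for degenerate resampled columns).
#' @param debug If `TRUE`, record the objective after every sweep
#'   (`objective_trace`), for verifying monotone descent.
#' @return List of class `enet_fit`: `beta` (named coefficients at the last
#'   `lambda`), `intercept`, `lambda`, `beta_path`/`intercept_path` over the
#'   grid, sweep counts, and optionally the objective traces.
#' @export
enet_fit <- function(X, y, lambda, config = enet_config(),
                     penalty_factors = rep(1, ncol(X)),
                     skip = rep(FALSE, ncol(X)), debug = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  assert_that(all(is.finite(X)) && all(is.finite(y)),
              "X and y must be finite")
  assert_that(all(lambda >= 0), "lambda must be non-negative")
  assert_that(all(penalty_factors >= 0), "penalty factors must be non-negative")
  lam <- sort(as.numeric(lambda), decreasing = TRUE)
  res <- cd_enet_path(X, y, lam, config$alpha, as.numeric(penalty_factors),
                      config$convergence_tol, as.integer(config$max_sweeps),
                      as.logical(skip), debug)
  last <- length(lam)
  beta <- res$beta[, last]
  names(beta) <- colnames(X)
  rownames(res$beta) <- colnames(X)
  out <- list(beta = beta, intercept = res$intercept[last],
              lambda = lam, beta_path = res$beta,
              intercept_path = res$intercept, sweeps = res$sweeps,
              alpha = config$alpha, penalty_factors = penalty_factors)
  if (debug) out$objective_trace <- res$objective_trace
  structure(out, class = "enet_fit")
}

#' Cross-validated penalty selection by minimum deviance
#'
#' Lays a geometric grid of `lambda_grid_size` penalties from `lambda_max`
#' down to `lambda_max * lambda_min_ratio`, assigns subjects to `n_folds`
#' folds at random, and for each fold fits the warm-started path on the
#' training part and scores held-out Gaussian deviance (mean squared error).
#' Returns the penalty minimizing the fold-averaged deviance; ties break
#' toward the larger (more parsimonious) penalty.
#'
#' @inheritParams enet_fit
#' @param seed Optional integer; when given, fold assignment is drawn under
#'   this seed without disturbing the caller's RNG stream. When `NULL`
#'   (default) the current RNG stream is used, so enclosing procedures such
#'   as [bootstrap_vip()] stay reproducible end to end.
#' @param groups Optional integer/character vector, one entry per row,
#'   identifying the underlying subject. Folds partition distinct subjects,
#'   so rows sharing a group (bootstrap duplicates) are never split between
#'   training and held-out folds — splitting them would leak the held-out
#'   response into training and bias selection toward small penalties.
#'   Default: every row its own subject.
#' @return List: `lambda` (the selected penalty), `lambda_grid`,
#'   `cv_deviance` (fold-averaged curve), `fold_id`.
#' @export
cv_select_lambda <- function(X, y, config = enet_config(),
                             penalty_factors = rep(1, ncol(X)),
                             skip = rep(FALSE, ncol(X)), seed = NULL,
                             groups = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(n >= config$n_folds,
              sprintf("need at least n_folds = %d usable rows", config$n_folds))
  if (is.null(groups)) groups <- seq_len(n)
  assert_that(length(groups) == n, "groups must have one entry per row")
  ug <- unique(groups)
  assert_that(length(ug) >= config$n_folds,
              sprintf("need at least n_folds = %d distinct subjects",
                      config$n_folds))
  lmax <- lambda_max_skipped(X, y, config$alpha, penalty_factors, skip)
  grid <- lambda_grid(lmax, config)
  draw_folds <- function() {
    gf <- sample(rep_len(seq_len(config$n_folds), length(ug)))
    gf[match(groups, ug)]
  }
  fold_id <- if (is.null(seed)) draw_folds() else withr::with_seed(seed, draw_folds())
  dev <- matrix(NA_real_, config$n_folds, length(grid))
  for (k in seq_len(config$n_folds)) {
    tr <- fold_id != k
    skip_k <- skip | apply(X[tr, , drop = FALSE], 2, function(col) var(col) == 0)
    fit <- enet_fit(X[tr, , drop = FALSE], y[tr], grid, config,
                    penalty_factors, skip = skip_k)
    pred <- X[!tr, , drop = FALSE] %*% fit$beta_path +
      rep(fit$intercept_path, each = sum(!tr))
    dev[k, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv_dev <- colMeans(dev)
  best <- which.min(cv_dev)  # grid is decreasing: first minimum = largest lambda
  list(lambda = grid[best], lambda_grid = grid, cv_deviance = cv_dev,
       fold_id = fold_id)
}

# lambda_max that honours frozen (skip) columns in both the unpenalized fit
# and the max over penalized columns.
lambda_max_skipped <- function(X, y, alpha, pf, skip) {
  pen <- which(pf > 0 & !skip)
  assert_that(length(pen) > 0, "no penalized columns: lambda_max undefined")
  r0 <- unpenalized_residual(X, y, pf, skip)
  max(abs(crossprod(X[, pen, drop = FALSE], r0)) /
        (nrow(X) * alpha * pf[pen])) * (1 + 1e-12)
}

#' Bootstrap stability selection with variable inclusion probabilities
#'
#' The stability layer around the elastic net: subjects are resampled with
#' replacement `n_bootstrap` times; within each resample the penalty is
#' chosen by [cv_select_lambda()] and the elastic net refit at that penalty
#' with analyte predictors penalized (factor 1) and nuisance covariates
#' unpenalized (factor 0). A predictor's variable inclusion probability (VIP)
#' is the fraction of resamples in which its coefficient is nonzero
#' (`|beta| > 1e-8`); predictors with VIP at or above `vip_threshold` are
#' selected. Bootstrap coefficient means and percentile confidence intervals
#' are reported on the fitted (normalized-predictor) scale. Nuisance
#' covariates never appear in the selection report.
#'
#' Resamples in which a predictor column is constant freeze that coefficient
#' at zero for the resample (counting as non-inclusion); this is tallied in
#' `degenerate_freezes`.
#'
#' @param X Matrix of penalized predictors (subjects x analytes), typically
#'   min-max normalized.
#' @param y Response vector (outcome metabolite concentration, raw scale).
#' @param nuisance Optional matrix of unpenalized covariates, row-aligned
#'   with `X`.
#' @param config An [enet_config()]; `config$seed` governs all resampling.
#' @return Object of class `stability_result`: `summary` data frame
#'   (predictor, vip, boot_mean_coef, ci_low, ci_high, selected), `lambda`
#'   (per-resample selected penalties), `coef` (B x p bootstrap coefficient
#'   matrix), `nuisance` (covariate names), `config`.
#' @export
bootstrap_vip <- function(X, y, nuisance = NULL, config = enet_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  assert_that(length(y) == n, "X and y must be row-aligned")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(as.data.frame(nuisance))
    storage.mode(nuisance) <- "double"
    assert_that(nrow(nuisance) == n, "nuisance must be row-aligned with y")
  }
  p <- ncol(X)
  q <- if (is.null(nuisance)) 0L else ncol(nuisance)
  design <- if (q > 0) cbind(X, nuisance) else X
  pf <- c(rep(1, p), rep(0, q))
  B <- config$n_bootstrap

  coef_mat <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(X)))
  lambda_b <- numeric(B)
  freezes <- 0L
  withr::with_seed(config$seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      Db <- design[idx, , drop = FALSE]
      yb <- y[idx]
      skip <- apply(Db, 2, function(col) var(col) == 0)
      if (any(skip[seq_len(p)])) freezes <- freezes + sum(skip[seq_len(p)])
      sel <- cv_select_lambda(Db, yb, config, pf, skip = skip, groups = idx)
      fit <- enet_fit(Db, yb, sel$lambda, config, pf, skip = skip)
      coef_mat[b, ] <- fit$beta[seq_len(p)]
      lambda_b[b] <- sel$lambda
    }
  })
  if (freezes > 0)
    message(freezes,
            " constant predictor column(s) across resamples frozen at zero")

  probs <- c((1 - config$ci_level) / 2, (1 + config$ci_level) / 2)
  ci <- apply(coef_mat, 2, quantile, probs = probs, names = FALSE)
  vip <- colMeans(abs(coef_mat) > 1e-8)
  summary <- data.frame(predictor = colnames(X), vip = vip,
                        boot_mean_coef = colMeans(coef_mat),
                        ci_low = ci[1, ], ci_high = ci[2, ],
                        selected = vip >= config$vip_threshold,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary, lambda = lambda_b, coef = coef_mat,
                 nuisance = colnames(nuisance),
                 degenerate_freezes = freezes, config = config),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability_result: %d predictors, B = %d resamples, VIP threshold %.2f\n",
              nrow(x$summary), length(x$lambda), x$config$vip_threshold))
  sel <- x$summary[x$summary$selected, , drop = FALSE]
  if (nrow(sel)) {
    cat("selected:\n")
    print(sel[order(-sel$vip), ], row.names = FALSE, digits = 3)
  } else cat("no predictors selected\n")
  invisible(x)
}

#' Predictors surviving the VIP threshold
#'
#' @param result A [bootstrap_vip()] result.
#' @param threshold Inclusive VIP cutoff (default 0.75).
#' @return Character vector of selected predictors, VIP descending. Nuisance
#'   covariates are never returned (they are not scored).
#' @export
threshold_vip <- function(result, threshold = 0.75) {
  assert_that(inherits(result, "stability_result"),
              "result must come from bootstrap_vip()")
  s <- result$summary
  s <- s[s$vip >= threshold, , drop = FALSE]
  s$predictor[order(-s$vip)]
}

#' Sensitivity of VIPs to the L1/L2 mixing fraction
#'
#' Re-runs [bootstrap_vip()] over a grid of `alpha` values, returning the VIP
#' of every predictor at each mix. Intended as a reporting utility; the main
#' analysis fixes one `alpha`.
#'
#' @inheritParams bootstrap_vip
#' @param alphas Vector of mixing fractions in `(0, 1]`.
#' @return Data frame: alpha, predictor, vip, selected.
#' @export
vip_alpha_sweep <- function(X, y, nuisance = NULL, config = enet_config(),
                            alphas = c(0.25, 0.5, 0.75, 1)) {
  out <- lapply(alphas, function(a) {
    cfg <- config
    cfg$alpha <- a
    res <- bootstrap_vip(X, y, nuisance, cfg)
    cbind(alpha = a, res$summary[, c("predictor", "vip", "selected")])
  })
  do.call(rbind, out)
}
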