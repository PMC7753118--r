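test_that("min-max normalization maps columns onto [0, 1] invertibly", {
  expect_equal(unname(minmax_normalize(cbind(a = c(0, 5, 10)))$x[, 1]),
               c(0, 0.5, 1))
  canon <- cbind(u = c(0, 0.25, 1))
  expect_equal(minmax_normalize(canon)$x, canon)
  set.seed(3)
  m <- matrix(rnorm(200, 10, 4), 20, dimnames = list(NULL, letters[1:10]))
  nm <- minmax_normalize(m)
  expect_true(all(nm$x >= 0 & nm$x <= 1))
  expect_equal(unname(apply(nm$x, 2, min)), rep(0, 10))
  expect_equal(unname(apply(nm$x, 2, max)), rep(1, 10))
  back <- sweep(sweep(nm$x, 2, nm$range, "*"), 2, nm$min, "+")
  expect_equal(back, m)
  m[, "c"] <- 2
  expect_error(minmax_normalize(m), "c")
})

test_that("elastic net at lambda = 0 equals the least-squares solution", {
  set.seed(5)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- 2 + X %*% c(1, -0.5, 0, 0.3, 0) + rnorm(40, 0, 0.4)
  fit <- enet_fit(X, y, 0)
  o <- ols_oracle(cbind(1, X), y)
  expect_equal(unname(c(fit$intercept, fit$beta)), unname(o$b),
               tolerance = 1e-6)
})

test_that("all penalized coefficients are exactly zero at and above lambda_max", {
  set.seed(6)
  X <- matrix(rnorm(300), 30, 10)
  y <- rnorm(30) + X[, 1]
  lmax <- lambda_max(X, y, alpha = 0.5)
  expect_equal(lmax, max(abs(crossprod(X, y - mean(y)))) / (30 * 0.5))
  for (lam in c(lmax, 1.5 * lmax)) {
    fit <- enet_fit(X, y, lam)
    expect_identical(unname(fit$beta), rep(0, 10))
    expect_equal(fit$intercept, mean(y))
  }
  # just below lambda_max at least one coefficient activates
  expect_gt(sum(enet_fit(X, y, 0.95 * lmax)$beta != 0), 0)
})

test_that("single standardized predictor matches the soft-threshold closed form", {
  set.seed(8)
  x <- rnorm(50)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # centered, x'x/n = 1
  y <- 1.5 * x + rnorm(50, 0, 0.5)
  b_ols <- mean(x * (y - mean(y)))
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (alpha in c(0.3, 0.5, 1)) {
    cfg <- enet_config(alpha = alpha)
    for (lam in c(0.05, 0.3, 1)) {
      fit <- enet_fit(cbind(x = x), y, lam, cfg)
      expect_equal(unname(fit$beta),
                   soft(b_ols, lam * alpha) / (1 + lam * (1 - alpha)),
                   tolerance = 1e-7)
    }
  }
})

test_that("solver agrees with a brute-force objective minimizer on tiny problems", {
  set.seed(9)
  cases <- list(list(n = 8, p = 2, alpha = 0.5, lambda = 0.1),
                list(n = 10, p = 3, alpha = 0.7, lambda = 0.05),
                list(n = 9, p = 3, alpha = 1.0, lambda = 0.2))
  for (cs in cases) {
    X <- matrix(rnorm(cs$n * cs$p), cs$n, cs$p)
    y <- X %*% rnorm(cs$p) + rnorm(cs$n, 0, 0.5)
    fit <- enet_fit(X, y, cs$lambda, enet_config(alpha = cs$alpha))
    brute <- enet_brute(X, y, cs$lambda, cs$alpha)
    f_cd <- enet_objective_r(X, y, fit$intercept, fit$beta, cs$lambda, cs$alpha)
    expect_equal(f_cd, brute$value, tolerance = 1e-6)
    expect_equal(unname(fit$beta), brute$beta, tolerance = 1e-4)
  }
})

test_that("solver matches glmnet across the penalty mix", {
  skip_if_not_installed("glmnet")
  set.seed(10)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- drop(X %*% c(1, -1, 0.5, rep(0, 5)) + rnorm(60))
  # glmnet standardizes the response internally, which rescales its L1 and
  # ridge penalties differently; solving on the unit-variance response with
  # the exactly transformed (alpha, lambda) pair makes the objectives match:
  # lam_g * alpha_g = lam * alpha / s and lam_g * (1 - alpha_g) = lam * (1 - alpha)
  s <- sqrt(mean((y - mean(y))^2))
  for (alpha in c(0.5, 1)) {
    for (lam in c(0.02, 0.1, 0.4)) {
      l1 <- lam * alpha / s
      l2 <- lam * (1 - alpha)
      g <- glmnet::glmnet(X, y / s, alpha = l1 / (l1 + l2), lambda = l1 + l2,
                          standardize = FALSE, thresh = 1e-14)
      fit <- enet_fit(X, y, lam, enet_config(alpha = alpha,
                                             convergence_tol = 1e-9))
      expect_equal(unname(fit$beta), as.numeric(g$beta) * s,
                   tolerance = 1e-4)
      expect_equal(fit$intercept, as.numeric(g$a0) * s, tolerance = 1e-4)
    }
  }
})

test_that("unpenalized columns are fitted freely at any penalty", {
  set.seed(12)
  X <- matrix(rnorm(200), 50, 4)
  Z <- cbind(rnorm(50))
  y <- 3 + 2 * Z[, 1] + rnorm(50, 0, 0.3)
  D <- cbind(X, Z)
  pf <- c(rep(1, 4), 0)
  fit <- enet_fit(D, y, 10, enet_config(), penalty_factors = pf)
  expect_identical(unname(fit$beta[1:4]), rep(0, 4))
  # unpenalized coefficient equals OLS of y on (1, Z)
  o <- ols_oracle(cbind(1, Z), y)
  expect_equal(unname(fit$beta[5]), unname(o$b[2]), tolerance = 1e-6)
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  set.seed(14)
  for (i in 1:5) {
    X <- matrix(rnorm(40 * 6), 40, 6)
    y <- rnorm(40)
    fit <- enet_fit(X, y, c(0.5, 0.1, 0.01), enet_config(), debug = TRUE)
    for (tr in fit$objective_trace)
      expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("warm-started path is continuous in lambda", {
  set.seed(15)
  X <- minmax_normalize(matrix(rnorm(80 * 10), 80, 10))$x
  y <- X %*% c(2, -1, rep(0, 8)) + rnorm(80, 0, 0.5)
  cfg <- enet_config()
  grid <- cytomet:::lambda_grid(lambda_max(X, y, cfg$alpha), cfg)
  fit <- enet_fit(X, y, grid, cfg)
  steps <- apply(abs(diff(t(fit$beta_path))), 1, max)
  expect_lt(max(steps), 0.5)
})

test_that("cv grid spans lambda_max down to the configured ratio", {
  set.seed(16)
  X <- matrix(rnorm(25 * 4), 25, 4)
  y <- rnorm(25)
  cfg <- enet_config(lambda_grid_size = 30, lambda_min_ratio = 1e-3)
  sel <- cv_select_lambda(X, y, cfg, seed = 1)
  lmax <- lambda_max(X, y, cfg$alpha)
  expect_equal(sel$lambda_grid[1], lmax)
  expect_equal(sel$lambda_grid[30], lmax * 1e-3)
  expect_error(cv_select_lambda(X[1:3, ], y[1:3], cfg), "n_folds")
})

test_that("cv selects a small penalty when the signal is strong and noiseless", {
  set.seed(18)
  X <- matrix(rnorm(100 * 20), 100, 20)
  y <- drop(X[, 1] * 2 - X[, 2])          # noiseless, 2 of 20 predictors
  cfg <- enet_config()
  sel <- cv_select_lambda(X, y, cfg, seed = 2)
  expect_lt(sel$lambda, sel$lambda_grid[cfg$lambda_grid_size / 2])
  expect_lt(sel$cv_deviance[which(sel$lambda_grid == sel$lambda)],
            sel$cv_deviance[1])
})

test_that("cv stays parsimonious under a pure-noise response", {
  set.seed(19)
  nz <- replicate(60, {
    X <- matrix(rnorm(63 * 20), 63, 20)
    y <- rnorm(63)
    sel <- cv_select_lambda(X, y)
    sum(abs(enet_fit(X, y, sel$lambda)$beta) > 1e-8)
  })
  expect_gte(mean(nz <= 2), 0.65)
  expect_lt(median(nz), 2)
})

test_that("a single bootstrap resample gives only 0/1 inclusion probabilities", {
  set.seed(20)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40) + X[, 1]
  res <- bootstrap_vip(X, y, config = enet_config(n_bootstrap = 1, seed = 2))
  expect_true(all(res$summary$vip %in% c(0, 1)))
  expect_true(all(res$summary$ci_low <= res$summary$ci_high))
})

test_that("stability selection is bit-reproducible under one seed", {
  set.seed(22)
  X <- matrix(rnorm(50 * 8), 50, 8)
  Z <- cbind(age = rnorm(50))
  y <- X %*% c(1.5, rep(0, 7)) + rnorm(50)
  cfg <- enet_config(n_bootstrap = 25, seed = 123)
  a <- bootstrap_vip(X, y, Z, cfg)
  b <- bootstrap_vip(X, y, Z, cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$coef, b$coef)
  expect_identical(a$lambda, b$lambda)
})

test_that("VIP rises with the true effect size", {
  vip_at <- function(effect, seed) {
    set.seed(seed)
    X <- matrix(rnorm(80 * 10), 80, 10)
    y <- effect * X[, 1] + rnorm(80)
    bootstrap_vip(X, y,
                  config = enet_config(n_bootstrap = 60, seed = seed)
    )$summary$vip[1]
  }
  seeds <- 1:5
  weak <- mean(sapply(seeds, function(s) vip_at(0.15, s)))
  strong <- mean(sapply(seeds, function(s) vip_at(1.0, s)))
  expect_gt(strong, weak)
  expect_gt(strong, 0.9)
})

test_that("a constant predictor column is frozen at zero with a note", {
  set.seed(23)
  X <- cbind(flat = rep(2, 40), ok = rnorm(40))
  y <- rnorm(40) + X[, "ok"]
  expect_message(
    res <- bootstrap_vip(X, y, config = enet_config(n_bootstrap = 10, seed = 4)),
    "frozen")
  expect_equal(res$summary$vip[res$summary$predictor == "flat"], 0)
})

test_that("threshold_vip is inclusive at the cutoff and skips nuisance terms", {
  fake <- structure(list(
    summary = data.frame(predictor = c("a", "b", "c"),
                         vip = c(0.80, 0.74, 0.75),
                         boot_mean_coef = 0, ci_low = 0, ci_high = 0,
                         selected = c(TRUE, FALSE, TRUE)),
    lambda = numeric(0), coef = NULL, nuisance = c("age", "sex"),
    config = enet_config()), class = "stability_result")
  expect_identical(threshold_vip(fake, 0.75), c("a", "c"))
  fake$summary$vip <- c(0, 0, 0)
  expect_identical(threshold_vip(fake, 0.75), character(0))
})

test_that("a result with five analytes above threshold returns exactly those five", {
  vips <- c(0.99, 0.93, 0.88, 0.81, 0.76, 0.71, 0.40, 0.12)
  fake <- structure(list(
    summary = data.frame(predictor = paste0("cyt", 1:8), vip = vips,
                         boot_mean_coef = 0, ci_low = 0, ci_high = 0,
                         selected = vips >= 0.75),
    lambda = numeric(0), coef = NULL, nuisance = "age",
    config = enet_config()), class = "stability_result")
  expect_identical(threshold_vip(fake, 0.75), paste0("cyt", 1:5))
})

test_that("strong predictors dominate the VIP ranking", {
  set.seed(24)
  X <- matrix(rnorm(120 * 15), 120, 15,
              dimnames = list(NULL, paste0("a", 1:15)))
  y <- X[, 1:5] %*% rep(1.2, 5) + rnorm(120, 0, 0.6)
  res <- bootstrap_vip(X, y, config = enet_config(n_bootstrap = 80, seed = 6))
  survivors <- threshold_vip(res, 0.75)
  expect_true(all(paste0("a", 1:5) %in% survivors))
  # the survivor list is exactly the set at or above the cutoff, VIP-sorted
  s <- res$summary[res$summary$vip >= 0.75, ]
  expect_identical(survivors, s$predictor[order(-s$vip)])
  expect_identical(survivors[1],
                   res$summary$predictor[which.max(res$summary$vip)])
})
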