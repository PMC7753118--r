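make_panel <- function(n, nd_counts) {
  # nd_counts: named integer vector, analytes in columns
  analytes <- names(nd_counts)
  set.seed(4)
  values <- matrix(rlnorm(n * length(analytes), 2, 0.5), n,
                   dimnames = list(NULL, analytes))
  mask <- matrix(FALSE, n, length(analytes), dimnames = list(NULL, analytes))
  for (a in analytes) if (nd_counts[[a]] > 0) {
    mask[seq_len(nd_counts[[a]]), a] <- TRUE
    values[seq_len(nd_counts[[a]]), a] <- NA
  }
  analyte_panel(values, mask, setNames(rep(1.5, length(analytes)), analytes))
}

test_that("nd_exclusion applies the strict >20% rule", {
  # 13/63 = 20.6% excluded; 12/63 = 19.0% retained
  panel <- make_panel(63, c(hi = 13L, lo = 12L))
  out <- suppressMessages(nd_exclusion(panel, 0.20))
  expect_false(out$retained[["hi"]])
  expect_true(out$retained[["lo"]])
  expect_identical(out$exclusions, "hi")
  expect_error(nd_exclusion(panel, 1.5), "0, 1")
})

test_that("heavily censored analytes are excluded by name and the rest imputed at LOD/2", {
  nd <- setNames(rep(2L, 8), c("IL-6", "IL-8", "IL-10", "IL-15",
                               "GM-CSF", "VEGF", "CCL2", "TNF-a"))
  nd[c("IL-10", "IL-15", "GM-CSF", "VEGF")] <- 30L
  panel <- make_panel(63, nd)
  out <- suppressMessages(nd_exclusion(panel, 0.20))
  expect_setequal(out$exclusions, c("IL-10", "IL-15", "GM-CSF", "VEGF"))
  # retained analytes: ND cells imputed at half the LOD (1.5/2)
  expect_equal(unname(out$values[1:2, "IL-6"]), c(0.75, 0.75))
  expect_false(anyNA(panel_matrix(out)))
})

test_that("pooled t reproduces published group statistics from summaries", {
  # metabolite rows: mean +/- SD per group, printed |t|
  rows <- list(
    NAA = list(6.62, 0.43, 7.14, 0.54, 5.67),
    GSH = list(1.70, 0.26, 1.54, 0.16, 3.77),
    Glx = list(9.90, 1.31, 9.20, 1.17, 2.95),
    Glu = list(8.11, 0.99, 7.68, 1.04, 2.21),
    mI  = list(5.24, 1.06, 4.29, 0.86, 5.13))
  for (m in names(rows)) {
    r <- rows[[m]]
    res <- pooled_t(mean1 = r[[1]], sd1 = r[[2]], n1 = 63,
                    mean2 = r[[3]], sd2 = r[[4]], n2 = 49)
    expect_equal(abs(res$statistic), r[[5]], tolerance = 0.02)
    expect_identical(res$df, 110)
  }
})

test_that("pooled t from raw vectors equals pooled t from their summaries", {
  set.seed(7)
  x <- rnorm(30, 5, 2); y <- rnorm(20, 4, 1.5)
  a <- pooled_t(x, y)
  b <- pooled_t(mean1 = mean(x), sd1 = sd(x), n1 = 30,
                mean2 = mean(y), sd2 = sd(y), n2 = 20)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  z <- rnorm(10)
  same <- pooled_t(z, z)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("chi-square on the sex table matches the published statistic", {
  res <- chi_square_2x2(17, 46, 28, 21)
  expect_equal(res$statistic, 10.43, tolerance = 0.005 / 10.43)
  expect_identical(res$df, 1L)
  expect_lt(res$p, 0.0015)
})

test_that("chi-square is zero for proportional tables and invariant to swaps", {
  expect_equal(chi_square_2x2(10, 20, 30, 60)$statistic, 0)
  expect_equal(chi_square_2x2(5, 5, 5, 5)$statistic, 0)
  a <- chi_square_2x2(17, 46, 28, 21)
  b <- chi_square_2x2(28, 21, 17, 46)   # swap rows
  d <- chi_square_2x2(46, 17, 21, 28)   # swap columns
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$statistic, d$statistic)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
})

test_that("ANCOVA group F matches a normal-equations oracle on a small fixture", {
  outcome <- c(5.1, 6.2, 5.9, 7.3, 4.8, 6.9, 5.5, 7.1)
  group <- c("a", "a", "a", "a", "b", "b", "b", "b")
  covs <- cbind(age = c(31, 45, 38, 52, 29, 48, 35, 50),
                sex = c(0, 1, 0, 1, 1, 0, 1, 0))
  res <- ancova_group_effect(outcome, group, covs)
  D <- cbind(1, c(0, 0, 0, 0, 1, 1, 1, 1), covs)
  o <- ols_oracle(D, outcome)
  F_oracle <- (o$b[2] / o$se[2])^2
  expect_equal(res$statistic, unname(F_oracle), tolerance = 1e-8)
  expect_equal(res$p, unname(pf(F_oracle, 1, 4, lower.tail = FALSE)),
               tolerance = 1e-8)
})

test_that("ANCOVA with no covariates equals the pooled t squared", {
  set.seed(11)
  y <- rnorm(40); g <- rep(c("x", "y"), each = 20)
  res <- ancova_group_effect(y, g)
  tt <- pooled_t(y[1:20], y[21:40])
  expect_equal(res$statistic, tt$statistic^2, tolerance = 1e-8)
})

test_that("ANCOVA F has mean about 1 under the null", {
  set.seed(21)
  g <- rep(c("bd", "hc"), c(63, 49))
  Fs <- replicate(1000, {
    covs <- cbind(age = rnorm(112, 40, 12), sex = rbinom(112, 1, 0.5))
    ancova_group_effect(rnorm(112), g, covs)$statistic
  })
  expect_equal(mean(Fs), 1, tolerance = 0.15)
})

test_that("ANCOVA rejects collinear designs by name", {
  y <- rnorm(20); g <- rep(c("a", "b"), 10)
  covs <- cbind(age = 1:20, age2 = 2 * (1:20))
  expect_error(ancova_group_effect(y, g, covs), "age2")
})

test_that("pearson_r matches the covariance oracle and handles exact lines", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson_r(x, x)$statistic, 1)
  expect_equal(pearson_r(x, -2 * x + 3)$statistic, -1)
  set.seed(13)
  a <- rnorm(50); b <- 0.4 * a + rnorm(50)
  r_oracle <- mean((a - mean(a)) * (b - mean(b))) /
    (sd(a) * sd(b)) * 50 / 49
  expect_equal(pearson_r(a, b)$statistic, r_oracle, tolerance = 1e-10)
  expect_error(pearson_r(a, rep(1, 50)), "variance")
})

test_that("BH adjustment matches the hand computation and its invariants", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(17)
  for (i in 1:20) {
    p <- runif(15)
    q <- fdr_adjust(p)
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})
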