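#' Construct an analyte panel
#'
#' Container for a multiplex immunoassay panel: a subjects x analytes
#' concentration matrix, a non-detected (below limit-of-detection) mask, and
#' per-analyte LODs. Non-detected cells keep no sentinel value; QC decisions
#' (exclusion, imputation) are taken downstream by [nd_exclusion()].
#'
#' @param values Numeric matrix, subjects in rows, analytes in named columns.
#'   Cells flagged non-detected may be `NA`.
#' @param nd_mask Logical matrix, same shape: `TRUE` where the measurement was
#'   below the analyte's LOD.
#' @param lod Named numeric vector of per-analyte limits of detection.
#' @param subject_id Optional subject identifiers (default from row names).
#' @return An object of class `analyte_panel`.
#' @export
analyte_panel <- function(values, nd_mask, lod, subject_id = rownames(values)) {
  values <- as.matrix(values)
  nd_mask <- as.matrix(nd_mask)
  assert_that(all(dim(values) == dim(nd_mask)),
              "values and nd_mask must have identical dimensions")
  assert_that(!is.null(colnames(values)), "values must have analyte column names")
  assert_that(all(colnames(values) %in% names(lod)),
              "every analyte needs an entry in lod")
  assert_that(!anyNA(nd_mask), "nd_mask must be TRUE/FALSE for every cell")
  detected <- values[!nd_mask]
  assert_that(all(is.na(detected) | detected > 0),
              "detected analyte values must be positive")
  if (is.null(subject_id)) subject_id <- seq_len(nrow(values))
  structure(
    list(values = values, nd_mask = nd_mask,
         lod = lod[colnames(values)],
         retained = stats::setNames(rep(TRUE, ncol(values)), colnames(values)),
         subject_id = as.character(subject_id)),
    class = "analyte_panel")
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat(sprintf("analyte_panel: %d subjects x %d analytes (%d retained)\n",
              nrow(x$values), ncol(x$values), sum(x$retained)))
  cat(sprintf("non-detected cells: %d (%.1f%%)\n", sum(x$nd_mask),
              100 * mean(x$nd_mask)))
  invisible(x)
}

#' Exclude heavily censored analytes and impute the rest
#'
#' Analytes whose non-detected fraction exceeds `threshold` (strictly) are
#' dropped from downstream analysis; for retained analytes, non-detected
#' cells are imputed at a fixed fraction of the limit of detection
#' (conventionally LOD/2). Excluded analytes stay in the object, flagged.
#'
#' @param panel An [analyte_panel()].
#' @param threshold Maximum tolerated non-detected fraction; an analyte is
#'   excluded iff `ND/n > threshold`. Default 0.20.
#' @param impute_factor Imputed value for non-detected cells of retained
#'   analytes, as a fraction of the analyte's LOD. Default 0.5.
#' @return The panel with `retained` updated, ND cells of retained analytes
#'   imputed, and an `exclusions` character vector attached.
#' @export
nd_exclusion <- function(panel, threshold = 0.20, impute_factor = 0.5) {
  assert_that(inherits(panel, "analyte_panel"), "panel must be an analyte_panel")
  assert_that(is.numeric(threshold) && threshold >= 0 && threshold <= 1,
              "threshold must lie in [0, 1]")
  nd_frac <- colMeans(panel$nd_mask)
  panel$retained <- nd_frac <= threshold
  excluded <- colnames(panel$values)[!panel$retained]
  if (length(excluded))
    message("excluding analytes with non-detected fraction > ",
            threshold, ": ", paste(excluded, collapse = ", "))
  for (a in colnames(panel$values)[panel$retained]) {
    nd <- panel$nd_mask[, a]
    if (any(nd)) panel$values[nd, a] <- impute_factor * panel$lod[[a]]
  }
  panel$exclusions <- excluded
  panel
}

#' Retained, imputed analyte matrix
#'
#' @param panel An [analyte_panel()] after [nd_exclusion()].
#' @return Numeric matrix restricted to retained analytes.
#' @export
panel_matrix <- function(panel) {
  panel$values[, panel$retained, drop = FALSE]
}

test_result <- function(label, stat_name, statistic, df, p, extra = NULL) {
  out <- data.frame(label = label, stat_name = stat_name,
                    statistic = statistic, df = df, p = p,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, as.data.frame(extra))
  out
}

#' Two-sample pooled-variance t test
#'
#' Student's t with the pooled variance estimate and `n1 + n2 - 2` degrees of
#' freedom, two-tailed. Callable either on raw per-subject vectors (`x`, `y`)
#' or on published summary statistics (means, SDs, group sizes), which lets
#' group statistics from a printed table be re-derived exactly.
#'
#' @param x,y Optional raw value vectors for the two groups.
#' @param mean1,sd1,n1,mean2,sd2,n2 Summary statistics, used when `x`/`y` are
#'   not given.
#' @param label Row label for the result.
#' @return One-row data frame: label, statistic name, t, df, two-tailed p.
#' @examples
#' pooled_t(mean1 = 6.62, sd1 = 0.43, n1 = 63, mean2 = 7.14, sd2 = 0.54, n2 = 49)
#' @export
pooled_t <- function(x = NULL, y = NULL, mean1, sd1, n1, mean2, sd2, n2,
                     label = "t-test") {
  if (!is.null(x) || !is.null(y)) {
    assert_that(!is.null(x) && !is.null(y), "both x and y are required")
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  assert_that(n1 >= 2 && n2 >= 2, "each group needs at least 2 observations")
  assert_that(sd1 > 0 || sd2 > 0, "at least one group must have positive SD")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  test_result(label, "t", tval, df, 2 * pt(-abs(tval), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction, 1 degree of freedom,
#' two-sided. Cell layout is `rbind(c(a, b), c(c, d))` (rows = groups,
#' columns = categories).
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param label Row label for the result.
#' @return One-row data frame: label, statistic name, chi2, df, p.
#' @examples
#' chi_square_2x2(17, 46, 28, 21)
#' @export
chi_square_2x2 <- function(a, b, c, d, label = "chi-square") {
  counts <- c(a, b, c, d)
  assert_that(all(counts >= 0) && sum(counts) > 0,
              "counts must be non-negative with a positive total")
  tab <- rbind(c(a, b), c(c, d))
  margins <- c(row1 = a + b, row2 = c + d, col1 = a + c, col2 = b + d)
  zero <- names(margins)[margins == 0]
  if (length(zero))
    stop("chi-square undefined: zero margin(s) ", paste(zero, collapse = ", "),
         call. = FALSE)
  res <- stats::chisq.test(tab, correct = FALSE)
  test_result(label, "chi2", unname(res$statistic), unname(res$parameter),
              res$p.value)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Ordinary-least-squares fit of the outcome on an intercept, a group
#' indicator (reference-cell coded), and the covariates; reports the partial
#' F statistic (1 numerator df) for the group term.
#'
#' @param outcome Numeric outcome vector.
#' @param group Two-level factor/character/logical group labels; the first
#'   level (alphabetically for character input) is the reference.
#' @param covariates Numeric matrix or data frame of adjustment covariates,
#'   or `NULL` for an unadjusted comparison (then `F = t^2` of the pooled t).
#' @param label Row label for the result.
#' @return One-row data frame: label, "F", the partial F for group, its
#'   numerator df (always 1) with residual df in `df2`, and the p-value.
#' @export
ancova_group_effect <- function(outcome, group, covariates = NULL,
                                label = "group") {
  group <- as.factor(group)
  assert_that(nlevels(group) == 2, "group must have exactly two levels")
  g <- as.numeric(group == levels(group)[2])
  if (is.null(covariates)) {
    Z <- matrix(numeric(0), nrow = length(outcome), ncol = 0)
  } else {
    Z <- as.matrix(as.data.frame(covariates))
    storage.mode(Z) <- "double"
  }
  assert_that(!anyNA(outcome) && !anyNA(g) && !anyNA(Z),
              "missing values must be removed before the ANCOVA fit")
  design <- cbind(`(Intercept)` = 1, group = g, Z)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(design, outcome)
  df2 <- length(outcome) - ncol(design)
  sigma2 <- sum(fit$residuals^2) / df2
  xtx_inv <- chol2inv(chol(crossprod(design)))
  se_g <- sqrt(sigma2 * xtx_inv[2, 2])
  Fval <- (fit$coefficients[["group"]] / se_g)^2
  out <- test_result(label, "F", Fval, 1, pf(Fval, 1, df2, lower.tail = FALSE))
  out$df2 <- df2
  out
}

#' Pearson correlation with two-tailed p
#'
#' Correlation coefficient with the usual t transform
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with positive variance.
#' @param label Row label for the result.
#' @return One-row data frame: label, "r", r, df, p.
#' @export
pearson_r <- function(x, y, label = "correlation") {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  assert_that(length(x) >= 3, "need at least 3 complete pairs")
  assert_that(sd(x) > 0 && sd(y) > 0, "inputs must have nonzero variance")
  r <- cor(x, y)
  df <- length(x) - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tval), df)
  }
  test_result(label, "r", r, df, p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (q-values) with the usual monotonicity
#' enforcement; input order is preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return q-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(p_values) {
  assert_that(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
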