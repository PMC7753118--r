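#' Confirmatory generalized linear model (Gaussian, identity link)
#'
#' Models a metabolite concentration on selected predictors plus nuisance
#' covariates by least squares, reporting per-term slope, standard error,
#' Wald statistic `(b/se)^2` and its two-sided p-value from the chi-square
#' distribution with 1 df. Predictors enter on their raw (unnormalized)
#' scale, so slopes are in outcome units per predictor unit.
#'
#' @param outcome Numeric response vector.
#' @param predictors Matrix or data frame of predictors of interest.
#' @param covariates Optional matrix/data frame of nuisance covariates.
#' @return Object of class `glm_result`: a data frame with one row per term
#'   (term, b, se, wald, p), with the model log-likelihood and `n` attached
#'   as attributes `loglik` and `n`.
#' @export
fit_glm <- function(outcome, predictors, covariates = NULL) {
  Xp <- as.matrix(as.data.frame(predictors))
  storage.mode(Xp) <- "double"
  if (is.null(colnames(Xp))) colnames(Xp) <- paste0("x", seq_len(ncol(Xp)))
  Z <- if (is.null(covariates)) NULL else {
    z <- as.matrix(as.data.frame(covariates))
    storage.mode(z) <- "double"
    z
  }
  design <- cbind(`(Intercept)` = 1, Xp, Z)
  n <- length(outcome)
  assert_that(!anyNA(design) && !anyNA(outcome),
              "missing values must be removed before fitting")
  assert_that(n > ncol(design),
              "too few observations for the number of model terms")
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(design, outcome)
  df_res <- n - ncol(design)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df_res
  se <- sqrt(sigma2 * diag(chol2inv(chol(crossprod(design)))))
  b <- fit$coefficients
  wald <- (b / se)^2
  out <- data.frame(term = colnames(design), b = unname(b), se = unname(se),
                    wald = unname(wald),
                    p = unname(pchisq(wald, df = 1, lower.tail = FALSE)),
                    row.names = NULL, stringsAsFactors = FALSE)
  # Gaussian log-likelihood at the MLE variance rss/n
  attr(out, "loglik") <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  attr(out, "n") <- n
  class(out) <- c("glm_result", "data.frame")
  out
}

#' A-priori glutamate model: IL-9 and TNF-alpha
#'
#' Convenience wrapper fitting the pre-specified model of glutamate
#' concentration on the two cytokines with prior evidence in bipolar
#' disorder, IL-9 and TNF-alpha, adjusted for the same nuisance covariates as
#' the confirmatory models. Results are identical to calling [fit_glm()] on
#' the corresponding columns.
#'
#' @param data Data frame holding columns `IL-9`, `TNF-a`, `Glu`, and any
#'   requested covariates.
#' @param covariates Character vector of nuisance covariate column names
#'   present in `data` (may be empty).
#' @return A `glm_result` from [fit_glm()].
#' @export
step1_glu_model <- function(data, covariates = character()) {
  needed <- c("IL-9", "TNF-a", "Glu", covariates)
  missing_cols <- setdiff(needed, names(data))
  assert_that(length(missing_cols) == 0,
              paste("data missing columns:", paste(missing_cols, collapse = ", ")))
  fit_glm(data[["Glu"]], data[, c("IL-9", "TNF-a"), drop = FALSE],
          if (length(covariates)) data[, covariates, drop = FALSE] else NULL)
}
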