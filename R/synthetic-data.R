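#' Names of the 27-plex immune analyte panel
#'
#' Cytokines, chemokines and growth factors of the multiplex bead assay:
#' 16 cytokines (IL-1b ... TNF-a), 6 chemokines (CCL2 ... CXCL10) and
#' 5 growth factors (bFGF ... VEGF). ASCII spellings are used throughout
#' (`IL-1b` for IL-1beta, `IFN-g` for IFN-gamma, `TNF-a` for TNF-alpha,
#' `PDGF-b` for PDGF-beta).
#'
#' @return Character vector of 27 analyte names.
#' @export
panel_analytes <- function() {
  c("IL-1b", "IL-1ra", "IL-2", "IL-4", "IL-5", "IL-6", "IL-7", "IL-8",
    "IL-9", "IL-10", "IL-12", "IL-13", "IL-15", "IL-17", "IFN-g", "TNF-a",
    "CCL2", "CCL3", "CCL4", "CCL5", "CCL11", "CXCL10",
    "bFGF", "G-CSF", "GM-CSF", "PDGF-b", "VEGF")
}

#' Outcome metabolites of the anterior-cingulate voxel
#' @return Character vector: Glu, Glx, NAA, GSH, mI.
#' @export
panel_metabolites <- function() c("Glu", "Glx", "NAA", "GSH", "mI")

default_log_means <- function(analytes) {
  base <- stats::setNames(rep(log(10), length(analytes)), analytes)
  scale_up <- c("IL-1ra" = log(120), "IL-8" = log(25), "CCL2" = log(60),
                "CCL3" = log(15), "CCL4" = log(80), "CCL5" = log(4000),
                "CCL11" = log(90), "CXCL10" = log(500), "bFGF" = log(30),
                "G-CSF" = log(40), "PDGF-b" = log(1500), "VEGF" = log(50),
                "TNF-a" = log(20), "IL-6" = log(6), "IL-1b" = log(4))
  base[names(scale_up)[names(scale_up) %in% analytes]] <-
    scale_up[names(scale_up) %in% analytes]
  base
}

default_effect_map <- function() {
  data.frame(
    analyte    = c("IL-9", "IL-1b", "IL-4", "bFGF", "TNF-a", "CCL4", "CCL5"),
    metabolite = c("Glu",  "mI",    "mI",   "mI",   "GSH",   "GSH",  "NAA"),
    slope      = c(0.06,   0.20,    0.15,   0.02,   0.008,   0.002,  1e-4),
    stringsAsFactors = FALSE)
}

default_covariate_effects <- function() {
  data.frame(
    covariate  = c("age", "n_manic"),
    metabolite = c("mI", "GSH"),
    slope      = c(0.035, 0.02),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated case-control cohort:
#' group sizes, a correlated multivariate log-normal analyte panel with
#' per-analyte limit-of-detection censoring, metabolite outcomes generated
#' from a sparse linear model on (latent, uncensored) analytes plus
#' demographic/clinical covariates plus Gaussian noise, uniform Cramer-Rao
#' lower bounds, and Dirichlet voxel tissue composition. The defaults emulate
#' a cohort of 63 bipolar-disorder inpatients and 49 healthy controls, with
#' the patients older on average and with more females, four heavily censored
#' analytes, and sparse analyte effects on mI, GSH, NAA and Glu.
#'
#' @param n_bd,n_hc Group sizes (patients, controls).
#' @param analyte_names Analyte panel (default [panel_analytes()]).
#' @param analyte_log_mean,analyte_log_sd Named log-scale means/SDs of the
#'   log-normal analyte marginals.
#' @param analyte_corr Log-scale correlation matrix (symmetric positive
#'   definite, unit diagonal). Default exchangeable with rho = 0.3.
#' @param lod_quantile_per_analyte Per-analyte censoring quantile in `[0, 1)`:
#'   the LOD is placed at this quantile of the analyte's marginal, so it is
#'   also the expected non-detected fraction.
#' @param effect_map Data frame (analyte, metabolite, slope): sparse true
#'   effects on the concentration scale.
#' @param covariate_effects Data frame (covariate, metabolite, slope).
#' @param noise_sd_per_metabolite Named residual SDs.
#' @param baseline_bd,baseline_hc Named per-metabolite group offsets.
#' @param crlb_range Interval (percent) for uniform CRLB draws.
#' @param tissue_dirichlet_means GM/WM/CSF mean percentages (sum 100).
#' @param tissue_concentration Dirichlet concentration (larger = tighter).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_bd = 63, n_hc = 49,
                       analyte_names = panel_analytes(),
                       analyte_log_mean = default_log_means(analyte_names),
                       analyte_log_sd = stats::setNames(
                         rep(0.6, length(analyte_names)), analyte_names),
                       analyte_corr = NULL,
                       lod_quantile_per_analyte = NULL,
                       effect_map = default_effect_map(),
                       covariate_effects = default_covariate_effects(),
                       noise_sd_per_metabolite = c(Glu = 1.0, Glx = 1.25,
                                                   NAA = 0.48, GSH = 0.21,
                                                   mI = 0.90),
                       baseline_bd = c(Glu = 8.11, Glx = 9.90, NAA = 6.62,
                                       GSH = 1.70, mI = 5.24),
                       baseline_hc = c(Glu = 7.68, Glx = 9.20, NAA = 7.14,
                                       GSH = 1.54, mI = 4.29),
                       crlb_range = c(2, 15),
                       tissue_dirichlet_means = c(gm = 21, wm = 77.5, csf = 1.5),
                       tissue_concentration = 30,
                       seed = 1L) {
  p <- length(analyte_names)
  if (is.null(analyte_corr)) {
    analyte_corr <- matrix(0.3, p, p,
                           dimnames = list(analyte_names, analyte_names))
    diag(analyte_corr) <- 1
  }
  if (is.null(lod_quantile_per_analyte)) {
    lod_quantile_per_analyte <- stats::setNames(rep(0.05, p), analyte_names)
    heavy <- intersect(c("IL-10", "IL-15", "GM-CSF", "VEGF"), analyte_names)
    lod_quantile_per_analyte[heavy] <- 0.35
  }
  cfg <- structure(
    list(n_bd = n_bd, n_hc = n_hc, analyte_names = analyte_names,
         analyte_log_mean = analyte_log_mean[analyte_names],
         analyte_log_sd = analyte_log_sd[analyte_names],
         analyte_corr = analyte_corr,
         lod_quantile_per_analyte = lod_quantile_per_analyte[analyte_names],
         effect_map = effect_map, covariate_effects = covariate_effects,
         noise_sd_per_metabolite = noise_sd_per_metabolite,
         baseline_bd = baseline_bd, baseline_hc = baseline_hc,
         crlb_range = crlb_range,
         tissue_dirichlet_means = tissue_dirichlet_means,
         tissue_concentration = tissue_concentration,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  p <- length(cfg$analyte_names)
  C <- cfg$analyte_corr
  assert_that(is.matrix(C) && all(dim(C) == p), "analyte_corr has wrong shape")
  assert_that(max(abs(C - t(C))) < 1e-12, "analyte_corr must be symmetric")
  assert_that(max(abs(diag(C) - 1)) < 1e-12,
              "analyte_corr must have unit diagonal")
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("analyte_corr is not positive definite (smallest eigenvalue ",
         signif(ev, 3), ")", call. = FALSE)
  assert_that(all(cfg$analyte_log_sd > 0), "analyte log SDs must be positive")
  assert_that(all(cfg$noise_sd_per_metabolite >= 0),
              "noise SDs must be non-negative")
  q <- cfg$lod_quantile_per_analyte
  assert_that(all(q >= 0 & q < 1), "lod quantiles must lie in [0, 1)")
  tm <- cfg$tissue_dirichlet_means
  assert_that(all(tm > 0) && abs(sum(tm) - 100) < 1e-9,
              "tissue means must be positive and sum to 100")
  metab <- names(cfg$baseline_bd)
  assert_that(all(cfg$effect_map$analyte %in% cfg$analyte_names) &&
                all(cfg$effect_map$metabolite %in% metab),
              "effect_map keys must be analyte x metabolite pairs")
  invisible(cfg)
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  pmin(pmax(rnorm(n, mean, sd), lower), upper)
}

#' Generate a synthetic cohort
#'
#' Draws a full seeded cohort under a [sim_config()]: demographics and
#' clinical covariates (patients older and more often female than controls by
#' construction, mirroring the real-world confounding this analysis must
#' adjust for), a correlated log-normal analyte panel with limit-of-detection
#' censoring, metabolite concentrations from the configured sparse linear
#' model, uniform CRLBs, and Dirichlet voxel tissue percentages summing to
#' 100. Identical seeds give identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `subjects` (data frame),
#'   `panel` ([analyte_panel()]), `metabolites` (long data frame),
#'   `ground_truth` (true effect maps plus latent uncensored analyte matrix),
#'   and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_bd + cfg$n_hc
  id <- sprintf("S%03d", seq_len(n))
  group <- c(rep("BD", cfg$n_bd), rep("HC", cfg$n_hc))
  bd <- group == "BD"

  age <- numeric(n)
  age[bd] <- rtruncnorm1(cfg$n_bd, 46.81, 11.94, 18, 65)
  age[!bd] <- rtruncnorm1(cfg$n_hc, 33.70, 11.14, 18, 65)
  sex <- ifelse(rbinom(n, 1, ifelse(bd, 46 / 63, 21 / 49)) == 1, "F", "M")

  onset <- numeric(n)
  onset[bd] <- pmin(rtruncnorm1(cfg$n_bd, 29.01, 11.15, 14, 60), age[bd] - 1)
  n_depressive <- ifelse(bd, stats::rnbinom(n, mu = 6.24, size = 2), 0)
  n_manic <- ifelse(bd, stats::rnbinom(n, mu = 3.54, size = 1.5), 0)
  bmi <- rtruncnorm1(n, 26.25, 5.34, 16, 45)
  on_lithium <- bd & rbinom(n, 1, 32 / 63) == 1
  lithium <- ifelse(on_lithium, round(runif(n, 0.4, 1.0), 2), 0)
  hdrs <- ifelse(bd, round(pmax(rnorm(n, 16.86, 9.24), 0)), 0)

  subjects <- data.frame(subject_id = id, group = group, age = age, sex = sex,
                         onset = onset, n_depressive = n_depressive,
                         n_manic = n_manic, bmi = bmi, lithium = lithium,
                         hdrs = hdrs, stringsAsFactors = FALSE)

  # analyte panel: multivariate log-normal, then LOD censoring at the
  # configured marginal quantile
  p <- length(cfg$analyte_names)
  D <- diag(cfg$analyte_log_sd, p)
  Sigma <- D %*% cfg$analyte_corr %*% D
  Z <- MASS::mvrnorm(n, mu = cfg$analyte_log_mean, Sigma = Sigma)
  latent <- exp(Z)
  dimnames(latent) <- list(id, cfg$analyte_names)
  lod <- qlnorm(cfg$lod_quantile_per_analyte, cfg$analyte_log_mean,
                cfg$analyte_log_sd)
  names(lod) <- cfg$analyte_names
  nd_mask <- sweep(latent, 2, lod, "<")
  observed <- latent
  observed[nd_mask] <- NA_real_
  panel <- analyte_panel(observed, nd_mask, lod, subject_id = id)

  # metabolites from the sparse linear model on latent analytes + covariates
  metab <- names(cfg$baseline_bd)
  covariate_values <- cbind(age = age, sex = as.numeric(sex == "F"),
                            onset = onset, n_depressive = n_depressive,
                            n_manic = n_manic, bmi = bmi, lithium = lithium,
                            hdrs = hdrs)
  conc <- matrix(0, n, length(metab), dimnames = list(id, metab))
  for (m in metab) {
    mu <- ifelse(bd, cfg$baseline_bd[[m]], cfg$baseline_hc[[m]])
    em <- cfg$effect_map[cfg$effect_map$metabolite == m, , drop = FALSE]
    for (k in seq_len(nrow(em)))
      mu <- mu + em$slope[k] * latent[, em$analyte[k]]
    ce <- cfg$covariate_effects[cfg$covariate_effects$metabolite == m, ,
                                drop = FALSE]
    for (k in seq_len(nrow(ce)))
      mu <- mu + ce$slope[k] * covariate_values[, ce$covariate[k]]
    conc[, m] <- mu + rnorm(n, 0, cfg$noise_sd_per_metabolite[[m]])
  }

  # voxel tissue composition: scaled Dirichlet, exact sum 100
  shape <- cfg$tissue_concentration * cfg$tissue_dirichlet_means / 100
  g <- cbind(rgamma(n, shape[1]), rgamma(n, shape[2]), rgamma(n, shape[3]))
  tissue <- 100 * g / rowSums(g)

  crlb <- matrix(runif(n * length(metab), cfg$crlb_range[1], cfg$crlb_range[2]),
                 n, length(metab))
  metabolites <- data.frame(
    subject_id = rep(id, times = length(metab)),
    metabolite = rep(metab, each = n),
    raw_conc = as.vector(conc),
    crlb_pct = as.vector(crlb),
    gm_pct = rep(tissue[, 1], times = length(metab)),
    wm_pct = rep(tissue[, 2], times = length(metab)),
    csf_pct = rep(tissue[, 3], times = length(metab)),
    stringsAsFactors = FALSE)

  ground_truth <- list(true_effect_map = cfg$effect_map,
                       true_covariate_effects = cfg$covariate_effects,
                       latent_analytes = latent, lod = lod,
                       seed = cfg$seed)
  structure(list(subjects = subjects, panel = panel,
                 metabolites = metabolites, ground_truth = ground_truth,
                 config = cfg),
            class = "sim_cohort")
}
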