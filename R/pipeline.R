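#' Pipeline configuration
#'
#' Bundles every threshold and path of the end-to-end analysis. Defaults are
#' the analysis design values: analytes excluded above 20% non-detected,
#' metabolite fits kept below 20% CRLB, VIP selection at 0.75 with 5-fold
#' cross-validation inside each bootstrap resample.
#'
#' @param input_dir Directory holding `subjects.csv`, `analytes.csv`,
#'   `analyte_lod.csv`, `metabolites.csv` (see [write_fixture()]).
#' @param output_dir Directory for result files (created if needed).
#' @param enet An [enet_config()] for the stability-selection stage.
#' @param nd_threshold Non-detected fraction above which an analyte is
#'   excluded.
#' @param crlb_threshold CRLB reliability cutoff in percent.
#' @param covariates Nuisance covariate names; `sex` is coded F = 1, M = 0 and
#'   `n_episodes` is derived as depressive + manic episode counts.
#' @param outcomes Metabolites modeled by stability selection.
#' @param fdr_level Nominal false-discovery-rate level (reporting only).
#' @param seed Master seed; per-outcome stability seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            enet = enet_config(),
                            nd_threshold = 0.20, crlb_threshold = 20,
                            covariates = c("age", "sex", "onset",
                                           "n_episodes", "bmi", "lithium"),
                            outcomes = c("mI", "NAA", "GSH"),
                            fdr_level = 0.05, seed = 1L) {
  structure(list(input_dir = input_dir, output_dir = output_dir, enet = enet,
                 nd_threshold = nd_threshold, crlb_threshold = crlb_threshold,
                 covariates = covariates, outcomes = outcomes,
                 fdr_level = fdr_level, seed = as.integer(seed)),
            class = "pipeline_config")
}

covariate_matrix <- function(subjects, covariates) {
  cols <- list()
  for (cv in covariates) {
    cols[[cv]] <- switch(cv,
      sex = as.numeric(subjects$sex == "F"),
      n_episodes = subjects$n_depressive + subjects$n_manic,
      {
        assert_that(cv %in% names(subjects),
                    paste("unknown covariate:", cv))
        as.numeric(subjects[[cv]])
      })
  }
  do.call(cbind, cols)
}

metabolite_wide <- function(met, subjects, value = "corrected_conc",
                            reliable_only = TRUE) {
  metabs <- unique(met$metabolite)
  out <- matrix(NA_real_, nrow(subjects), length(metabs),
                dimnames = list(subjects$subject_id, metabs))
  use <- if (reliable_only && "reliable" %in% names(met)) met$reliable else TRUE
  m <- met[use, , drop = FALSE]
  out[cbind(match(m$subject_id, subjects$subject_id),
            match(m$metabolite, metabs))] <- m[[value]]
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in order: analyte limit-of-detection QC ([nd_exclusion()]); CSF
#' partial-volume correction and CRLB filtering ([correct_metabolites()]);
#' group comparisons (pooled t for continuous rows, chi-square for sex, and
#' age/sex-adjusted ANCOVAs for metabolites) with Benjamini-Hochberg q-values;
#' metabolite-clinical Pearson correlations; the a-priori IL-9/TNF-a model of
#' glutamate; one bootstrap stability selection per outcome metabolite; and a
#' confirmatory GLM on the VIP survivors of each outcome. Writes
#' `group_stats.csv`, `correlations.csv`, `stability_results.csv`,
#' `lambda_trace.csv`, `glm_results.csv` and a `manifest.json` echoing the
#' configuration, seed, versions and per-stage row counts (the manifest
#' carries no timestamps, so reruns under one seed are byte-identical).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate and final table.
#' @export
run_pipeline <- function(config) {
  cohort <- read_fixture(config$input_dir)
  subjects <- cohort$subjects
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  message("sex coded F = 1, M = 0 in all adjusted models")
  message("note: min-max normalization is fitted once on the full sample ",
          "before bootstrap resampling")

  # stage 1: analyte QC
  panel <- nd_exclusion(cohort$panel, config$nd_threshold)
  X_all <- panel_matrix(panel)

  # stage 2: metabolite correction + reliability
  met <- correct_metabolites(cohort$metabolites, config$crlb_threshold)
  conc <- metabolite_wide(met, subjects)
  metabs <- colnames(conc)

  # stage 3: univariate layer
  bd <- subjects$group == "BD"
  grp_rows <- list()
  add_row <- function(label, res, mean_bd = NA, sd_bd = NA,
                      mean_hc = NA, sd_hc = NA) {
    grp_rows[[length(grp_rows) + 1]] <<- cbind(
      data.frame(label = label, mean_bd = mean_bd, sd_bd = sd_bd,
                 mean_hc = mean_hc, sd_hc = sd_hc),
      res[, c("stat_name", "statistic", "df", "p")])
  }
  cont_row <- function(label, x) {
    a <- x[bd & !is.na(x)]; h <- x[!bd & !is.na(x)]
    add_row(label, pooled_t(a, h, label = label),
            mean(a), sd(a), mean(h), sd(h))
  }
  cont_row("age", subjects$age)
  sex_tab <- table(factor(subjects$group, c("BD", "HC")),
                   factor(subjects$sex, c("M", "F")))
  add_row("sex", chi_square_2x2(sex_tab[1, 1], sex_tab[1, 2],
                                sex_tab[2, 1], sex_tab[2, 2]))
  first <- met[met$metabolite == metabs[1], ]
  ord <- match(subjects$subject_id, first$subject_id)
  cont_row("gray_matter", first$gm_pct[ord])
  cont_row("white_matter", first$wm_pct[ord])
  cont_row("csf", first$csf_pct[ord])
  for (m in metabs) cont_row(m, conc[, m])
  group_stats <- do.call(rbind, grp_rows)
  group_stats$q <- fdr_adjust(group_stats$p)

  # age/sex-adjusted group effects, FDR-corrected across metabolites
  adj_rows <- lapply(metabs, function(m) {
    ok <- !is.na(conc[, m])
    res <- ancova_group_effect(conc[ok, m], subjects$group[ok],
                               cbind(age = subjects$age,
                                     sex = as.numeric(subjects$sex == "F"))[ok, ],
                               label = m)
    res
  })
  ancova_stats <- do.call(rbind, adj_rows)
  ancova_stats$q <- fdr_adjust(ancova_stats$p)

  # metabolite vs clinical correlations (within-BD for illness variables)
  clin_all <- c("age", "bmi")
  clin_bd <- c("onset", "n_depressive", "n_manic", "hdrs", "lithium")
  cor_rows <- list()
  for (m in metabs) {
    y <- conc[, m]
    for (v in clin_all) {
      ok <- !is.na(y)
      if (sd(subjects[[v]][ok]) > 0)
        cor_rows[[length(cor_rows) + 1]] <-
          cbind(metabolite = m, variable = v,
                pearson_r(subjects[[v]][ok], y[ok])[
                  , c("statistic", "df", "p")])
    }
    for (v in clin_bd) {
      ok <- bd & !is.na(y)
      if (sum(ok) >= 3 && sd(subjects[[v]][ok]) > 0 && sd(y[ok]) > 0)
        cor_rows[[length(cor_rows) + 1]] <-
          cbind(metabolite = m, variable = v,
                pearson_r(subjects[[v]][ok], y[ok])[
                  , c("statistic", "df", "p")])
    }
  }
  correlations <- do.call(rbind, cor_rows)
  names(correlations)[names(correlations) == "statistic"] <- "r"
  correlations$q <- fdr_adjust(correlations$p)

  # stage 4: a-priori glutamate model (IL-9, TNF-a)
  covar <- covariate_matrix(subjects, config$covariates)
  glm_rows <- list()
  if (all(c("IL-9", "TNF-a") %in% colnames(X_all)) && "Glu" %in% metabs) {
    ok <- !is.na(conc[, "Glu"])
    dat <- cbind(as.data.frame(X_all[ok, c("IL-9", "TNF-a"), drop = FALSE],
                               check.names = FALSE),
                 Glu = conc[ok, "Glu"],
                 as.data.frame(covar[ok, , drop = FALSE]))
    res <- step1_glu_model(dat, covariates = colnames(covar))
    glm_rows[["Glu"]] <- cbind(outcome = "Glu", as.data.frame(res))
  } else {
    warning("IL-9/TNF-a or Glu unavailable after QC; a-priori model skipped",
            call. = FALSE)
  }

  # stage 5: stability selection per outcome metabolite
  stab_results <- list()
  lambda_trace <- list()
  stab_objects <- list()
  for (i in seq_along(config$outcomes)) {
    m <- config$outcomes[i]
    assert_that(m %in% metabs, paste("outcome metabolite missing:", m))
    ok <- !is.na(conc[, m])
    Xn <- minmax_normalize(X_all[ok, , drop = FALSE])$x
    Zn <- minmax_normalize(covar[ok, , drop = FALSE])$x
    cfg <- config$enet
    cfg$seed <- config$seed + i
    res <- bootstrap_vip(Xn, conc[ok, m], nuisance = Zn, config = cfg)
    stab_objects[[m]] <- res
    stab_results[[m]] <- cbind(outcome = m, res$summary)
    lambda_trace[[m]] <- data.frame(outcome = m,
                                    bootstrap = seq_along(res$lambda),
                                    lambda = res$lambda)
  }
  stability_results <- do.call(rbind, stab_results)
  lambda_trace <- do.call(rbind, lambda_trace)

  # stage 6: confirmatory GLMs on survivors (raw predictor scale)
  for (m in config$outcomes) {
    survivors <- threshold_vip(stab_objects[[m]],
                               config$enet$vip_threshold)
    if (length(survivors) == 0) {
      message("no predictors selected for ", m)
      glm_rows[[m]] <- data.frame(outcome = m, term = "(none selected)",
                                  b = NA_real_, se = NA_real_,
                                  wald = NA_real_, p = NA_real_)
      next
    }
    ok <- !is.na(conc[, m])
    res <- fit_glm(conc[ok, m], X_all[ok, survivors, drop = FALSE],
                   covar[ok, , drop = FALSE])
    glm_rows[[m]] <- cbind(outcome = m, as.data.frame(res))
  }
  glm_results <- do.call(rbind, c(glm_rows, list(make.row.names = FALSE)))

  # outputs + manifest
  paths <- file.path(config$output_dir,
                     c("group_stats.csv", "correlations.csv",
                       "stability_results.csv", "lambda_trace.csv",
                       "glm_results.csv", "ancova_stats.csv"))
  write_plain_csv(group_stats, paths[1])
  write_plain_csv(correlations, paths[2])
  write_plain_csv(stability_results, paths[3])
  write_plain_csv(lambda_trace, paths[4])
  write_plain_csv(glm_results, paths[5])
  write_plain_csv(ancova_stats, paths[6])

  manifest <- list(
    package = "cytomet",
    package_version = as.character(packageVersion("cytomet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(nd_threshold = config$nd_threshold,
                      crlb_threshold = config$crlb_threshold,
                      vip_threshold = config$enet$vip_threshold,
                      fdr_level = config$fdr_level),
    enet = unclass(config$enet),
    covariates = config$covariates,
    outcomes = config$outcomes,
    stage_counts = list(
      subjects_in = nrow(subjects),
      analytes_in = ncol(cohort$panel$values),
      analytes_excluded_nd = length(panel$exclusions),
      analytes_retained = sum(panel$retained),
      metabolite_records_in = nrow(cohort$metabolites),
      metabolite_records_reliable = sum(met$reliable),
      subjects_per_outcome = as.list(
        setNames(as.integer(colSums(!is.na(conc))[config$outcomes]),
                 config$outcomes))),
    excluded_analytes = panel$exclusions)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(subjects = subjects, panel = panel, metabolites = met,
                 concentrations = conc, group_stats = group_stats,
                 ancova_stats = ancova_stats, correlations = correlations,
                 stability = stab_objects,
                 stability_results = stability_results,
                 lambda_trace = lambda_trace, glm_results = glm_results,
                 manifest = manifest))
}

#' Write the demonstration fixture
#'
#' Generates and writes the default synthetic cohort: 63 patients + 49
#' controls, the 27-analyte panel with four heavily censored analytes
#' (IL-10, IL-15, GM-CSF, VEGF), and sparse true analyte effects on mI, GSH,
#' NAA and Glu.
#'
#' @param seed Integer seed.
#' @param directory Target directory.
#' @return Invisibly, the generated `sim_cohort`.
#' @export
make_demo <- function(seed = 1L, directory) {
  cohort <- generate_cohort(sim_config(seed = seed))
  write_fixture(cohort, directory)
  invisible(cohort)
}
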