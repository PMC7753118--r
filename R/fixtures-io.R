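# Delimited-text fixture layer. Numeric cells are written with %.17g so
# doubles round-trip exactly; an empty analyte cell means non-detected.

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

write_plain_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }), check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

#' Write a synthetic cohort to a fixture directory
#'
#' Serializes a [generate_cohort()] result as plain delimited text:
#' `subjects.csv`, `analytes.csv` (one column per analyte, empty cell =
#' non-detected), `analyte_lod.csv`, `metabolites.csv`, and a
#' `ground_truth.json` sidecar holding the true sparse effect map, covariate
#' effects and the latent (uncensored) analyte matrix. Values round-trip
#' losslessly through [read_fixture()], and identical seeds produce
#' byte-identical files.
#'
#' @param cohort A `sim_cohort` from [generate_cohort()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(cohort, directory) {
  assert_that(inherits(cohort, "sim_cohort"),
              "cohort must come from generate_cohort()")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(directory), paste("cannot create", directory))
  paths <- file.path(directory, c("subjects.csv", "analytes.csv",
                                  "analyte_lod.csv", "metabolites.csv",
                                  "ground_truth.json"))
  names(paths) <- c("subjects", "analytes", "lod", "metabolites",
                    "ground_truth")

  write_plain_csv(cohort$subjects, paths["subjects"])

  panel <- cohort$panel
  adf <- cbind(data.frame(subject_id = panel$subject_id,
                          stringsAsFactors = FALSE),
               as.data.frame(panel$values, check.names = FALSE))
  write_plain_csv(adf, paths["analytes"])
  write_plain_csv(data.frame(analyte = names(panel$lod),
                             lod = unname(panel$lod),
                             stringsAsFactors = FALSE), paths["lod"])
  write_plain_csv(cohort$metabolites, paths["metabolites"])

  gt <- cohort$ground_truth
  gt_json <- list(
    true_effect_map = gt$true_effect_map,
    true_covariate_effects = gt$true_covariate_effects,
    lod = as.list(gt$lod),
    seed = gt$seed,
    subject_id = rownames(gt$latent_analytes),
    analyte = colnames(gt$latent_analytes),
    latent_analytes = unname(as.data.frame(gt$latent_analytes)))
  jsonlite::write_json(gt_json, paths["ground_truth"], digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a fixture directory back into cohort tables
#'
#' Inverse of [write_fixture()]. The analyte non-detected mask is
#' reconstructed from empty cells.
#'
#' @param directory Directory written by [write_fixture()].
#' @return A list of class `sim_cohort` (without the generating `config`):
#'   `subjects`, `panel`, `metabolites`, `ground_truth`.
#' @export
read_fixture <- function(directory) {
  need <- file.path(directory, c("subjects.csv", "analytes.csv",
                                 "analyte_lod.csv", "metabolites.csv"))
  missing <- need[!file.exists(need)]
  assert_that(length(missing) == 0,
              paste("fixture files missing:", paste(missing, collapse = ", ")))
  subjects <- read.csv(need[1], check.names = FALSE, stringsAsFactors = FALSE)
  adf <- read.csv(need[2], check.names = FALSE, stringsAsFactors = FALSE)
  lod_df <- read.csv(need[3], check.names = FALSE, stringsAsFactors = FALSE)
  metabolites <- read.csv(need[4], check.names = FALSE,
                          stringsAsFactors = FALSE)

  values <- as.matrix(adf[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- adf$subject_id
  nd_mask <- is.na(values)
  lod <- stats::setNames(lod_df$lod, lod_df$analyte)
  panel <- analyte_panel(values, nd_mask, lod, subject_id = adf$subject_id)

  gt_path <- file.path(directory, "ground_truth.json")
  ground_truth <- NULL
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    latent <- as.matrix(gt$latent_analytes)
    dimnames(latent) <- list(gt$subject_id, gt$analyte)
    ground_truth <- list(true_effect_map = gt$true_effect_map,
                         true_covariate_effects = gt$true_covariate_effects,
                         latent_analytes = latent,
                         lod = unlist(gt$lod), seed = gt$seed)
  }
  structure(list(subjects = subjects, panel = panel,
                 metabolites = metabolites, ground_truth = ground_truth),
            class = "sim_cohort")
}
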