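#' CSF fraction of a spectroscopy voxel
#'
#' Computes the fraction of the voxel occupied by cerebrospinal fluid from
#' tissue-segmentation outputs: `fCSF = CSF / (GM + WM + CSF)`. Inputs may be
#' on any common scale (percentages summing to ~100 or fractions summing to
#' ~1); the ratio is scale-invariant.
#'
#' @param gm_pct,wm_pct,csf_pct Non-negative gray-matter, white-matter and
#'   CSF contents of the voxel. Vectorized.
#' @return CSF fraction(s) in `[0, 1]`.
#' @examples
#' csf_fraction(21.06, 77.45, 1.44)
#' @export
csf_fraction <- function(gm_pct, wm_pct, csf_pct) {
  if (any(gm_pct < 0 | wm_pct < 0 | csf_pct < 0, na.rm = TRUE))
    stop("tissue contents must be non-negative", call. = FALSE)
  total <- gm_pct + wm_pct + csf_pct
  if (any(total <= 0, na.rm = TRUE))
    stop("CSF fraction undefined: GM + WM + CSF is zero for at least one voxel",
         call. = FALSE)
  csf_pct / total
}

#' CSF partial-volume correction of a metabolite concentration
#'
#' Rescales a water-referenced metabolite concentration to the tissue
#' compartment of the voxel: `corrected = raw / (1 - fCSF)`. With no CSF in
#' the voxel the concentration is unchanged; the correction grows strictly
#' with the CSF fraction.
#'
#' @param raw_conc Non-negative concentration (institutional units). Vectorized.
#' @param fcsf CSF fraction(s) in `[0, 1)`, e.g. from [csf_fraction()].
#' @return Corrected concentration(s), always `>= raw_conc`.
#' @examples
#' correct_concentration(7.68, csf_fraction(21.06, 77.45, 1.44))
#' @export
correct_concentration <- function(raw_conc, fcsf) {
  if (any(raw_conc < 0, na.rm = TRUE))
    stop("raw_conc must be non-negative", call. = FALSE)
  if (any(fcsf < 0 | fcsf >= 1, na.rm = TRUE))
    stop("fcsf must lie in [0, 1): correction divides by 1 - fcsf", call. = FALSE)
  raw_conc / (1 - fcsf)
}

#' Reliability filter on Cramer-Rao lower bounds
#'
#' Flags metabolite quantifications as reliable when the reported
#' Cramer-Rao lower bound is strictly below `threshold_pct`. Records at or
#' above the threshold (or with a missing CRLB) are retained but flagged, so
#' downstream statistics can exclude them without silently losing rows.
#'
#' @param records Data frame with a `crlb_pct` column (percent).
#' @param threshold_pct Reliability cutoff in percent; default 20.
#' @return `records` with a logical `reliable` column added/overwritten.
#' @export
crlb_filter <- function(records, threshold_pct = 20) {
  assert_that(is.data.frame(records) && "crlb_pct" %in% names(records),
              "records must be a data frame with a 'crlb_pct' column")
  crlb <- records$crlb_pct
  if (any(is.na(crlb))) {
    warning(sprintf("%d record(s) with missing CRLB flagged unreliable",
                    sum(is.na(crlb))), call. = FALSE)
  }
  if (any(crlb < 0, na.rm = TRUE))
    stop("crlb_pct must be non-negative", call. = FALSE)
  records$reliable <- !is.na(crlb) & crlb < threshold_pct
  records
}

#' Apply CSF correction and CRLB filtering to a metabolite table
#'
#' Convenience wrapper over [csf_fraction()], [correct_concentration()] and
#' [crlb_filter()] for the long-format metabolite schema
#' (`subject_id, metabolite, raw_conc, crlb_pct, gm_pct, wm_pct, csf_pct`).
#' Tissue columns are auto-detected as percentages (rows summing near 100) or
#' fractions (summing near 1); the ratio is the same either way, and the
#' detected convention is reported via `message()`.
#'
#' @param metabolites Data frame in the schema above.
#' @param crlb_threshold_pct CRLB reliability cutoff in percent.
#' @return The table with `fcsf`, `corrected_conc` and `reliable` columns added.
#' @export
correct_metabolites <- function(metabolites, crlb_threshold_pct = 20) {
  needed <- c("subject_id", "metabolite", "raw_conc", "crlb_pct",
              "gm_pct", "wm_pct", "csf_pct")
  missing_cols <- setdiff(needed, names(metabolites))
  assert_that(length(missing_cols) == 0,
              paste("metabolite table missing columns:",
                    paste(missing_cols, collapse = ", ")))
  sums <- metabolites$gm_pct + metabolites$wm_pct + metabolites$csf_pct
  convention <- if (stats::median(sums, na.rm = TRUE) > 50) "percentages" else "fractions"
  message("tissue columns interpreted as ", convention,
          " (median voxel sum ", signif(stats::median(sums, na.rm = TRUE), 4), ")")
  metabolites$fcsf <- csf_fraction(metabolites$gm_pct, metabolites$wm_pct,
                                   metabolites$csf_pct)
  metabolites$corrected_conc <- correct_concentration(metabolites$raw_conc,
                                                      metabolites$fcsf)
  crlb_filter(metabolites, crlb_threshold_pct)
}
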