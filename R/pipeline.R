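#' Assemble a validated pipeline run configuration
#'
#' Every fixed analysis constant lives here, in one audited place: the
#' pathologist-purity floor (0.30), the minimum biopsy-site stratum size
#' (50), the variant allele-frequency floor (0.05), the TMB-high cutoff
#' (10 mut/Mb), the minimum TMB-high/TMB-low cell count (10), the paired
#' biopsy window (90 days) and the significance level (0.05).
#'
#' @param specimens path to a specimen table or an in-memory data.frame.
#' @param site_map path to a site map or a named vector / data.frame.
#' @param variants optional path or data.frame of variant calls; when TMB
#'   scores are absent from the specimen table they are computed from here.
#' @param met_records optional path or data.frame of metastasis records;
#'   enables the metastasis-controlled and paired analyses.
#' @param panel_mb effective panel size (Mb) for TMB scoring.
#' @param min_purity,min_stratum,af_threshold,cutoff,min_cell,window_days,alpha
#'   analysis thresholds (defaults above).
#' @param adjust p-value adjustment for site contrasts (`"none"` or a
#'   `stats::p.adjust` method).
#' @param out_dir output directory for result tables and the manifest;
#'   `NULL` returns results in memory only.
#' @return list of class `run_config`.
#' @export
run_config <- function(specimens, site_map, variants = NULL,
                       met_records = NULL, panel_mb = 1.1,
                       min_purity = 0.30, min_stratum = 50,
                       af_threshold = 0.05, cutoff = 10, min_cell = 10,
                       window_days = 90, alpha = 0.05, adjust = "none",
                       out_dir = NULL) {
  chk <- function(x, name, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || x < lo || x > hi)
      stop(sprintf("run_config: `%s` must be a number in [%g, %g]",
                   name, lo, hi))
  }
  chk(min_purity, "min_purity", 0, 1)
  chk(af_threshold, "af_threshold", 0, 1)
  chk(alpha, "alpha", 0, 1)
  chk(min_stratum, "min_stratum", 0, Inf)
  chk(cutoff, "cutoff", 0, Inf)
  chk(min_cell, "min_cell", 0, Inf)
  chk(window_days, "window_days", 0, Inf)
  chk(panel_mb, "panel_mb", 1e-9, Inf)
  structure(list(specimens = specimens, site_map = site_map,
                 variants = variants, met_records = met_records,
                 panel_mb = panel_mb, min_purity = min_purity,
                 min_stratum = min_stratum, af_threshold = af_threshold,
                 cutoff = cutoff, min_cell = min_cell,
                 window_days = window_days, alpha = alpha, adjust = adjust,
                 out_dir = out_dir), class = "run_config")
}

.load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full biopsy-site analysis pipeline
#'
#' Executes, in order: specimen selection (latest specimen per patient,
#' purity filter, small-stratum drop, primary-site flagging), optional TMB
#' scoring from variants, per-cancer continuous models with re-gridded
#' site contrasts, the dichotomous TMB-high analysis, the biopsy-site
#' distribution, and — when metastasis records are supplied — the
#' metastasis-controlled contrasts and the paired within-patient test for
#' the most frequent qualifying site pair. Identical configuration and
#' inputs give identical outputs.
#'
#' @param config a [run_config()].
#' @return list with `cohort` (filtered specimens), `contrasts`,
#'   `dichotomous`, `site_distribution`, `met_controlled`, `paired`,
#'   and `manifest` (thresholds and CONSORT-style filter counts). When
#'   `out_dir` is set, result tables are written as tab-separated text and
#'   the manifest as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  specimens <- .load_input(config$specimens, read_specimen_table)
  site_map <- if (is.character(config$site_map) &&
                  length(config$site_map) == 1L)
    read_site_map(config$site_map) else as_site_map(config$site_map)
  variants <- .load_input(config$variants, read_variant_table)
  met_records <- .load_input(config$met_records, read_met_records)

  if ((is.null(specimens$tmb) || all(is.na(specimens$tmb))) &&
      !is.null(variants)) {
    sc <- score_tmb_all(variants, panel_mb = config$panel_mb,
                        af_threshold = config$af_threshold)
    specimens$tmb <- sc$tmb[match(specimens$specimen_id, sc$specimen_id)]
    specimens$tmb[is.na(specimens$tmb)] <- 0
  }

  all_specimens <- specimens  # pre-deduplication set, for the paired analysis
  sel <- select_cohort(specimens, site_map, min_purity = config$min_purity,
                       min_n = config$min_stratum)
  cohort <- sel$specimens

  contrasts <- suppressMessages(
    run_all(cohort, site_map, alpha = config$alpha, adjust = config$adjust))
  counts <- tabulate_high(cohort, cutoff = config$cutoff)
  dich <- compare_sites(counts, reference_site = as_site_map(site_map),
                        min_cell = config$min_cell, alpha = config$alpha)
  dist <- site_distribution(cohort)

  met_controlled <- NULL
  paired <- NULL
  if (!is.null(met_records)) {
    met_controlled <- suppressMessages(
      run_met_controlled(cohort, met_records, site_map,
                         alpha = config$alpha))
    pairs <- find_biopsy_pairs(all_specimens,
                               window_days = config$window_days)
    if (nrow(pairs)) {
      key <- paste(pairs$site_a, pairs$site_b, sep = " / ")
      topkey <- names(sort(table(key), decreasing = TRUE))[1]
      top <- pairs[key == topkey, , drop = FALSE]
      paired <- c(list(site_pair = topkey, pairs = nrow(top)),
                  paired_site_test(top))
    }
  }

  manifest <- list(
    dialect = "tmbsite v1",
    thresholds = config[c("panel_mb", "min_purity", "min_stratum",
                          "af_threshold", "cutoff", "min_cell",
                          "window_days", "alpha", "adjust")],
    filter_counts = as.list(sel$counts),
    n_cancer_types = length(unique(cohort$cancer_type)),
    n_patients = length(unique(cohort$patient_id))
  )

  res <- list(cohort = cohort, contrasts = contrasts, dichotomous = dich,
              site_distribution = dist, met_controlled = met_controlled,
              paired = paired, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(x, nm) if (!is.null(x))
      .write_dialect(x, file.path(config$out_dir, paste0(nm, ".tsv")), nm)
    out(cohort, "cohort")
    out(contrasts, "contrasts")
    out(dich, "dichotomous")
    out(dist, "site_distribution")
    out(met_controlled, "met_controlled")
    jsonlite::write_json(
      c(manifest, list(paired = paired[!vapply(paired, is.data.frame,
                                               logical(1))])),
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  }
  res
}
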