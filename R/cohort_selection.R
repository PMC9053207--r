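#' Keep each patient's most recently collected specimen
#'
#' When a patient has several specimens, the one with the latest collection
#' date is retained. Date ties are broken deterministically by the
#' lexicographically smallest `specimen_id`.
#'
#' @param specimens specimen table (see [read_specimen_table()] for the
#'   dialect); `collection_date` must be present on every row.
#' @return specimen table with at most one row per patient, a subset of the
#'   input rows.
#' @export
select_latest_specimen <- function(specimens) {
  if (nrow(specimens) == 0L) return(specimens)
  if (any(is.na(specimens$collection_date)))
    stop("collection_date missing on some specimens")
  # latest date first; equal (patient, date) broken by smallest specimen_id
  ord <- order(specimens$patient_id,
               -as.integer(as.Date(specimens$collection_date)),
               specimens$specimen_id, method = "radix")
  s <- specimens[ord, , drop = FALSE]
  s[!duplicated(s$patient_id), , drop = FALSE]
}

#' Apply the tumor-purity quality filter
#'
#' Retains specimens whose pathologist-estimated tumor purity is at least
#' `min_purity` (inclusive: 30% purity passes the default filter). The
#' pathologist estimate is used because specimen adequacy is assessed by
#' pathologist review; switch `purity_var` to use the computational
#' estimate instead.
#'
#' @param specimens specimen table.
#' @param min_purity minimum tumor purity fraction (default 0.30).
#' @param purity_var which purity column the rule applies to.
#' @return filtered specimen table; the number of removed specimens is
#'   reported via `message()`.
#' @export
apply_quality_filters <- function(specimens, min_purity = 0.30,
                                  purity_var = c("purity_pathologist",
                                                 "purity_computational")) {
  purity_var <- match.arg(purity_var)
  if (nrow(specimens) == 0L) return(specimens)
  keep <- specimens[[purity_var]] >= min_purity
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("apply_quality_filters: removed %d specimen(s) with %s < %g",
                    n_drop, purity_var, min_purity))
  specimens[keep, , drop = FALSE]
}

#' Drop small biopsy-site strata
#'
#' Within each cancer type independently, removes all specimens whose
#' biopsy-site stratum holds fewer than `min_n` specimens (a stratum of
#' exactly `min_n` is kept). Strata are counted on the table as passed in,
#' i.e. after any preceding filters.
#'
#' @param specimens specimen table.
#' @param min_n minimum stratum size (default 50).
#' @return filtered specimen table.
#' @export
drop_small_strata <- function(specimens, min_n = 50) {
  if (nrow(specimens) == 0L) return(specimens)
  key <- paste(specimens$cancer_type, specimens$biopsy_site, sep = "\r")
  counts <- table(key)
  specimens[counts[key] >= min_n, , drop = FALSE]
}

#' Flag specimens biopsied at their cancer's primary site
#'
#' Sets `is_primary_site` to `TRUE` exactly where the biopsy site equals
#' the curated primary/reference site for that cancer type.
#'
#' @param specimens specimen table.
#' @param site_map named character vector or two-column data.frame
#'   (`cancer_type`, `primary_site`) mapping every cancer type present to
#'   its reference site.
#' @return specimen table with `is_primary_site` recomputed.
#' @export
assign_primary_flag <- function(specimens, site_map) {
  site_map <- as_site_map(site_map)
  missing_ct <- setdiff(unique(specimens$cancer_type), names(site_map))
  if (length(missing_ct))
    stop("site map lacks cancer type(s): ", paste(missing_ct, collapse = ", "))
  specimens$is_primary_site <-
    specimens$biopsy_site == unname(site_map[specimens$cancer_type])
  specimens
}

#' @noRd
as_site_map <- function(site_map) {
  if (is.data.frame(site_map)) {
    if (!all(c("cancer_type", "primary_site") %in% names(site_map)))
      stop("site map data.frame needs columns cancer_type, primary_site")
    site_map <- setNames(site_map$primary_site, site_map$cancer_type)
  }
  if (is.null(names(site_map)) || anyDuplicated(names(site_map)))
    stop("site map must be uniquely named by cancer type")
  site_map
}

#' Run the full specimen-selection pipeline
#'
#' Applies, in this frozen order: latest specimen per patient, then the
#' purity filter, then the small-stratum drop, then primary-site flagging.
#' The order matters (stratum counts are taken after deduplication and
#' purity filtering) and is therefore fixed and tested.
#'
#' @inheritParams apply_quality_filters
#' @inheritParams drop_small_strata
#' @inheritParams assign_primary_flag
#' @return list with the filtered `specimens` and a `counts` vector of
#'   specimen numbers after each step (for CONSORT-style audit).
#' @export
select_cohort <- function(specimens, site_map, min_purity = 0.30,
                          min_n = 50) {
  counts <- c(input = nrow(specimens))
  specimens <- select_latest_specimen(specimens)
  counts["latest_specimen"] <- nrow(specimens)
  specimens <- suppressMessages(
    apply_quality_filters(specimens, min_purity = min_purity))
  counts["purity_filter"] <- nrow(specimens)
  specimens <- drop_small_strata(specimens, min_n = min_n)
  counts["stratum_filter"] <- nrow(specimens)
  specimens <- assign_primary_flag(specimens, site_map)
  list(specimens = specimens, counts = counts)
}
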