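#' Score tumor mutational burden from variant calls
#'
#' TMB is the count of somatic nonsynonymous mutations per megabase of
#' sequenced coding territory. Variants with allele frequency below
#' `af_threshold` are treated as noise and excluded; the threshold is
#' inclusive (AF exactly at the threshold counts).
#'
#' @param variants data.frame of calls for ONE specimen with columns
#'   `allele_frequency` (fraction in \[0,1\]), `functional_class`
#'   (`"nonsynonymous"`, `"synonymous"` or other) and `somatic_status`
#'   (`"somatic"`, `"germline"` or `"unknown"`). A `specimen_id` column, if
#'   present, must be constant.
#' @param panel_mb effective panel size in megabases (> 0), the denominator.
#'   Panels differ in coding territory, so this is a required input.
#' @param af_threshold minimum allele frequency for a call to count
#'   (default 0.05).
#' @return TMB score in mut/Mb (>= 0); an empty variant list scores 0.
#' @export
#' @examples
#' v <- data.frame(allele_frequency = c(0.3, 0.04),
#'                 functional_class = "nonsynonymous",
#'                 somatic_status = "somatic")
#' score_tmb(v, panel_mb = 1.1)  # only the AF 0.3 call counts
score_tmb <- function(variants, panel_mb, af_threshold = 0.05) {
  if (!is.numeric(panel_mb) || length(panel_mb) != 1L || panel_mb <= 0)
    stop("panel_mb must be a single positive number")
  if (is.null(variants) || nrow(variants) == 0L) return(0)
  if ("specimen_id" %in% names(variants) &&
      length(unique(variants$specimen_id)) > 1L)
    stop("variants from multiple specimens passed to score_tmb; ",
         "score one specimen at a time")
  if (any(variants$allele_frequency < 0 | variants$allele_frequency > 1))
    stop("allele_frequency must lie in [0, 1]")
  n <- sum(variants$somatic_status == "somatic" &
             variants$functional_class == "nonsynonymous" &
             variants$allele_frequency >= af_threshold)
  n / panel_mb
}

#' Score TMB for every specimen in a variant table
#'
#' @param variants variant table with a `specimen_id` column (the
#'   [generate_cohort()] / [read_variant_table()] dialect).
#' @inheritParams score_tmb
#' @return data.frame with `specimen_id` and `tmb`.
#' @export
score_tmb_all <- function(variants, panel_mb, af_threshold = 0.05) {
  sids <- unique(variants$specimen_id)
  tmb <- vapply(split(variants, factor(variants$specimen_id, levels = sids)),
                score_tmb, numeric(1),
                panel_mb = panel_mb, af_threshold = af_threshold)
  data.frame(specimen_id = sids, tmb = unname(tmb), stringsAsFactors = FALSE)
}

#' Classify a TMB score against the clinical TMB-high cutoff
#'
#' The pan-tumor clinical threshold is 10 mut/Mb, inclusive: a score of
#' exactly 10 is TMB-high.
#'
#' @param score TMB score(s) in mut/Mb, >= 0.
#' @param cutoff TMB-high cutoff in mut/Mb (default 10).
#' @return character vector, `"high"` or `"low"`.
#' @export
classify_tmb_high <- function(score, cutoff = 10) {
  if (any(score < 0)) stop("TMB score must be >= 0")
  ifelse(score >= cutoff, "high", "low")
}
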