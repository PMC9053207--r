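#' Tabulate TMB-high counts per cancer type and biopsy site
#'
#' Counts, within each (cancer type, biopsy site) stratum, how many
#' specimens are TMB-high (score >= `cutoff`, inclusive) and the stratum
#' total. Empty strata do not appear.
#'
#' @param specimens filtered specimen table.
#' @param cutoff TMB-high cutoff in mut/Mb (default 10).
#' @return data.frame with `cancer_type`, `site`, `n_high`, `n_total`.
#' @export
tabulate_high <- function(specimens, cutoff = 10) {
  if (nrow(specimens) == 0L)
    return(data.frame(cancer_type = character(), site = character(),
                      n_high = integer(), n_total = integer()))
  high <- classify_tmb_high(specimens$tmb, cutoff = cutoff) == "high"
  agg <- stats::aggregate(
    cbind(n_high = high, n_total = rep(1L, length(high))),
    by = list(cancer_type = specimens$cancer_type,
              site = specimens$biopsy_site),
    FUN = sum)
  agg$n_high <- as.integer(agg$n_high)
  agg$n_total <- as.integer(agg$n_total)
  agg[order(agg$cancer_type, agg$site), , drop = FALSE]
}

# Woolf (log-scale normal) CI for the cross-product odds ratio
.woolf_ci <- function(a, b, c, d, alpha) {
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  lor <- log((a * d) / (b * c))
  exp(c(lor - z * se, lor + z * se))
}

#' Compare TMB-high fractions between sites and the reference site
#'
#' For each cancer type and non-reference site: the percentage-point
#' difference in TMB-high fraction, the cross-product odds ratio with a
#' Woolf (log-scale) confidence interval, and a Pearson chi-square test on
#' the 2x2 table (no continuity correction unless `correct = TRUE`).
#' Comparisons where either tissue of the pair has fewer than `min_cell`
#' TMB-high or fewer than `min_cell` TMB-low specimens are skipped: the
#' row is returned with `skipped = TRUE` and the inferential fields `NA`.
#'
#' @param counts a [tabulate_high()] table.
#' @param reference_site reference site label; either a single label or a
#'   named vector per cancer type (a primary-site map).
#' @param min_cell minimum TMB-high and TMB-low count per tissue
#'   (default 10).
#' @param alpha confidence level for the OR interval is `1 - alpha`.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return data.frame with one row per (cancer type, site):
#'   `pct_site`, `pct_reference`, `pct_difference` (percentage points),
#'   `odds_ratio`, `or_ci_low`, `or_ci_high`, `p_value`, `skipped`,
#'   `skip_reason`. A zero cell leaves the odds ratio `NA` with
#'   `skip_reason = "zero_cell"` (no continuity fudge).
#' @export
compare_sites <- function(counts, reference_site, min_cell = 10,
                          alpha = 0.05, correct = FALSE) {
  ref_map <- if (is.null(names(reference_site)))
    setNames(rep(reference_site, length(unique(counts$cancer_type))),
             unique(counts$cancer_type)) else reference_site
  rows <- list()
  for (ct in unique(counts$cancer_type)) {
    tab <- counts[counts$cancer_type == ct, , drop = FALSE]
    ref <- unname(ref_map[ct])
    if (!ref %in% tab$site)
      stop(sprintf("reference site %s absent for cancer type %s", ref, ct))
    rtab <- tab[tab$site == ref, ]
    m_high <- rtab$n_high; m_low <- rtab$n_total - rtab$n_high
    for (j in which(tab$site != ref)) {
      n_high <- tab$n_high[j]; n_low <- tab$n_total[j] - tab$n_high[j]
      res <- data.frame(
        cancer_type = ct, site = tab$site[j], reference_site = ref,
        pct_site = 100 * n_high / tab$n_total[j],
        pct_reference = 100 * m_high / rtab$n_total,
        pct_difference = 100 * (n_high / tab$n_total[j] -
                                  m_high / rtab$n_total),
        odds_ratio = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
        p_value = NA_real_, skipped = FALSE, skip_reason = NA_character_,
        stringsAsFactors = FALSE)
      if (min(n_high, n_low, m_high, m_low) < min_cell) {
        res$skipped <- TRUE
        res$skip_reason <- "min_cell"
      } else if (min(n_high, n_low, m_high, m_low) == 0L) {
        res$skip_reason <- "zero_cell"  # OR undefined; no continuity fudge
      } else {
        res$odds_ratio <- (n_high * m_low) / (n_low * m_high)
        ci <- .woolf_ci(n_high, n_low, m_high, m_low, alpha)
        res$or_ci_low <- ci[1]; res$or_ci_high <- ci[2]
        m22 <- matrix(c(n_high, n_low, m_high, m_low), nrow = 2,
                      byrow = TRUE)
        res$p_value <- suppressWarnings(
          chisq.test(m22, correct = correct)$p.value)
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of biopsy sites within each cancer type
#'
#' Counts and percentages of specimens per biopsy site, where percentages
#' are of the cancer type's total (they sum to 100 within rounding).
#'
#' @param specimens specimen table.
#' @return data.frame with `cancer_type`, `site`, `n`, `pct`.
#' @export
site_distribution <- function(specimens) {
  if (nrow(specimens) == 0L)
    return(data.frame(cancer_type = character(), site = character(),
                      n = integer(), pct = numeric()))
  agg <- stats::aggregate(
    list(n = rep(1L, nrow(specimens))),
    by = list(cancer_type = specimens$cancer_type,
              site = specimens$biopsy_site),
    FUN = sum)
  tot <- tapply(agg$n, agg$cancer_type, sum)
  agg$pct <- 100 * agg$n / as.vector(tot[agg$cancer_type])
  agg <- agg[order(agg$cancer_type, -agg$n), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
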