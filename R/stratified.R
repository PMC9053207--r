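#' Restrict a comparison to metastasis-documented primary patients
#'
#' For the comparison of one metastatic target site against the primary
#' site, keeps (i) every specimen biopsied at `target_site` and (ii)
#' primary-site specimens only for patients with a metastasis record at
#' `target_site` dated strictly before the specimen's collection date.
#' This removes primary-biopsy patients with no documented metastasis at
#' the compared site, the imbalance that can confound unrestricted
#' site-versus-primary contrasts.
#'
#' @param specimens specimen table for one cancer type, with
#'   `is_primary_site` set (see [assign_primary_flag()]).
#' @param met_records data.frame `patient_id`, `site`, `record_date`.
#' @param target_site metastatic site being compared.
#' @return subset of `specimens`.
#' @export
filter_by_met_history <- function(specimens, met_records, target_site) {
  at_target <- specimens$biopsy_site == target_site
  mr <- met_records[met_records$site == target_site, , drop = FALSE]
  ok_primary <- specimens$is_primary_site & vapply(
    seq_len(nrow(specimens)), function(i) {
      if (!specimens$is_primary_site[i]) return(FALSE)
      dates <- mr$record_date[mr$patient_id == specimens$patient_id[i]]
      any(as.Date(dates) < as.Date(specimens$collection_date[i]))
    }, logical(1))
  specimens[at_target | ok_primary, , drop = FALSE]
}

#' Metastasis-controlled site contrasts
#'
#' For each requested (cancer type, target site) pair: restrict the
#' stratum with [filter_by_met_history()], then run the usual model chain
#' ([fit_site_model()] on the two remaining sites, reference grid,
#' response re-grid, contrast against the primary site). Strata failing
#' model preconditions are skipped with the reason recorded in the
#' `"skipped"` attribute.
#'
#' @param specimens filtered cohort.
#' @param met_records metastasis-history records.
#' @param site_map primary-site map (see [assign_primary_flag()]).
#' @param target_sites named list: cancer type -> character vector of
#'   metastatic sites to test; defaults to every non-primary site present.
#' @param alpha,covariates see [emm_contrasts()] / [fit_site_model()].
#' @return contrast data.frame, one row per (cancer type, target site).
#' @export
run_met_controlled <- function(specimens, met_records, site_map,
                               target_sites = NULL, alpha = 0.05,
                               covariates = c("median_coverage",
                                              "purity_pathologist",
                                              "purity_computational")) {
  site_map <- as_site_map(site_map)
  specimens <- assign_primary_flag(specimens, site_map)
  rows <- list(); skipped <- list()
  for (ct in unique(specimens$cancer_type)) {
    stratum <- specimens[specimens$cancer_type == ct, , drop = FALSE]
    ref <- unname(site_map[ct])
    targets <- if (!is.null(target_sites)) target_sites[[ct]] else
      setdiff(unique(stratum$biopsy_site), ref)
    for (ts in targets) {
      res <- tryCatch({
        sub <- filter_by_met_history(stratum, met_records, ts)
        sub <- sub[sub$biopsy_site %in% c(ts, ref), , drop = FALSE]
        if (!any(sub$is_primary_site))
          stop("no eligible primary patients for target site ", ts)
        fit <- fit_site_model(sub, covariates = covariates)
        ctr <- emm_contrasts(regrid_response(reference_grid(fit)),
                             reference_site = ref, alpha = alpha)
        ctr[ctr$site == ts, , drop = FALSE]
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(cancer_type = ct, site = ts, reason = res)
      } else {
        rows[[length(rows) + 1L]] <- cbind(cancer_type = ct, res)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (length(skipped)) {
    sk <- do.call(rbind, skipped)
    for (i in seq_len(nrow(sk)))
      message(sprintf("run_met_controlled: skipped %s/%s: %s",
                      sk$cancer_type[i], sk$site[i], sk$reason[i]))
    if (!is.null(out)) attr(out, "skipped") <- sk
  }
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out
}

#' Find within-patient biopsy pairs from different sites
#'
#' Scans the pre-deduplication specimen table (patients may contribute
#' several specimens) for patients with two biopsies from *different*
#' sites collected at most `window_days` apart (inclusive: a 90-day gap
#' qualifies under the default window). For each patient and unordered
#' site pair, the qualifying combination with the smallest gap is emitted
#' (ties broken by earliest collection dates). Site labels within a pair
#' are ordered alphabetically (`site_a < site_b`).
#'
#' @param specimens specimen table (multiple rows per patient allowed).
#' @param window_days maximum days between the two collections
#'   (default 90).
#' @param sites optional length-2 character vector restricting pairs to
#'   one specific site pair (e.g. `c("lung", "brain")`).
#' @return data.frame `patient_id`, `site_a`, `site_b`, `tmb_a`, `tmb_b`,
#'   `gap_days`.
#' @export
find_biopsy_pairs <- function(specimens, window_days = 90, sites = NULL) {
  empty <- data.frame(patient_id = character(), site_a = character(),
                      site_b = character(), tmb_a = numeric(),
                      tmb_b = numeric(), gap_days = integer())
  if (nrow(specimens) == 0L) return(empty)
  if (!is.null(sites)) {
    stopifnot(length(sites) == 2L)
    specimens <- specimens[specimens$biopsy_site %in% sites, , drop = FALSE]
  }
  rows <- list()
  for (sub in split(specimens, specimens$patient_id)) {
    if (nrow(sub) < 2L || length(unique(sub$biopsy_site)) < 2L) next
    # deterministic scan order regardless of input row order
    sub <- sub[order(as.Date(sub$collection_date), sub$specimen_id), ,
               drop = FALSE]
    cmb <- utils::combn(nrow(sub), 2)
    best <- list()
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      if (sub$biopsy_site[i] == sub$biopsy_site[j]) next
      gap <- abs(as.integer(as.Date(sub$collection_date[j]) -
                              as.Date(sub$collection_date[i])))
      if (gap > window_days) next
      ord <- order(c(sub$biopsy_site[i], sub$biopsy_site[j]))
      ii <- c(i, j)[ord]
      key <- paste(sub$biopsy_site[ii], collapse = "\r")
      if (is.null(best[[key]]) || gap < best[[key]]$gap_days) {
        best[[key]] <- data.frame(
          patient_id = sub$patient_id[1],
          site_a = sub$biopsy_site[ii[1]], site_b = sub$biopsy_site[ii[2]],
          tmb_a = sub$tmb[ii[1]], tmb_b = sub$tmb[ii[2]],
          gap_days = gap, stringsAsFactors = FALSE)
      }
    }
    rows <- c(rows, unname(best[sort(names(best))]))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$site_a, out$site_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact paired test of TMB between two biopsy sites
#'
#' Wilcoxon signed-rank test on `tmb_a - tmb_b`, two-sided. Zero
#' differences are dropped and ties receive mid-ranks. For `n <= max_exact`
#' remaining pairs the null distribution of the positive-rank sum is
#' enumerated exactly over all `2^n` sign assignments (via its
#' generating-function convolution — required because small paired designs,
#' e.g. 9 lung/brain pairs, demand an exact small-sample test); larger n
#' uses the normal approximation with tie correction. A paired t-test on
#' `log(tmb + 1)` is available via `method = "t"`.
#'
#' @param pairs a [find_biopsy_pairs()] table (needs `tmb_a`, `tmb_b`).
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @param max_exact largest n for exact enumeration (default 25).
#' @return list with `statistic`, `p_value`, `n` (pairs used), `method`,
#'   and `reason` (non-`NA` when no test could be run: fewer than 2
#'   non-zero differences).
#' @export
paired_site_test <- function(pairs, method = c("wilcoxon", "t"),
                             max_exact = 25) {
  method <- match.arg(method)
  d <- pairs$tmb_a - pairs$tmb_b
  if (method == "t") {
    ld <- log(pairs$tmb_a + 1) - log(pairs$tmb_b + 1)
    if (length(ld) < 2L || all(ld == 0) || stats::sd(ld) == 0)
      return(list(statistic = NA_real_, p_value = NA_real_,
                  n = length(ld), method = method,
                  reason = "need >= 2 pairs with variation"))
    tt <- stats::t.test(ld)
    return(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                n = length(ld), method = method, reason = NA_character_))
  }
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L)
    return(list(statistic = NA_real_, p_value = NA_real_, n = n,
                method = method, reason = "need >= 2 non-zero differences"))
  r <- rank(abs(d))  # mid-ranks for tied magnitudes
  w <- sum(r[d > 0])
  if (n <= max_exact) {
    p <- .signed_rank_exact_p(r, w)
  } else {
    mu <- sum(r) / 2
    sig <- sqrt(sum(r^2) / 4)
    p <- min(1, 2 * pnorm(-abs(w - mu) / sig))
  }
  list(statistic = w, p_value = p, n = n, method = method,
       reason = NA_character_)
}

# exact two-sided p for the positive-rank sum: distribution of W over all
# 2^n sign assignments by convolution on doubled (integer) ranks
.signed_rank_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))  # mid-ranks are multiples of 1/2
  counts <- c(1)                      # counts[k+1] = #assignments with sum k
  for (r in r2) {
    shifted <- c(numeric(r), counts)
    counts <- c(counts, numeric(r)) + shifted
  }
  support <- seq_along(counts) - 1
  mu2 <- sum(r2) / 2                  # distribution symmetric about mu2
  dev <- abs(2 * w - mu2)
  sum(counts[abs(support - mu2) >= dev - 1e-9]) / 2^length(r2)
}
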