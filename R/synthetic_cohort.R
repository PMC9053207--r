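#' Build a synthetic cohort configuration
#'
#' Bundles and validates everything [generate_cohort()] needs to emit a
#' reproducible synthetic clinico-genomic cohort: per-cancer, per-site
#' log-normal TMB with additive site shifts on the log(TMB+1) scale,
#' coverage and purity covariates entering the same linear predictor,
#' multiple specimens per patient, and dated metastasis records.
#'
#' @param site_effects data.frame with columns `cancer_type`, `site`,
#'   `is_primary` (logical), `delta_log` (additive shift on the log(TMB+1)
#'   scale; 0 for the primary site by convention) and `n_specimens`
#'   (patients contributing their latest specimen at that site). Exactly one
#'   site per cancer type must have `is_primary = TRUE`.
#' @param mu_log baseline mean of log(TMB+1) at the primary site; either a
#'   single number or a named vector, one entry per cancer type.
#' @param sigma_log residual standard deviation on the log scale (> 0).
#' @param beta_coverage,beta_purity_path,beta_purity_comp covariate
#'   coefficients on the log(TMB+1) scale per standardized covariate unit.
#'   Coverage is standardized to z-scores inside the generator; purities are
#'   drawn uniform on `purity_range` and standardized by the uniform's
#'   theoretical mean and sd, so all betas are per-sd effects and the
#'   marginal site means are unchanged by the covariates.
#' @param coverage_mean,coverage_sd median-coverage distribution (reads);
#'   defaults emulate a high-quality targeted panel (~500x).
#' @param purity_range interval in \[0,1\] for both tumor-purity estimates;
#'   the default lower bound 0.20 guarantees some specimens fall below the
#'   0.30 purity filter so downstream QC is exercised.
#' @param met_prob probability a patient additionally carries an unrelated
#'   ("noise") dated metastasis record.
#' @param multi_specimen_prob probability a patient contributes a second,
#'   strictly earlier specimen (exercises latest-specimen deduplication).
#' @param panel_mb effective panel size in megabases used when synthesizing
#'   variant lists (number of qualifying variants = round(TMB * panel_mb)).
#' @param seed integer seed; equal configs give byte-identical cohorts.
#'
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(
#'   site_effects = data.frame(
#'     cancer_type = "NSCLC", site = c("lung", "brain"),
#'     is_primary = c(TRUE, FALSE), delta_log = c(0, 0.4),
#'     n_specimens = c(100, 60)),
#'   mu_log = 2, sigma_log = 0.6, seed = 1)
#' cohort <- generate_cohort(cfg)
#' head(cohort$specimens)
cohort_config <- function(site_effects,
                          mu_log,
                          sigma_log,
                          beta_coverage = 0,
                          beta_purity_path = 0,
                          beta_purity_comp = 0,
                          coverage_mean = 500,
                          coverage_sd = 75,
                          purity_range = c(0.20, 1.00),
                          met_prob = 0.15,
                          multi_specimen_prob = 0.10,
                          panel_mb = 1.1,
                          seed = 1L) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort_config field `%s`: %s", field, msg),
         call. = FALSE)
  }
  if (!is.data.frame(site_effects))
    stop_field("site_effects", "must be a data.frame")
  need <- c("cancer_type", "site", "is_primary", "delta_log", "n_specimens")
  miss <- setdiff(need, names(site_effects))
  if (length(miss))
    stop_field("site_effects", paste("missing columns:",
                                     paste(miss, collapse = ", ")))
  if (any(site_effects$n_specimens < 0))
    stop_field("site_effects", "n_specimens must be >= 0")
  for (ct in unique(site_effects$cancer_type)) {
    rows <- site_effects[site_effects$cancer_type == ct, ]
    if (sum(rows$is_primary) != 1L)
      stop_field("site_effects",
                 sprintf("cancer type %s must have exactly one primary site", ct))
    if (any(rows$delta_log[rows$is_primary] != 0))
      stop_field("site_effects",
                 sprintf("primary-site delta_log must be 0 (cancer type %s)", ct))
    if (anyDuplicated(rows$site))
      stop_field("site_effects",
                 sprintf("duplicated site within cancer type %s", ct))
  }
  cts <- unique(site_effects$cancer_type)
  if (length(mu_log) == 1L && is.null(names(mu_log)))
    mu_log <- setNames(rep(as.numeric(mu_log), length(cts)), cts)
  if (!all(cts %in% names(mu_log)))
    stop_field("mu_log", "must be scalar or named for every cancer type")
  if (!is.numeric(sigma_log) || length(sigma_log) != 1L || sigma_log <= 0)
    stop_field("sigma_log", "must be a single positive number")
  if (length(purity_range) != 2L || any(purity_range < 0) ||
      any(purity_range > 1) || purity_range[1] >= purity_range[2])
    stop_field("purity_range", "must be an increasing interval within [0,1]")
  for (p in c("met_prob", "multi_specimen_prob")) {
    v <- get(p)
    if (!is.numeric(v) || v < 0 || v > 1) stop_field(p, "must be in [0,1]")
  }
  if (coverage_sd < 0) stop_field("coverage_sd", "must be >= 0")
  if (panel_mb <= 0) stop_field("panel_mb", "must be > 0")
  structure(list(
    site_effects = site_effects[need],
    mu_log = mu_log[cts],
    sigma_log = sigma_log,
    beta_coverage = beta_coverage,
    beta_purity_path = beta_purity_path,
    beta_purity_comp = beta_purity_comp,
    coverage_mean = coverage_mean,
    coverage_sd = coverage_sd,
    purity_range = purity_range,
    met_prob = met_prob,
    multi_specimen_prob = multi_specimen_prob,
    panel_mb = panel_mb,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# standardized-uniform helper: z-score of a U(a,b) draw
.std_unif <- function(x, range) {
  (x - mean(range)) / (diff(range) / sqrt(12))
}

#' Generate a synthetic clinico-genomic cohort
#'
#' Draws, per configured (cancer type, site) stratum, one "index" specimen
#' per patient with TMB `max(exp(mu_log + delta_log + covariate terms +
#' Normal(0, sigma_log)) - 1, 0)`, plus (with probability
#' `multi_specimen_prob`) a strictly earlier second specimen, variant lists
#' consistent with each specimen's TMB under the [score_tmb()] rule, and
#' dated metastasis records: every specimen biopsied at a non-primary site
#' contributes a record at that site dated before its collection, and noise
#' records are added with probability `met_prob`.
#'
#' @param config a [cohort_config()].
#' @param with_variants set `FALSE` to skip variant synthesis (the
#'   specimen and metastasis tables are unaffected); useful in
#'   simulation loops that only need TMB scores.
#' @return list with data.frames `specimens` (one row per specimen, the
#'   [read_specimen_table()] dialect), `variants` (per-variant rows with
#'   allele frequency, functional class and somatic status; `NULL` when
#'   `with_variants = FALSE`) and `met_records` (`patient_id`, `site`,
#'   `record_date`).
#' @details Variant synthesis: `round(tmb * panel_mb)` qualifying variants
#'   (somatic, nonsynonymous, AF drawn uniform on \[0.05, 0.60\]) plus
#'   Poisson numbers of sub-threshold (AF in \[0.01, 0.05)), synonymous and
#'   germline decoys, so re-scoring the variants reproduces the stored TMB
#'   up to the `0.5 / panel_mb` rounding granularity. Collection dates span
#'   a five-year window.
#' @export
generate_cohort <- function(config, with_variants = TRUE) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  set.seed(config$seed)
  se <- config$site_effects
  date0 <- as.Date("2016-01-01")
  date_span <- 5L * 365L

  spec_rows <- list()
  met_rows <- list()
  pat_counter <- 0L
  # one specimen batch drawn under the parameters of site_effects row `row`
  draw_specimen <- function(ids, suffix, dates, row) {
    k <- length(ids)
    cov_z <- rnorm(k)
    pp <- runif(k, config$purity_range[1], config$purity_range[2])
    pc <- runif(k, config$purity_range[1], config$purity_range[2])
    eta <- config$mu_log[[se$cancer_type[row]]] + se$delta_log[row] +
      config$beta_coverage * cov_z +
      config$beta_purity_path * .std_unif(pp, config$purity_range) +
      config$beta_purity_comp * .std_unif(pc, config$purity_range) +
      rnorm(k, 0, config$sigma_log)
    data.frame(
      specimen_id = paste0(ids, suffix),
      patient_id = ids,
      cancer_type = se$cancer_type[row],
      biopsy_site = se$site[row],
      collection_date = dates,
      tmb = pmax(exp(eta) - 1, 0),
      purity_pathologist = pp,
      purity_computational = pc,
      median_coverage = config$coverage_mean + config$coverage_sd * cov_z,
      is_primary_site = se$is_primary[row],
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(se))) {
    n <- se$n_specimens[i]
    if (n == 0L) next
    pid <- sprintf("P%06d", pat_counter + seq_len(n))
    pat_counter <- pat_counter + n
    dates <- date0 + sample.int(date_span, n, replace = TRUE)
    spec_rows[[length(spec_rows) + 1L]] <- draw_specimen(pid, "_S1", dates, i)
    # guaranteed metastasis history for metastatic index specimens
    if (!se$is_primary[i]) {
      met_rows[[length(met_rows) + 1L]] <- data.frame(
        patient_id = pid, site = se$site[i],
        record_date = dates - sample(30:365, n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    # a second, strictly earlier specimen from any site of the same cancer
    # (10-200 days back, so some cross-site pairs fall inside 90 days)
    extra <- which(runif(n) < config$multi_specimen_prob)
    if (length(extra)) {
      ct_rows <- which(se$cancer_type == se$cancer_type[i])
      extra_row <- ct_rows[sample.int(length(ct_rows), length(extra),
                                      replace = TRUE)]
      extra_dates <- dates[extra] - sample(10:200, length(extra),
                                           replace = TRUE)
      for (j in unique(extra_row)) {
        sel <- extra_row == j
        spec_rows[[length(spec_rows) + 1L]] <-
          draw_specimen(pid[extra[sel]], "_S0", extra_dates[sel], j)
        if (!se$is_primary[j]) {
          met_rows[[length(met_rows) + 1L]] <- data.frame(
            patient_id = pid[extra[sel]], site = se$site[j],
            record_date = extra_dates[sel] -
              sample(30:365, sum(sel), replace = TRUE),
            stringsAsFactors = FALSE)
        }
      }
    }
    # noise records at a random site, any date in the window
    noisy <- runif(n) < config$met_prob
    if (any(noisy)) {
      met_rows[[length(met_rows) + 1L]] <- data.frame(
        patient_id = pid[noisy],
        site = sample(unique(se$site), sum(noisy), replace = TRUE),
        record_date = date0 + sample.int(date_span, sum(noisy),
                                         replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  specimens <- do.call(rbind, spec_rows)
  rownames(specimens) <- NULL
  met_records <- if (length(met_rows)) do.call(rbind, met_rows) else
    data.frame(patient_id = character(), site = character(),
               record_date = as.Date(character()))
  rownames(met_records) <- NULL
  variants <- if (with_variants)
    .synthesize_variants(specimens, config$panel_mb) else NULL
  list(specimens = specimens, variants = variants, met_records = met_records)
}

# one variant table consistent with each specimen's stored TMB:
# round(tmb * panel_mb) somatic nonsynonymous calls at AF >= 0.05, plus
# sub-threshold / synonymous / germline decoys that the scorer must ignore
.synthesize_variants <- function(specimens, panel_mb) {
  n_qual <- as.integer(round(specimens$tmb * panel_mb))
  n_sub <- stats::rpois(nrow(specimens), 2)
  n_syn <- stats::rpois(nrow(specimens), 2)
  n_germ <- stats::rpois(nrow(specimens), 1)
  total <- n_qual + n_sub + n_syn + n_germ
  sid <- rep(specimens$specimen_id, total)
  af <- numeric(length(sid))
  fclass <- character(length(sid))
  status <- character(length(sid))
  grp <- rep(rep(c("qual", "sub", "syn", "germ"), nrow(specimens)),
             as.vector(rbind(n_qual, n_sub, n_syn, n_germ)))
  af[grp == "qual"] <- runif(sum(grp == "qual"), 0.05, 0.60)
  af[grp == "sub"] <- runif(sum(grp == "sub"), 0.01, 0.0499)
  af[grp == "syn"] <- runif(sum(grp == "syn"), 0.05, 0.60)
  af[grp == "germ"] <- runif(sum(grp == "germ"), 0.30, 0.60)
  fclass[grp %in% c("qual", "sub", "germ")] <- "nonsynonymous"
  fclass[grp == "syn"] <- "synonymous"
  status[grp %in% c("qual", "sub", "syn")] <- "somatic"
  status[grp == "germ"] <- "germline"
  nv <- length(sid)
  data.frame(
    specimen_id = sid,
    chrom = sample(as.character(1:22), nv, replace = TRUE),
    pos = sample.int(5e7L, nv, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
    allele_frequency = af,
    functional_class = fclass,
    somatic_status = status,
    stringsAsFactors = FALSE
  )
}

#' Population values of the re-gridded site contrasts implied by a config
#'
#' For each non-primary site, returns the value to which the re-gridded
#' estimated-marginal-mean contrast of [emm_contrasts()] converges as the
#' stratum grows: `exp(E[log(TMB+1)]) - 1` at that site minus the same
#' quantity at the primary site, with covariates held at their means. With
#' the generator's centered covariates the log-scale marginal mean is
#' `E[max(mu_log + delta_log + Normal(0, sigma_log), 0)]`, evaluated by
#' Monte Carlo over the noise distribution (the flooring of TMB at 0 makes
#' this differ — negligibly for `mu_log >> sigma_log` — from
#' `mu_log + delta_log`).
#'
#' Note this is the population value of the *re-gridded marginal mean*
#' (a geometric-mean-style location), not the arithmetic group mean of TMB,
#' which for a log-normal outcome is larger by a factor
#' `exp(sigma_log^2 / 2)`.
#'
#' @param config a [cohort_config()].
#' @param n_mc Monte-Carlo draws for the noise integral.
#' @return data.frame with `cancer_type`, `site`, `true_diff` (mut/Mb).
#' @export
true_effect_table <- function(config, n_mc = 1e6) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  se <- config$site_effects
  set.seed(config$seed + 1L)  # independent of the cohort draw
  eps <- rnorm(n_mc, 0, config$sigma_log)
  emm_value <- function(mu) exp(mean(pmax(mu + eps, 0))) - 1
  out <- lapply(unique(se$cancer_type), function(ct) {
    rows <- se[se$cancer_type == ct, ]
    ref_val <- emm_value(config$mu_log[[ct]])
    alt <- rows[!rows$is_primary, , drop = FALSE]
    if (!nrow(alt)) return(NULL)
    data.frame(
      cancer_type = ct,
      site = alt$site,
      true_diff = vapply(alt$delta_log, function(d)
        emm_value(config$mu_log[[ct]] + d) - ref_val, numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
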