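spec_row <- function(sid, pid, site, date, tmb = 5, primary = FALSE,
                     ct = "NSCLC") {
  data.frame(specimen_id = sid, patient_id = pid, cancer_type = ct,
             biopsy_site = site, collection_date = as.Date(date), tmb = tmb,
             purity_pathologist = 0.5, purity_computational = 0.5,
             median_coverage = 500, is_primary_site = primary,
             stringsAsFactors = FALSE)
}

met_row <- function(pid, site, date) {
  data.frame(patient_id = pid, site = site,
             record_date = as.Date(date), stringsAsFactors = FALSE)
}

test_that("metastasis-history filter keeps only documented primaries", {
  sp <- rbind(
    spec_row("T1", "P1", "brain", "2019-06-01"),              # target site
    spec_row("L1", "P2", "lung", "2019-06-01", primary = TRUE),
    spec_row("L2", "P3", "lung", "2019-06-01", primary = TRUE),
    spec_row("L3", "P4", "lung", "2019-06-01", primary = TRUE))
  mets <- rbind(
    met_row("P3", "brain", "2019-07-01"),   # after collection: excluded
    met_row("P4", "brain", "2019-05-31"))   # one day before: included
  out <- filter_by_met_history(sp, mets, "brain")
  expect_setequal(out$specimen_id, c("T1", "L3"))
  # target-site specimens pass unchanged; output is a subset of input
  expect_true(all(out$specimen_id %in% sp$specimen_id))
})

test_that("met-controlled contrasts match the unrestricted ones absent confounding", {
  cfg <- two_site_config(n_per_site = 250, delta = 0.4, sigma = 0.5,
                         seed = 61, met_prob = 0.6, multi_specimen_prob = 0)
  co <- generate_cohort(cfg, with_variants = FALSE)
  sp <- assign_primary_flag(co$specimens, c(NSCLC = "lung"))
  unres <- emm_contrasts(regrid_response(reference_grid(
    fit_site_model(sp))), "lung")
  unres <- unres[unres$site == "brain", ]
  mc <- suppressMessages(
    run_met_controlled(sp, co$met_records, c(NSCLC = "lung")))
  # met-bearing primaries share the TMB distribution of the others, so the
  # restricted estimate agrees within joint sampling noise
  expect_lt(abs(mc$estimate - unres$estimate),
            3 * sqrt(mc$se^2 + unres$se^2))
  # no eligible primary patients -> skipped stratum
  none <- suppressMessages(run_met_controlled(
    sp, met_row("nobody", "brain", "2000-01-01"), c(NSCLC = "lung")))
  expect_null(none)
})

test_that("met-history control removes a constructed confounder", {
  # Null site effect, but primaries WITH a prior brain met drawn with
  # elevated TMB: the unrestricted contrast is biased negative, while the
  # met-controlled contrast (which keeps only those primaries) re-centers.
  est_unres <- est_ctrl <- numeric(30)
  for (s in 1:30) {
    set.seed(800 + s)
    n <- 150
    shift <- 0.5
    prim_met <- c(rep(TRUE, n / 2), rep(FALSE, n / 2))
    sp <- rbind(
      spec_row(paste0("B", 1:n), paste0("pb", 1:n), "brain",
               "2019-06-01", tmb = exp(rnorm(n, 2 + shift, 0.5)) - 1),
      spec_row(paste0("L", 1:n), paste0("pl", 1:n), "lung", "2019-06-01",
               tmb = exp(rnorm(n, 2 + shift * prim_met, 0.5)) - 1,
               primary = TRUE))
    mets <- met_row(paste0("pl", which(prim_met)), "brain", "2019-01-01")
    u <- emm_contrasts(regrid_response(reference_grid(
      fit_site_model(sp, covariates = character(0)))), "lung")
    est_unres[s] <- u$estimate[u$site == "brain"]
    m <- suppressMessages(run_met_controlled(
      sp, mets, c(NSCLC = "lung"), covariates = character(0)))
    est_ctrl[s] <- m$estimate
  }
  # unrestricted comparison inflates the brain effect (bias ~ +2.7 mut/Mb);
  # restricting to met-documented primaries removes it (estimate noise per
  # replicate is ~1.2 mut/Mb, so the mean of 30 has se ~ 0.22)
  expect_gt(mean(est_unres), 2)
  expect_lt(abs(mean(est_ctrl)), 1)
})

test_that("biopsy pairs respect the window, distinct sites and minimal gap", {
  sp <- rbind(
    spec_row("A1", "P1", "lung", "2019-01-01"),
    spec_row("A2", "P1", "brain", "2019-04-01"),   # day 90: in
    spec_row("B1", "P2", "lung", "2019-01-01"),
    spec_row("B2", "P2", "brain", "2019-04-02"),   # day 91: out
    spec_row("C1", "P3", "lung", "2019-01-01"),
    spec_row("C2", "P3", "lung", "2019-01-11"))    # same site: out
  pairs <- find_biopsy_pairs(sp, window_days = 90)
  expect_equal(pairs$patient_id, "P1")
  expect_equal(pairs$gap_days, 90L)
  # minimal-gap pair chosen when several qualify
  sp2 <- rbind(
    spec_row("D1", "P4", "lung", "2019-01-01", tmb = 1),
    spec_row("D2", "P4", "brain", "2019-02-15", tmb = 2),
    spec_row("D3", "P4", "brain", "2019-01-10", tmb = 3))
  p2 <- find_biopsy_pairs(sp2)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$gap_days, 9L)
  expect_equal(p2$tmb_a, 3)  # site_a = brain (alphabetical)
  # invariant to input row order
  expect_equal(find_biopsy_pairs(sp2[c(3, 1, 2), ]), p2)
})

test_that("paired test is exact for small n and matches full enumeration", {
  mk_pairs <- function(d) {
    data.frame(patient_id = paste0("P", seq_along(d)), site_a = "brain",
               site_b = "lung", tmb_a = 10 + d, tmb_b = 10,
               gap_days = 1, stringsAsFactors = FALSE)
  }
  # 9 all-positive differences: p = 2 / 2^9
  res <- paired_site_test(mk_pairs(1:9))
  expect_equal(res$p_value, 2 / 512)
  expect_equal(res$p_value, enumerate_signed_rank_p(1:9))
  # perfectly symmetric differences sit at the center: p = 1
  sym <- paired_site_test(mk_pairs(c(3, -3, 5, -5)))
  expect_equal(sym$p_value, 1)
  # single pair / all-zero differences: no test, with reason
  expect_match(paired_site_test(mk_pairs(1))$reason, "2 non-zero")
  expect_match(paired_site_test(mk_pairs(c(0, 0, 0)))$reason, "2 non-zero")
  # random fixtures incl. ties agree with literal 2^n enumeration
  set.seed(55)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)
    expect_equal(paired_site_test(mk_pairs(d))$p_value,
                 enumerate_signed_rank_p(d), tolerance = 1e-12,
                 info = paste("diffs:", paste(d, collapse = ",")))
  }
  # tie-free case agrees with the stats::wilcox.test exact p
  d <- c(1.3, -2.7, 4.1, 5.9, -0.4, 2.2, 7.5, -3.3)
  expect_equal(paired_site_test(mk_pairs(d))$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # paired t alternative runs on the log scale
  tt <- paired_site_test(mk_pairs(1:9), method = "t")
  expect_lt(tt$p_value, 0.01)
})
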