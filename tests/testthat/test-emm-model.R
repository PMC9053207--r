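test_that("two-site no-covariate fit reduces to the difference of group means", {
  sp <- fixture_six()
  fit <- fit_site_model(sp, covariates = character(0))
  y <- log(sp$tmb + 1)
  dm <- mean(y[sp$biopsy_site == "beta"]) - mean(y[sp$biopsy_site == "alpha"])
  expect_equal(unname(fit$coefficients[".fbeta"]), dm, tolerance = 1e-12)
})

test_that("coefficients and covariance match the pseudoinverse oracle", {
  sp <- fixture_six()
  fit <- fit_site_model(sp, covariates = "median_coverage")
  o <- oracle_emm_chain(sp, "median_coverage", "alpha")
  expect_equal(unname(fit$coefficients), unname(o$beta), tolerance = 1e-10)
  expect_equal(unname(fit$covariance), unname(o$Sigma), tolerance = 1e-10)
  expect_equal(fit$residual_df, o$df)
})

test_that("constant response gives zero site effects and zero variance", {
  sp <- fixture_six()
  sp$tmb <- 4
  fit <- fit_site_model(sp, covariates = character(0))
  expect_equal(unname(fit$coefficients[".fbeta"]), 0, tolerance = 1e-12)
  expect_equal(fit$sigma2, 0, tolerance = 1e-20)
})

test_that("model preconditions are enforced", {
  sp <- fixture_six()
  expect_error(fit_site_model(sp[1:3, ]), "at least 2 levels")
  sp$dup <- sp$median_coverage  # aliased column
  expect_error(fit_site_model(sp, covariates = c("median_coverage", "dup")),
               "aliased|rank-deficient")
})

test_that("reference grid fixes covariates at stratum means", {
  sp <- fixture_six()
  fit0 <- fit_site_model(sp, covariates = character(0))
  g0 <- reference_grid(fit0)
  # no covariates: eta are the per-site fitted values
  y <- log(sp$tmb + 1)
  expect_equal(unname(g0$eta),
               c(mean(y[sp$biopsy_site == "alpha"]),
                 mean(y[sp$biopsy_site == "beta"])), tolerance = 1e-12)
  # centered covariate: eta equals intercept (+ site coefficient)
  sp2 <- sp
  sp2$median_coverage <- sp2$median_coverage - mean(sp2$median_coverage)
  fitc <- fit_site_model(sp2, covariates = "median_coverage")
  gc <- reference_grid(fitc)
  expect_equal(unname(gc$eta),
               unname(c(fitc$coefficients["(Intercept)"],
                        fitc$coefficients["(Intercept)"] +
                          fitc$coefficients[".fbeta"])), tolerance = 1e-12)
  # full fixture: eta and eta_cov match the oracle
  fit <- fit_site_model(sp, covariates = "median_coverage")
  g <- reference_grid(fit)
  o <- oracle_emm_chain(sp, "median_coverage", "alpha")
  expect_equal(unname(g$eta), o$eta, tolerance = 1e-10)
  expect_equal(unname(g$eta_cov), unname(o$eta_cov), tolerance = 1e-10)
})

test_that("response re-gridding applies exp(eta)-1 with a delta-method covariance", {
  sp <- fixture_six()
  fit <- fit_site_model(sp, covariates = "median_coverage")
  g <- reference_grid(fit)
  r <- regrid_response(g)
  expect_equal(unname(r$mean), unname(exp(g$eta) - 1), tolerance = 1e-12)
  # eta = log(11) must map to 10 mut/Mb
  expect_equal(exp(log(11)) - 1, 10)
  # covariance matches an independent finite-difference Jacobian oracle
  J <- num_jacobian(function(e) exp(e) - 1, unname(g$eta))
  expect_equal(unname(r$cov), unname(J %*% g$eta_cov %*% t(J)),
               tolerance = 1e-8)
})

test_that("contrast table matches the end-to-end brute-force chain", {
  sp <- fixture_six()
  for (covs in list(character(0), "median_coverage",
                    c("median_coverage", "purity_pathologist",
                      "purity_computational"))) {
    fit <- fit_site_model(sp, covariates = covs)
    ctr <- emm_contrasts(regrid_response(reference_grid(fit)), "alpha")
    o <- oracle_emm_chain(sp, covs, "alpha")
    expect_equal(ctr$estimate, o$estimate, tolerance = 1e-8)
    expect_equal(ctr$ci_low, o$ci_low, tolerance = 1e-8)
    expect_equal(ctr$ci_high, o$ci_high, tolerance = 1e-8)
    expect_equal(ctr$p_value, o$p_value, tolerance = 1e-8)
  }
  # larger random stratum, same agreement
  cfg <- two_site_config(n_per_site = 100, seed = 31, beta_coverage = 0.2)
  sp2 <- generate_cohort(cfg, with_variants = FALSE)$specimens
  sp2 <- select_latest_specimen(sp2)
  covs <- c("median_coverage", "purity_pathologist")
  fit <- fit_site_model(sp2, covariates = covs)
  ctr <- emm_contrasts(regrid_response(reference_grid(fit)), "lung")
  o <- oracle_emm_chain(sp2, covs, "lung")
  expect_equal(ctr$estimate, o$estimate, tolerance = 1e-8)
  expect_equal(ctr$p_value, o$p_value, tolerance = 1e-8)
})

test_that("contrasts agree with the emmeans reference implementation", {
  skip_if_not_installed("emmeans")
  sp <- fixture_six()
  sp$y <- log(sp$tmb + 1)
  sp$site <- factor(sp$biopsy_site)
  fit_lm <- lm(y ~ site + median_coverage, data = sp)
  rg <- update(emmeans::ref_grid(fit_lm),
               tran = emmeans::make.tran("genlog", 1))
  emm <- emmeans::regrid(emmeans::emmeans(rg, "site"), transform = "response")
  ctr_ref <- as.data.frame(emmeans::contrast(emm, "trt.vs.ctrl", ref = "alpha",
                                             infer = c(TRUE, TRUE)))
  fit <- fit_site_model(sp, covariates = "median_coverage")
  ctr <- emm_contrasts(regrid_response(reference_grid(fit)), "alpha")
  beta_row <- ctr[ctr$site == "beta", ]
  expect_equal(beta_row$estimate, ctr_ref$estimate, tolerance = 1e-6)
  expect_equal(beta_row$se, ctr_ref$SE, tolerance = 1e-6)
  expect_equal(beta_row$p_value, ctr_ref$p.value, tolerance = 1e-6)
})

test_that("degenerate deterministic responses give an exact contrast", {
  sp <- fixture_six()
  sp$tmb <- ifelse(sp$biopsy_site == "alpha", 4, 9)
  fit <- fit_site_model(sp, covariates = character(0))
  ctr <- emm_contrasts(regrid_response(reference_grid(fit)), "alpha")
  b <- ctr[ctr$site == "beta", ]
  expect_equal(b$estimate, 5, tolerance = 1e-10)
  expect_equal(b$ci_low, 5, tolerance = 1e-10)   # CI collapses
  expect_equal(b$ci_high, 5, tolerance = 1e-10)
  expect_equal(b$p_value, 0)
  ref <- ctr[ctr$site == "alpha", ]
  expect_equal(ref$estimate, 0)
  expect_equal(ref$p_value, 1)
  expect_error(emm_contrasts(regrid_response(reference_grid(fit)), "gamma"),
               "unknown reference")
})

test_that("contrasts are invariant to covariate centering and site relabeling", {
  cfg <- two_site_config(n_per_site = 80, seed = 41, beta_coverage = 0.2)
  sp <- select_latest_specimen(
    generate_cohort(cfg, with_variants = FALSE)$specimens)
  base <- emm_contrasts(regrid_response(reference_grid(
    fit_site_model(sp, covariates = "median_coverage"))), "lung")
  # shifting a covariate by a constant changes nothing
  sp2 <- sp
  sp2$median_coverage <- sp2$median_coverage + 1000
  shifted <- emm_contrasts(regrid_response(reference_grid(
    fit_site_model(sp2, covariates = "median_coverage"))), "lung")
  expect_equal(shifted$estimate, base$estimate, tolerance = 1e-8)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-8)
  # renaming the non-reference site only renames the row
  sp3 <- sp
  sp3$biopsy_site[sp3$biopsy_site == "brain"] <- "zbrain"
  ren <- emm_contrasts(regrid_response(reference_grid(
    fit_site_model(sp3, covariates = "median_coverage"))), "lung")
  expect_equal(ren$estimate[ren$site == "zbrain"],
               base$estimate[base$site == "brain"], tolerance = 1e-10)
})

test_that("pooled metastatic contrast ignores metastatic site labels", {
  cfg <- cohort_config(
    site_effects = data.frame(
      cancer_type = "bladder", site = c("bladder", "lung", "lymph_node"),
      is_primary = c(TRUE, FALSE, FALSE), delta_log = c(0, -0.3, 0.3),
      n_specimens = c(150, 80, 80)),
    mu_log = 1.8, sigma_log = 0.5, seed = 19, multi_specimen_prob = 0)
  sp <- generate_cohort(cfg, with_variants = FALSE)$specimens
  a <- metastatic_vs_primary(sp)
  sp2 <- sp
  sp2$biopsy_site[!sp2$is_primary_site] <-
    paste0("x_", sp2$biopsy_site[!sp2$is_primary_site])
  b <- metastatic_vs_primary(sp2)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_error(metastatic_vs_primary(sp[sp$is_primary_site, ]),
               "both primary and metastatic")
})

test_that("run_all emits one pooled row plus one row per site level", {
  cfg <- cohort_config(
    site_effects = data.frame(
      cancer_type = "NSCLC", site = c("lung", "brain", "liver"),
      is_primary = c(TRUE, FALSE, FALSE), delta_log = c(0, 0.4, 0.1),
      n_specimens = c(120, 70, 70)),
    mu_log = 2, sigma_log = 0.6, seed = 23, multi_specimen_prob = 0)
  sp <- generate_cohort(cfg, with_variants = FALSE)$specimens
  tab <- suppressMessages(run_all(sp, c(NSCLC = "lung")))
  expect_equal(sum(tab$contrast_type == "pooled"), 1)
  expect_equal(sum(tab$contrast_type == "site"), 3)  # incl. reference row
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})
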