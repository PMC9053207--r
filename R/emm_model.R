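#' Fit the per-cancer-type linear model on log(TMB+1)
#'
#' TMB scores are approximately log-normal, so the model is ordinary least
#' squares of `log(tmb + 1)` on the biopsy-site factor plus quality
#' covariates (median sequencing coverage and the two tumor-purity
#' estimates by default). Each cancer type is fit independently; pass one
#' stratum at a time.
#'
#' @param specimens specimen table for a single cancer type.
#' @param covariates character vector of covariate column names; use
#'   `character(0)` for a site-only model.
#' @param factor_var the factor of interest (default `"biopsy_site"`;
#'   [metastatic_vs_primary()] swaps in a two-level metastatic indicator).
#' @return An object of class `tmb_fit`: the `lm` fit plus the coefficient
#'   vector, its covariance `sigma2 * (X'X)^-1`, residual df, residual
#'   variance, the factor levels and covariate names, and the response
#'   transform (fixed as `g(eta) = exp(eta) - 1`).
#' @export
#' @examples
#' cfg <- cohort_config(
#'   site_effects = data.frame(
#'     cancer_type = "NSCLC", site = c("lung", "brain"),
#'     is_primary = c(TRUE, FALSE), delta_log = c(0, 0.4),
#'     n_specimens = c(80, 80)),
#'   mu_log = 2, sigma_log = 0.5, seed = 42)
#' fit <- fit_site_model(generate_cohort(cfg)$specimens)
#' emm_contrasts(regrid_response(reference_grid(fit)), "lung")
fit_site_model <- function(specimens,
                           covariates = c("median_coverage",
                                          "purity_pathologist",
                                          "purity_computational"),
                           factor_var = "biopsy_site") {
  if (length(unique(specimens$cancer_type)) > 1L)
    stop("fit one cancer type at a time")
  levs <- sort(unique(as.character(specimens[[factor_var]])))
  if (length(levs) < 2L)
    stop("need at least 2 levels of ", factor_var, " to fit the site model")
  dat <- specimens
  dat$.y <- log(dat$tmb + 1)
  dat$.f <- factor(as.character(dat[[factor_var]]), levels = levs)
  rhs <- paste(c(".f", covariates), collapse = " + ")
  fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  X <- model.matrix(fit)
  if (fit$rank < ncol(X)) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (fit$df.residual <= 0L)
    stop("no residual degrees of freedom (n must exceed the design rank)")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / fit$df.residual
  structure(list(
    lm = fit,
    coefficients = coef(fit),
    # suppressWarnings: summary.lm warns on (legitimate) zero-residual fits
    covariance = sigma2 * suppressWarnings(summary(fit)$cov.unscaled),
    residual_df = fit$df.residual,
    sigma2 = sigma2,
    factor_var = factor_var,
    levels = levs,
    covariates = covariates,
    transform = function(eta) exp(eta) - 1,
    n_by_level = table(dat$.f),
    covariate_means = if (length(covariates))
      colMeans(dat[, covariates, drop = FALSE]) else numeric(0)
  ), class = "tmb_fit")
}

#' @export
print.tmb_fit <- function(x, ...) {
  cat(sprintf("log(TMB+1) linear model: %d %s level(s), %d covariate(s), %d df\n",
              length(x$levels), x$factor_var, length(x$covariates),
              x$residual_df))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Build the estimated-marginal-mean reference grid
#'
#' One grid row per factor level, with every covariate fixed at its
#' arithmetic mean over the fitted stratum (the standard EMM reference
#' grid, unweighted). Returns the grid's linear predictions on the
#' log(TMB+1) scale and their covariance.
#'
#' @param fit a [fit_site_model()] result.
#' @param specimens optional specimen table over which to take covariate
#'   means; defaults to the specimens the model was fit to.
#' @return An object of class `tmb_grid` with elements `levels`, `linear_rows`
#'   (the L matrix), `eta` (`L beta`), `eta_cov` (`L Sigma L'`), `df`,
#'   `scale = "log"`.
#' @export
reference_grid <- function(fit, specimens = NULL) {
  stopifnot(inherits(fit, "tmb_fit"))
  cov_means <- if (is.null(specimens)) fit$covariate_means else {
    miss <- setdiff(fit$covariates, names(specimens))
    if (length(miss)) stop("covariate(s) missing from specimens: ",
                           paste(miss, collapse = ", "))
    colMeans(specimens[fit$covariates])
  }
  newdata <- data.frame(.f = factor(fit$levels, levels = fit$levels))
  for (v in fit$covariates) newdata[[v]] <- cov_means[[v]]
  tt <- stats::delete.response(terms(fit$lm))
  L <- model.matrix(tt, newdata)
  eta <- drop(L %*% fit$coefficients)
  structure(list(
    levels = fit$levels,
    linear_rows = L,
    eta = setNames(eta, fit$levels),
    eta_cov = L %*% fit$covariance %*% t(L),
    df = fit$residual_df,
    n_by_level = fit$n_by_level,
    scale = "log"
  ), class = "tmb_grid")
}

#' Re-grid marginal means to the response (mut/Mb) scale
#'
#' Back-transforms the log-scale grid through `g(eta) = exp(eta) - 1` and
#' propagates the covariance by the first-order delta method:
#' `m = exp(eta) - 1`, `V = D eta_cov D'` with `D = diag(exp(eta))`.
#' Contrasts formed on the re-gridded scale are therefore differences of
#' marginal means in mut/Mb rather than log units.
#'
#' @param grid a log-scale `tmb_grid` from [reference_grid()].
#' @return A `tmb_grid` with `scale = "response"`, `mean` (mut/Mb) and
#'   `cov` replacing `eta` / `eta_cov`.
#' @export
regrid_response <- function(grid) {
  stopifnot(inherits(grid, "tmb_grid"), grid$scale == "log")
  d <- exp(grid$eta)
  grid$mean <- d - 1
  grid$cov <- diag(d, length(d)) %*% grid$eta_cov %*% diag(d, length(d))
  dimnames(grid$cov) <- list(grid$levels, grid$levels)
  grid$scale <- "response"
  grid
}

#' Site-versus-reference contrasts of re-gridded marginal means
#'
#' For each factor level, the difference in marginal mean TMB (mut/Mb)
#' relative to the reference site, with a t-based confidence interval and
#' two-sided p-value using the model's residual degrees of freedom. The
#' reference level is included as a zero row (estimate 0, p = 1), matching
#' forest-plot conventions.
#'
#' @param grid a response-scale `tmb_grid` from [regrid_response()].
#' @param reference_site the reference/primary level.
#' @param alpha two-sided confidence level is `1 - alpha` (default 0.05).
#' @param adjust p-value adjustment across the non-reference contrasts;
#'   `"none"` (default, raw p-values) or any `stats::p.adjust` method such
#'   as `"BH"`.
#' @return data.frame with one row per level: `site`, `reference_site`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p_value`, `n_site`,
#'   `n_reference`.
#' @export
emm_contrasts <- function(grid, reference_site, alpha = 0.05,
                          adjust = "none") {
  stopifnot(inherits(grid, "tmb_grid"))
  if (grid$scale != "response")
    stop("emm_contrasts expects a response-scale grid; call regrid_response()")
  r <- match(reference_site, grid$levels)
  if (is.na(r)) stop("unknown reference site: ", reference_site)
  m <- grid$mean
  V <- grid$cov
  est <- m - m[r]
  se <- sqrt(pmax(diag(V) + V[r, r] - 2 * V[, r], 0))
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  p <- 2 * pt(-abs(tstat), df = grid$df)
  p[seq_along(p) == r] <- 1
  if (adjust != "none") {
    idx <- seq_along(p) != r
    p[idx] <- stats::p.adjust(p[idx], method = adjust)
  }
  tcrit <- qt(1 - alpha / 2, df = grid$df)
  n <- as.integer(grid$n_by_level[grid$levels])
  out <- data.frame(
    site = grid$levels,
    reference_site = reference_site,
    estimate = unname(est),
    se = unname(se),
    ci_low = unname(est - tcrit * se),
    ci_high = unname(est + tcrit * se),
    p_value = unname(p),
    n_site = n,
    n_reference = n[r],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Pooled metastatic-versus-primary contrast for one cancer type
#'
#' Replaces the biopsy-site factor with a two-level indicator (primary vs
#' all metastatic sites pooled), keeping the same covariates and the same
#' model / reference-grid / re-grid / contrast machinery, and returns the
#' single metastatic-minus-primary difference in mut/Mb. Pooling
#' heterogeneous metastatic sites can mask opposite-signed site effects —
#' compare against the per-site contrasts of [run_all()].
#'
#' @inheritParams fit_site_model
#' @param alpha see [emm_contrasts()].
#' @return one-row contrast data.frame (metastatic minus primary).
#' @export
metastatic_vs_primary <- function(specimens,
                                  covariates = c("median_coverage",
                                                 "purity_pathologist",
                                                 "purity_computational"),
                                  alpha = 0.05) {
  if (!any(specimens$is_primary_site) || all(specimens$is_primary_site))
    stop("need both primary and metastatic specimens")
  specimens$met_status <- ifelse(specimens$is_primary_site,
                                 "primary", "metastatic")
  fit <- fit_site_model(specimens, covariates = covariates,
                        factor_var = "met_status")
  ctr <- emm_contrasts(regrid_response(reference_grid(fit)),
                       reference_site = "primary", alpha = alpha)
  ctr[ctr$site == "metastatic", , drop = FALSE]
}

#' Fit all per-cancer models and assemble the full contrast table
#'
#' For every cancer type in the cohort: the pooled metastatic-vs-primary
#' contrast plus each site's contrast against the mapped primary site.
#' Strata that fail model preconditions (single site level, rank
#' deficiency, no residual df) are skipped with the reason recorded in the
#' `"skipped"` attribute of the result.
#'
#' @param specimens filtered cohort (all cancer types).
#' @param site_map primary-site map (see [assign_primary_flag()]).
#' @param alpha,adjust,covariates see [emm_contrasts()] / [fit_site_model()].
#' @return data.frame of contrasts with a `contrast_type` column
#'   (`"pooled"` or `"site"`); raw p-values unless `adjust` is set.
#' @export
run_all <- function(specimens, site_map, alpha = 0.05, adjust = "none",
                    covariates = c("median_coverage", "purity_pathologist",
                                   "purity_computational")) {
  site_map <- as_site_map(site_map)
  specimens <- assign_primary_flag(specimens, site_map)
  skipped <- list()
  rows <- list()
  for (ct in unique(specimens$cancer_type)) {
    stratum <- specimens[specimens$cancer_type == ct, , drop = FALSE]
    pooled <- tryCatch(
      metastatic_vs_primary(stratum, covariates = covariates, alpha = alpha),
      error = function(e) conditionMessage(e))
    if (is.character(pooled)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(cancer_type = ct, contrast = "pooled", reason = pooled)
    } else {
      pooled <- cbind(cancer_type = ct, contrast_type = "pooled", pooled)
      rows[[length(rows) + 1L]] <- pooled
    }
    persite <- tryCatch({
      fit <- fit_site_model(stratum, covariates = covariates)
      emm_contrasts(regrid_response(reference_grid(fit)),
                    reference_site = unname(site_map[ct]),
                    alpha = alpha, adjust = adjust)
    }, error = function(e) conditionMessage(e))
    if (is.character(persite)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(cancer_type = ct, contrast = "site", reason = persite)
    } else {
      rows[[length(rows) + 1L]] <-
        cbind(cancer_type = ct, contrast_type = "site", persite)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (length(skipped)) {
    sk <- do.call(rbind, skipped)
    for (i in seq_len(nrow(sk)))
      message(sprintf("run_all: skipped %s/%s: %s",
                      sk$cancer_type[i], sk$contrast[i], sk$reason[i]))
    if (!is.null(out)) attr(out, "skipped") <- sk
  }
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out
}
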