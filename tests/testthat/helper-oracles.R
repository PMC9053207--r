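# Independent brute-force oracles. These re-derive the model chain from
# first principles (SVD pseudoinverse, explicit grid rows, numerical
# Jacobian, direct t formulas) and share no code with the package
# implementation they check.

# Moore-Penrose pseudoinverse via SVD
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    diag(1 / s$d[keep], sum(keep)) %*%
    t(s$u[, keep, drop = FALSE])
}

# explicit design matrix: intercept, treatment-coded site indicators
# (levels sorted, first = baseline), then covariates as given
oracle_design <- function(specimens, covariates) {
  levs <- sort(unique(specimens$biopsy_site))
  X <- matrix(1, nrow(specimens), 1)
  for (l in levs[-1]) X <- cbind(X, as.numeric(specimens$biopsy_site == l))
  for (v in covariates) X <- cbind(X, specimens[[v]])
  list(X = X, levels = levs)
}

# full chain: pseudoinverse OLS -> covariate-mean grid -> delta-method
# response regrid -> t contrasts vs reference
oracle_emm_chain <- function(specimens, covariates, reference_site,
                             alpha = 0.05) {
  y <- log(specimens$tmb + 1)
  d <- oracle_design(specimens, covariates)
  X <- d$X
  beta <- drop(pinv(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  Sigma <- sigma2 * pinv(t(X) %*% X)
  k <- length(d$levels)
  L <- matrix(0, k, ncol(X))
  L[, 1] <- 1
  for (i in seq_len(k - 1)) L[i + 1, 1 + i] <- 1
  if (length(covariates))
    for (j in seq_along(covariates))
      L[, k + j] <- mean(specimens[[covariates[j]]])
  eta <- drop(L %*% beta)
  eta_cov <- L %*% Sigma %*% t(L)
  m <- exp(eta) - 1
  D <- diag(exp(eta), k)
  V <- D %*% eta_cov %*% D
  r <- match(reference_site, d$levels)
  est <- m - m[r]
  se <- sqrt(pmax(diag(V) + V[r, r] - 2 * V[, r], 0))
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  p <- 2 * pt(-abs(tstat), df)
  p[r] <- 1
  tc <- qt(1 - alpha / 2, df)
  list(levels = d$levels, beta = beta, Sigma = Sigma, eta = eta,
       eta_cov = eta_cov, m = m, V = V, df = df, sigma2 = sigma2,
       estimate = est, se = se, ci_low = est - tc * se,
       ci_high = est + tc * se, p_value = p)
}

# numerical Jacobian of g applied elementwise, for the delta-method check
num_jacobian <- function(g, eta, h = 1e-6) {
  k <- length(eta)
  J <- matrix(0, k, k)
  for (j in seq_len(k)) {
    e <- numeric(k); e[j] <- h
    J[, j] <- (g(eta + e) - g(eta - e)) / (2 * h)
  }
  J
}

# exact two-sided signed-rank p by literal enumeration of all 2^n sign
# assignments (the independent oracle for paired_site_test)
enumerate_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# small deterministic fixture: 2 sites, 1 covariate, 6 specimens
fixture_six <- function() {
  data.frame(
    specimen_id = paste0("S", 1:6),
    patient_id = paste0("P", 1:6),
    cancer_type = "CT",
    biopsy_site = c("alpha", "alpha", "alpha", "beta", "beta", "beta"),
    collection_date = as.Date("2019-01-01") + 0:5,
    tmb = c(2.1, 3.5, 4.0, 7.2, 9.9, 6.4),
    purity_pathologist = c(0.45, 0.60, 0.35, 0.80, 0.55, 0.70),
    purity_computational = c(0.50, 0.55, 0.40, 0.75, 0.60, 0.65),
    median_coverage = c(480, 520, 505, 495, 530, 510),
    is_primary_site = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# standard two-site synthetic config used across tests
two_site_config <- function(n_per_site = 200, delta = 0.4, sigma = 0.6,
                            mu = 2, seed = 1, ...) {
  cohort_config(
    site_effects = data.frame(
      cancer_type = "NSCLC", site = c("lung", "brain"),
      is_primary = c(TRUE, FALSE), delta_log = c(0, delta),
      n_specimens = c(n_per_site, n_per_site)),
    mu_log = mu, sigma_log = sigma, seed = seed, ...)
}
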