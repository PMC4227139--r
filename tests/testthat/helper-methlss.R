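# Shared fixture builders. Everything is generated in code; no stored data.

# intercept + one centered continuous covariate, BMI-like scale
make_design <- function(n, seed = NULL, sd = 5) {
  if (!is.null(seed)) set.seed(seed)
  cc <- rnorm(n, 0, sd)
  cc <- cc - mean(cc)
  list(X = cbind("(Intercept)" = 1, cov = cc), cov = cc)
}

# beta-model site draw on explicit linear predictors
draw_beta_site <- function(cc, mu0 = 0.12, sigma0 = 0.17,
                           gamma_mu = 0, gamma_sigma = 0) {
  as.numeric(simulate_beta_site(cc, mu0, sigma0, gamma_mu, gamma_sigma,
                                center = FALSE))
}

# log-likelihood computed from first principles, independent of the fitter
loglik_gaussian_direct <- function(g1, g2, y, X1, X2) {
  sum(dnorm(y, drop(X1 %*% g1), exp(drop(X2 %*% g2)), log = TRUE))
}

loglik_beta_direct <- function(g1, g2, y, X1, X2) {
  mu <- plogis(drop(X1 %*% g1))
  sg <- plogis(drop(X2 %*% g2))
  phi <- 1 / sg^2 - 1
  sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}
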