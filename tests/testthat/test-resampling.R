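test_that("greedy covariate selection follows successive residual correlation", {
  set.seed(190)
  y <- rnorm(50)
  cand <- cbind(y, matrix(rnorm(150), 50))
  expect_identical(select_correlated_covariates(y, cand, 2)[1], 1L)
  expect_identical(select_correlated_covariates(y, cand, 0), integer(0))
  # constant columns are skipped with a warning
  cand2 <- cbind(const = rep(1, 50), x = rnorm(50))
  expect_warning(sel <- select_correlated_covariates(y, cand2, 1), "constant")
  expect_identical(sel, 2L)
  w <- capture_warnings(select_correlated_covariates(y, cand2, 3))
  expect_match(w, "fewer than k", all = FALSE)
})

test_that("greedy selection reproduces a hand-executed trace", {
  # 6 observations, 4 candidates: oracle executes the greedy definition
  # explicitly (max |cor| with the running least-squares residual)
  y <- c(1.0, 2.1, 2.9, 4.2, 4.8, 6.1)
  cand <- cbind(a = c(1, 2, 3, 4, 5, 6),
                b = c(2, 1, 4, 3, 6, 5),
                c = c(1, 1, 2, 2, 3, 3),
                d = c(6, 5, 4, 3, 2, 1))
  oracle <- integer(0)
  r <- y
  for (step in 1:3) {
    pool <- setdiff(1:4, oracle)
    cors <- sapply(pool, function(j) abs(cor(r, cand[, j])))
    oracle <- c(oracle, pool[which.max(cors)])
    r <- residuals(lm(y ~ cand[, oracle]))
  }
  expect_identical(select_correlated_covariates(y, cand, 3), oracle)
})

test_that("genomic windows are inclusive at the 5 Mb half-width", {
  pos <- c(1e6, 4e6, 6.0e6, 11e6, 11000001)
  expect_identical(window_candidates(6e6, pos, 5e6), 1:4)
})

test_that("resampling p-values respect their discrete support and formula", {
  set.seed(191)
  d <- make_design(300)
  y <- transform_beta(draw_beta_site(d$cov, 0.2, 0.17), "logit2")
  fit <- methlss_fit(y, d$X, d$X, family = "gaussian")
  rs <- resample_pvalue(fit, "sigma", "cov", B = 30, seed = 5)
  expect_equal(rs$p.value,
               (1 + sum(abs(rs$statistics) >= abs(rs$t_obs))) /
                 (rs$B_effective + 1))
  expect_gte(rs$p.value, 1 / (rs$B_effective + 1))
  expect_lte(rs$p.value, 1)
  # |t*| >= |t_obs| always holds at t_obs = 0, so the formula gives p = 1
  expect_equal((1 + sum(abs(rs$statistics) >= 0)) / (rs$B_effective + 1), 1)
  # reproducibility
  rs2 <- resample_pvalue(fit, "sigma", "cov", B = 30, seed = 5)
  expect_identical(rs$statistics, rs2$statistics)
})

test_that("resampling p-values are uniform on their support under the null", {
  set.seed(192)
  d <- make_design(200)
  B <- 19
  p <- replicate(250, {
    y <- transform_beta(draw_beta_site(d$cov, plogis(rnorm(1, -2.2, 0.6)),
                                       plogis(rnorm(1, -1.6, 0.3))), "logit2")
    fit <- methlss_fit(y, d$X, d$X, family = "gaussian")
    resample_pvalue(fit, "sigma", "cov", B = B)$p.value
  })
  counts <- table(factor(round(p * (B + 1)), levels = 1:(B + 1)))
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})

test_that("a strong true effect drives the resampling p to its minimum", {
  set.seed(193)
  d <- make_design(1763)
  hits <- replicate(60, {
    y <- transform_beta(draw_beta_site(d$cov, 0.5, 0.17, gamma_mu = 0.05),
                        "logit2")
    fit <- methlss_fit(y, d$X, d$X, family = "gaussian")
    rs <- resample_pvalue(fit, "mu", "cov", B = 100)
    rs$p.value == 1 / (rs$B_effective + 1)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("screening without genetic candidates reduces to plain fits", {
  set.seed(194)
  n <- 150
  cc <- rnorm(n, 0, 5)
  covs <- data.frame(bmi = cc, row.names = paste0("S", 1:n))
  vals <- t(replicate(3, draw_beta_site(cc - mean(cc), 0.2, 0.17)))
  dimnames(vals) <- list(paste0("cg", 1:3), rownames(covs))
  out <- screen_sites(vals, covs, ~ bmi, tested = "bmi", model = "lo+")
  X <- model.matrix(~ bmi, covs)
  for (s in 1:3) {
    fit <- methlss_fit(transform_beta(vals[s, ], "logit2"), X, X, "gaussian")
    for (pp in c("mu", "sigma")) {
      row <- out[out$site == rownames(vals)[s] & out$submodel == pp, ]
      w <- wald_test(fit, pp, "bmi")
      expect_equal(row$estimate, w$estimate, tolerance = 1e-10)
      expect_equal(row$p_asymptotic, w$p.value, tolerance = 1e-10)
    }
  }
  out2 <- screen_sites(vals, covs, ~ bmi, tested = "bmi", model = "lo+")
  expect_identical(out, out2)
})

test_that("resampling with genetic covariates defuses SNP-driven false sigma hits", {
  # multimodal SNP-driven site where the genotype also shifts the covariate
  # (cis-SNP with a true effect on the phenotype), no true covariate effect
  # on sigma: the asymptotic sigma-test fires spuriously; including the
  # selected SNPs and using resampling inference keeps the error down
  set.seed(195)
  n <- 1763; reps <- 60
  asym <- resam <- logical(reps)
  for (r in seq_len(reps)) {
    g <- generate_genotypes(n, 0.3)
    cc <- 1.5 * (g - mean(g)) + rnorm(n, 0, 5); cc <- cc - mean(cc)
    y <- simulate_beta_site(cc, 0.2, 0.15, gamma_mu = 0, gamma_sigma = 0,
                            offset_mu = 1.5 * (g - mean(g)), center = FALSE)
    yl <- transform_beta(as.numeric(y), "logit2")
    X <- cbind("(Intercept)" = 1, bmi = cc)
    fit <- methlss_fit(yl, X, X, family = "gaussian")
    asym[r] <- wald_test(fit, "sigma", "bmi")$p.value < 0.05
    cand <- cbind(snp1 = g, snp2 = generate_genotypes(n, 0.2),
                  snp3 = generate_genotypes(n, 0.4))
    sel <- select_correlated_covariates(yl, cand, 3)
    Xg <- cbind(X, cand[, sel, drop = FALSE])
    fitg <- methlss_fit(yl, Xg, Xg, family = "gaussian")
    rs <- tryCatch(resample_pvalue(fitg, "sigma", "bmi", B = 50),
                   error = function(e) NULL)
    resam[r] <- if (is.null(rs)) NA else rs$p.value < 0.05
  }
  expect_gt(mean(asym), mean(resam, na.rm = TRUE))
  expect_gt(mean(!resam, na.rm = TRUE), 0.6)
})
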