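test_that("Fisher enrichment matches hypergeometric enumeration", {
  f <- fisher_enrichment(10, 10, 10, 10)
  expect_equal(f$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(f$p.value, 1)

  # margins (5,5)/(5,5): only a = 0 and a = 5 are as extreme, each 1/C(10,5)
  expect_equal(fisher_enrichment(5, 0, 0, 5)$p.value, 2 / 252, tolerance = 1e-12)

  # margins (4,4)/(4,4): enumeration over a = 0..4 gives 34/70
  probs <- sapply(0:4, function(a) choose(4, a) * choose(4, 4 - a) / choose(8, 4))
  expect_equal(fisher_enrichment(3, 1, 1, 3)$p.value,
               sum(probs[probs <= probs[4] + 1e-12]), tolerance = 1e-12)
  expect_equal(fisher_enrichment(3, 1, 1, 3)$p.value, 34 / 70, tolerance = 1e-12)
  expect_error(fisher_enrichment(-1, 0, 0, 1), "non-negative")
})

test_that("the median-split Bartlett test matches the textbook formula", {
  # two groups of 10 with sample variances exactly 1 and 4
  z <- as.numeric(scale(1:10))            # mean 0, sd 1
  y <- c(z, 2 * z)
  covariate <- rep(c(0, 1), each = 10)
  bt <- bartlett_median_split(y, covariate)
  sp2 <- (9 * 1 + 9 * 4) / 18
  num <- 18 * log(sp2) - 9 * (log(1) + log(4))
  C <- 1 + (1 / (3 * 1)) * (1 / 9 + 1 / 9 - 1 / 18)
  expect_equal(bt$statistic, num / C, tolerance = 1e-10)
  expect_equal(bt$p.value, pchisq(num / C, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(bt$n_low, 10L)

  # identical group variances give statistic 0, p = 1
  bt0 <- bartlett_median_split(c(z, z + 5), covariate)
  expect_equal(bt0$statistic, 0, tolerance = 1e-12)
  expect_equal(bt0$p.value, 1)
  expect_error(bartlett_median_split(rep(c(1, 2), each = 5), rep(c(0, 1), each = 5)),
               "zero variance")
})

test_that("the median-split Bartlett test holds its level for random groupings", {
  set.seed(200)
  rej <- replicate(1000, {
    bartlett_median_split(rnorm(40), rnorm(40))$p.value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("a zero-effect screen produces no genome-wide flags", {
  set.seed(210)
  n <- 250
  cc <- rnorm(n, 0, 5); cc <- cc - mean(cc)
  covs <- data.frame(bmi = cc, row.names = paste0("S", 1:n))
  vals <- t(sapply(1:300, function(s)
    draw_beta_site(cc * 0, plogis(rnorm(1, -2.2, 0.6)), plogis(rnorm(1, -1.6, 0.3)))))
  dimnames(vals) <- list(paste0("cg", 1:300), rownames(covs))
  res <- run_ewas(vals, covs, ~ bmi, tested = "bmi", model = "lo+",
                  threshold = 1.3e-7)
  expect_identical(sum(res$dmc), 0L)
  expect_identical(sum(res$dvc), 0L)
})

test_that("true location effects are flagged as DMCs at a Bonferroni threshold", {
  set.seed(211)
  n <- 1763; n_sites <- 200; n_true <- 20
  cc <- rnorm(n, 0, 5); cc <- cc - mean(cc)
  covs <- data.frame(bmi = cc, row.names = paste0("S", 1:n))
  ok <- replicate(10, {
    vals <- t(sapply(seq_len(n_sites), function(s)
      draw_beta_site(cc, plogis(rnorm(1, -2.2, 0.6)), plogis(rnorm(1, -1.6, 0.3)),
                     gamma_mu = if (s <= n_true) 0.05 else 0)))
    dimnames(vals) <- list(paste0("cg", seq_len(n_sites)), rownames(covs))
    res <- run_ewas(vals, covs, ~ bmi, tested = "bmi", model = "lo+",
                    threshold = 0.05 / n_sites)
    sum(res$dmc & res$site %in% paste0("cg", 1:n_true)) >= 16
  })
  expect_gte(mean(ok), 0.9)
})

test_that("flags are invariant to site and sample ordering", {
  set.seed(212)
  n <- 200
  cc <- rnorm(n, 0, 5)
  covs <- data.frame(bmi = cc, row.names = paste0("S", 1:n))
  vals <- t(sapply(1:6, function(s)
    draw_beta_site(cc - mean(cc), 0.2, 0.17, gamma_mu = 0.03)))
  dimnames(vals) <- list(paste0("cg", 1:6), rownames(covs))
  r1 <- run_ewas(vals, covs, ~ bmi, tested = "bmi", model = "lo+", threshold = 0.05)
  perm_sites <- sample(6); perm_samp <- sample(n)
  r2 <- run_ewas(vals[perm_sites, perm_samp], covs[perm_samp, , drop = FALSE],
                 ~ bmi, tested = "bmi", model = "lo+", threshold = 0.05)
  m <- match(paste(r1$site, r1$submodel), paste(r2$site, r2$submodel))
  expect_identical(r1$dmc, r2$dmc[m])
  expect_identical(r1$dvc, r2$dvc[m])
})

test_that("the resampling confirmation step fills p-values for flagged sites only", {
  set.seed(213)
  n <- 300
  cc <- rnorm(n, 0, 5); cc <- cc - mean(cc)
  covs <- data.frame(bmi = cc, row.names = paste0("S", 1:n))
  vals <- rbind(cg_eff = draw_beta_site(cc, 0.3, 0.17, gamma_mu = 0.08),
                cg_null = draw_beta_site(cc, 0.3, 0.17))
  colnames(vals) <- rownames(covs)
  res <- run_ewas(vals, covs, ~ bmi, tested = "bmi", model = "lo+",
                  threshold = 1e-4, resampling = list(B = 30), seed = 2)
  flagged <- res$dmc | res$dvc
  expect_true(all(!is.na(res$p_resampling[flagged])))
  expect_true(all(is.na(res$p_resampling[!flagged])))
})

test_that("discovery/replication validation builds the enrichment table", {
  disc <- data.frame(site = paste0("cg", 1:8), term = "bmi", submodel = "sigma",
                     p_asymptotic = 1e-9,
                     p_resampling = c(rep(0.01, 4), rep(0.6, 4)),
                     stringsAsFactors = FALSE)
  repl <- data.frame(site = paste0("cg", 1:8), term = "bmi", submodel = "sigma",
                     p_asymptotic = c(0.01, 0.02, 0.03, 0.2, 0.5, 0.6, 0.01, 0.9),
                     stringsAsFactors = FALSE)
  v <- validate_associations(disc, repl)
  expect_identical(unname(v$counts["resampling_sig", "validated"]), 3L)
  expect_identical(unname(v$counts["not_sig", "validated"]), 1L)
  expect_equal(v$enrichment$p.value,
               fisher.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p.value)
})
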