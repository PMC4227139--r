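test_that("fixed-scale Gaussian fit coincides with OLS and the closed-form sigma", {
  d <- make_design(120, seed = 1)
  y <- 0.3 + 0.05 * d$cov + rnorm(120, 0, 0.4)
  fit <- methlss_fit(y, d$X, family = "gaussian")
  ols <- lm.fit(d$X, y)
  expect_equal(unname(coef(fit, "mu")), unname(ols$coefficients),
               tolerance = 1e-12)
  expect_equal(unname(exp(coef(fit, "sigma"))),
               sqrt(mean(ols$residuals^2)), tolerance = 1e-12)
  expect_true(fit$converged)

  # variable-scale fit with intercept-only X2 reproduces the fixed-scale fit
  ones <- matrix(1, 120, 1, dimnames = list(NULL, "(Intercept)"))
  fit2 <- methlss_fit(y, d$X, ones, family = "gaussian")
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("fixed-scale beta fit matches a brute-force likelihood search", {
  set.seed(20)
  d <- make_design(20, sd = 1)
  y <- draw_beta_site(d$cov, mu0 = 0.3, sigma0 = 0.25, gamma_mu = 0.5)
  fit <- methlss_fit(y, d$X, family = "beta")
  expect_true(fit$converged)

  # independent oracle: nested grid refinement of the same log-likelihood
  ll <- function(th) loglik_beta_direct(th[1:2], th[3], y, d$X,
                                        matrix(1, 20, 1))
  center <- c(0, 0, 0); width <- c(3, 3, 3)
  for (round in 1:12) {
    grid <- expand.grid(g0 = seq(center[1] - width[1], center[1] + width[1], length.out = 11),
                        g1 = seq(center[2] - width[2], center[2] + width[2], length.out = 11),
                        s0 = seq(center[3] - width[3], center[3] + width[3], length.out = 11))
    vals <- apply(grid, 1, ll)
    center <- as.numeric(grid[which.max(vals), ])
    width <- width * 0.35
  }
  est <- c(coef(fit, "mu"), coef(fit, "sigma"))
  expect_equal(unname(est), center, tolerance = 1e-3)
  expect_gte(fit$loglik + 1e-6, ll(center))
})

test_that("fixed-scale beta regression agrees with an established GAM fitter", {
  skip_if_not_installed("mgcv")
  set.seed(8)
  d <- make_design(400, sd = 1)
  y <- draw_beta_site(d$cov, mu0 = 0.3, sigma0 = 0.2, gamma_mu = 0.4)
  fit <- methlss_fit(y, d$X, family = "beta")
  x <- d$cov
  g <- mgcv::gam(y ~ x, family = mgcv::betar(link = "logit"))
  expect_equal(unname(coef(fit, "mu")), unname(coef(g)), tolerance = 5e-3)
})

test_that("the fitted point is a local likelihood optimum for both families", {
  set.seed(40)
  d <- make_design(300, sd = 1)
  y <- draw_beta_site(d$cov, 0.25, 0.2, gamma_mu = 0.3, gamma_sigma = 0.2)
  for (fam in c("beta", "gaussian")) {
    yy <- if (fam == "gaussian") transform_beta(y, "logit2") else y
    fit <- methlss_fit(yy, d$X, d$X, family = fam)
    lfun <- if (fam == "gaussian") loglik_gaussian_direct else loglik_beta_direct
    th <- c(coef(fit, "mu"), coef(fit, "sigma"))
    expect_equal(fit$loglik, lfun(th[1:2], th[3:4], yy, d$X, d$X),
                 tolerance = 1e-8)
    for (i in 1:100) {
      pert <- th + rnorm(4, 0, 0.02)
      expect_lte(lfun(pert[1:2], pert[3:4], yy, d$X, d$X), fit$loglik + 1e-8)
    }
  }
})

test_that("all eight model specs recover their generating coefficients", {
  # mean absolute estimation bias per coefficient stays below 0.02
  set.seed(55)
  n <- 2000; reps <- 50
  d <- make_design(n, sd = 1)
  g1 <- c(-1, 0.15); g2 <- c(-1.6, 0.1)
  for (code in model_codes()) {
    sp <- model_spec(code)
    fixed <- sp$scale_mode == "fixed"
    err <- matrix(NA_real_, reps, if (fixed) 2 else 4)
    for (r in seq_len(reps)) {
      if (sp$family == "beta") {
        eta2 <- if (fixed) g2[1] else g2[1] + g2[2] * d$cov
        y <- rbetams(n, plogis(g1[1] + g1[2] * d$cov), plogis(eta2))
        y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
        fit <- methlss_fit(y, d$X, if (fixed) NULL else d$X, family = "beta")
      } else {
        eta2 <- if (fixed) g2[1] else g2[1] + g2[2] * d$cov
        y <- rnorm(n, g1[1] + g1[2] * d$cov, exp(eta2))
        fit <- methlss_fit(y, d$X, if (fixed) NULL else d$X, family = "gaussian")
      }
      truth <- if (fixed) c(g1, g2[1]) else c(g1, g2)
      est <- c(coef(fit, "mu"), coef(fit, "sigma"))
      err[r, ] <- (est - truth)[seq_len(ncol(err))]
    }
    bias <- abs(colMeans(err))
    expect_true(all(bias < 0.02),
                info = paste0(code, ": max |bias| = ", signif(max(bias), 3)))
  }
})

test_that("standard errors are calibrated for the variable-scale beta model", {
  set.seed(60)
  n <- 2000; reps <- 200
  x <- rnorm(n)
  X <- cbind("(Intercept)" = 1, x = x)
  truth <- c(-1, 0.5, -2, 0.3)
  hit <- matrix(NA, reps, 4)
  zmat <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    y <- rbetams(n, plogis(-1 + 0.5 * x), plogis(-2 + 0.3 * x))
    y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
    fit <- methlss_fit(y, X, X, family = "beta")
    est <- c(coef(fit, "mu"), coef(fit, "sigma"))
    se <- c(fit$se$mu, fit$se$sigma)
    hit[r, ] <- abs(est - truth) < 3 * se
    zmat[r, ] <- (est - truth) / se
  }
  # overall 3-SE coverage at its nominal level, and unit-variance z-scores
  expect_gte(mean(hit), 0.99)
  expect_true(all(abs(apply(zmat, 2, sd) - 1) < 0.15))
})

test_that("rank-deficient designs are rejected naming the offending column", {
  d <- make_design(50, seed = 2)
  X <- cbind(d$X, dup = d$X[, 2])
  expect_error(methlss_fit(rnorm(50), X, family = "gaussian"), "dup")
})

test_that("Wald tests are estimate/SE ratios against the t distribution", {
  d <- make_design(150, seed = 5)
  y <- 0.1 + 0.2 * d$cov + rnorm(150, 0, 0.5)
  fit <- methlss_fit(y, d$X, d$X, family = "gaussian")
  w <- wald_test(fit, "mu", "cov")
  est <- coef(fit, "mu")[["cov"]]
  se <- fit$se$mu[["cov"]]
  expect_equal(w$statistic, est / se, tolerance = 1e-12)
  expect_equal(w$p.value, 2 * pt(-abs(est / se), 150 - 4), tolerance = 1e-12)
  expect_error(wald_test(fit, "mu", "nope"), "no coefficient")
})

test_that("Wald p-values are uniform under a correctly specified null", {
  set.seed(70)
  n <- 250
  d <- make_design(n)
  p <- replicate(500, {
    y <- draw_beta_site(d$cov, plogis(rnorm(1, -2.2, 0.6)), plogis(rnorm(1, -1.6, 0.3)))
    fit <- methlss_fit(y, d$X, family = "beta")
    wald_test(fit, "mu", "cov")$p.value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("quantile residuals behave as advertised", {
  d <- make_design(200, seed = 81)
  y <- 0.2 + 0.1 * d$cov + rnorm(200, 0, 0.3)
  fit <- methlss_fit(y, d$X, d$X, family = "gaussian")
  r <- residuals(fit)
  mu <- fitted(fit, "mu"); sg <- fitted(fit, "sigma")
  expect_equal(r, (y - mu) / sg, tolerance = 1e-12)

  # an observation at its fitted conditional median has residual zero
  y2 <- y; y2[1] <- mu[1]
  fit2 <- fit; fit2$y <- y2
  expect_equal(residuals(fit2)[1], 0, tolerance = 1e-12)

  # correctly specified beta model: residuals are N(0,1) in distribution
  set.seed(82)
  d2 <- make_design(2000, sd = 1)
  pass <- replicate(100, {
    yb <- rbetams(2000, plogis(-1.5 + 0.2 * d2$cov), plogis(-1.7 + 0.1 * d2$cov))
    yb <- pmin(pmax(yb, 1e-12), 1 - 1e-12)
    f <- methlss_fit(yb, d2$X, d2$X, family = "beta")
    suppressWarnings(ks.test(residuals(f), "pnorm"))$p.value > 0.01
  })
  expect_gte(mean(pass), 0.95)
})

test_that("Shapiro-Wilk wrapper holds its level and rejects heavy tails", {
  set.seed(90)
  rej <- replicate(1000, residual_normality(rnorm(500))$p.value < 0.05)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
  expect_lt(residual_normality(rt(1000, 2))$p.value, 1e-6)
  expect_error(residual_normality(rep(1, 10)), "constant")
})

test_that("the formula interface transforms, drops incomplete rows and predicts", {
  set.seed(101)
  df <- data.frame(bmi = rnorm(300, 28, 5), age = rnorm(300, 61, 9))
  df$y <- rbetams(300, plogis(-1 + 0.02 * (df$bmi - 28)), 0.2)
  df$bmi[5] <- NA
  expect_message(fit <- methlss(y ~ bmi + age, data = df, model = "lo+"),
                 "1 incomplete")
  expect_equal(fit$n, 299L)
  expect_identical(fit$transform, "logit2")
  expect_identical(fit$scale_mode, "variable")
  # response stored transformed
  expect_equal(fit$y, transform_beta(df$y[-5], "logit2"))
  pr <- predict(fit, newdata = data.frame(bmi = 28, age = 61), "mu")
  expect_true(is.finite(pr))
  # fixed-scale code forces the intercept-only scale
  fit2 <- methlss(y ~ bmi, data = df[-5, ], model = "be")
  expect_identical(fit2$scale_mode, "fixed")
  expect_identical(fit2$family, "beta")
  # coefficient table serialization covers both submodels
  ct <- coef_table(fit2)
  expect_identical(ct$submodel, c("mu", "mu", "sigma"))
  expect_true(all(is.finite(ct$p.value)))
})

test_that("simulate() draws from the fitted family reproducibly", {
  set.seed(110)
  df <- data.frame(bmi = rnorm(200, 28, 5))
  df$y <- rbetams(200, 0.3, 0.2)
  fit <- methlss(y ~ bmi, data = df, model = "be+")
  s1 <- simulate(fit, nsim = 2, seed = 4)
  s2 <- simulate(fit, nsim = 2, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))
})
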