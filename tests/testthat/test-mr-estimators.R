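test_that("Wald ratio arithmetic, symmetry and degenerate cases", {
  r <- wald_ratio(0.1, 0.005, 0.05, 0.01)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(wald_ratio(0.1, 0.005, 0, 0.01)$estimate, 0)
  # simultaneous sign flip leaves the ratio unchanged
  r2 <- wald_ratio(-0.1, 0.005, -0.05, 0.01)
  expect_equal(r2$estimate, r$estimate)
  expect_mrm_error(wald_ratio(0, 0.005, 0.05, 0.01), "mrmediate_undefined_ratio")
})

test_that("IVW reduces to the Wald ratio for a single instrument", {
  h <- make_hset(0.1, 0.05, 0.01)
  ivw <- mr_ivw(h)
  wr <- wald_ratio(0.1, 1e-4, 0.05, 0.01)
  expect_equal(ivw$estimate, wr$estimate)
  expect_equal(ivw$se, wr$se)
  expect_equal(ivw$pval, wr$pval)
})

test_that("IVW on a proportional toy gives the exact slope with zero heterogeneity", {
  h <- make_hset(c(0.1, 0.2, 0.1), c(0.05, 0.10, 0.05), rep(0.01, 3))
  r <- mr_ivw(h)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$q_stat, 0)
  expect_identical(r$method, "ivw_fe")
  expect_equal(r$q_pval, 1)
})

test_that("IVW equals the dense-grid minimizer of the weighted RSS", {
  set.seed(101)
  h <- draw_hset(20, theta = -0.4)
  r <- mr_ivw(h, model = "fe")
  w <- 1 / h$se_Gamma^2
  grid <- seq(-2, 2, by = 1e-4)
  rss <- vapply(grid, function(t) sum(w * (h$Gamma - t * h$gamma)^2), numeric(1))
  expect_lt(abs(r$estimate - grid[which.min(rss)]), 1e-4 + 1e-12)
})

test_that("multiplicative random effects never shrink the fixed-effect SE", {
  set.seed(7)
  for (i in 1:20) {
    h <- draw_hset(15, theta = 0.3,
                   alpha = rnorm(15, 0, sample(c(0, 0.02), 1)))
    fe <- mr_ivw(h, model = "fe")
    mre <- mr_ivw(h, model = "mre")
    expect_gte(mre$se, fe$se)
    expect_equal(mre$estimate, fe$estimate)
  }
})

test_that("auto model selection follows the Q p < 0.05 rule", {
  h_hom <- make_hset(c(0.1, 0.2, 0.1), c(0.05, 0.10, 0.05), rep(0.01, 3))
  expect_identical(mr_ivw(h_hom, "auto")$method, "ivw_fe")
  set.seed(13)
  h_het <- draw_hset(20, theta = 0.3, alpha = rnorm(20, 0, 0.05))
  fit <- mr_ivw(h_het, "auto")
  if (fit$q_pval < 0.05) {
    expect_identical(fit$method, "ivw_mre")
    expect_match(fit$model_note, "random effects")
  }
})

test_that("Cochran's Q matches hand arithmetic and is zero iff ratios agree", {
  h <- make_hset(c(0.1, 0.2), c(0.06, 0.08), c(0.01, 0.02))
  # w = (1e4, 2.5e3); theta = (60+40)/(100+100) = 0.5
  # Q = 1e4*(0.06-0.05)^2 + 2.5e3*(0.08-0.10)^2 = 1 + 1 = 2
  q <- cochran_q(h)
  expect_equal(q$q, 2, tolerance = 1e-12)
  expect_equal(q$df, 1)
  expect_equal(q$pval, pchisq(2, 1, lower.tail = FALSE))
  h0 <- make_hset(c(0.1, 0.2, 0.3), c(0.07, 0.14, 0.21), c(0.01, 0.03, 0.02))
  expect_equal(cochran_q(h0)$q, 0, tolerance = 1e-20)
  expect_equal(cochran_q(h0)$pval, 1)
  expect_mrm_error(cochran_q(make_hset(0.1, 0.05, 0.01)),
                   "mrmediate_insufficient_instruments")
})

test_that("Egger recovers an exact affine relationship and ignores orientation", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  G <- 0.02 + 0.6 * g
  h <- make_hset(g, G, c(0.01, 0.02, 0.015, 0.01))
  r <- mr_egger(h)
  expect_equal(r$estimate, 0.6, tolerance = 1e-10)
  expect_equal(r$egger_intercept, 0.02, tolerance = 1e-10)
  # flipping the sign of any single pair leaves the fit unchanged
  for (j in 1:4) {
    g2 <- g; G2 <- G
    g2[j] <- -g2[j]; G2[j] <- -G2[j]
    r2 <- mr_egger(make_hset(g2, G2, c(0.01, 0.02, 0.015, 0.01)))
    expect_equal(r2$estimate, r$estimate, tolerance = 1e-12)
    expect_equal(r2$egger_intercept, r$egger_intercept, tolerance = 1e-12)
  }
  expect_mrm_error(mr_egger(make_hset(c(0.1, 0.2), c(0.1, 0.2), c(0.01, 0.01))),
                   "mrmediate_insufficient_instruments")
})

test_that("Egger coefficients and scaled SEs match a weighted lm fit", {
  set.seed(31)
  h <- draw_hset(25, theta = 0.5, alpha = rnorm(25, 0.03, 0.02))
  r <- mr_egger(h)
  w <- 1 / h$se_Gamma^2
  fit <- lm(h$Gamma ~ h$gamma, weights = w)
  cf <- summary(fit)$coefficients
  expect_equal(r$egger_intercept, cf[1, 1], tolerance = 1e-10)
  expect_equal(r$estimate, cf[2, 1], tolerance = 1e-10)
  # overdispersed data: the floor at 1 is inactive, so SEs agree with lm's
  sigma <- summary(fit)$sigma
  expect_gt(sigma, 1)  # pleiotropy makes the draw overdispersed by design
  expect_equal(r$se, cf[2, 2], tolerance = 1e-10)
  expect_equal(r$egger_intercept_se, cf[1, 2], tolerance = 1e-10)
  expect_equal(r$egger_intercept_pval, cf[1, 4], tolerance = 1e-10)
})

test_that("Egger intercept tracks planted directional pleiotropy", {
  set.seed(53)
  alpha_mean <- 0.03
  ints <- replicate(400, {
    h <- draw_hset(40, theta = 0.2, alpha = rnorm(40, alpha_mean, 0.01))
    mr_egger(h)$egger_intercept
  })
  mc_se <- sd(ints) / sqrt(length(ints))
  expect_lt(abs(mean(ints) - alpha_mean), 4 * mc_se)
})

test_that("weighted median interpolates the ratio distribution", {
  h <- make_hset(c(1, 1, 1), c(0.2, 0.5, 0.9), c(1, 1, 1))
  r <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(r$estimate, 0.5)
  # an instrument holding > 50% of the weight pins the estimate near its ratio
  hdom <- make_hset(c(1, 1, 1), c(0.2, 0.5, 0.9),
                    c(1 / sqrt(0.2), 1 / sqrt(0.6), 1 / sqrt(0.2)))
  rdom <- mr_weighted_median(hdom, n_boot = 50, seed = 1)
  expect_equal(rdom$estimate, 0.5)
  expect_mrm_error(mr_weighted_median(make_hset(1, 1, 1), 10, 1),
                   "mrmediate_insufficient_instruments")
})

test_that("weighted median stays within the ratio range and is order/sign invariant", {
  set.seed(77)
  for (i in 1:10) {
    h <- draw_hset(12, theta = 0.4, alpha = rnorm(12, 0, 0.03))
    r <- mr_weighted_median(h, n_boot = 30, seed = 5)
    ratios <- h$Gamma / h$gamma
    expect_gte(r$estimate, min(ratios))
    expect_lte(r$estimate, max(ratios))
    perm <- sample(12)
    hp <- make_hset(h$gamma[perm], h$Gamma[perm], h$se_Gamma[perm],
                    se_gamma = h$se_gamma[perm])
    expect_equal(mr_weighted_median(hp, n_boot = 30, seed = 5)$estimate, r$estimate)
    hf <- make_hset(-h$gamma, -h$Gamma, h$se_Gamma, se_gamma = h$se_gamma)
    expect_equal(mr_weighted_median(hf, n_boot = 30, seed = 5)$estimate, r$estimate)
  }
})

test_that("IVW and Egger are invariant to instrument order and joint sign flips", {
  set.seed(19)
  h <- draw_hset(15, theta = -0.2, alpha = rnorm(15, 0, 0.02))
  perm <- sample(15)
  hp <- make_hset(h$gamma[perm], h$Gamma[perm], h$se_Gamma[perm],
                  se_gamma = h$se_gamma[perm])
  hf <- make_hset(-h$gamma, -h$Gamma, h$se_Gamma, se_gamma = h$se_gamma)
  for (fit in list(mr_ivw, mr_egger)) {
    expect_equal(fit(hp)$estimate, fit(h)$estimate, tolerance = 1e-12)
    expect_equal(fit(hf)$estimate, fit(h)$estimate, tolerance = 1e-12)
  }
})

test_that("MR-PRESSO empirical p has the add-one lower bound on a gross outlier", {
  set.seed(88)
  h <- draw_hset(20, theta = 0.5)
  h$Gamma[3] <- h$Gamma[3] + 10 * h$se_Gamma[3]
  r <- mr_presso(h, n_sim = 499, seed = 4)
  # observed statistic exceeds every simulated one: add-one floor
  expect_equal(r$global_pval, 1 / 500)
  expect_identical(r$outlier_snp_ids, "rs003")
  expect_lt(abs(r$corrected$estimate - 0.5), abs(r$raw$estimate - 0.5))
  expect_mrm_error(mr_presso(make_hset(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))),
                   "mrmediate_insufficient_instruments")
})

test_that("MR-PRESSO keeps the null global test calm", {
  set.seed(211)
  calm <- replicate(40, {
    h <- draw_hset(20, theta = 0.3)
    mr_presso(h, n_sim = 300, seed = sample.int(1e6, 1))$global_pval > 0.05
  })
  expect_gte(mean(calm), 0.9)
})

test_that("multivariable IVW solves an exact two-exposure system", {
  set.seed(303)
  x1 <- runif(10, 0.02, 0.08)
  x2 <- runif(10, 0.02, 0.08)
  G <- 1.5 * x1 - 0.7 * x2
  fit <- mr_mvmr(cbind(a = x1, b = x2), G, rep(0.01, 10))
  expect_equal(fit$a$estimate, 1.5, tolerance = 1e-10)
  expect_equal(fit$b$estimate, -0.7, tolerance = 1e-10)
  expect_equal(fit$a$q_df, 8)
})

test_that("multivariable IVW matches a weighted no-intercept lm on random instances", {
  set.seed(404)
  for (i in 1:5) {
    J <- 40
    X <- cbind(x1 = runif(J, 0.02, 0.08), x2 = rnorm(J, 0, 0.03))
    se <- runif(J, 0.005, 0.02)
    G <- 0.8 * X[, 1] - 0.3 * X[, 2] + rnorm(J, 0, se)
    w <- 1 / se^2
    fit <- mr_mvmr(X, G, se)
    ref <- lm(G ~ 0 + X, weights = w)
    expect_equal(unname(c(fit$x1$estimate, fit$x2$estimate)),
                 unname(coef(ref)), tolerance = 1e-10)
    sigma <- summary(ref)$sigma
    if (sigma > 1) {
      expect_equal(unname(c(fit$x1$se, fit$x2$se)),
                   unname(summary(ref)$coefficients[, 2]), tolerance = 1e-10)
    }
  }
})

test_that("an all-zero column is aliased and the other matches univariable IVW", {
  set.seed(505)
  h <- draw_hset(15, theta = 0.4)
  fit <- mr_mvmr(cbind(x = h$gamma, z = 0), h$Gamma, h$se_Gamma)
  expect_equal(fit$x$estimate, mr_ivw(h, "fe")$estimate, tolerance = 1e-12)
  expect_true(is.na(fit$z$estimate))
  expect_match(fit$z$model_note, "aliased")
})

test_that("multivariable IVW rejects under-identified and collinear designs", {
  X <- cbind(a = c(0.1, 0.2), b = c(0.2, 0.4))
  expect_mrm_error(mr_mvmr(X, c(0.1, 0.2), c(0.01, 0.01)),
                   "mrmediate_underidentified")
  X2 <- cbind(a = c(0.1, 0.2, 0.3, 0.1), b = 2 * c(0.1, 0.2, 0.3, 0.1))
  expect_mrm_error(mr_mvmr(X2, rep(0.1, 4), rep(0.01, 4)),
                   "mrmediate_collinearity")
})

test_that("result accessors expose estimate, CI and serializations", {
  h <- make_hset(c(0.1, 0.2, 0.1), c(0.05, 0.10, 0.05), rep(0.01, 3))
  r <- mr_ivw(h)
  expect_equal(unname(coef(r)), r$estimate)
  ci <- confint(r)
  expect_equal(unname(ci[1, ]), c(r$ci_low, r$ci_high))
  expect_lte(r$ci_low, r$estimate)
  expect_gte(r$ci_high, r$estimate)
  tab <- mr_result_table(list(r, mr_egger(make_hset(
    c(0.1, 0.2, 0.3), 0.01 + 0.5 * c(0.1, 0.2, 0.3), rep(0.01, 3)
  ))))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("method", "estimate", "q_pval", "egger_intercept") %in% names(tab)))
  js <- jsonlite::fromJSON(mr_result_json(r))
  expect_equal(js$estimate, r$estimate)
  res <- residuals(r)
  expect_equal(unname(res), h$Gamma - r$estimate * h$gamma)
})
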