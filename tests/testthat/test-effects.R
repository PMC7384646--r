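fake_fit <- function(b1, b2, v11, v22, v12, modifier = "pct_black") {
  nm <- c("pm25_window", paste0("pm25_window:", modifier))
  cov <- matrix(c(v11, v12, v12, v22), 2, 2, dimnames = list(nm, nm))
  structure(list(beta = stats::setNames(c(b1, b2), nm),
                 se = sqrt(diag(cov)), cov = cov, converged = TRUE,
                 grad_maxnorm = 0,
                 spec = cc_model_spec(modifier)), class = "cc_fit")
}

test_that("percent change matches its closed form and anchors", {
  pc <- percent_change(0, 0.001)
  expect_equal(pc$percent_change, 0)
  # multiplicative symmetry of the CI around the null
  expect_equal((1 + pc$ci_high / 100) * (1 + pc$ci_low / 100), 1,
               tolerance = 1e-12)
  expect_equal(percent_change(log(2) / 10, 0.01)$percent_change, 100)
  # round trip through the headline-scale transform
  expect_equal(percent_change(log(1.0235) / 10, 0.005)$percent_change,
               2.35, tolerance = 1e-10)
  b <- 0.00198
  expect_equal(percent_change_inv(percent_change(b, 1e-3)$percent_change),
               b, tolerance = 1e-12)
})

test_that("percent change is monotone in beta and in delta", {
  betas <- seq(-0.05, 0.05, length.out = 21)
  pcs <- vapply(betas,
                function(b) percent_change(b, 1e-3)$percent_change,
                numeric(1))
  expect_true(all(diff(pcs) > 0))
  pcd <- vapply(c(1, 5, 10, 20),
                function(d) percent_change(0.002, 1e-3,
                                           delta = d)$percent_change,
                numeric(1))
  expect_true(all(diff(pcd) > 0))
  expect_true(all(pcs > -100))
})

test_that("effect at a modifier value follows the delta-method closed form", {
  fit <- fake_fit(0.001, 0.0002, 1e-8, 4e-10, 0)
  e5 <- effect_at_modifier(fit, 5)
  expect_equal(e5$percent_change, 100 * (exp(10 * 0.002) - 1),
               tolerance = 1e-10)
  se5 <- sqrt(1e-8 + 25 * 4e-10)
  expect_equal(e5$ci_low, 100 * (exp(10 * (0.002 - 1.96 * se5)) - 1),
               tolerance = 1e-4)

  # m = 0 reduces exactly to the exposure coefficient alone
  e0 <- effect_at_modifier(fit, 0)
  expect_equal(e0[, c("percent_change", "ci_low", "ci_high")],
               percent_change(0.001, 1e-4)[
                 , c("percent_change", "ci_low", "ci_high")],
               tolerance = 1e-10)

  # no modification: identical estimate at every m
  flat <- fake_fit(0.002, 0, 1e-8, 0, 0)
  ee <- effect_at_modifier(flat, c(0, 10, 50))
  expect_equal(ee$percent_change, rep(ee$percent_change[1], 3))
  expect_equal(ee$ci_low, rep(ee$ci_low[1], 3))
})

test_that("modifier percentiles use the nearest-rank convention", {
  expect_equal(unname(modifier_percentiles(0:100)), c(10, 50, 90))
  x <- c(rep(3.7, 5), 1:9)
  expect_equal(unname(modifier_percentiles(rep(1:12, 4))[2]), 6)
  expect_error(modifier_percentiles(rep(1:5, 10)), "distinct")
  # all-equal beyond the distinctness gate is exercised via p=100
  expect_equal(unname(modifier_percentiles(1:10, probs = 100)), 10)
})

test_that("categorical effects combine reference and interaction terms", {
  nm <- c("pm25_window", paste0("pm25_window:rrs_G", 2:5))
  b <- c(0.014, -0.002, -0.006, -0.010, -0.012)
  cv <- diag(c(2e-5, 1e-6, 1e-6, 1e-6, 1e-6))
  cv[1, 2:5] <- cv[2:5, 1] <- -4e-7
  dimnames(cv) <- list(nm, nm)
  fit <- structure(list(beta = stats::setNames(b, nm), se = sqrt(diag(cv)),
                        cov = cv, converged = TRUE, grad_maxnorm = 0,
                        spec = cc_model_spec("rrs_category")),
                   class = "cc_fit")
  ce <- categorical_effects(fit)
  expect_equal(ce$label, paste0("G", 1:5))
  expect_equal(ce$percent_change[1], 100 * (exp(10 * 0.014) - 1))
  expect_equal(ce$percent_change[5], 100 * (exp(10 * 0.002) - 1))
  se5 <- sqrt(2e-5 + 1e-6 + 2 * (-4e-7))
  expect_equal(ce$ci_high[5], 100 * (exp(10 * (0.002 + 1.96 * se5)) - 1),
               tolerance = 1e-4)
  expect_true(is.na(ce$interaction_p[1]))
  expect_equal(ce$interaction_p[2],
               2 * pnorm(-abs(-0.002 / sqrt(1e-6))))

  # interaction coefficients of zero give identical effects everywhere
  cv0 <- diag(c(2e-5, rep(0, 4))); dimnames(cv0) <- list(nm, nm)
  fit0 <- structure(list(beta = stats::setNames(c(0.01, rep(0, 4)), nm),
                         se = sqrt(diag(cv0)), cov = cv0, converged = TRUE,
                         grad_maxnorm = 0,
                         spec = cc_model_spec("rrs_category")),
                    class = "cc_fit")
  ce0 <- categorical_effects(fit0)
  expect_equal(ce0$percent_change, rep(ce0$percent_change[1], 5))
  # a category with beta2 = -beta1 has exactly zero percent change
  fitc <- structure(list(beta = stats::setNames(c(0.01, -0.01, 0, 0, 0),
                                                nm),
                         se = sqrt(diag(cv)), cov = cv, converged = TRUE,
                         grad_maxnorm = 0,
                         spec = cc_model_spec("rrs_category")),
                    class = "cc_fit")
  expect_equal(categorical_effects(fitc)$percent_change[2], 0)
})

test_that("absent categories are reported as missing, not zero", {
  nm <- c("pm25_window", "pm25_window:rrs_G2")
  cv <- diag(c(2e-5, 1e-6)); dimnames(cv) <- list(nm, nm)
  fit <- structure(list(beta = stats::setNames(c(0.01, 0.001), nm),
                        se = sqrt(diag(cv)), cov = cv, converged = TRUE,
                        grad_maxnorm = 0,
                        spec = cc_model_spec("rrs_category")),
                   class = "cc_fit")
  ce <- categorical_effects(fit)
  expect_true(all(is.na(ce$percent_change[3:5])))
  expect_false(is.na(ce$percent_change[2]))
})

test_that("effect at the centered-modifier mean matches the marginal fit", {
  cfg <- tiny_config(seed = 23, delta_star = 2e-4, modifier = "pct_black")
  study <- simulate_study(cfg)
  recs <- merge(study$events, study$scores, by = "block_group_id")
  recs$pb_c <- recs$pct_black - mean(recs$pct_black)
  dsn <- build_matched_sets(recs, study$exposure)
  fit_int <- fit_cc_model(dsn, cc_model_spec("pct_black",
                                             exposure = "pm25_window"))
  # interaction on the centered modifier, evaluated at its mean (= 0),
  # should match in point estimate up to refitting noise ~ none: the
  # models are reparameterizations of each other only at m = mean, so
  # compare at the decedent mean of the raw modifier
  mbar <- mean(recs$pct_black)
  e <- effect_at_modifier(fit_int, mbar)
  spec0 <- cc_model_spec("none")
  # marginal model without interaction
  fit0 <- fit_cc_model(dsn, spec0)
  e0 <- percent_change(fit0$beta[["pm25_window"]],
                       fit0$se[["pm25_window"]])
  expect_equal(e$percent_change, e0$percent_change, tolerance = 0.25)
})
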