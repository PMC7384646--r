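one_set <- list(X = matrix(c(1, 0, 0), ncol = 1,
                           dimnames = list(NULL, "x")),
                set_id = c(1, 1, 1), is_case = c(1, 0, 0))

test_that("log-likelihood matches softmax closed forms", {
  expect_equal(conditional_loglik(0, one_set$X, one_set$set_id,
                                  one_set$is_case), log(1 / 3))
  expect_equal(conditional_loglik(log(2), one_set$X, one_set$set_id,
                                  one_set$is_case), -log(2))
  # beta = 0: sum over sets of -log(1 + M_i)
  rs <- random_sets(25, beta = 0.4, n_ref = 4, seed = 2)
  expect_equal(conditional_loglik(0, rs$X, rs$set_id, rs$is_case),
               -25 * log(5))
})

test_that("likelihood is numerically stable for extreme coefficients", {
  ll <- conditional_loglik(800, one_set$X, one_set$set_id, one_set$is_case)
  expect_true(is.finite(ll))
  ll <- conditional_loglik(-800, one_set$X, one_set$set_id,
                           one_set$is_case)
  expect_true(is.finite(ll))
})

test_that("analytic gradient matches central finite differences", {
  rs <- random_sets_multi(30, p = 3, n_ref = 3, beta = c(0.3, -0.2, 0.1),
                          seed = 3)
  for (b in list(c(0, 0, 0), c(0.5, -1, 0.25), c(-0.3, 0.8, -0.6))) {
    g <- attr(conditional_loglik(b, rs$X, rs$set_id, rs$is_case,
                                 gradient = TRUE), "gradient")
    gn <- num_grad(function(bb) conditional_loglik(bb, rs$X, rs$set_id,
                                                   rs$is_case), b)
    expect_equal(unname(g), gn, tolerance = 1e-6)
  }
})

test_that("likelihood is concave: Hessian negative semidefinite", {
  set.seed(9)
  for (rep in 1:5) {
    rs <- random_sets_multi(20, p = 3, n_ref = 3, seed = rep)
    b <- rnorm(3)
    H <- attr(conditional_loglik(b, rs$X, rs$set_id, rs$is_case,
                                 hessian = TRUE), "hessian")
    expect_true(all(eigen(H, symmetric = TRUE,
                          only.values = TRUE)$values < 1e-8))
  }
})

test_that("likelihood is invariant to per-set constant covariate offsets", {
  rs <- random_sets_multi(15, p = 2, n_ref = 3, seed = 4)
  set.seed(10)
  offs <- matrix(rnorm(15 * 2, sd = 50), 15, 2)
  Xoff <- rs$X + offs[rs$set_id, ]
  b <- c(0.7, -0.4)
  expect_equal(
    conditional_loglik(b, rs$X, rs$set_id, rs$is_case),
    conditional_loglik(b, Xoff, rs$set_id, rs$is_case),
    tolerance = 1e-12)
})

test_that("antisymmetric two-set design forces the fit to zero", {
  X <- matrix(c(1, 0, 0, 1), ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_clogit_design(X, set_id = c(1, 1, 2, 2),
                           is_case = c(1, 0, 1, 0))
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), 0)
  expect_equal(fit$loglik, -2 * log(2))
})

test_that("separation raises an explicit error naming the column", {
  X <- matrix(c(1, 0), ncol = 1, dimnames = list(NULL, "pm"))
  expect_error(fit_clogit_design(X, c(1, 1), c(1, 0)),
               "separation.*pm|pm.*separation")
})

test_that("stratum-constant columns raise a rank-deficiency error", {
  rs <- random_sets_multi(10, p = 2, n_ref = 3, seed = 5)
  # a modifier main effect: constant within every set
  Xbad <- cbind(rs$X, modifier_main = rep(rnorm(10), each = 4))
  expect_error(fit_clogit_design(Xbad, rs$set_id, rs$is_case),
               "modifier_main")
  # collinear duplicated column
  Xdup <- cbind(rs$X, x1_copy = rs$X[, 1])
  expect_error(fit_clogit_design(Xdup, rs$set_id, rs$is_case),
               "x1_copy|collinear")
})

test_that("Newton solution matches a dense grid-search argmax", {
  rs <- random_sets(50, beta = 0.6, n_ref = 3, seed = 6)
  fit <- fit_clogit_design(rs$X, rs$set_id, rs$is_case)
  expect_true(fit$converged)
  expect_lt(fit$grad_maxnorm, 1e-8)
  bgrid <- grid_argmax(rs$X, rs$set_id, rs$is_case)
  expect_equal(unname(fit$beta), bgrid, tolerance = 1e-4)
})

test_that("with one referent per set the fit uses only within-pair differences", {
  rs <- random_sets_multi(40, p = 2, n_ref = 1, beta = c(0.5, -0.3),
                          seed = 7)
  fit <- fit_clogit_design(rs$X, rs$set_id, rs$is_case)
  # shifting each pair by its own constant leaves the fit untouched
  set.seed(11)
  offs <- matrix(rnorm(40 * 2, sd = 10), 40, 2)
  fit2 <- fit_clogit_design(rs$X + offs[rs$set_id, ], rs$set_id,
                            rs$is_case)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-9)
  expect_equal(fit$se, fit2$se, tolerance = 1e-9)
})

test_that("coefficients and SEs agree with survival::clogit to 1e-6", {
  library(survival)
  cfg <- tiny_config(seed = 21)
  census <- simulate_census(cfg)
  exposure <- simulate_exposure(cfg, census)
  sim <- simulate_events(cfg, census, exposure)
  recs <- merge(sim$events, segregation_scores(census),
                by = "block_group_id")
  dsn <- build_matched_sets(recs, exposure)
  fit <- fit_cc_model(dsn, cc_model_spec("pct_black"))
  expect_true(fit$converged)

  df <- as.data.frame(dsn)
  tc <- fit$temp_center
  df$temp <- df$temp_window - tc
  df$pmxm <- df$pm25_window * df$pct_black
  ref <- survival::clogit(
    is_case ~ pm25_window + dow + temp + I(temp^2) + pmxm +
      survival::strata(record_id), data = df)
  expect_equal(unname(fit$beta["pm25_window"]),
               unname(coef(ref)["pm25_window"]), tolerance = 1e-6)
  expect_equal(unname(fit$beta[length(fit$beta)]),
               unname(coef(ref)["pmxm"]), tolerance = 1e-6)
  se_ref <- sqrt(diag(vcov(ref)))
  expect_equal(unname(fit$se["pm25_window"]),
               unname(se_ref["pm25_window"]), tolerance = 1e-6)
  expect_equal(unname(fit$se[length(fit$se)]), unname(se_ref["pmxm"]),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("temperature centering does not move the exposure estimate", {
  cfg <- tiny_config(seed = 22)
  study <- simulate_study(cfg)
  recs <- merge(study$events, study$scores, by = "block_group_id")
  dsn <- build_matched_sets(recs, study$exposure)
  dm <- cc_design_matrix(dsn, cc_model_spec())
  fit1 <- fit_clogit_design(dm$X, dm$set_id, dm$is_case)
  Xun <- dm$X
  tw <- Xun[, "temp"] + dm$temp_center   # uncentered parameterization
  Xun[, "temp"] <- tw
  Xun[, "temp_sq"] <- tw^2
  fit2 <- fit_clogit_design(Xun, dm$set_id, dm$is_case)
  expect_equal(fit1$beta["pm25_window"], fit2$beta["pm25_window"],
               tolerance = 1e-7)
  expect_equal(fit1$se["pm25_window"], fit2$se["pm25_window"],
               tolerance = 1e-7)
})

test_that("Wald test closed forms and refusal on non-convergence", {
  rs <- random_sets(60, beta = 0.5, n_ref = 3, seed = 8)
  fit <- fit_clogit_design(rs$X, rs$set_id, rs$is_case)
  w <- wald_test(fit, "x")
  expect_equal(w$z, unname(fit$beta / fit$se))
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))

  fit0 <- fit
  fit0$beta["x"] <- 0
  expect_equal(wald_test(fit0, "x")$p, 1)
  fit0$beta["x"] <- 1.96 * fit0$se["x"]
  expect_equal(wald_test(fit0, "x")$p, 0.05, tolerance = 1e-3)

  bad <- fit_clogit_design(rs$X, rs$set_id, rs$is_case, max_iter = 0L)
  expect_false(bad$converged)
  expect_error(wald_test(bad, "x"), "converge")
})

test_that("NAAQS restriction removes days and drops affected sets", {
  mk_set <- function(id, pm_case, pm_refs) {
    data.frame(record_id = id,
               date = as.Date("2009-07-01") + seq(0, length(pm_refs)),
               is_case = c(1L, rep(0L, length(pm_refs))),
               pm25 = c(pm_case, pm_refs),
               pm25_window = c(pm_case, pm_refs),
               temp_window = 20)
  }
  dsn <- rbind(mk_set("s1", 40, c(10, 12)),   # case above -> set dropped
               mk_set("s2", 12, c(45, 11)),   # one referent removed
               mk_set("s3", 20, c(50, 60)),   # no referent left -> dropped
               mk_set("s4", 10, c(10, 10)),   # untouched
               mk_set("s5", 34.9, c(35, 20)))  # boundary kept
  out <- restrict_below_threshold(dsn, 35)
  expect_setequal(unique(out$record_id), c("s2", "s4", "s5"))
  expect_equal(nrow(out[out$record_id == "s2", ]), 2L)
  lg <- attr(out, "log")
  expect_equal(lg$n_sets_before, 5L)
  expect_equal(lg$n_sets_after, 3L)
  expect_equal(lg$n_sets_dropped_case, 1L)
  expect_equal(lg$n_sets_dropped_no_referent, 1L)
  # all-below input is unchanged
  low <- rbind(mk_set("a", 10, c(9, 8)), mk_set("b", 20, c(30, 5)))
  expect_equal(nrow(restrict_below_threshold(low, 35)), nrow(low))
})

test_that("fit serializes to JSON with coefficients and diagnostics", {
  rs <- random_sets(30, beta = 0.4, seed = 9)
  fit <- fit_clogit_design(rs$X, rs$set_id, rs$is_case)
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$coefficients$x, unname(fit$beta), tolerance = 1e-12)
  expect_true(js$convergence$converged)
  expect_equal(js$n_sets, 30)
})
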