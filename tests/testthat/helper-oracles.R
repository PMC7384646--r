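# Independent oracles and small fixture builders used across the suite.

# Brute-force referent enumeration: scan every day of the case day's
# month and keep those a multiple of 3 days away from the case day.
brute_referents <- function(case_day) {
  case_day <- as.Date(case_day)
  lt <- as.POSIXlt(case_day)
  first <- as.Date(sprintf("%d-%02d-01", lt$year + 1900L, lt$mon + 1L))
  last <- seq(first, by = "month", length.out = 2)[2] - 1
  days <- seq(first, last, by = "day")
  days[days != case_day & as.integer(days - case_day) %% 3L == 0L]
}

# Central finite-difference gradient of a scalar function.
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Coarse-to-fine grid-search argmax of the one-parameter conditional
# log-likelihood; independent of the Newton path.
grid_argmax <- function(X, set_id, is_case, lo = -4, hi = 4) {
  f <- function(b) conditional_loglik(b, X, set_id, is_case)
  g1 <- seq(lo, hi, by = 1e-3)
  v1 <- vapply(g1, f, numeric(1))
  b1 <- g1[which.max(v1)]
  g2 <- seq(b1 - 1e-3, b1 + 1e-3, by = 1e-5)
  v2 <- vapply(g2, f, numeric(1))
  g2[which.max(v2)]
}

# Random one-covariate matched sets with a known generating beta:
# within each set the case day is drawn with softmax probability.
random_sets <- function(n_sets, beta = 0.5, n_ref = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n_sets * (n_ref + 1)), ncol = 1,
              dimnames = list(NULL, "x"))
  set_id <- rep(seq_len(n_sets), each = n_ref + 1)
  is_case <- integer(length(set_id))
  for (s in seq_len(n_sets)) {
    rows <- which(set_id == s)
    p <- exp(beta * X[rows, 1])
    is_case[sample(rows, 1, prob = p / sum(p))] <- 1L
  }
  list(X = X, set_id = set_id, is_case = is_case)
}

# Multi-covariate random matched sets for derivative/concavity checks.
random_sets_multi <- function(n_sets, p = 3, n_ref = 3, beta = NULL,
                              seed = 1) {
  set.seed(seed)
  n <- n_sets * (n_ref + 1)
  X <- matrix(rnorm(n * p), ncol = p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- rep(0, p)
  set_id <- rep(seq_len(n_sets), each = n_ref + 1)
  is_case <- integer(n)
  for (s in seq_len(n_sets)) {
    rows <- which(set_id == s)
    pr <- exp(drop(X[rows, , drop = FALSE] %*% beta))
    is_case[sample(rows, 1, prob = pr / sum(pr))] <- 1L
  }
  list(X = X, set_id = set_id, is_case = is_case)
}

# A small but fully featured synthetic study for unit tests.
tiny_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_block_groups = 60L, n_tracts = 15L,
               start = "2009-06-01", end = "2009-09-30",
               grid_nx = 4L, grid_ny = 3L, base_rate = 0.04)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cc_sim_config, args)
}
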