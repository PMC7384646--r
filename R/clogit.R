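#' Conditional logistic log-likelihood for matched sets
#'
#' Each matched set contributes the log softmax probability of its case
#' row among all rows of the set:
#' \deqn{\ell(\beta) = \sum_s [ x_{case,s}\beta - \log \sum_{j \in s}
#'   \exp(x_j\beta) ].}
#' Stratum-constant covariates cancel from every contribution, which is
#' why modifier main effects are inestimable in this design. The log-sum-exp
#' is stabilized by subtracting the per-set maximum, so the result is
#' finite for every finite `beta`.
#'
#' @param beta Coefficient vector (length `ncol(X)`).
#' @param X Numeric design matrix, one row per (set, day).
#' @param set_id Integer/character vector mapping rows to matched sets.
#' @param is_case 0/1 vector with exactly one 1 per set.
#' @param gradient,hessian Also return the analytic derivatives as
#'   attributes `gradient` / `hessian`?
#' @return Scalar log-likelihood, optionally with derivative attributes.
#' @export
conditional_loglik <- function(beta, X, set_id, is_case,
                               gradient = FALSE, hessian = FALSE) {
  X <- as.matrix(X)
  stopifnot(length(beta) == ncol(X), nrow(X) == length(set_id),
            nrow(X) == length(is_case))
  if (any(!is.finite(X))) stop("design matrix must be finite")
  idx <- cl_index(set_id, is_case)
  cl_core(beta, X, idx, gradient = gradient, hessian = hessian)
}

# Precomputed set structure: integer set ids, case rows, and a padded
# (set x max-set-size) row-index matrix for vectorized per-set maxima.
cl_index <- function(set_id, is_case) {
  sid <- match(set_id, unique(set_id))
  cs <- rowsum(as.numeric(is_case), sid, reorder = TRUE)
  if (any(cs != 1)) stop("every matched set needs exactly one case row")
  S <- max(sid)
  n <- length(sid)
  ord <- order(sid)
  nper <- tabulate(sid)
  M <- max(nper)
  pos <- sequence(nper)              # position within set, in sid order
  pad <- matrix(n + 1L, S, M)        # sentinel row
  pad[cbind(sid[ord], pos)] <- ord
  list(sid = sid, case = which(is_case == 1), pad = pad, S = S, n = n,
       nper = nper)
}

cl_core <- function(beta, X, idx, gradient = FALSE, hessian = FALSE) {
  eta <- drop(X %*% beta)
  etap <- c(eta, -Inf)
  EM <- matrix(etap[idx$pad], idx$S, ncol(idx$pad))
  mx_s <- EM[, 1]
  if (ncol(EM) > 1) {
    for (j in 2:ncol(EM)) mx_s <- pmax(mx_s, EM[, j])
  }
  w <- exp(eta - mx_s[idx$sid])
  denom <- rowSums(exp(EM - mx_s))
  ll <- sum(eta[idx$case]) - sum(log(denom) + mx_s)

  if (gradient || hessian) {
    p <- w / denom[idx$sid]
    Xp <- X * p
    g <- colSums(X[idx$case, , drop = FALSE]) - colSums(Xp)
    if (gradient) attr(ll, "gradient") <- g
    if (hessian) {
      xbar <- rowsum(Xp, idx$sid, reorder = TRUE)   # per-set weighted sums
      H <- -(crossprod(X * sqrt(p)) - crossprod(xbar))
      attr(ll, "hessian") <- H
    }
  }
  ll
}

#' Newton-Raphson maximizer of the matched-set conditional likelihood
#'
#' Fits conditional logistic regression by Newton-Raphson with
#' step-halving, starting at `beta = 0`. Convergence requires the
#' gradient max-norm to fall below `tol`, measured in standardized
#' covariate units (the gradient with respect to coefficients of
#' columns scaled to unit within-set standard deviation) so the
#' criterion is equivariant to the units of the covariates; for
#' columns already of order one it coincides with the raw-unit norm.
#' Before fitting, the design is
#' centered within sets and checked for full column rank: stratum-constant
#' columns (such as modifier main effects) and collinear columns raise an
#' error naming the offending columns. Monotone likelihoods (separation)
#' are detected when a standardized coefficient diverges and raise an
#' error naming the column.
#'
#' @inheritParams conditional_loglik
#' @param tol Gradient max-norm tolerance (default 1e-8), in
#'   standardized covariate units (see Details).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return Object of class `cc_fit`: list with `beta`, `se`, `cov`,
#'   `loglik`, `loglik_null`, `n_sets`, `n_rows`, `n_iterations`,
#'   `converged`, `grad_maxnorm`.
#' @export
fit_clogit_design <- function(X, set_id, is_case, tol = 1e-8,
                              max_iter = 50L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X))) {
    bad <- colnames(X)[apply(!is.finite(X), 2, any)]
    stop("non-finite values in design column(s): ",
         paste(bad, collapse = ", "))
  }
  sid <- as.integer(factor(set_id, levels = unique(set_id)))
  S <- max(sid)

  # within-set centering exposes inestimable / collinear columns
  nper <- tabulate(sid)
  Xc <- X - rowsum(X, sid, reorder = TRUE)[sid, , drop = FALSE] / nper[sid]
  sdc <- apply(Xc, 2, stats::sd)
  const_cols <- colnames(X)[sdc == 0]
  if (length(const_cols)) {
    stop("column(s) constant within every matched set (inestimable, ",
         "main effects of person/place attributes cancel from the ",
         "conditional likelihood): ", paste(const_cols, collapse = ", "))
  }
  qr_c <- qr(Xc)
  if (qr_c$rank < ncol(X)) {
    bad <- colnames(X)[qr_c$pivot[(qr_c$rank + 1):ncol(X)]]
    stop("within-set-centered design is rank deficient; collinear ",
         "column(s): ", paste(bad, collapse = ", "))
  }

  p <- ncol(X)
  # Optimize in a standardized parameterization: columns centered at
  # their overall means (a global shift is constant within every set, so
  # the likelihood is unchanged) and scaled to unit within-set sd. This
  # keeps gradient sums far from the floating-point cancellation floor;
  # coefficients, covariance and the gradient transform back exactly
  # (beta = beta_std / sd, grad = grad_std * sd).
  Xs <- (X - rep(colMeans(X), each = nrow(X))) *
    rep(1 / sdc, each = nrow(X))
  beta <- rep(0, p)
  idx <- cl_index(sid, is_case)
  ll <- cl_core(beta, Xs, idx, gradient = TRUE, hessian = TRUE)
  ll0 <- as.numeric(ll)
  it <- 0L
  repeat {
    g <- attr(ll, "gradient")   # standardized units: per within-set sd
    if (max(abs(g)) < tol || it >= max_iter) break
    H <- attr(ll, "hessian")
    step <- tryCatch(solve(H, -g), error = function(e) {
      qr.solve(H + diag(1e-10, p), -g)
    })
    # step halving
    lam <- 1
    repeat {
      cand <- beta + lam * step
      llc <- cl_core(cand, Xs, idx, gradient = TRUE, hessian = TRUE)
      if (as.numeric(llc) >= as.numeric(ll) - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    beta <- cand
    ll <- llc
    it <- it + 1L
    if (any(abs(beta) > 12)) {   # beta is per within-set sd here
      stop("separation / monotone likelihood detected: coefficient for ",
           colnames(X)[which.max(abs(beta))],
           " diverges (|beta|*sd > 12); the conditional likelihood has ",
           "no finite maximum")
    }
  }
  g <- attr(ll, "gradient")                # standardized-units gradient
  converged <- max(abs(g)) < tol
  H <- attr(ll, "hessian")
  cov_s <- solve(-H)
  cov <- cov_s * tcrossprod(1 / sdc)       # back-transform covariance
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(beta / sdc, colnames(X))
  structure(list(
    beta = beta, se = sqrt(diag(cov)), cov = cov,
    loglik = as.numeric(ll), loglik_null = ll0,
    n_sets = S, n_rows = nrow(X),
    n_iterations = it, converged = converged,
    grad_maxnorm = max(abs(g))), class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("Conditional logistic fit:", x$n_sets, "matched sets,",
      x$n_rows, "person-days\n")
  z <- x$beta / x$se
  tab <- data.frame(estimate = x$beta, se = x$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  print(round(tab, 6))
  cat("loglik:", format(x$loglik), " iterations:", x$n_iterations,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Wald test for one coefficient of a conditional logistic fit
#'
#' @param fit A converged [fit_clogit_design()] / [fit_cc_model()] result.
#' @param coef Coefficient name or index.
#' @return List with `z` and two-sided `p`.
#' @export
wald_test <- function(fit, coef) {
  stopifnot(inherits(fit, "cc_fit"))
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge (gradient max-norm ",
         format(fit$grad_maxnorm), "); Wald inference refused")
  }
  b <- fit$beta[coef]
  s <- fit$se[coef]
  if (any(is.na(b))) stop("unknown coefficient: ", coef)
  z <- unname(b / s)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Model specification for the case-crossover mortality model
#'
#' Describes the design-matrix recipe: the lag-window PM2.5 exposure
#' term, adjustment for day of week (six indicators, Sunday reference)
#' and linear plus quadratic lag-window temperature (centered at the
#' sample mean before squaring), and optionally one multiplicative
#' exposure-by-modifier interaction. Modifier main effects are never
#' included: they are constant within a matched set and cancel from the
#' conditional likelihood.
#'
#' @param modifier One of `"none"`, `"race"`, `"pct_black"`,
#'   `"pct_white"`, `"ird"` (continuous interactions) or
#'   `"rrs_category"` (four interaction dummies, G1 reference).
#' @param exposure Name of the exposure column, default `"pm25_window"`.
#' @return Object of class `cc_model_spec`.
#' @export
cc_model_spec <- function(modifier = c("none", "race", "pct_black",
                                       "pct_white", "ird", "rrs_category"),
                          exposure = "pm25_window") {
  modifier <- match.arg(modifier)
  structure(list(modifier = modifier, exposure = exposure),
            class = "cc_model_spec")
}

#' Build the model design matrix from a long matched-set table
#'
#' @param design Long design from [build_matched_sets()].
#' @param spec A [cc_model_spec()].
#' @return List with `X` (matrix), `set_id`, `is_case`, `temp_center`.
#' @keywords internal
cc_design_matrix <- function(design, spec) {
  design <- as.data.frame(design)
  tc <- mean(design$temp_window)
  tw <- design$temp_window - tc
  dow <- day_of_week(design$date)
  dow_mat <- stats::model.matrix(~dow)[, -1, drop = FALSE]
  colnames(dow_mat) <- sub("^dow", "dow_", colnames(dow_mat))
  X <- cbind(pm25_window = design[[spec$exposure]],
             dow_mat, temp = tw, temp_sq = tw^2)
  if (spec$modifier == "race") {
    m <- as.numeric(design$race == "black")
    X <- cbind(X, `pm25_window:race_black` = X[, "pm25_window"] * m)
  } else if (spec$modifier %in% c("pct_black", "pct_white", "ird")) {
    m <- design[[spec$modifier]]
    if (is.null(m)) stop("modifier column absent from design: ",
                         spec$modifier)
    X <- cbind(X, X[, "pm25_window"] * m)
    colnames(X)[ncol(X)] <- paste0("pm25_window:", spec$modifier)
  } else if (spec$modifier == "rrs_category") {
    rc <- factor(design$rrs_category, levels = paste0("G", 1:5))
    dums <- stats::model.matrix(~rc)[, -1, drop = FALSE]  # G2..G5 vs G1
    pres <- levels(rc)[-1] %in% unique(as.character(rc))
    dums <- dums[, pres, drop = FALSE]
    inter <- dums * X[, "pm25_window"]
    colnames(inter) <- paste0("pm25_window:rrs_", sub("^rc", "",
                              colnames(dums)))
    X <- cbind(X, inter)
  }
  list(X = X, set_id = design$record_id,
       is_case = design$is_case, temp_center = tc)
}

#' Fit the case-crossover mortality model
#'
#' High-level wrapper: builds the design matrix described by a
#' [cc_model_spec()] from a long matched-set table and maximizes the
#' conditional logistic likelihood.
#'
#' @param design Long design from [build_matched_sets()] (optionally
#'   merged with segregation scores).
#' @param spec A [cc_model_spec()]; defaults to the unmodified model.
#' @param ... Passed to [fit_clogit_design()].
#' @return A `cc_fit` with the spec and temperature centering constant
#'   attached (`$spec`, `$temp_center`).
#' @export
fit_cc_model <- function(design, spec = cc_model_spec(), ...) {
  n_dropped_modifier <- 0L
  if (spec$modifier != "none") {
    modcol <- if (spec$modifier == "race") "race" else spec$modifier
    if (is.null(design[[modcol]])) {
      stop("modifier column absent from design: ", modcol)
    }
    # flagged-undefined scores (e.g. IRD of a single-race tract) exclude
    # the affected decedents from that modifier's analysis
    bad <- unique(design$record_id[is.na(design[[modcol]])])
    if (length(bad)) {
      design <- design[!(design$record_id %in% bad), ]
      n_dropped_modifier <- length(bad)
    }
  }
  dm <- cc_design_matrix(design, spec)
  fit <- fit_clogit_design(dm$X, dm$set_id, dm$is_case, ...)
  fit$spec <- spec
  fit$temp_center <- dm$temp_center
  fit$n_dropped_modifier_missing <- n_dropped_modifier
  fit
}

#' Restrict matched sets to days below a PM2.5 threshold
#'
#' Sensitivity-analysis filter mirroring restriction to periods below the
#' 24-hour National Ambient Air Quality Standard (35 ug/m3): any day
#' (case or referent) whose own daily PM2.5 exceeds the threshold is
#' removed; a set is dropped entirely when its case day is removed or no
#' referent day remains.
#'
#' @param design Long design with a daily `pm25` column.
#' @param threshold PM2.5 threshold in ug/m3, default 35.
#' @return Filtered design; attribute `log` reports counts of removed
#'   days and dropped sets.
#' @export
restrict_below_threshold <- function(design, threshold = 35) {
  stopifnot(threshold > 0)
  dt <- data.table::as.data.table(design)
  n0 <- nrow(dt)
  sets0 <- length(unique(dt$record_id))
  drop_sets <- unique(dt[pm25 > threshold & is_case == 1L, record_id])
  dt <- dt[pm25 <= threshold & !(record_id %in% drop_sets)]
  nref <- dt[, list(nref = sum(is_case == 0L)), by = "record_id"]
  no_ref <- nref[nref == 0L, record_id]
  dt <- dt[!(record_id %in% no_ref)]
  attr(dt, "log") <- list(
    n_days_removed = n0 - nrow(dt),
    n_sets_before = sets0,
    n_sets_after = length(unique(dt$record_id)),
    n_sets_dropped_case = length(drop_sets),
    n_sets_dropped_no_referent = length(no_ref))
  dt
}

#' Serialize a fit to JSON
#'
#' @param fit A `cc_fit`.
#' @param path Optional output path; if `NULL`, the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "cc_fit"))
  obj <- list(
    coefficients = as.list(fit$beta),
    se = as.list(fit$se),
    covariance = unname(fit$cov),
    loglik = fit$loglik,
    n_sets = fit$n_sets,
    convergence = list(converged = fit$converged,
                       iterations = fit$n_iterations,
                       grad_maxnorm = fit$grad_maxnorm))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
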