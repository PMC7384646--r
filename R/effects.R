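#' Percent change per exposure increment
#'
#' Transforms a per-unit log odds ratio to the reporting scale used for
#' short-term air-pollution effects: the percent change in mortality risk
#' per `delta` (default 10 ug/m3) increase in exposure,
#' \deqn{PC = 100 (e^{\delta\beta} - 1)},
#' with a Wald confidence interval transformed the same way.
#'
#' @param beta Per-unit log odds estimate.
#' @param se Its standard error (>= 0).
#' @param delta Exposure increment, default 10.
#' @param conf Confidence level, default 0.95.
#' @param label Optional label carried into the result.
#' @return One-row data frame (`label`, `percent_change`, `ci_low`,
#'   `ci_high`), class `cc_effect`.
#' @export
percent_change <- function(beta, se, delta = 10, conf = 0.95,
                           label = "overall") {
  stopifnot(se >= 0, delta > 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(
    label = label,
    percent_change = 100 * (exp(delta * beta) - 1),
    ci_low = 100 * (exp(delta * (beta - z * se)) - 1),
    ci_high = 100 * (exp(delta * (beta + z * se)) - 1),
    stringsAsFactors = FALSE)
  class(out) <- c("cc_effect", "data.frame")
  out
}

#' Inverse of the percent-change transform
#'
#' @param pc Percent change per `delta` units.
#' @param delta Exposure increment, default 10.
#' @return The per-unit log odds `beta`.
#' @export
percent_change_inv <- function(pc, delta = 10) {
  log(1 + pc / 100) / delta
}

#' Exposure effect at a stated modifier value
#'
#' For a fit with a continuous exposure-by-modifier interaction, the
#' per-unit log odds at modifier value `m` is \eqn{b(m) = \beta_1 + m
#' \beta_2} with delta-method standard error
#' \eqn{se(m) = \sqrt{v_{11} + m^2 v_{22} + 2 m v_{12}}}. The result is
#' reported as percent change per `delta` units of exposure.
#'
#' @param fit A converged `cc_fit` whose spec includes a continuous
#'   modifier (or `race`).
#' @param m Modifier value(s) at which to evaluate the effect.
#' @param delta Exposure increment, default 10.
#' @param label Optional labels, recycled along `m`.
#' @return `cc_effect` data frame, one row per value of `m`, with an
#'   `interaction_p` column (single-coefficient Wald test).
#' @export
effect_at_modifier <- function(fit, m, delta = 10, label = NULL) {
  stopifnot(inherits(fit, "cc_fit"))
  exposure <- fit$spec$exposure %||% "pm25_window"
  inter <- grep(paste0("^", exposure, ":"), names(fit$beta), value = TRUE)
  if (length(inter) != 1) {
    stop("fit does not contain a single continuous interaction term")
  }
  b1 <- fit$beta[[exposure]]
  b2 <- fit$beta[[inter]]
  v11 <- fit$cov[exposure, exposure]
  v22 <- fit$cov[inter, inter]
  v12 <- fit$cov[exposure, inter]
  bm <- b1 + m * b2
  sem <- sqrt(v11 + m^2 * v22 + 2 * m * v12)
  if (is.null(label)) label <- paste0("m=", format(m))
  out <- do.call(rbind, lapply(seq_along(m), function(i) {
    percent_change(bm[i], sem[i], delta = delta, label = label[i])
  }))
  out$interaction_p <- wald_test(fit, inter)$p
  out
}

#' Nearest-rank percentiles of a modifier over decedents
#'
#' Empirical percentiles of a modifier across the analysis population
#' (one value per matched set / decedent), using the nearest-rank
#' convention: the p-th percentile is the value at sorted position
#' `ceiling(n * p / 100)`.
#'
#' @param x Modifier values, one per decedent.
#' @param probs Percentiles to report, default 10, 50, 90.
#' @return Named numeric vector (`p10`, `p50`, `p90`, ...).
#' @export
modifier_percentiles <- function(x, probs = c(10, 50, 90)) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 10) {
    stop("need at least 10 distinct modifier values")
  }
  s <- sort(x)
  n <- length(s)
  out <- s[pmin(n, pmax(1L, ceiling(n * probs / 100)))]
  names(out) <- paste0("p", probs)
  out
}

#' Per-category exposure effects for the five-level RRS interaction
#'
#' For a fit with four exposure-by-RRS-category interaction dummies
#' (G2..G5 versus the most black-segregated reference group G1), returns
#' the percent change per `delta` units in each category:
#' the G1 effect is the exposure coefficient itself; each other
#' category's log odds is \eqn{\beta_1 + \beta_{2c}} with delta-method
#' standard error from the corresponding 2x2 covariance block. The
#' per-category Wald interaction p-value (dummy vs reference) is
#' reported alongside. Categories absent from the fitted data are
#' reported with `NA` estimates, not zero.
#'
#' @param fit A converged `cc_fit` from the `rrs_category` model spec.
#' @param delta Exposure increment, default 10.
#' @return `cc_effect` data frame with one row per category G1..G5 and an
#'   `interaction_p` column (`NA` for the reference).
#' @export
categorical_effects <- function(fit, delta = 10) {
  stopifnot(inherits(fit, "cc_fit"))
  exposure <- fit$spec$exposure %||% "pm25_window"
  b1 <- fit$beta[[exposure]]
  v11 <- fit$cov[exposure, exposure]
  rows <- list(cbind(percent_change(b1, sqrt(v11), delta = delta,
                                    label = "G1"), interaction_p = NA_real_))
  for (g in paste0("G", 2:5)) {
    nm <- paste0(exposure, ":rrs_", g)
    if (!nm %in% names(fit$beta)) {
      r <- data.frame(label = g, percent_change = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      interaction_p = NA_real_, stringsAsFactors = FALSE)
      class(r) <- c("cc_effect", "data.frame")
      rows <- c(rows, list(r))
      next
    }
    b2 <- fit$beta[[nm]]
    se <- sqrt(v11 + fit$cov[nm, nm] + 2 * fit$cov[exposure, nm])
    r <- percent_change(b1 + b2, se, delta = delta, label = g)
    r$interaction_p <- wald_test(fit, nm)$p
    rows <- c(rows, list(r))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cc_effect", "data.frame")
  out
}

#' Forest-style plot of effect estimates
#'
#' Point estimates and confidence intervals of percent change per
#' exposure increment, one row per label (base graphics).
#'
#' @param x A `cc_effect` data frame.
#' @param xlab X-axis label.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cc_effect <- function(x, xlab = "% change per 10 µg/m³ PM2.5",
                           ...) {
  keep <- !is.na(x$percent_change)
  x2 <- x[keep, , drop = FALSE]
  n <- nrow(x2)
  y <- rev(seq_len(n))
  rng <- range(c(x2$ci_low, x2$ci_high, 0))
  graphics::plot(x2$percent_change, y, xlim = rng, ylim = c(0.5, n + 0.5),
                 pch = 16, yaxt = "n", ylab = "", xlab = xlab, ...)
  graphics::segments(x2$ci_low, y, x2$ci_high, y)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = y, labels = x2$label, las = 1)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
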