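## weighted least-squares asymmetry regression kernel.
## y: effects; x: precision ordinate (SE or 1/sqrt(n)); w: weights.
## With w = 1/x^2 this is Egger's classic test applied to the funnel plot
## built on x: the WLS coefficient of x equals the intercept of the OLS
## regression of y/x on 1/x.
.egger_fit <- function(y, x, w) {
  k <- length(y)
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0)
    stop("degenerate design: the precision predictor is constant", call. = FALSE)
  b <- sum(w * (x - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  res <- y - a - b * x
  s2 <- sum(w * res^2) / (k - 2)
  se_b <- sqrt(s2 / sxx)
  if (se_b == 0) {
    tval <- if (abs(b) < 1e-12) 0 else sign(b) * Inf
  } else tval <- b / se_b
  p <- 2 * stats::pt(-abs(tval), df = k - 2)
  list(coef = b, se_coef = se_b, t = tval, p = p, intercept = a, df = k - 2)
}

.precision_vec <- function(data, predictor) {
  switch(predictor,
         SE = data$se,
         inv_sqrt_n = 1 / sqrt(data$n_ctrl + data$n_int))
}

#' Egger-type regression test for funnel-plot asymmetry
#'
#' Weighted least-squares regression of the study effects \eqn{\theta_i} on
#' a precision ordinate \eqn{x_i}, with weights \eqn{1/x_i^2}; the
#' asymmetry coefficient is the coefficient of \eqn{x_i}, tested two-sided
#' against a t distribution with \eqn{k - 2} degrees of freedom.
#'
#' For `predictor = "SE"` (\eqn{x_i = se_i}, weights \eqn{1/se_i^2}) this is
#' algebraically identical to Egger's classic intercept test: the OLS
#' regression of the standardized effects \eqn{\theta_i/se_i} on the
#' precisions \eqn{1/se_i}, testing the intercept. For
#' `predictor = "inv_sqrt_n"` the same construction is applied to the
#' funnel plot that uses the sample-size-based ordinate
#' \eqn{x_i = 1/\sqrt{n_i}} (weights \eqn{n_i}), which removes the
#' artifactual coupling between a standardized mean difference and its
#' standard error.
#'
#' @param data A [meta_dataset()] with at least 3 studies.
#' @param predictor `"SE"` or `"inv_sqrt_n"`.
#' @return An object of class `"egger_result"`: `coef`, `se_coef`,
#'   `t_stat`, `p`, `intercept` (the limit estimate as precision grows),
#'   `predictor`, `k`, `df`.
#' @examples
#' d <- meta_dataset(c(1, 2, 3), c(1, 2, 3), c(10, 10, 10), c(10, 10, 10), "RMD")
#' egger_test(d)   # coef = 1: constant standardized effect
#' @export
egger_test <- function(data, predictor = c("SE", "inv_sqrt_n")) {
  predictor <- match.arg(predictor)
  .check_meta(data, 3L, "Egger's regression")
  x <- .precision_vec(data, predictor)
  f <- .egger_fit(data$estimate, x, 1 / x^2)
  structure(list(coef = f$coef, se_coef = f$se_coef, t_stat = f$t, p = f$p,
                 intercept = f$intercept, predictor = predictor,
                 k = nrow(data), df = f$df),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat("Egger regression test for funnel-plot asymmetry\n")
  cat(sprintf("  predictor: %s (k = %d)\n",
              if (x$predictor == "SE") "standard error" else "1/sqrt(n)", x$k))
  cat(sprintf("  asymmetry coefficient: %.4f (SE %.4f)\n", x$coef, x$se_coef))
  cat(sprintf("  t = %.4f, df = %d, p = %.4g\n", x$t_stat, x$df, x$p))
  invisible(x)
}

#' Begg-Mazumdar rank-correlation test
#'
#' Kendall rank correlation (tau-b, with tie correction) between the
#' standardized effect deviations
#' \eqn{(\theta_i - \hat\mu_F)/\sqrt{se_i^2 - SE(\hat\mu_F)^2}} and the
#' sampling variances \eqn{se_i^2}, where \eqn{\hat\mu_F} is the
#' fixed-effect pooled estimate. The p-value uses the normal approximation
#' for Kendall's S with the standard tie correction.
#'
#' @param data A [meta_dataset()] with at least 3 studies.
#' @return An object of class `"begg_result"`: `kendall_tau`, `p`, `k`.
#' @export
begg_test <- function(data) {
  .check_meta(data, 3L, "the Begg-Mazumdar test")
  y <- data$estimate
  v <- data$se^2
  f <- .pool_fixed_vec(y, v)
  vstar <- v - 1 / f$sw          # v_i - var(mu_F); positive for k >= 2
  z <- (y - f$mu) / sqrt(vstar)
  kt <- .kendall_tau_b(z, v)
  structure(list(kendall_tau = kt$tau, p = kt$p, k = nrow(data)),
            class = "begg_result")
}

## Kendall tau-b with tie-corrected normal approximation for S
.kendall_tau_b <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  S <- sum(dx[lower.tri(dx)] * dy[lower.tri(dy)])
  tie_term <- function(z, f) {
    t <- table(z); t <- t[t > 1]
    if (!length(t)) 0 else sum(f(as.numeric(t)))
  }
  n0 <- n * (n - 1) / 2
  n1 <- tie_term(x, function(t) t * (t - 1) / 2)
  n2 <- tie_term(y, function(t) t * (t - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  tau <- if (denom > 0) S / denom else 0
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- tie_term(x, function(t) t * (t - 1) * (2 * t + 5))
  vu <- tie_term(y, function(t) t * (t - 1) * (2 * t + 5))
  v1 <- tie_term(x, function(t) t * (t - 1)) * tie_term(y, function(t) t * (t - 1)) /
    (2 * n * (n - 1))
  v2 <- tie_term(x, function(t) t * (t - 1) * (t - 2)) *
    tie_term(y, function(t) t * (t - 1) * (t - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  p <- if (varS > 0) 2 * stats::pnorm(-abs(S) / sqrt(varS)) else 1
  list(tau = tau, p = min(1, p), S = S)
}

#' @export
print.begg_result <- function(x, ...) {
  cat("Begg-Mazumdar rank correlation test\n")
  cat(sprintf("  Kendall tau = %.4f (k = %d), p = %.4g\n", x$kendall_tau, x$k, x$p))
  invisible(x)
}

## one estimation of the number of missing studies, for data mirrored so
## that the missing side is the LEFT (observed excess on the right).
## mu: current centre. Returns the L0 or R0 estimate (unrounded).
## deviations from the centre, snapped to a relative tolerance so that
## exactly mirrored studies tie and an exactly central study counts as
## neither side (guards the rank sums against 1-ulp noise in the centre)
.snap_dev <- function(y, mu) {
  dev <- y - mu
  tol <- 1e-8 * max(abs(dev), 1e-300)
  dev[abs(dev) < tol] <- 0
  list(dev = dev, bins = round(abs(dev) / tol))
}

.k0_estimate <- function(y, mu, estimator) {
  k <- length(y)
  s <- .snap_dev(y, mu)
  dev <- s$dev
  r <- rank(s$bins, ties.method = "average")
  if (estimator == "L0") {
    Tn <- sum(r[dev > 0])
    (4 * Tn - k * (k + 1)) / (2 * k - 1)
  } else {
    ## R0: length of the run of most-extreme ranks that all lie right of mu
    pos <- dev > 0
    ord <- order(r, decreasing = TRUE)
    gamma <- 0
    for (i in ord) { if (pos[i]) gamma <- gamma + 1 else break }
    gamma - 1
  }
}

#' Duval and Tweedie's trim-and-fill
#'
#' Estimates the number of studies missing from one side of a funnel plot,
#' imputes mirror-image counterparts, and re-computes the pooled effect.
#' Iteratively: the random-effects ([pool_random()]) estimate centres the
#' plot; the rank-based `L0` estimator (default; `R0` available) counts the
#' excess extreme studies on the overrepresented side; those studies are
#' trimmed and the centre re-estimated; the loop repeats until the count
#' stabilizes. The final missing studies are imputed by reflecting the
#' trimmed studies around the adjusted centre, keeping each source study's
#' standard error and sample sizes, and the adjusted pooled estimate is the
#' random-effects pool of observed plus filled studies.
#'
#' `side` is the side of the plot where studies are suspected missing.
#' `"auto"` follows the proposed direction of the intervention effect:
#' if the pooled estimate is positive, small or negative studies would be
#' the unpublished ones, so the missing side is the left (and conversely).
#'
#' @param data A [meta_dataset()] with at least 3 studies.
#' @param side `"auto"`, `"left"` or `"right"`.
#' @param estimator `"L0"` (default) or `"R0"`.
#' @param maxiter Iteration cap; exceeding it raises an error.
#' @return An object of class `"trimfill_result"`: `k0` (number of imputed
#'   studies), `side`, `estimator`, `adjusted` (a `"pool_result"` on
#'   observed + filled studies), `filled` (a [meta_dataset()] of the
#'   imputed studies), `augmented` (observed + filled), `iterations`.
#'   When `k0 = 0` the adjusted pool equals the unadjusted [pool_random()].
#' @examples
#' d <- meta_dataset(3:5, rep(1, 3), rep(10, 3), rep(10, 3), "RMD")
#' trim_and_fill(d, side = "left")
#' @export
trim_and_fill <- function(data, side = c("auto", "left", "right"),
                          estimator = c("L0", "R0"), maxiter = 50L) {
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  .check_meta(data, 3L, "trim-and-fill")
  y0 <- data$estimate
  v0 <- data$se^2
  k <- length(y0)
  if (side == "auto") {
    mu0 <- .pool_dl_vec(y0, v0)$mu
    side <- if (mu0 >= 0) "left" else "right"
  }
  ## work on the orientation with the missing side on the left
  flip <- side == "right"
  y <- if (flip) -y0 else y0
  ord <- order(y)                      # ascending; rightmost are trimmed
  ys <- y[ord]; vs <- v0[ord]
  k0 <- 0L
  iter <- 0L
  repeat {
    keep <- seq_len(k - k0)
    mu <- .pool_dl_vec(ys[keep], vs[keep])$mu
    k0new <- min(k - 1L, max(0L, as.integer(round(.k0_estimate(ys, mu, estimator)))))
    iter <- iter + 1L
    if (k0new == k0) break
    if (iter >= maxiter)
      stop("trim-and-fill did not converge in ", maxiter, " iterations",
           call. = FALSE)
    k0 <- k0new
  }
  keep <- seq_len(k - k0)
  mu_trim <- .pool_dl_vec(ys[keep], vs[keep])$mu
  idx_orig <- ord                       # positions in the original data
  if (k0 > 0) {
    trimmed <- idx_orig[(k - k0 + 1):k]
    fill_est <- 2 * mu_trim - y[trimmed]
    if (flip) fill_est <- -fill_est
    filled <- meta_dataset(fill_est, data$se[trimmed], data$n_ctrl[trimmed],
                           data$n_int[trimmed], .measure_tag(data),
                           study_id = paste0("fill_", data$study_id[trimmed]))
  } else {
    filled <- meta_dataset(numeric(0), numeric(0), integer(0), integer(0),
                           .measure_tag(data))
  }
  aug <- rbind(as.data.frame(data), as.data.frame(filled))
  augmented <- meta_dataset(aug$estimate, aug$se, aug$n_ctrl, aug$n_int,
                            .measure_tag(data), study_id = aug$study_id)
  adjusted <- pool_random(augmented)
  structure(list(k0 = k0, side = side, estimator = estimator,
                 adjusted = adjusted, filled = filled, augmented = augmented,
                 iterations = iter),
            class = "trimfill_result")
}

#' @export
print.trimfill_result <- function(x, ...) {
  cat("Duval-Tweedie trim-and-fill\n")
  cat(sprintf("  estimated missing studies on the %s side: %d (%s estimator)\n",
              x$side, x$k0, x$estimator))
  cat(sprintf("  adjusted pooled estimate: %.4f (SE %.4f)\n",
              x$adjusted$mu_hat, x$adjusted$se_mu))
  invisible(x)
}

## fast internal version for the simulation engine: returns k0 and the
## adjusted random-effects mean only. y, v vectors; missing side left if
## the DL mean is >= 0 (auto rule).
.trimfill_fast <- function(y, v, maxiter = 50L) {
  k <- length(y)
  mu0 <- .pool_dl_vec(y, v)$mu
  flip <- mu0 < 0
  if (flip) y <- -y
  ord <- order(y)
  ys <- y[ord]; vs <- v[ord]
  k0 <- 0L
  for (iter in seq_len(maxiter)) {
    keep <- seq_len(k - k0)
    mu <- .pool_dl_vec(ys[keep], vs[keep])$mu
    s <- .snap_dev(ys, mu)
    dev <- s$dev
    r <- rank(s$bins, ties.method = "average")
    L0 <- (4 * sum(r[dev > 0]) - k * (k + 1)) / (2 * k - 1)
    k0new <- min(k - 1L, max(0L, as.integer(round(L0))))
    if (k0new == k0) break
    k0 <- k0new
  }
  keep <- seq_len(k - k0)
  mu_trim <- .pool_dl_vec(ys[keep], vs[keep])$mu
  if (k0 > 0) {
    fe <- 2 * mu_trim - ys[(k - k0 + 1):k]
    adj <- .pool_dl_vec(c(ys, fe), c(vs, vs[(k - k0 + 1):k]))$mu
  } else adj <- .pool_dl_vec(ys, vs)$mu
  if (flip) adj <- -adj
  list(k0 = k0, adjusted = adj)
}
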