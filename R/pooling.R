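## inverse-variance pooling kernels, shared with trim-and-fill and the
## simulation engine; y = effects, v = squared standard errors

.pool_fixed_vec <- function(y, v) {
  w <- 1 / v
  sw <- sum(w)
  mu <- sum(w * y) / sw
  list(mu = mu, se = 1 / sqrt(sw), w = w, sw = sw)
}

.pool_dl_vec <- function(y, v) {
  f <- .pool_fixed_vec(y, v)
  k <- length(y)
  Q <- sum(f$w * (y - f$mu)^2)
  C <- f$sw - sum(f$w^2) / f$sw
  tau2 <- max(0, (Q - (k - 1)) / C)
  ws <- 1 / (v + tau2)
  list(mu = sum(ws * y) / sum(ws), se = 1 / sqrt(sum(ws)), tau2 = tau2, Q = Q)
}

.new_pool <- function(mu, se, tau2, model, k) {
  structure(list(mu_hat = mu, se_mu = se, tau2 = tau2, model = model, k = k,
                 ci_lb = mu - stats::qnorm(0.975) * se,
                 ci_ub = mu + stats::qnorm(0.975) * se),
            class = "pool_result")
}

#' @export
print.pool_result <- function(x, ...) {
  cat(sprintf("%s-effect pooled estimate (k = %d)\n",
              if (x$model == "fixed") "Fixed" else "Random", x$k))
  cat(sprintf("  mu = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$mu_hat, x$se_mu, x$ci_lb, x$ci_ub))
  if (x$model == "random") cat(sprintf("  tau^2 (DerSimonian-Laird) = %.4f\n", x$tau2))
  invisible(x)
}

.check_meta <- function(data, min_k, what) {
  stopifnot(inherits(data, "meta_dataset"))
  if (nrow(data) < min_k)
    stop("insufficient studies: ", what, " requires at least ", min_k,
         " studies, got ", nrow(data), call. = FALSE)
  invisible(data)
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Pools a meta-analysis dataset with inverse-variance weights
#' \eqn{w_i = 1/se_i^2}: \eqn{\hat\mu = \sum w_i \theta_i / \sum w_i},
#' \eqn{SE(\hat\mu) = 1/\sqrt{\sum w_i}}. Used internally as the
#' re-estimation step of trim-and-fill and as the centring estimate of the
#' Begg-Mazumdar test.
#'
#' @param data A [meta_dataset()] with at least 2 studies.
#' @return An object of class `"pool_result"` with elements `mu_hat`,
#'   `se_mu`, `tau2` (0 for the fixed-effect model), `model`, `k`.
#' @examples
#' d <- meta_dataset(c(2, 4), c(1, 2), c(10, 10), c(10, 10), "RMD")
#' pool_fixed(d)   # mu_hat = 2.4
#' @export
pool_fixed <- function(data) {
  .check_meta(data, 2L, "pooling")
  f <- .pool_fixed_vec(data$estimate, data$se^2)
  .new_pool(f$mu, f$se, 0, "fixed", nrow(data))
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' Pools a meta-analysis dataset under the random-effects model with the
#' closed-form DerSimonian-Laird moment estimator of the between-study
#' variance \eqn{\tau^2} (truncated at zero), weights
#' \eqn{w_i^* = 1/(se_i^2 + \tau^2)}, and a plain Wald standard error.
#' This is the summary estimate used as the funnel-plot centreline and
#' inside every trim-and-fill iteration.
#'
#' @inheritParams pool_fixed
#' @return A `"pool_result"`; `tau2 = 0` (and agreement with [pool_fixed()])
#'   whenever Cochran's Q is at most `k - 1`.
#' @examples
#' d <- meta_dataset(c(0, 10), c(1, 1), c(10, 10), c(10, 10), "RMD")
#' pool_random(d)   # mu_hat = 5, tau2 = 49
#' @export
pool_random <- function(data) {
  .check_meta(data, 2L, "pooling")
  r <- .pool_dl_vec(data$estimate, data$se^2)
  .new_pool(r$mu, r$se, r$tau2, "random", nrow(data))
}
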