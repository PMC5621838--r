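test_that("Egger regression reproduces hand WLS and the classic intercept form", {
  # (theta, se) = (1,1),(2,2),(3,3): standardized effects all 1, so the
  # classic regression of theta/se on 1/se has slope 0 and intercept 1
  d <- meta_dataset(1:3, 1:3, rep(10, 3), rep(10, 3), "RMD")
  e <- egger_test(d, predictor = "SE")
  expect_equal(e$coef, 1, tolerance = 1e-12)

  # independent normal-equations oracle via lm on random datasets
  set.seed(3)
  for (i in 1:10) {
    d <- random_meta(sample(4:30, 1))
    e <- egger_test(d, predictor = "SE")
    fit <- lm(estimate ~ se, data = d, weights = 1 / d$se^2)
    cf <- summary(fit)$coefficients
    expect_equal(e$coef, cf["se", "Estimate"], tolerance = 1e-10)
    expect_equal(e$se_coef, cf["se", "Std. Error"], tolerance = 1e-10)
    expect_equal(e$p, cf["se", "Pr(>|t|)"], tolerance = 1e-10)
    # classic formulation: OLS of theta/se on 1/se, testing the intercept
    classic <- summary(lm(I(estimate / se) ~ I(1 / se), data = d))$coefficients
    expect_equal(e$coef, classic["(Intercept)", "Estimate"], tolerance = 1e-10)
    expect_equal(e$p, classic["(Intercept)", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("Egger test agrees with metafor's weighted regression test", {
  library(metafor)
  set.seed(5)
  for (i in 1:8) {
    d <- random_meta(sample(5:40, 1))
    m <- rma(yi = d$estimate, vi = d$se^2, method = "DL",
             ni = d$n_ctrl + d$n_int)
    rt <- regtest(m, model = "lm", predictor = "sei")
    e <- egger_test(d, predictor = "SE")
    expect_equal(e$t_stat, as.numeric(rt$zval), tolerance = 1e-8)
    expect_equal(e$p, as.numeric(rt$pval), tolerance = 1e-8)
  }
})

test_that("Egger handles constant effects and degenerate designs", {
  d <- meta_dataset(rep(2, 5), seq(0.5, 1.5, length.out = 5),
                    rep(10, 5), rep(10, 5), "RMD")
  e <- egger_test(d)
  expect_equal(e$coef, 0)
  expect_equal(e$p, 1)
  same_x <- meta_dataset(1:5, rep(1, 5), rep(10, 5), rep(10, 5), "RMD")
  expect_error(egger_test(same_x, predictor = "SE"), "degenerate design")
  expect_error(egger_test(meta_dataset(1:2, c(1, 2), c(5, 5), c(5, 5), "RMD")),
               "insufficient")
})

test_that("mirroring a dataset negates the Egger coefficient, preserving p", {
  set.seed(9)
  for (pred in c("SE", "inv_sqrt_n")) {
    d <- random_meta(20)
    dm <- meta_dataset(-d$estimate, d$se, d$n_ctrl, d$n_int, "RMD")
    e1 <- egger_test(d, pred)
    e2 <- egger_test(dm, pred)
    expect_equal(e2$coef, -e1$coef)
    expect_equal(e2$p, e1$p)
  }
})

test_that("the 1/sqrt(n) predictor uses the study size, not the SE", {
  set.seed(13)
  d <- random_meta(15)
  e <- egger_test(d, predictor = "inv_sqrt_n")
  x <- 1 / sqrt(d$n_ctrl + d$n_int)
  fit <- summary(lm(estimate ~ x, data = d, weights = (d$n_ctrl + d$n_int)))
  expect_equal(e$coef, fit$coefficients["x", "Estimate"], tolerance = 1e-10)
  expect_equal(e$p, fit$coefficients["x", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("Begg-Mazumdar: ties give tau 0, perfect concordance gives tau 1", {
  flat <- meta_dataset(rep(1, 5), rep(0.7, 5), rep(10, 5), rep(10, 5), "RMD")
  b <- begg_test(flat)
  expect_equal(b$kendall_tau, 0)

  # construct 4 studies whose standardized deviations are concordant with
  # their variances: all 6 pairs concordant, tau = 6/6 = 1
  d <- meta_dataset(c(0.5, 1.8, 3.5, 6), c(0.5, 1, 1.5, 2),
                    rep(10, 4), rep(10, 4), "RMD")
  f <- pool_fixed(d)
  z <- (d$estimate - f$mu_hat) / sqrt(d$se^2 - f$se_mu^2)
  expect_true(all(diff(z) > 0))  # deviations increase with variance
  expect_equal(begg_test(d)$kendall_tau, 1)
})

test_that("Begg test matches metafor's rank correlation test", {
  library(metafor)
  set.seed(17)
  for (i in 1:8) {
    d <- random_meta(sample(5:30, 1))
    b <- begg_test(d)
    m <- ranktest(rma(yi = d$estimate, vi = d$se^2, method = "DL"), exact = FALSE)
    expect_equal(b$kendall_tau, as.numeric(m$tau), tolerance = 1e-8)
    expect_equal(b$p, as.numeric(m$pval), tolerance = 1e-8)
  }
})

test_that("trim-and-fill leaves symmetric data alone", {
  y <- c(1, 2, 3, 4, 5)  # symmetric about 3
  d <- meta_dataset(y, rep(1, 5), rep(10, 5), rep(10, 5), "RMD")
  tf <- trim_and_fill(d, side = "left")
  expect_equal(tf$k0, 0)
  expect_equal(nrow(tf$filled), 0)
  expect_equal(tf$adjusted$mu_hat, pool_random(d)$mu_hat)
  expect_equal(tf$adjusted$se_mu, pool_random(d)$se_mu)
})

test_that("one trim iteration matches a brute-force rank-sum computation", {
  # the spec instance: {1..5} with the two left-most removed
  d <- meta_dataset(c(3, 4, 5), rep(1, 3), rep(10, 3), rep(10, 3), "RMD")
  brute_L0 <- function(y, mu) {
    dev <- y - mu
    r <- rank(abs(dev), ties.method = "first")
    (4 * sum(r[dev > 0]) - length(y) * (length(y) + 1)) / (2 * length(y) - 1)
  }
  # DL centre of {3,4,5} with equal SEs is the mean, 4; hand rank sums:
  # |dev| = (1,0,1) -> ranks (2,1,3), positive side rank sum 3,
  # L0 = (12 - 12)/5 = 0: this remnant is itself symmetric
  expect_equal(brute_L0(d$estimate, 4), 0)
  expect_equal(trim_and_fill(d, side = "left")$k0, 0)

  # genuinely asymmetric instance: mass on the right of the centre
  y <- c(0, 2.8, 3, 3.2, 3.4, 3.6)
  d2 <- meta_dataset(y, rep(1, 6), rep(10, 6), rep(10, 6), "RMD")
  mu1 <- pool_random(d2)$mu_hat
  expect_gt(brute_L0(y, mu1), 0.5)   # first iteration already trims
  tf <- trim_and_fill(d2, side = "left")
  expect_gt(tf$k0, 0)
  expect_lt(tf$adjusted$mu_hat, pool_random(d2)$mu_hat)
})

test_that("trim-and-fill matches metafor on censored datasets", {
  library(metafor)
  set.seed(23)
  for (i in 1:10) {
    k <- sample(10:40, 1)
    se <- runif(k, 0.2, 0.9)
    y <- rnorm(k, 1, se)
    drop <- order(y)[seq_len(sample(2:5, 1))]
    d <- meta_dataset(y[-drop], se[-drop], rep(10, k - length(drop)),
                      rep(10, k - length(drop)), "SMD_g")
    tf <- trim_and_fill(d, side = "left")
    mf <- trimfill(rma(yi = d$estimate, vi = d$se^2, method = "DL"),
                   side = "left", estimator = "L0")
    expect_equal(tf$k0, mf$k0)
    expect_equal(tf$adjusted$mu_hat, as.numeric(coef(mf)), tolerance = 1e-8)
  }
})

test_that("re-running trim-and-fill on its augmented output matches the reference", {
  # the L0 estimator is idempotent up to rank-tie granularity: a mirrored
  # pair ties in |deviation| and the tie-break can re-impute a couple of
  # studies. The behavior must match the reference implementation exactly
  # and shrink sharply relative to the first pass.
  library(metafor)
  set.seed(29)
  for (i in 1:5) {
    d <- censored_meta(k = 24, m = sample(2:5, 1))
    tf <- trim_and_fill(d, side = "left")
    tf2 <- trim_and_fill(tf$augmented, side = "left")
    a <- tf$augmented
    mf <- trimfill(rma(yi = a$estimate, vi = a$se^2, method = "DL"),
                   side = "left", estimator = "L0")
    expect_equal(tf2$k0, mf$k0)
    expect_lt(tf2$k0, tf$k0)
  }
  # exact idempotence on data already symmetric about the pooled estimate
  sym <- meta_dataset(c(1:9, 9:1 + 10), rep(c(0.4, 0.7, 1), 6),
                      rep(10, 18), rep(10, 18), "RMD")
  tfs <- trim_and_fill(sym, side = "left")
  expect_equal(tfs$k0, 0)
  expect_equal(trim_and_fill(tfs$augmented, side = "left")$k0, 0)
})

test_that("the auto side follows the direction of the pooled effect", {
  d <- censored_meta(k = 20, m = 3, mu = 2)       # positive effect
  expect_equal(trim_and_fill(d, side = "auto")$side, "left")
  dm <- meta_dataset(-d$estimate, d$se, d$n_ctrl, d$n_int, "RMD")
  expect_equal(trim_and_fill(dm, side = "auto")$side, "right")
  # mirrored data give the mirrored adjustment
  tf <- trim_and_fill(d, side = "auto")
  tfm <- trim_and_fill(dm, side = "auto")
  expect_equal(tfm$k0, tf$k0)
  expect_equal(tfm$adjusted$mu_hat, -tf$adjusted$mu_hat, tolerance = 1e-10)
})

test_that("filled studies inherit the precision and size of their sources", {
  d <- censored_meta(k = 25, m = 4)
  tf <- trim_and_fill(d, side = "left")
  expect_gt(tf$k0, 0)
  expect_equal(nrow(tf$filled), tf$k0)
  expect_true(all(tf$filled$se %in% d$se))
  expect_true(all(tf$filled$n_ctrl %in% d$n_ctrl))
  # mirrors of right-side studies land left of the unadjusted centre
  expect_true(all(tf$filled$estimate < pool_random(d)$mu_hat + 1e-9))
})
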