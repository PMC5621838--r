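## group-size rules for the two study-size classes: intervention n is
## uniform on its range and the control n is the intervention n plus an
## independent uniform offset, giving totals of 12-30 (small) / 60-320
## (large) subjects per study
.size_rules <- list(
  small = list(int_n = 7:14,    offset = -2:2),
  large = list(int_n = 40:150,  offset = -20:20)
)

#' Configuration of one simulation scenario
#'
#' Describes one Monte-Carlo scenario: the number of studies per
#' meta-analysis, the study-size class, the true intervention effect, the
#' subject-level outcome distribution, the sham arm, whether a stepwise
#' publication-bias filter is applied, and the number of repetitions.
#'
#' The defaults emulate preclinical outcome data: control subjects are
#' normal with mean 30 and SD 10; the intervention shifts the mean by
#' `delta_mu` (0, 5 or 10 give true standardized effects of 0, 0.5 and 1);
#' small studies total 12-30 subjects (intervention arm 7-14, control
#' within 2), large studies 60-320 (intervention 40-150, control within
#' 20); sham arms have 4-6 subjects from a normal with mean 70 and SD 4.
#'
#' @param k_studies Number of studies per simulated meta-analysis (>= 3).
#' @param size_class `"small"` or `"large"`.
#' @param delta_mu True difference between intervention and control means,
#'   in outcome units.
#' @param reps Number of Monte-Carlo repetitions.
#' @param bias Apply the stepwise significance censoring filter
#'   ([censor_studies()]) to each simulated meta-analysis.
#' @param measures Effect measures to compute, a subset of `"RMD"`,
#'   `"SMD_d"`, `"SMD_g"`, `"NMD"`.
#' @param seed Integer seed; every random draw of the scenario derives from
#'   it (per-repetition independent RNG streams).
#' @param ctrl_mean,sd_subject Control-arm outcome distribution.
#' @param sham_mean,sham_sd,sham_n_range Sham-arm outcome distribution and
#'   group-size range (used when `"NMD"` is requested).
#' @param nmd_baseline How the simulation engine forms the NMD
#'   normalization deficit: `"design"` (default) scales each study by the
#'   design control baseline minus that study's realized sham mean, so the
#'   deficit carries the sham arm's sampling error only, keeping the NMD
#'   standard error independent of the effect; `"realized"` uses the
#'   study's realized control mean (the literal formula), which couples the
#'   estimate and its SE through the shared denominator.
#' @param sampling `"subject"` draws individual subject outcomes and
#'   summarizes them; `"summary"` draws the arm mean and SD directly from
#'   their exact sampling distributions (normal and scaled chi,
#'   distributionally identical), useful for very large scenarios.
#' @return An object of class `"scenario_config"`.
#' @examples
#' scenario_config(k_studies = 30, delta_mu = 10, reps = 100, seed = 1)
#' @export
scenario_config <- function(k_studies = 30,
                            size_class = c("small", "large"),
                            delta_mu = 0,
                            reps = 1000,
                            bias = FALSE,
                            measures = c("RMD", "SMD_g"),
                            seed = 1L,
                            ctrl_mean = 30, sd_subject = 10,
                            sham_mean = 70, sham_sd = 4,
                            sham_n_range = c(4L, 6L),
                            nmd_baseline = c("design", "realized"),
                            sampling = c("subject", "summary")) {
  size_class <- match.arg(size_class)
  nmd_baseline <- match.arg(nmd_baseline)
  sampling <- match.arg(sampling)
  measures <- match.arg(measures, c("RMD", "SMD_d", "SMD_g", "NMD"),
                        several.ok = TRUE)
  stopifnot(k_studies >= 3, k_studies == round(k_studies),
            reps >= 1, reps == round(reps),
            is.numeric(delta_mu), length(delta_mu) == 1L,
            sd_subject > 0, sham_sd > 0,
            length(sham_n_range) == 2L, sham_n_range[1] >= 2,
            sham_n_range[1] <= sham_n_range[2])
  structure(list(k_studies = as.integer(k_studies), size_class = size_class,
                 delta_mu = delta_mu, reps = as.integer(reps),
                 bias = isTRUE(bias), measures = measures,
                 seed = as.integer(seed),
                 ctrl_mean = ctrl_mean, sd_subject = sd_subject,
                 sham_mean = sham_mean, sham_sd = sham_sd,
                 sham_n_range = as.integer(sham_n_range),
                 nmd_baseline = nmd_baseline, sampling = sampling),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: %d %s studies/meta-analysis, delta_mu = %g, %s, %d reps (seed %d)\n",
              x$k_studies, x$size_class, x$delta_mu,
              if (x$bias) "stepwise censoring" else "unbiased", x$reps, x$seed))
  cat("  measures:", paste(x$measures, collapse = ", "), "\n")
  invisible(x)
}

## draw k studies' arm summaries as a data frame; uses the current RNG state
.draw_arms <- function(config, k) {
  rule <- .size_rules[[config$size_class]]
  ni <- sample(rule$int_n, k, replace = TRUE)
  nc <- ni + sample(rule$offset, k, replace = TRUE)
  mu_c <- config$ctrl_mean
  mu_i <- config$ctrl_mean + config$delta_mu
  sd_s <- config$sd_subject
  if (config$sampling == "subject") {
    summarize <- function(n, mu) {
      g <- rep.int(seq_len(k), n)
      x <- stats::rnorm(length(g), mu, sd_s)
      s1 <- rowsum(x, g)[, 1]
      s2 <- rowsum(x * x, g)[, 1]
      m <- s1 / n
      list(mean = m, sd = sqrt(pmax(0, (s2 - n * m^2) / (n - 1))))
    }
    a_c <- summarize(nc, mu_c)
    a_i <- summarize(ni, mu_i)
  } else {
    draw_sum <- function(n, mu) {
      list(mean = stats::rnorm(k, mu, sd_s / sqrt(n)),
           sd = sd_s * sqrt(stats::rchisq(k, n - 1) / (n - 1)))
    }
    a_c <- draw_sum(nc, mu_c)
    a_i <- draw_sum(ni, mu_i)
  }
  out <- data.frame(study_id = seq_len(k),
                    mean_ctrl = a_c$mean, sd_ctrl = a_c$sd, n_ctrl = nc,
                    mean_int = a_i$mean, sd_int = a_i$sd, n_int = ni)
  if ("NMD" %in% config$measures) {
    ns <- sample(config$sham_n_range[1]:config$sham_n_range[2], k, replace = TRUE)
    if (config$sampling == "subject") {
      g <- rep.int(seq_len(k), ns)
      x <- stats::rnorm(length(g), config$sham_mean, config$sham_sd)
      s1 <- rowsum(x, g)[, 1]
      s2 <- rowsum(x * x, g)[, 1]
      m <- s1 / ns
      out$mean_sham <- m
      out$sd_sham <- sqrt(pmax(0, (s2 - ns * m^2) / (ns - 1)))
    } else {
      out$mean_sham <- stats::rnorm(k, config$sham_mean, config$sham_sd / sqrt(ns))
      out$sd_sham <- config$sham_sd * sqrt(stats::rchisq(k, ns - 1) / (ns - 1))
    }
    out$n_sham <- ns
  }
  out
}

#' Draw one simulated study
#'
#' Draws a single two-arm study under a scenario configuration:
#' intervention group size uniform over its class range, control size
#' within the class offset of it, subject outcomes normal, arms summarized
#' to mean/SD/n. A sham arm is attached when the scenario requests the
#' NMD. Uses (and advances) R's global random number generator.
#'
#' @param config A [scenario_config()].
#' @return A [study_data()] object.
#' @export
draw_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  a <- .draw_arms(config, 1L)
  study_data(arm_summary(a$mean_ctrl, a$sd_ctrl, a$n_ctrl),
             arm_summary(a$mean_int, a$sd_int, a$n_int),
             sham = if ("mean_sham" %in% names(a))
               arm_summary(a$mean_sham, a$sd_sham, a$n_sham) else NULL)
}

## vectorized two-sided pooled-variance t-test p-value from arm summaries
.t_test_p_vec <- function(mc, sc, nc, mi, si, ni) {
  sp2 <- ((nc - 1) * sc^2 + (ni - 1) * si^2) / (nc + ni - 2)
  tt <- (mi - mc) / sqrt(sp2 * (1 / nc + 1 / ni))
  2 * stats::pt(-abs(tt), df = nc + ni - 2)
}

#' Two-sample Student t-test from arm summaries
#'
#' The classic pooled-variance two-sample t-test computed from the two
#' arms' means, SDs and sizes; two-sided p-value. This is the per-study
#' significance used by the stepwise censoring filter.
#'
#' @param study A [study_data()].
#' @return The two-sided p-value.
#' @examples
#' s <- study_data(arm_summary(30, 10, 10), arm_summary(40, 10, 10))
#' study_t_test(s)   # t = 2.236 on 18 df
#' @export
study_t_test <- function(study) {
  stopifnot(inherits(study, "study_data"))
  c_ <- study$control; i_ <- study$intervention
  if (c_$sd == 0 && i_$sd == 0)
    stop("degenerate variance: both arms have zero SD", call. = FALSE)
  .t_test_p_vec(c_$mean, c_$sd, c_$n, i_$mean, i_$sd, i_$n)
}

#' Stepwise publication-bias censoring
#'
#' Emulates selective publication by removing simulated studies according
#' to their two-sided Student t-test p-value: studies with `p < 0.05` are
#' retained with probability 0.9, studies with `0.05 <= p < 0.10` with
#' probability 0.5, and studies with `p >= 0.10` with probability 0.1
#' (i.e. 10%/50%/90% removal). Order is preserved; surviving studies are
#' not replenished.
#'
#' @param studies A data frame of arm summaries (as from [draw_study()]'s
#'   underlying table, with `mean_ctrl`, `sd_ctrl`, `n_ctrl`, `mean_int`,
#'   `sd_int`, `n_int`), or a list of [study_data()] objects.
#' @param retain_probs Retention probabilities for the three p-value strata
#'   `[0, 0.05)`, `[0.05, 0.10)`, `[0.10, 1]`.
#' @return The censored object, same type as the input. Raises an error if
#'   every study is censored.
#' @export
censor_studies <- function(studies, retain_probs = c(0.9, 0.5, 0.1)) {
  stopifnot(length(retain_probs) == 3, all(retain_probs >= 0), all(retain_probs <= 1))
  if (is.data.frame(studies)) {
    if (!nrow(studies)) stop("no studies to censor", call. = FALSE)
    p <- .t_test_p_vec(studies$mean_ctrl, studies$sd_ctrl, studies$n_ctrl,
                       studies$mean_int, studies$sd_int, studies$n_int)
  } else {
    if (!length(studies)) stop("no studies to censor", call. = FALSE)
    p <- vapply(studies, study_t_test, numeric(1))
  }
  pr <- ifelse(p < 0.05, retain_probs[1],
               ifelse(p < 0.10, retain_probs[2], retain_probs[3]))
  keep <- stats::runif(length(p)) < pr
  if (!any(keep))
    stop("empty meta-analysis: every study was censored", call. = FALSE)
  if (is.data.frame(studies)) studies[keep, , drop = FALSE] else studies[keep]
}

## effect table for one measure from a drawn arms data frame
.effects_from_arms <- function(arms, measure, config) {
  if (measure == "NMD") {
    deficit <- switch(config$nmd_baseline,
                      design = config$ctrl_mean - arms$mean_sham,
                      realized = arms$mean_ctrl - arms$mean_sham)
    compute_effects(arms, "NMD", nmd_deficit = deficit)
  } else {
    compute_effects(arms, measure)
  }
}

#' Simulate one meta-analysis per requested measure
#'
#' Draws `k_studies` studies under the scenario, applies the censoring
#' filter if `bias` is on, and computes every requested effect measure from
#' the same underlying draws, so the per-measure datasets are paired study
#' for study.
#'
#' @param config A [scenario_config()].
#' @return A named list of [meta_dataset()] objects, one per measure, with
#'   attribute `k_post` (the post-censoring study count).
#' @export
simulate_meta <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  arms <- .draw_arms(config, config$k_studies)
  if (config$bias) arms <- censor_studies(arms)
  out <- lapply(config$measures, .effects_from_arms, arms = arms, config = config)
  names(out) <- config$measures
  attr(out, "k_post") <- nrow(arms)
  out
}

## per-repetition independent RNG streams derived from one root seed
.rng_streams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

.with_stream <- function(stream, expr) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  assign(".Random.seed", stream, envir = globalenv())
  expr
}

#' Run a Monte-Carlo scenario
#'
#' Repeats [simulate_meta()] `reps` times and, for every repetition, every
#' requested measure and every precision predictor, runs the Egger
#' asymmetry test, the random-effects pool and (optionally) trim-and-fill,
#' then aggregates rejection percentages and the distribution of filled
#' counts and pooled estimates. Fully reproducible from `config$seed`;
#' repetitions use independent RNG streams so their order is immaterial.
#'
#' @param config A [scenario_config()].
#' @param predictors Precision predictors for the Egger test, a subset of
#'   `"SE"`, `"inv_sqrt_n"`.
#' @param trimfill Run trim-and-fill per repetition (L0, side chosen by the
#'   sign of the pooled estimate).
#' @param begg Also run the Begg-Mazumdar test per repetition.
#' @param alpha Significance level for the rejection percentages.
#' @return An object of class `"scenario_summary"`; its `results` element
#'   is a data frame with one row per measure x predictor holding
#'   `egger_reject_pct`, the median/min/max Egger p-value, and per measure
#'   the mean/min/max of the filled-study count, pooled estimate, and
#'   trim-and-fill-adjusted estimate.
#' @examples
#' cfg <- scenario_config(k_studies = 30, delta_mu = 10, reps = 20, seed = 42)
#' run_scenario(cfg, trimfill = FALSE)
#' @export
run_scenario <- function(config, predictors = c("SE", "inv_sqrt_n"),
                         trimfill = TRUE, begg = FALSE, alpha = 0.05) {
  stopifnot(inherits(config, "scenario_config"))
  predictors <- match.arg(predictors, c("SE", "inv_sqrt_n"), several.ok = TRUE)
  streams <- .rng_streams(config$seed, config$reps)
  measures <- config$measures
  cells <- expand.grid(measure = measures, predictor = predictors,
                       stringsAsFactors = FALSE)
  egger_p <- matrix(NA_real_, nrow = config$reps, ncol = nrow(cells))
  begg_p <- if (begg) matrix(NA_real_, config$reps, length(measures)) else NULL
  pooled <- matrix(NA_real_, config$reps, length(measures))
  filled <- matrix(NA_real_, config$reps, length(measures))
  adjusted <- matrix(NA_real_, config$reps, length(measures))
  k_post <- integer(config$reps)
  degenerate <- 0L
  for (r in seq_len(config$reps)) {
    metas <- .with_stream(streams[[r]], {
      tryCatch(simulate_meta(config), error = function(e) NULL)
    })
    if (is.null(metas) || attr(metas, "k_post") < 3L) {
      degenerate <- degenerate + 1L
      next
    }
    k_post[r] <- attr(metas, "k_post")
    for (m in seq_along(measures)) {
      d <- metas[[m]]
      v <- d$se^2
      pooled[r, m] <- .pool_dl_vec(d$estimate, v)$mu
      for (j in seq_len(nrow(cells))) {
        if (cells$measure[j] != measures[m]) next
        x <- .precision_vec(d, cells$predictor[j])
        egger_p[r, j] <- .egger_fit(d$estimate, x, 1 / x^2)$p
      }
      if (begg) {
        f <- .pool_fixed_vec(d$estimate, v)
        z <- (d$estimate - f$mu) / sqrt(v - 1 / f$sw)
        begg_p[r, m] <- .kendall_tau_b(z, v)$p
      }
      if (trimfill) {
        tf <- .trimfill_fast(d$estimate, v)
        filled[r, m] <- tf$k0
        adjusted[r, m] <- tf$adjusted
      }
    }
  }
  summ3 <- function(x) c(mean = mean(x, na.rm = TRUE),
                         min = suppressWarnings(min(x, na.rm = TRUE)),
                         max = suppressWarnings(max(x, na.rm = TRUE)))
  res <- cells
  res$egger_reject_pct <- vapply(seq_len(nrow(cells)), function(j)
    100 * mean(egger_p[, j] < alpha, na.rm = TRUE), numeric(1))
  res$egger_p_median <- apply(egger_p, 2, stats::median, na.rm = TRUE)
  res$egger_p_min <- apply(egger_p, 2, min, na.rm = TRUE)
  res$egger_p_max <- apply(egger_p, 2, max, na.rm = TRUE)
  mi <- match(res$measure, measures)
  for (nm in c("pooled", "filled", "adjusted")) {
    mat <- get(nm)
    s <- apply(mat, 2, summ3)
    res[[paste0(nm, "_mean")]] <- s["mean", mi]
    res[[paste0(nm, "_min")]] <- s["min", mi]
    res[[paste0(nm, "_max")]] <- s["max", mi]
  }
  if (begg) {
    res$begg_reject_pct <- 100 * colMeans(begg_p < alpha, na.rm = TRUE)[mi]
  }
  structure(list(config = config, results = res,
                 reps = config$reps, degenerate = degenerate,
                 k_post = summ3(k_post[k_post > 0]),
                 egger_p = egger_p, cells = cells),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, digits = 3, ...) {
  print(x$config)
  if (x$config$bias)
    cat(sprintf("  post-censoring studies: mean %.1f (range %d-%d); degenerate reps: %d\n",
                x$k_post["mean"], as.integer(x$k_post["min"]),
                as.integer(x$k_post["max"]), x$degenerate))
  cols <- intersect(c("measure", "predictor", "egger_reject_pct", "egger_p_median",
                      "filled_mean", "pooled_mean", "adjusted_mean",
                      "begg_reject_pct"), names(x$results))
  out <- x$results[, cols]
  out <- out[, !vapply(out, function(z) all(is.nan(z)), logical(1)), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = digits)
  print(out, row.names = FALSE)
  invisible(x)
}
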