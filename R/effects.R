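#' Summary statistics for one experimental arm
#'
#' Bundles the mean, standard deviation and sample size of a single arm
#' (control, intervention or sham) of a two-arm study.
#'
#' @param mean Arm mean, in outcome units.
#' @param sd Arm standard deviation, in outcome units; must be non-negative.
#' @param n Number of subjects in the arm; integer, at least 2 so that the
#'   standard deviation is estimable.
#'
#' @return An object of class `"arm_summary"`: a list with elements `mean`,
#'   `sd` and `n`.
#' @examples
#' arm_summary(mean = 30, sd = 10, n = 10)
#' @export
arm_summary <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("'sd' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd), n = as.integer(n)),
            class = "arm_summary")
}

#' A two-arm study, optionally with a sham reference arm
#'
#' The unit of meta-analysis and of simulation: a control arm, an
#' intervention arm, and optionally a sham arm of normal, unlesioned and
#' untreated subjects. The sham arm anchors the normalized mean difference
#' scale and is required by [normalized_mean_difference()].
#'
#' @param control,intervention [arm_summary()] objects (or lists with
#'   `mean`, `sd`, `n`).
#' @param sham Optional [arm_summary()] for the sham arm, or `NULL`.
#'
#' @return An object of class `"study_data"`.
#' @examples
#' study_data(arm_summary(30, 10, 10), arm_summary(40, 10, 10))
#' @export
study_data <- function(control, intervention, sham = NULL) {
  as_arm <- function(a, what) {
    if (inherits(a, "arm_summary")) return(a)
    if (is.list(a) && all(c("mean", "sd", "n") %in% names(a)))
      return(arm_summary(a$mean, a$sd, a$n))
    stop("'", what, "' must be an arm_summary", call. = FALSE)
  }
  control <- as_arm(control, "control")
  intervention <- as_arm(intervention, "intervention")
  if (!is.null(sham)) sham <- as_arm(sham, "sham")
  structure(list(control = control, intervention = intervention, sham = sham),
            class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  fmt <- function(a) sprintf("mean %.4g, sd %.4g, n %d", a$mean, a$sd, a$n)
  cat("Two-arm study\n")
  cat("  control:      ", fmt(x$control), "\n")
  cat("  intervention: ", fmt(x$intervention), "\n")
  if (!is.null(x$sham)) cat("  sham:         ", fmt(x$sham), "\n")
  invisible(x)
}

## vectorized effect kernels -------------------------------------------------
## these operate on parallel vectors of arm summaries and are shared by the
## single-study wrappers, compute_effects() and the simulation engine.

.rmd_vec <- function(mc, sc, nc, mi, si, ni) {
  list(estimate = mi - mc, se = sqrt(si^2 / ni + sc^2 / nc))
}

.pooled_sd_vec <- function(sc, nc, si, ni) {
  sqrt(((nc - 1) * sc^2 + (ni - 1) * si^2) / (nc + ni - 2))
}

## small-sample correction factor; m = residual df (n_ctrl + n_int - 2)
.hedges_j <- function(m, exact = FALSE) {
  if (exact) {
    ## Gamma-ratio form, computed on the log scale for stability
    exp(lgamma(m / 2) - log(sqrt(m / 2)) - lgamma((m - 1) / 2))
  } else {
    1 - 3 / (4 * m - 1)
  }
}

.smd_vec <- function(mc, sc, nc, mi, si, ni, correct = FALSE, exact_j = FALSE) {
  sp <- .pooled_sd_vec(sc, nc, si, ni)
  d <- (mi - mc) / sp
  ## (nc + ni)/(nc ni) written as 1/nc + 1/ni to avoid integer overflow
  vard <- 1 / nc + 1 / ni + d^2 / (2 * (nc + ni))
  if (correct) {
    j <- .hedges_j(nc + ni - 2, exact = exact_j)
    list(estimate = j * d, se = j * sqrt(vard), pooled_sd = sp)
  } else {
    list(estimate = d, se = sqrt(vard), pooled_sd = sp)
  }
}

## deficit = M_ctrl - M_sham (the normalization denominator); callers may
## substitute a deficit that treats the lesioned baseline as fixed.
.nmd_vec <- function(mc, sc, nc, mi, si, ni, deficit, orient = TRUE) {
  est <- 100 * (mi - mc) / deficit
  se <- sqrt((100 * sc / deficit)^2 / nc + (100 * si / deficit)^2 / ni)
  ## literal value is negative whenever the intervention moves the mean
  ## toward sham; flipping the sign reports improvement as positive
  if (orient) est <- -est
  list(estimate = est, se = se)
}

.new_effect <- function(estimate, se, measure, nc, ni) {
  if (!is.finite(se) || se <= 0)
    stop("degenerate variance: standard error of the ", measure,
         " is not positive (all arm standard deviations zero?)", call. = FALSE)
  structure(list(estimate = estimate, se = se, measure = measure,
                 n_ctrl = as.integer(nc), n_int = as.integer(ni),
                 n_total = as.integer(nc + ni)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s effect estimate: %.4f (SE %.4f), n = %d + %d\n",
              x$measure, x$estimate, x$se, x$n_ctrl, x$n_int))
  invisible(x)
}

#' Raw mean difference
#'
#' The intervention-minus-control difference in means, in the original
#' outcome units, with standard error
#' \deqn{SE_{RMD} = \sqrt{SD_{int}^2/n_{int} + SD_{ctrl}^2/n_{ctrl}}.}
#' The standard error depends on the arm variances and sizes only, never on
#' the effect itself.
#'
#' @param study A [study_data()] object.
#' @return An object of class `"effect_estimate"` with elements `estimate`,
#'   `se`, `measure` (`"RMD"`), `n_ctrl`, `n_int`, `n_total`.
#' @examples
#' s <- study_data(arm_summary(30, 10, 10), arm_summary(40, 10, 10))
#' raw_mean_difference(s)   # estimate 10, se sqrt(20)
#' @seealso [cohens_d()], [hedges_g()], [normalized_mean_difference()]
#' @export
raw_mean_difference <- function(study) {
  stopifnot(inherits(study, "study_data"))
  c_ <- study$control; i_ <- study$intervention
  r <- .rmd_vec(c_$mean, c_$sd, c_$n, i_$mean, i_$sd, i_$n)
  .new_effect(r$estimate, r$se, "RMD", c_$n, i_$n)
}

#' Standardized mean difference (Cohen's d)
#'
#' The mean difference divided by the pooled within-study standard
#' deviation,
#' \deqn{d = (M_{int} - M_{ctrl}) / SD_{pooled},}
#' with
#' \deqn{SE_d = \sqrt{\frac{n_{ctrl}+n_{int}}{n_{ctrl} n_{int}} +
#'   \frac{d^2}{2(n_{ctrl}+n_{int})}}.}
#' Note that the standard error increases with \eqn{|d|}: two studies of the
#' same size have different SEs if their observed effects differ. This
#' coupling is what distorts SMD-versus-SE funnel plots.
#'
#' @inheritParams raw_mean_difference
#' @return An `"effect_estimate"` with `measure = "SMD_d"`.
#' @examples
#' s <- study_data(arm_summary(30, 10, 10), arm_summary(40, 10, 10))
#' cohens_d(s)   # estimate 1, se sqrt(0.225)
#' @export
cohens_d <- function(study) {
  stopifnot(inherits(study, "study_data"))
  c_ <- study$control; i_ <- study$intervention
  r <- .smd_vec(c_$mean, c_$sd, c_$n, i_$mean, i_$sd, i_$n, correct = FALSE)
  if (!is.finite(r$pooled_sd) || r$pooled_sd <= 0)
    stop("degenerate variance: pooled SD is zero", call. = FALSE)
  .new_effect(r$estimate, r$se, "SMD_d", c_$n, i_$n)
}

#' Standardized mean difference with small-sample correction (Hedges' g)
#'
#' Cohen's d multiplied by the correction factor
#' \eqn{J = 1 - 3/(4m - 1)}, \eqn{m = n_{ctrl} + n_{int} - 2}, which removes
#' the small-sample upward bias of d; the variance is corrected by
#' \eqn{J^2}. For large samples g and d are nearly identical. The exact
#' gamma-ratio form of \eqn{J} is available via `exact_j = TRUE`; the two
#' agree to better than \eqn{10^{-3}} for \eqn{m \ge 4}.
#'
#' @inheritParams raw_mean_difference
#' @param exact_j Use the exact gamma-ratio correction factor instead of the
#'   standard approximation.
#' @return An `"effect_estimate"` with `measure = "SMD_g"`.
#' @examples
#' s <- study_data(arm_summary(30, 10, 10), arm_summary(40, 10, 10))
#' hedges_g(s)   # (1 - 3/71) * 1 = 0.9577
#' @export
hedges_g <- function(study, exact_j = FALSE) {
  stopifnot(inherits(study, "study_data"))
  c_ <- study$control; i_ <- study$intervention
  r <- .smd_vec(c_$mean, c_$sd, c_$n, i_$mean, i_$sd, i_$n,
                correct = TRUE, exact_j = exact_j)
  if (!is.finite(r$pooled_sd) || r$pooled_sd <= 0)
    stop("degenerate variance: pooled SD is zero", call. = FALSE)
  .new_effect(r$estimate, r$se, "SMD_g", c_$n, i_$n)
}

#' Normalized mean difference
#'
#' Expresses the intervention effect as a percentage of the control-versus-
#' sham deficit:
#' \deqn{NMD = 100\% \times \frac{(M_{int}-M_{sham}) - (M_{ctrl}-M_{sham})}
#'   {M_{ctrl}-M_{sham}},}
#' with standard error
#' \deqn{SE_{NMD} = \sqrt{\frac{(100\, SD_{ctrl}/(M_{ctrl}-M_{sham}))^2}{n_{ctrl}}
#'   + \frac{(100\, SD_{int}/(M_{ctrl}-M_{sham}))^2}{n_{int}}}.}
#' The sham arm enters only through its mean: the deficit is treated as a
#' fixed per-study scaling, so the SE carries no contribution from the sham
#' arm's SD or size. Requires a sham arm and \eqn{M_{ctrl} \ne M_{sham}}.
#'
#' The literal formula is negative whenever the intervention moves the mean
#' toward the sham value, whichever direction the lesion shifted the scale;
#' with `orient_improvement_positive = TRUE` (default) the sign is flipped
#' so that improvement is reported as a positive percentage.
#'
#' @inheritParams raw_mean_difference
#' @param orient_improvement_positive Report improvement (movement toward
#'   the sham mean) as positive. Set `FALSE` for the literal formula value.
#' @return An `"effect_estimate"` with `measure = "NMD"`, on the percent
#'   scale (an estimate of 25 means 25%).
#' @examples
#' s <- study_data(arm_summary(30, 10, 10), arm_summary(40, 10, 10),
#'                 sham = arm_summary(70, 4, 5))
#' normalized_mean_difference(s)   # 25% improvement
#' @export
normalized_mean_difference <- function(study, orient_improvement_positive = TRUE) {
  stopifnot(inherits(study, "study_data"))
  if (is.null(study$sham))
    stop("normalized mean difference requires a sham arm", call. = FALSE)
  c_ <- study$control; i_ <- study$intervention
  deficit <- c_$mean - study$sham$mean
  if (deficit == 0)
    stop("control and sham means are equal: NMD denominator is zero", call. = FALSE)
  r <- .nmd_vec(c_$mean, c_$sd, c_$n, i_$mean, i_$sd, i_$n,
                deficit = deficit, orient = orient_improvement_positive)
  .new_effect(r$estimate, r$se, "NMD", c_$n, i_$n)
}

#' Precision of an effect estimate
#'
#' The funnel-plot ordinate for one study: the standard error, its
#' reciprocal, or the sample-size-based precision \eqn{1/\sqrt{n}} with
#' \eqn{n} the total study sample size. The sample-size-based kind is
#' independent of the observed effect and therefore immune to the SMD-SE
#' coupling.
#'
#' @param effect An `"effect_estimate"`.
#' @param kind One of `"SE"`, `"inv_SE"`, `"inv_sqrt_n"`.
#' @return A positive scalar.
#' @examples
#' s <- study_data(arm_summary(30, 10, 10), arm_summary(40, 10, 10))
#' precision(cohens_d(s), "inv_sqrt_n")   # 1/sqrt(20)
#' @export
precision <- function(effect, kind = c("SE", "inv_SE", "inv_sqrt_n")) {
  stopifnot(inherits(effect, "effect_estimate"))
  kind <- match.arg(kind)
  switch(kind,
         SE = effect$se,
         inv_SE = 1 / effect$se,
         inv_sqrt_n = 1 / sqrt(effect$n_total))
}

#' A meta-analysis dataset of homogeneous effect estimates
#'
#' An ordered collection of effect estimates, all on the same measure,
#' forming one meta-analysis. This is the input to the pooling, asymmetry
#' and plotting functions.
#'
#' @param estimate,se Numeric vectors of effects and their standard errors
#'   (`se > 0`).
#' @param n_ctrl,n_int Integer vectors of per-arm sample sizes.
#' @param measure Effect measure tag: one of `"RMD"`, `"SMD_d"`, `"SMD_g"`,
#'   `"NMD"`.
#' @param study_id Optional study labels.
#'
#' @return A data frame of class `"meta_dataset"` with columns `study_id`,
#'   `estimate`, `se`, `n_ctrl`, `n_int` and attribute `measure`.
#' @examples
#' meta_dataset(c(1, 2, 3), c(0.5, 0.4, 0.6), c(10, 12, 9), c(10, 11, 10), "SMD_g")
#' @export
meta_dataset <- function(estimate, se, n_ctrl, n_int, measure,
                         study_id = NULL) {
  measure <- match.arg(measure, c("RMD", "SMD_d", "SMD_g", "NMD"))
  k <- length(estimate)
  stopifnot(length(se) == k, length(n_ctrl) == k, length(n_int) == k)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be positive and finite", call. = FALSE)
  if (is.null(study_id)) study_id <- seq_len(k)
  out <- data.frame(study_id = study_id, estimate = as.numeric(estimate),
                    se = as.numeric(se), n_ctrl = as.integer(n_ctrl),
                    n_int = as.integer(n_int))
  structure(out, measure = measure, class = c("meta_dataset", "data.frame"))
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("Meta-analysis dataset: %d studies, measure %s\n",
              nrow(x), attr(x, "measure")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more studies\n")
  invisible(x)
}

.measure_tag <- function(data) attr(data, "measure")

#' Compute a meta-analysis dataset from arm-level summaries
#'
#' Applies one effect measure to every row of a table of arm summaries (the
#' "arms" layout, see [read_arms_csv()]) and returns the resulting
#' [meta_dataset()].
#'
#' @param arms A data frame with columns `mean_ctrl`, `sd_ctrl`, `n_ctrl`,
#'   `mean_int`, `sd_int`, `n_int`, optionally `mean_sham` (and `study_id`).
#' @param measure One of `"RMD"`, `"SMD_d"`, `"SMD_g"`, `"NMD"`.
#' @param nmd_deficit For `measure = "NMD"` only: the normalization deficit
#'   \eqn{M_{ctrl} - M_{sham}} per study. Default `NULL` uses each study's
#'   realized `mean_ctrl - mean_sham` (the literal formula); a numeric
#'   vector or scalar substitutes a fixed deficit scale.
#' @param orient_improvement_positive See [normalized_mean_difference()].
#' @param exact_j See [hedges_g()].
#' @return A [meta_dataset()].
#' @export
compute_effects <- function(arms, measure = c("SMD_g", "SMD_d", "RMD", "NMD"),
                            nmd_deficit = NULL,
                            orient_improvement_positive = TRUE,
                            exact_j = FALSE) {
  measure <- match.arg(measure)
  need <- c("mean_ctrl", "sd_ctrl", "n_ctrl", "mean_int", "sd_int", "n_int")
  miss <- setdiff(need, names(arms))
  if (length(miss))
    stop("arms table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mc <- arms$mean_ctrl; sc <- arms$sd_ctrl; nc <- arms$n_ctrl
  mi <- arms$mean_int; si <- arms$sd_int; ni <- arms$n_int
  r <- switch(measure,
    RMD = .rmd_vec(mc, sc, nc, mi, si, ni),
    SMD_d = .smd_vec(mc, sc, nc, mi, si, ni, correct = FALSE),
    SMD_g = .smd_vec(mc, sc, nc, mi, si, ni, correct = TRUE, exact_j = exact_j),
    NMD = {
      if (is.null(nmd_deficit)) {
        if (!"mean_sham" %in% names(arms))
          stop("measure 'NMD' requires a 'mean_sham' column (or 'nmd_deficit')",
               call. = FALSE)
        nmd_deficit <- mc - arms$mean_sham
      }
      if (any(nmd_deficit == 0))
        stop("NMD deficit (mean_ctrl - mean_sham) is zero for some study",
             call. = FALSE)
      .nmd_vec(mc, sc, nc, mi, si, ni, deficit = nmd_deficit,
               orient = orient_improvement_positive)
    })
  if (any(!is.finite(r$se)) || any(r$se <= 0))
    stop("degenerate variance: some study has a non-positive standard error",
         call. = FALSE)
  meta_dataset(r$estimate, r$se, nc, ni, measure,
               study_id = if ("study_id" %in% names(arms)) arms$study_id else NULL)
}

#' Read a CSV of arm-level summaries
#'
#' Reads the "arms" CSV layout: one row per study with columns `study_id`,
#' `mean_ctrl`, `sd_ctrl`, `n_ctrl`, `mean_int`, `sd_int`, `n_int` and
#' optionally `mean_sham`, `sd_sham`, `n_sham`. Header required, UTF-8.
#'
#' @param path Path to the CSV file.
#' @return A data frame of arm summaries suitable for [compute_effects()].
#' @export
read_arms_csv <- function(path) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("study_id", "mean_ctrl", "sd_ctrl", "n_ctrl",
            "mean_int", "sd_int", "n_int")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("'", path, "' is not an arms CSV: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  num <- setdiff(names(x), "study_id")
  for (cc in num) {
    if (!is.numeric(x[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[cc]]))) & !is.na(x[[cc]]))
      stop("'", path, "': column ", cc, " is not numeric (first offending row: ",
           if (length(bad)) bad[1] else NA, ")", call. = FALSE)
    }
  }
  bad <- which(x$n_ctrl < 2 | x$n_int < 2 | x$sd_ctrl < 0 | x$sd_int < 0)
  if (length(bad))
    stop("'", path, "': invalid arm summary in row ", bad[1],
         " (need n >= 2 and sd >= 0)", call. = FALSE)
  x
}

#' Read a CSV of precomputed effect estimates
#'
#' Reads the "effects" CSV layout: columns `study_id`, `estimate`, `se`,
#' `n_ctrl`, `n_int`, `measure` (one measure tag shared by all rows).
#'
#' @param path Path to the CSV file.
#' @return A [meta_dataset()].
#' @export
read_effects_csv <- function(path) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("study_id", "estimate", "se", "n_ctrl", "n_int", "measure")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("'", path, "' is not an effects CSV: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- unique(x$measure)
  if (length(m) != 1L)
    stop("'", path, "': all rows must share one measure tag, found: ",
         paste(m, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(x$se) | x$se <= 0)
  if (length(bad))
    stop("'", path, "': non-positive standard error in row ", bad[1], call. = FALSE)
  meta_dataset(x$estimate, x$se, x$n_ctrl, x$n_int, m, study_id = x$study_id)
}
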