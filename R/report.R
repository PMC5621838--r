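#' Build funnel-plot data
#'
#' Assembles the plotting data for a funnel plot of a meta-analysis
#' dataset: one point per study (effect, ordinate), the random-effects
#' pooled estimate as the centreline, and optionally the imputed studies
#' of a trim-and-fill adjustment flagged as filled points. A pure function
#' of its inputs.
#'
#' @param data A [meta_dataset()] (at least 1 study).
#' @param ordinate_kind `"SE"`, `"inv_SE"` or `"inv_sqrt_n"`; see
#'   [precision()].
#' @param trimfill Optional `"trimfill_result"` whose filled studies are
#'   added as open points mirrored about the adjusted centreline.
#' @return An object of class `"funnel_spec"`: `points` (data frame of
#'   `estimate`, `ordinate`), `filled_points`, `centreline`,
#'   `ordinate_kind`, and `invert_axis` (`TRUE` for the SE ordinate, so
#'   precise studies plot at the top).
#' @examples
#' d <- meta_dataset(c(1, 2, 3), c(0.4, 0.5, 0.6), rep(10, 3), rep(10, 3), "SMD_g")
#' f <- build_funnel(d)
#' @export
build_funnel <- function(data, ordinate_kind = c("SE", "inv_SE", "inv_sqrt_n"),
                         trimfill = NULL) {
  ordinate_kind <- match.arg(ordinate_kind)
  .check_meta(data, 1L, "funnel plotting")
  ord <- function(d) switch(ordinate_kind,
                            SE = d$se,
                            inv_SE = 1 / d$se,
                            inv_sqrt_n = 1 / sqrt(d$n_ctrl + d$n_int))
  pts <- data.frame(estimate = data$estimate, ordinate = ord(data))
  filled <- NULL
  if (!is.null(trimfill)) {
    stopifnot(inherits(trimfill, "trimfill_result"))
    centre <- trimfill$adjusted$mu_hat
    if (nrow(trimfill$filled))
      filled <- data.frame(estimate = trimfill$filled$estimate,
                           ordinate = ord(trimfill$filled))
  } else {
    centre <- if (nrow(data) >= 2) pool_random(data)$mu_hat else data$estimate[1]
  }
  structure(list(points = pts, filled_points = filled, centreline = centre,
                 ordinate_kind = ordinate_kind,
                 measure = .measure_tag(data),
                 invert_axis = ordinate_kind == "SE"),
            class = "funnel_spec")
}

#' Plot a funnel
#'
#' Renders a [build_funnel()] specification with base graphics: observed
#' studies as filled circles, trim-and-fill imputations as open circles,
#' the pooled estimate as a dashed vertical centreline. The SE axis is
#' inverted so that precise studies plot at the top; precision ordinates
#' (`1/SE`, `1/sqrt(n)`) ascend.
#'
#' @param x A `"funnel_spec"`.
#' @param xlab,ylab Axis labels; defaults derive from the measure and
#'   ordinate kind.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.funnel_spec <- function(x, xlab = NULL, ylab = NULL, ...) {
  if (is.null(xlab)) xlab <- paste("Effect size", paste0("(", x$measure, ")"))
  if (is.null(ylab)) ylab <- switch(x$ordinate_kind,
                                    SE = "Standard error",
                                    inv_SE = "Precision (1/SE)",
                                    inv_sqrt_n = expression(1 / sqrt(n)))
  all_y <- c(x$points$ordinate, x$filled_points$ordinate)
  all_x <- c(x$points$estimate, x$filled_points$estimate, x$centreline)
  ylim <- range(all_y)
  if (x$invert_axis) ylim <- rev(ylim)
  graphics::plot(x$points$estimate, x$points$ordinate, pch = 16,
                 xlim = range(all_x), ylim = ylim, xlab = xlab, ylab = ylab, ...)
  if (!is.null(x$filled_points))
    graphics::points(x$filled_points$estimate, x$filled_points$ordinate, pch = 1)
  graphics::abline(v = x$centreline, lty = 2)
  invisible(x)
}

#' Re-analyze a user-supplied meta-analysis CSV
#'
#' The end-user publication-bias workflow on one CSV file: read it (either
#' the "arms" layout of per-arm summaries or the "effects" layout of
#' precomputed effects), compute the requested effect measure if needed,
#' and for each precision predictor run the Egger test, trim-and-fill, the
#' random-effects pool and assemble funnel-plot data.
#'
#' @param path CSV path; the layout is auto-detected from the header
#'   (override with `dialect`).
#' @param measure Effect measure to compute for an arms CSV (ignored for an
#'   effects CSV, which carries its own tag).
#' @param predictors Egger precision predictors to run.
#' @param dialect `"auto"`, `"arms"` or `"effects"`.
#' @param side Trim-and-fill side, see [trim_and_fill()].
#' @param json Optional path: write the report as JSON.
#' @param svg Optional path prefix: write one funnel SVG per predictor
#'   (`<prefix>_<predictor>.svg`).
#' @return A list of class `"funnel_report"`: `data` (the
#'   [meta_dataset()]), `pool` (random-effects), and per predictor `egger`,
#'   `trimfill`, `funnel`.
#' @export
reanalyze_csv <- function(path, measure = c("SMD_g", "SMD_d", "RMD", "NMD"),
                          predictors = c("SE", "inv_sqrt_n"),
                          dialect = c("auto", "arms", "effects"),
                          side = "auto", json = NULL, svg = NULL) {
  measure <- match.arg(measure)
  dialect <- match.arg(dialect)
  predictors <- match.arg(predictors, c("SE", "inv_sqrt_n"), several.ok = TRUE)
  if (dialect == "auto") {
    hdr <- names(utils::read.csv(path, nrows = 1, fileEncoding = "UTF-8"))
    dialect <- if ("estimate" %in% hdr && "se" %in% hdr) "effects" else "arms"
  }
  data <- if (dialect == "effects") {
    read_effects_csv(path)
  } else {
    arms <- read_arms_csv(path)
    if (measure == "NMD" && !"mean_sham" %in% names(arms))
      stop("measure 'NMD' requires sham columns in the arms CSV", call. = FALSE)
    compute_effects(arms, measure)
  }
  pool <- pool_random(data)
  per_pred <- lapply(predictors, function(pr) {
    eg <- egger_test(data, predictor = pr)
    ordinate <- if (pr == "SE") "SE" else "inv_sqrt_n"
    tf <- trim_and_fill(data, side = side)
    list(egger = eg, trimfill = tf,
         funnel = build_funnel(data, ordinate, trimfill = tf))
  })
  names(per_pred) <- predictors
  rep <- structure(list(path = path, measure = .measure_tag(data),
                        k = nrow(data), data = data, pool = pool,
                        predictors = per_pred),
                   class = "funnel_report")
  if (!is.null(json)) write_report_json(rep, json)
  if (!is.null(svg)) {
    for (pr in predictors) {
      f <- paste0(svg, "_", gsub("[^a-z_]", "", tolower(pr)), ".svg")
      grDevices::svg(f, width = 6, height = 5)
      plot(per_pred[[pr]]$funnel)
      grDevices::dev.off()
    }
  }
  rep
}

#' Serialize a funnel report to JSON
#'
#' Writes the result fields of a [reanalyze_csv()] report (pooled estimate,
#' Egger test, trim-and-fill, funnel points) as a JSON record.
#'
#' @param report A `"funnel_report"`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "funnel_report"))
  as_rec <- function(pp) list(
    egger = list(coef = pp$egger$coef, se_coef = pp$egger$se_coef,
                 t_stat = pp$egger$t_stat, p = pp$egger$p,
                 predictor = pp$egger$predictor, k = pp$egger$k),
    trimfill = list(k0 = pp$trimfill$k0, side = pp$trimfill$side,
                    adjusted_mu = pp$trimfill$adjusted$mu_hat,
                    adjusted_se = pp$trimfill$adjusted$se_mu),
    funnel = list(points = pp$funnel$points,
                  filled_points = pp$funnel$filled_points,
                  centreline = pp$funnel$centreline,
                  ordinate_kind = pp$funnel$ordinate_kind))
  out <- list(path = report$path, measure = report$measure, k = report$k,
              pool = list(mu_hat = report$pool$mu_hat, se_mu = report$pool$se_mu,
                          tau2 = report$pool$tau2, model = report$pool$model),
              predictors = lapply(report$predictors, as_rec))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf("Publication-bias re-analysis of %s (%d studies, %s)\n",
              x$path, x$k, x$measure))
  print(x$pool)
  for (pr in names(x$predictors)) {
    cat("--- predictor:", pr, "---\n")
    print(x$predictors[[pr]]$egger)
    print(x$predictors[[pr]]$trimfill)
  }
  invisible(x)
}
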