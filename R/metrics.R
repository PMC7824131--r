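# Plane-agreement metrics and cohort statistics.
#
# All four pair metrics act on normalized coefficient 4-vectors; callers
# comparing planes of a cropped head cube should express both planes with
# the crop centre (seed) as origin (recenter_plane) so the offset d does not
# dominate the 4-vector.

check_metric_plane <- function(p) {
  if (!is_plane(p)) {
    v <- as.numeric(p)
    if (abs(sqrt(sum(v^2)) - 1) > 1e-9)
      warning("plane coefficients are not unit-norm; normalizing", call. = FALSE)
    p <- normalize_plane(v)
  }
  p
}

#' Included angle between two planes
#'
#' Arc-cosine of the absolute dot product of the two unit coefficient
#' 4-vectors, in degrees.  Zero iff the planes coincide; the absolute value
#' makes the metric independent of the sign of either representation.
#'
#' @param p1,p2 planes (`msp_plane` or raw 4-vectors; auto-normalized with a
#'   warning if needed).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
included_angle <- function(p1, p2) {
  v1 <- as.numeric(check_metric_plane(p1))
  v2 <- as.numeric(check_metric_plane(p2))
  if (sum(v1 * v2) < 0) v2 <- -v2
  # 2 asin(|v1 - v2| / 2) == acos(v1 . v2) for unit vectors, but is
  # numerically exact near zero (identical planes give exactly 0)
  d <- sqrt(sum((v1 - v2)^2))
  2 * asin(pmin(1, d / 2)) * 180 / pi
}

#' Euclidean distance between plane coefficient vectors
#'
#' `sqrt(sum((v1 - v2)^2))` over the unit 4-vectors, with the representation
#' sign chosen so the dot product is nonnegative (coinciding planes give 0).
#'
#' @inheritParams included_angle
#' @return Nonnegative scalar, at most `sqrt(2)` for distinct planes.
#' @export
coeff_distance <- function(p1, p2) {
  p1 <- as.numeric(check_metric_plane(p1))
  p2 <- as.numeric(check_metric_plane(p2))
  if (sum(p1 * p2) < 0) p2 <- -p2
  sqrt(sum((p1 - p2)^2))
}

#' Yaw angle of a plane
#'
#' `atan2(b, a)` in degrees, wrapped into `(-90, 90]`: the rotation of the
#' plane normal within the axial section.
#'
#' @param p a plane.
#' @return Degrees in `(-90, 90]`.
#' @export
yaw <- function(p) {
  p <- check_metric_plane(p)
  ang <- atan2(p[["b"]], p[["a"]]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Roll angle of a plane
#'
#' `atan(-c / sqrt(a^2 + b^2))` in degrees (two-argument form, so `a = b = 0`
#' yields +/-90 rather than an error).
#'
#' @param p a plane.
#' @return Degrees in `[-90, 90]`.
#' @export
roll <- function(p) {
  p <- check_metric_plane(p)
  atan2(-p[["c"]], sqrt(p[["a"]]^2 + p[["b"]]^2)) * 180 / pi
}

#' Pair metrics for a predicted/reference plane pair
#'
#' @param predicted,reference planes.
#' @return One-row tibble with columns `theta` (included angle, degrees),
#'   `dist` (coefficient distance), `dyaw`, `droll` (absolute yaw and roll
#'   differences, degrees).
#' @export
plane_pair_metrics <- function(predicted, reference) {
  tibble::tibble(
    theta = included_angle(predicted, reference),
    dist = coeff_distance(predicted, reference),
    dyaw = abs(yaw(predicted) - yaw(reference)),
    droll = abs(roll(predicted) - roll(reference))
  )
}

#' Evaluate a cohort of plane pairs
#'
#' Computes the four pair metrics for every case, their cohort means and
#' standard deviations, and the fractions of cases below the conventional
#' thresholds (coefficient distance < 0.05, included angle < 1 degree).
#'
#' @param pairs either a data frame with list-columns `predicted` and
#'   `reference`, or a list of `list(predicted =, reference =)` pairs.
#' @param dist_threshold,angle_threshold reporting thresholds.
#' @return An object of class `msp_cohort_eval`; `tidy()` returns the
#'   per-case table, `glance()` the one-row cohort summary.
#' @export
evaluate_cohort <- function(pairs, dist_threshold = 0.05, angle_threshold = 1) {
  if (is.data.frame(pairs)) {
    pred <- pairs$predicted; ref <- pairs$reference
  } else {
    if (length(pairs) < 1L) stop("empty cohort", call. = FALSE)
    pred <- lapply(pairs, `[[`, "predicted")
    ref <- lapply(pairs, `[[`, "reference")
  }
  if (length(pred) < 1L) stop("empty cohort", call. = FALSE)
  cases <- dplyr::bind_rows(Map(plane_pair_metrics, pred, ref))
  cases <- dplyr::mutate(cases, case = dplyr::row_number(), .before = 1L)
  summary <- tibble::tibble(
    n = nrow(cases),
    mean_theta = mean(cases$theta), sd_theta = stats::sd(cases$theta),
    mean_dist = mean(cases$dist), sd_dist = stats::sd(cases$dist),
    mean_dyaw = mean(cases$dyaw), sd_dyaw = stats::sd(cases$dyaw),
    mean_droll = mean(cases$droll), sd_droll = stats::sd(cases$droll),
    frac_dist_below = mean(cases$dist < dist_threshold),
    frac_angle_below = mean(cases$theta < angle_threshold)
  )
  structure(list(cases = cases, summary = summary,
                 dist_threshold = dist_threshold,
                 angle_threshold = angle_threshold),
            class = "msp_cohort_eval")
}

#' @export
print.msp_cohort_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cohort evaluation> n = %d cases\n", s$n))
  cat(sprintf("  included angle: %.4f deg (SD %.4f); %.1f%% below %.1f deg\n",
              s$mean_theta, s$sd_theta, 100 * s$frac_angle_below,
              x$angle_threshold))
  cat(sprintf("  coeff distance: %.4f (SD %.4f); %.1f%% below %.2f\n",
              s$mean_dist, s$sd_dist, 100 * s$frac_dist_below,
              x$dist_threshold))
  cat(sprintf("  yaw diff: %.4f deg; roll diff: %.4f deg\n",
              s$mean_dyaw, s$mean_droll))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.msp_cohort_eval <- function(x, ...) x$cases

#' @exportS3Method generics::glance
glance.msp_cohort_eval <- function(x, ...) x$summary

#' Paired agreement statistics between two measurement methods
#'
#' Summarises paired differences `methodB - methodA`: mean (bias), SD, 95%
#' confidence interval of the mean difference (t distribution, n - 1 df),
#' Pearson correlation, paired t-test p-value, and Bland-Altman 95% limits
#' of agreement `bias +/- 1.96 * SD`.
#'
#' @param methodA,methodB equal-length numeric vectors (length >= 3).
#' @param conf_level confidence level for the CI of the mean difference.
#' @return An object of class `msp_agreement`; see `tidy()`, `glance()` and
#'   `autoplot()` methods.  With zero-variance differences the p-value is
#'   reported as `NA` (marked not applicable) rather than propagating NaN.
#' @export
agreement <- function(methodA, methodB, conf_level = 0.95) {
  stopifnot(length(methodA) == length(methodB), length(methodA) >= 3L)
  d <- methodB - methodA
  n <- length(d)
  bias <- mean(d)
  sdd <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  se <- sdd / sqrt(n)
  r <- if (stats::sd(methodA) > 0 && stats::sd(methodB) > 0)
    stats::cor(methodA, methodB) else NA_real_
  applicable <- sdd > 1e-12 * max(1, abs(bias))
  p <- if (applicable)
    tryCatch(stats::t.test(methodB, methodA, paired = TRUE)$p.value,
             error = function(e) NA_real_)
    else NA_real_
  structure(list(
    n = n, bias = bias, sd = sdd,
    ci_low = bias - tq * se, ci_high = bias + tq * se,
    r = r, p = p, p_applicable = applicable,
    loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
    means = (methodA + methodB) / 2, diffs = d
  ), class = "msp_agreement")
}

#' @export
print.msp_agreement <- function(x, ...) {
  cat(sprintf("<agreement> n = %d paired cases\n", x$n))
  cat(sprintf("  bias %.4f (SD %.4f), 95%% CI [%.4f, %.4f]\n",
              x$bias, x$sd, x$ci_low, x$ci_high))
  cat(sprintf("  limits of agreement [%.4f, %.4f]\n", x$loa_low, x$loa_high))
  cat(sprintf("  r = %s, paired t-test p = %s\n",
              ifelse(is.na(x$r), "n/a", sprintf("%.4f", x$r)),
              ifelse(x$p_applicable, sprintf("%.4f", x$p), "n/a")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.msp_agreement <- function(x, ...) {
  tibble::tibble(mean = x$means, difference = x$diffs)
}

#' @exportS3Method generics::glance
glance.msp_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd = x$sd, ci_low = x$ci_low,
                 ci_high = x$ci_high, r = x$r, p = x$p,
                 loa_low = x$loa_low, loa_high = x$loa_high)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot of an agreement analysis
#'
#' Scatter of per-case means against differences with the bias line and the
#' 95% limits of agreement.
#'
#' @param object an `msp_agreement`.
#' @param ... ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.msp_agreement <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (B - A)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Yaw-roll consistency scatter plot
#'
#' One point per case (roll on x, yaw on y), optionally grouped by method.
#'
#' @param data data frame with numeric columns `roll` and `yaw` and an
#'   optional `method` column.
#' @return A ggplot object.
#' @export
plot_yaw_roll <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$roll, y = .data$yaw))
  if ("method" %in% names(data))
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$method), alpha = 0.7)
  else p <- p + ggplot2::geom_point(alpha = 0.7)
  p + ggplot2::labs(x = "Roll (degrees)", y = "Yaw (degrees)",
                    title = "Yaw-roll consistency") +
    ggplot2::theme_minimal()
}
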