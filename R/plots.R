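#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dose ladder of a profile
#'
#' One horizontal bar per member family on a log dose axis, showing the
#' CTDIvol range each family can produce; the primary family is
#' highlighted. The classic way to see whether the ranges chain with
#' little overlap.
#'
#' @param object A `gsi_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gsi_profile <- function(object, ...) {
  m <- tidy(object)
  m$role <- factor(m$role, levels = rev(intersect(role_levels, m$role)))
  ggplot2::ggplot(m, ggplot2::aes(y = .data$role)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$ctdi_min, xend = .data$ctdi_max,
                   yend = .data$role, colour = .data$primary),
      linewidth = 4, lineend = "butt") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "#0072B2"),
                                 labels = c(`TRUE` = "primary", `FALSE` = "other"),
                                 name = NULL) +
    ggplot2::labs(title = object$name, x = "CTDIvol (mGy)", y = NULL)
}

#' Fractional-mismatch curve of a coverage report
#'
#' |f| against target CTDIvol on a log dose axis, with the coverage
#' tolerance as a horizontal reference line. Spikes between grid values
#' show where the discrete dose grid matches targets less precisely;
#' outside the achievable range |f| grows without bound.
#'
#' @param object A `dose_match_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_match_report <- function(object, ...) {
  ggplot2::ggplot(object$targets,
                  ggplot2::aes(x = .data$target, y = abs(.data$f))) +
    ggplot2::geom_line(colour = "#0072B2") +
    ggplot2::geom_hline(yintercept = object$tolerance, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "target CTDIvol (mGy)", y = "|f| (fractional mismatch)",
                  title = sprintf("%s: %.0f%% of targets within %.0f%%",
                                  object$profile, 100 * object$covered_fraction,
                                  100 * object$tolerance))
}

#' Projected-noise profile of a simulated exam
#'
#' Per-family projected noise index along the scan axis, with the
#' prescribed noise index as a reference line; positions projected above
#' it are the ones a scanner would mark in orange.
#'
#' @param object An `aec_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aec_result <- function(object, ...) {
  prof <- tidyr::unnest(
    object$per_family[, c("role", "pni_profile")], "pni_profile")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$z_cm, y = .data$pni_hu,
                                     colour = .data$role)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$ni, linetype = "dashed") +
    ggplot2::labs(x = "z (cm)", y = "projected noise index (HU)",
                  title = sprintf("%s: target %.1f mGy, %s",
                                  object$profile, object$target_ctdi,
                                  object$recommendation))
}

#' Dose ladder report, optionally with a mismatch panel
#'
#' Renders the profile's dose ladder; when a target grid is given (or
#' defaulted) and patchwork is installed, adds the |f| curve beneath, in
#' the style of a profile design report. With `compare`, additional
#' profiles are drawn as side-by-side range bars on one axis.
#'
#' @param profile A `gsi_profile`.
#' @param targets Target grid for the mismatch panel; `NULL` for the
#'   report default, `numeric(0)` to omit the panel.
#' @param compare Optional list of further `gsi_profile`s for a
#'   range-comparison chart.
#' @param tolerance Coverage tolerance for the mismatch panel.
#' @return A ggplot (or patchwork combination).
#' @export
render_ladder <- function(profile, targets = NULL, compare = NULL,
                          tolerance = 0.05) {
  if (!is.null(compare)) {
    profs <- c(list(profile), compare)
    ranges <- purrr::map_dfr(profs, glance)
    ranges$name <- factor(ranges$name, levels = rev(ranges$name))
    return(
      ggplot2::ggplot(ranges, ggplot2::aes(y = .data$name)) +
        ggplot2::geom_segment(ggplot2::aes(x = .data$union_min,
                                           xend = .data$union_max,
                                           yend = .data$name),
                              linewidth = 4, colour = "#0072B2") +
        ggplot2::scale_x_log10() +
        ggplot2::labs(x = "CTDIvol (mGy)", y = NULL,
                      title = "Achievable CTDIvol range by profile")
    )
  }
  ladder <- autoplot.gsi_profile(profile)
  if (!is.null(targets) && length(targets) == 0) return(ladder)
  rep <- coverage_report(profile, targets = targets, tolerance = tolerance)
  curve <- autoplot.dose_match_report(rep) + ggplot2::labs(title = NULL)
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(ladder, curve, ncol = 1)
  } else {
    ladder
  }
}
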