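#' Nearest achievable CTDIvol
#'
#' The scanner uses whichever grid value is closest to the target dose; an
#' exact midpoint between two grid values resolves to the *lower* one (the
#' vendor's tie-break is unpublished; favouring the lower dose is this
#' package's recorded convention).
#'
#' @param doses An [achievable_doses()] vector (or sorted numeric).
#' @param target Target CTDIvol values (mGy), positive; vectorised.
#' @return Nearest grid value(s).
#' @export
#' @examples
#' nearest_achievable(achievable_doses(c(4, 8, 12)), 9)  # 8
nearest_achievable <- function(doses, target) {
  stopifnot(length(doses) > 0)
  if (any(target <= 0)) stop("target CTDIvol must be > 0", call. = FALSE)
  g <- sort(as.numeric(doses))
  # index of last grid value <= target, clamped into the grid
  lo <- pmin(pmax(findInterval(target, g), 1L), length(g))
  hi <- pmin(lo + 1L, length(g))
  pick_hi <- (g[hi] - target) < (target - g[lo])  # strict: midpoint ties go low
  g[ifelse(pick_hi, hi, lo)]
}

#' Signed fractional dose mismatch
#'
#' How far the nearest achievable dose falls from a target:
#' \deqn{f = (CTDI_{target} - CTDI_{actual}) / CTDI_{target}}
#' Zero iff the target is exactly achievable; positive when the grid can
#' only undershoot (e.g. targets above the range maximum).
#'
#' @inheritParams nearest_achievable
#' @return Signed fractional mismatch, vectorised over `target`.
#' @export
fractional_match <- function(doses, target) {
  (target - nearest_achievable(doses, target)) / target
}

#' Clinically-insignificant CTDIvol change threshold
#'
#' A dose change below about 25% does not produce a noticeable change in
#' image noise; report annotations use this named constant.
#' @export
CTDI_INSIGNIFICANT_CHANGE <- 0.25

#' Dose-matching precision of a profile
#'
#' Pools the achievable-dose grids of every member family and evaluates the
#' signed fractional mismatch `f` over a target grid. The default target
#' grid is 200 log-spaced points from half the union minimum to 1.5 times
#' the union maximum, so the report shows both the covered interior and the
#' degradation outside the achievable range.
#'
#' @param profile A `gsi_profile`.
#' @param targets Target CTDIvol grid (mGy); default as described.
#' @param tolerance Two-sided fractional tolerance defining "covered"
#'   (default 0.05, i.e. within ±5%).
#' @param n_grid Synthetic grid size per bounds-only family (see
#'   [ctdi_grid()]).
#' @return A `dose_match_report`: per-target tibble (`target`, `nearest`,
#'   `f`, `covered`) plus `union_min`, `union_max`, `tolerance`,
#'   `covered_fraction` fields.
#' @export
#' @examples
#' prof <- paper_profile("uab_liver")
#' glance(coverage_report(prof))
coverage_report <- function(profile, targets = NULL, tolerance = 0.05,
                            n_grid = 20) {
  stopifnot(inherits(profile, "gsi_profile"), nrow(profile$members) >= 1)
  grids <- purrr::map(seq_len(nrow(profile$members)),
                      function(i) as.numeric(ctdi_grid(profile$members[i, ], n_grid)))
  pool <- achievable_doses(unlist(grids), source = profile$name)
  if (is.null(targets)) {
    targets <- exp(seq(log(0.5 * min(pool)), log(1.5 * max(pool)), length.out = 200))
  }
  stopifnot(all(targets > 0))
  nearest <- nearest_achievable(pool, targets)
  f <- (targets - nearest) / targets
  rows <- tibble::tibble(target = targets, nearest = nearest, f = f,
                         covered = abs(f) <= tolerance)
  structure(
    list(profile = profile$name, doses = pool,
         union_min = min(pool), union_max = max(pool),
         tolerance = tolerance, targets = rows,
         covered_fraction = mean(rows$covered)),
    class = "dose_match_report"
  )
}

#' @export
print.dose_match_report <- function(x, ...) {
  cat(sprintf("<dose_match_report '%s': union %.1f-%.1f mGy, %d targets, %.0f%% within |f| <= %.2f>\n",
              x$profile, x$union_min, x$union_max, nrow(x$targets),
              100 * x$covered_fraction, x$tolerance))
  invisible(x)
}

#' @export
tidy.dose_match_report <- function(x, ...) x$targets

#' @export
glance.dose_match_report <- function(x, ...) {
  tibble::tibble(profile = x$profile, union_min = x$union_min,
                 union_max = x$union_max, tolerance = x$tolerance,
                 n_targets = nrow(x$targets),
                 covered_fraction = x$covered_fraction)
}

#' Noise-index to dose mismatch propagation
#'
#' Image noise scales as dose^(-1/2), so to first order a fractional
#' noise-index change of delta corresponds to a dose change of 2·delta.
#' A 2 HU deviation at a target noise index of 18 HU is an 11% noise change
#' and hence a 22% CTDIvol mismatch (integer-rounded display values) —
#' below the ~25% threshold at which a dose change becomes noticeable in
#' the image ([CTDI_INSIGNIFICANT_CHANGE]).
#'
#' @param ni_target Target noise index (HU), positive.
#' @param delta_ni Noise-index deviation (HU).
#' @return One-row tibble: `ni_percent`, `ctdi_percent` (exact), their
#'   integer-rounded display values, and whether the dose mismatch stays
#'   below the clinically-insignificant threshold.
#' @export
#' @examples
#' ni_to_ctdi_mismatch(18, 2)  # 11% noise, 22% dose
ni_to_ctdi_mismatch <- function(ni_target, delta_ni) {
  stopifnot(ni_target > 0)
  ni_pct <- 100 * delta_ni / ni_target
  ctdi_pct <- 2 * ni_pct
  tibble::tibble(
    ni_percent = ni_pct, ctdi_percent = ctdi_pct,
    ni_percent_display = round(ni_pct), ctdi_percent_display = round(ctdi_pct),
    clinically_insignificant = abs(ctdi_pct) / 100 < CTDI_INSIGNIFICANT_CHANGE
  )
}
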