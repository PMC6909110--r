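#' Synthetic patient thickness profile
#'
#' A patient is modelled as a water-equivalent thickness profile `d(z)`
#' along the scan axis, plus the calibration that turns thickness into a
#' required dose: `ctdi_ref` is the CTDIvol giving the target noise
#' `ni_ref` for a patient of reference thickness `d_ref`, and each
#' additional `d_double` cm of tissue doubles the required dose
#' (attenuation drops transmission roughly twofold per 5 cm in the
#' abdomen).
#'
#' @param z Scan-axis positions (cm), strictly increasing.
#' @param d Water-equivalent thickness at each `z` (cm), positive.
#' @param d_ref Reference thickness (cm, default 30).
#' @param d_double Thickness increase that doubles the required dose (cm,
#'   default 5).
#' @param ctdi_ref CTDIvol (mGy) producing noise `ni_ref` at `d_ref`
#'   (default 15).
#' @param ni_ref Noise index (HU) at which `ctdi_ref` is calibrated
#'   (default 18).
#' @return Tibble (`z_cm`, `d_cm`) of class `patient_model` carrying the
#'   calibration as attributes.
#' @export
#' @examples
#' patient_model(z = 0:10, d = rep(30, 11))
patient_model <- function(z, d, d_ref = 30, d_double = 5,
                          ctdi_ref = 15, ni_ref = 18) {
  stopifnot(length(z) == length(d), length(z) >= 1,
            all(diff(z) > 0), all(d > 0), d_double > 0,
            d_ref > 0, ctdi_ref > 0, ni_ref > 0)
  structure(tibble::tibble(z_cm = as.numeric(z), d_cm = as.numeric(d)),
            d_ref = d_ref, d_double = d_double,
            ctdi_ref = ctdi_ref, ni_ref = ni_ref,
            class = c("patient_model", class(tibble::tibble())))
}

patient_calibration <- function(patient) {
  list(d_ref = attr(patient, "d_ref"), d_double = attr(patient, "d_double"),
       ctdi_ref = attr(patient, "ctdi_ref"), ni_ref = attr(patient, "ni_ref"))
}

#' CTDIvol required for a given thickness and noise target
#'
#' The dose that yields image noise `ni` for water-equivalent thickness
#' `d`: exponential in thickness (doubling every `d_double` cm) and
#' inverse-square in the noise target (noise scales as dose^(-1/2)):
#' \deqn{CTDI(d, ni) = CTDI_{ref} \cdot (ni_{ref}/ni)^2 \cdot
#'       2^{(d - d_{ref})/d_{double}}}
#'
#' @param d Thickness values (cm), positive.
#' @param patient A [patient_model()] supplying the calibration.
#' @param ni Target noise index (HU), positive.
#' @return Required CTDIvol (mGy), vectorised over `d`.
#' @export
required_ctdi <- function(d, patient, ni) {
  if (any(d <= 0) || any(ni <= 0)) stop("thickness and noise index must be > 0",
                                        call. = FALSE)
  cal <- patient_calibration(patient)
  cal$ctdi_ref * (cal$ni_ref / ni)^2 * 2^((d - cal$d_ref) / cal$d_double)
}

#' Single target dose for a whole scan
#'
#' Without longitudinal current modulation the system picks one dose for
#' the entire scan length from the thickness profile. The aggregation the
#' vendor uses is unpublished; the default is the unweighted mean of the
#' per-slice requirements, with `max` and quantile alternatives available.
#'
#' @param patient A [patient_model()].
#' @param ni Target noise index (HU).
#' @param aggregate `"mean"` (default), `"max"`, or `"quantile"`.
#' @param prob Quantile level when `aggregate = "quantile"`.
#' @return Target CTDIvol (mGy).
#' @export
target_ctdi <- function(patient, ni, aggregate = c("mean", "max", "quantile"),
                        prob = 0.9) {
  aggregate <- match.arg(aggregate)
  req <- required_ctdi(patient$d_cm, patient, ni)
  switch(aggregate,
         mean = mean(req),
         max = max(req),
         quantile = unname(stats::quantile(req, prob)))
}

#' Tube current selection for a family
#'
#' Picks the grid dose closest to the target ([nearest_achievable()]) and,
#' when the family carries an explicit current list, the generating current.
#' Targets outside the achievable range clamp to the nearest endpoint.
#'
#' @param family One-row family table.
#' @param target Target CTDIvol (mGy), positive scalar.
#' @param n_grid Synthetic grid size for bounds-only families.
#' @return One-row tibble: `ma` (NA for bounds-only families),
#'   `actual_ctdi`.
#' @export
choose_current <- function(family, target, n_grid = 20) {
  stopifnot(length(target) == 1, target > 0)
  grid <- ctdi_grid(family, n_grid)
  actual <- nearest_achievable(grid, target)
  ma <- family$ma_grid[[1]]
  chosen_ma <- if (!is.null(ma) && length(ma) > 0 && is.finite(family$dose_coeff)) {
    doses <- ctdi_for_ma(family, ma)
    ma[which.min(abs(doses - actual))]
  } else NA_real_
  tibble::tibble(ma = chosen_ma, actual_ctdi = actual)
}

#' Projected noise index along the scan
#'
#' With a fixed delivered dose, the projected noise at position `z` follows
#' from the inverse-square noise–dose law:
#' `pni(z) = ni * sqrt(required(d(z), ni) / actual)`. Positions where the
#' projection exceeds the prescribed noise index are flagged (shown in
#' orange on the scanner); the summary shown to the operator is the
#' unweighted mean over the scan length.
#'
#' @param patient A [patient_model()].
#' @param actual_ctdi Delivered CTDIvol (mGy), positive.
#' @param ni Prescribed noise index (HU).
#' @return List: `pni_profile` tibble (`z_cm`, `pni_hu`, `above`),
#'   `avg_pni`, `above_mask`.
#' @export
projected_ni <- function(patient, actual_ctdi, ni) {
  stopifnot(actual_ctdi > 0)
  pni <- ni * sqrt(required_ctdi(patient$d_cm, patient, ni) / actual_ctdi)
  above <- pni > ni
  list(pni_profile = tibble::tibble(z_cm = patient$z_cm, pni_hu = pni,
                                    above = above),
       avg_pni = mean(pni), above_mask = above)
}

#' The operator's preset-switching rule
#'
#' Keep the primary preset family unless the average projected noise index
#' deviates from the prescribed noise index by *more than* `threshold` HU
#' (default 2): more than `threshold` below switches to the small family
#' (dose is higher than needed), more than `threshold` above switches to
#' the large family. Deviations of exactly `threshold` keep the primary.
#'
#' @param avg_pni Average projected noise index (HU).
#' @param ni Prescribed noise index (HU).
#' @param threshold Switching threshold (HU, default 2).
#' @return `"switch_small"`, `"keep_primary"`, or `"switch_large"`.
#' @export
#' @examples
#' technologist_rule(21, 18)  # "switch_large"
technologist_rule <- function(avg_pni, ni, threshold = 2) {
  dplyr::case_when(
    avg_pni < ni - threshold ~ "switch_small",
    avg_pni > ni + threshold ~ "switch_large",
    .default = "keep_primary"
  )
}

#' Simulate one AEC exam
#'
#' Runs the scan-time workflow for a profile and patient: one target dose
#' from the thickness profile, then per member family the selected current,
#' delivered dose, projected-noise profile, average PNI, and the
#' above/below flag. The switching rule is applied to the *primary*
#' family's average PNI; `switch_small` selects the profile's small role
#' and `switch_large` its large role (falling back to xlarge, then to
#' keeping the primary, when the role is absent).
#'
#' @param profile A `gsi_profile`.
#' @param patient A [patient_model()].
#' @param ni Prescribed noise index (HU).
#' @param threshold Switching threshold (HU, default 2).
#' @param n_grid Synthetic grid size for bounds-only families.
#' @param aggregate Passed to [target_ctdi()].
#' @return An `aec_result`: `target_ctdi`, per-family tibble, the primary's
#'   average PNI, the recommendation, and the selected role.
#' @export
#' @examples
#' prof <- paper_profile("uab_liver")
#' pat <- patient_model(z = seq(0, 40, length.out = 20), d = rep(30, 20))
#' simulate_exam(prof, pat, ni = 18)
simulate_exam <- function(profile, patient, ni, threshold = 2, n_grid = 20,
                          aggregate = "mean") {
  stopifnot(inherits(profile, "gsi_profile"), inherits(patient, "patient_model"),
            ni > 0)
  target <- target_ctdi(patient, ni, aggregate = aggregate)
  members <- profile$members
  per_family <- purrr::map_dfr(seq_len(nrow(members)), function(i) {
    fam <- members[i, ]
    sel <- choose_current(fam, target, n_grid = n_grid)
    proj <- projected_ni(patient, sel$actual_ctdi, ni)
    tibble::tibble(
      role = fam$role, family = fam$name,
      ma = sel$ma, actual_ctdi = sel$actual_ctdi,
      avg_pni = proj$avg_pni,
      flag = if (proj$avg_pni > ni) "above" else "at_or_below",
      pni_profile = list(proj$pni_profile)
    )
  })
  primary_pni <- per_family$avg_pni[per_family$role == profile$primary_role]
  rec <- technologist_rule(primary_pni, ni, threshold)
  selected_role <- switch(
    rec,
    keep_primary = profile$primary_role,
    switch_small = if ("small" %in% per_family$role) "small" else profile$primary_role,
    switch_large = if ("large" %in% per_family$role) "large"
                   else if ("xlarge" %in% per_family$role) "xlarge"
                   else profile$primary_role
  )
  structure(
    list(profile = profile$name, ni = ni, threshold = threshold,
         target_ctdi = target, per_family = per_family,
         primary_role = profile$primary_role, avg_pni_primary = primary_pni,
         recommendation = rec, selected_role = selected_role),
    class = "aec_result"
  )
}

#' @export
print.aec_result <- function(x, ...) {
  cat(sprintf("<aec_result '%s': NI %g HU, target %.1f mGy, primary AvgPNI %.1f HU -> %s (role %s)>\n",
              x$profile, x$ni, x$target_ctdi, x$avg_pni_primary,
              x$recommendation, x$selected_role))
  invisible(x)
}

#' Per-family table of a simulated exam
#'
#' @param x An `aec_result`.
#' @param ... Unused.
#' @return Tibble, one row per member family: selected current, delivered
#'   dose, average projected noise index, flag, and whether that row is the
#'   selected preset after applying the switching rule.
#' @export
tidy.aec_result <- function(x, ...) {
  out <- x$per_family
  out$selected <- out$role == x$selected_role
  out
}

#' @export
glance.aec_result <- function(x, ...) {
  tibble::tibble(profile = x$profile, ni = x$ni,
                 target_ctdi = x$target_ctdi,
                 avg_pni_primary = x$avg_pni_primary,
                 recommendation = x$recommendation,
                 selected_role = x$selected_role)
}
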