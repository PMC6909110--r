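#' Construct a preset-family table
#'
#' A preset family is one fixed scanner acquisition mode: scan field of view
#' (SFOV), focal spot, collimation, gantry rotation time and helical pitch,
#' together with the discrete set of tube currents it allows. Because the
#' current grid is discrete, each family can produce only a discrete set of
#' CTDIvol values, bounded by `ctdi_min` and `ctdi_max`.
#'
#' A family may be specified either by an explicit current grid plus a dose
#' coefficient (`ma_grid`, `dose_coeff`), or — as vendor documentation
#' usually prints it — by its CTDIvol range endpoints only (`ctdi_min`,
#' `ctdi_max`). When both are given they must agree to within 0.05 mGy
#' (one-decimal printing precision). For bounds-only families a synthetic
#' uniform dose grid stands in for the unpublished current list (see
#' [ctdi_grid()]).
#'
#' @param name Family label.
#' @param sfov Scan field of view label, e.g. `"Large Body"`.
#' @param focal_spot `"Large"` or `"XLarge"`.
#' @param collimation_mm Detector coverage in mm (e.g. 40, 80).
#' @param rotation_time_s Gantry rotation time in seconds.
#' @param pitch Helical pitch (table travel per rotation / collimation).
#' @param ctdi_min,ctdi_max Achievable CTDIvol bounds in mGy (optional when
#'   `ma_grid` and `dose_coeff` are given).
#' @param ma_grid Strictly increasing vector of available tube currents (mA),
#'   optional.
#' @param dose_coeff Dose coefficient in mGy per mA·s at pitch 1, optional.
#'
#' @return A one-row tibble with class `family_table`; rows of several
#'   families can be combined with [dplyr::bind_rows()].
#' @export
#' @examples
#' preset_family("small", "Large Body", "Large", 80, 0.5, 1.375,
#'               ctdi_min = 3.4, ctdi_max = 8.8)
preset_family <- function(name, sfov, focal_spot, collimation_mm,
                          rotation_time_s, pitch,
                          ctdi_min = NA_real_, ctdi_max = NA_real_,
                          ma_grid = NULL, dose_coeff = NA_real_) {
  fam <- tibble::tibble(
    name = as.character(name),
    sfov = as.character(sfov),
    focal_spot = as.character(focal_spot),
    collimation_mm = as.numeric(collimation_mm),
    rotation_time_s = as.numeric(rotation_time_s),
    pitch = as.numeric(pitch),
    ctdi_min = as.numeric(ctdi_min),
    ctdi_max = as.numeric(ctdi_max),
    ma_grid = list(if (is.null(ma_grid)) NULL else as.numeric(ma_grid)),
    dose_coeff = as.numeric(dose_coeff)
  )
  validate_family_table(as_family_table(fam))
}

as_family_table <- function(x) {
  if (!"ma_grid" %in% names(x)) x$ma_grid <- list(NULL)
  if (!"dose_coeff" %in% names(x)) x$dose_coeff <- NA_real_
  for (col in c("ctdi_min", "ctdi_max")) if (!col %in% names(x)) x[[col]] <- NA_real_
  class(x) <- union("family_table", class(x))
  x
}

#' Validate a family table
#'
#' Checks the structural invariants of every row: positive pitch, rotation
#' time and dose coefficient; a strictly increasing `ma_grid`;
#' `ctdi_min <= ctdi_max`; exactly one dose representation present (or both,
#' agreeing to within 0.05 mGy — one-decimal printing precision).
#'
#' @param families A family table (tibble).
#' @return The table, invisibly classed, or an error describing the first
#'   violated invariant.
#' @export
validate_family_table <- function(families) {
  families <- as_family_table(families)
  for (i in seq_len(nrow(families))) {
    f <- families[i, ]
    lbl <- sprintf("family '%s'", f$name)
    if (!f$focal_spot %in% c("Large", "XLarge"))
      stop(lbl, ": focal_spot must be 'Large' or 'XLarge'", call. = FALSE)
    if (!is.finite(f$pitch) || f$pitch <= 0)
      stop(lbl, ": pitch must be > 0", call. = FALSE)
    if (!is.finite(f$rotation_time_s) || f$rotation_time_s <= 0)
      stop(lbl, ": rotation_time_s must be > 0", call. = FALSE)
    ma <- f$ma_grid[[1]]
    has_grid <- !is.null(ma) && length(ma) > 0 && is.finite(f$dose_coeff)
    has_bounds <- is.finite(f$ctdi_min) && is.finite(f$ctdi_max)
    if (has_grid) {
      if (any(diff(ma) <= 0)) stop(lbl, ": ma_grid must be strictly increasing", call. = FALSE)
      if (any(ma <= 0)) stop(lbl, ": tube currents must be > 0", call. = FALSE)
      if (f$dose_coeff <= 0) stop(lbl, ": dose_coeff must be > 0", call. = FALSE)
    }
    if (has_bounds && f$ctdi_min > f$ctdi_max)
      stop(lbl, ": ctdi_min must be <= ctdi_max", call. = FALSE)
    if (!has_grid && !has_bounds)
      stop(lbl, ": provide either (ma_grid, dose_coeff) or (ctdi_min, ctdi_max)",
           call. = FALSE)
    if (has_grid && has_bounds) {
      ends <- range(ctdi_for_ma(f, ma))
      if (max(abs(ends - c(f$ctdi_min, f$ctdi_max))) > 0.05)
        stop(lbl, ": ma_grid endpoints disagree with (ctdi_min, ctdi_max) by > 0.05 mGy",
             call. = FALSE)
    }
  }
  families
}

#' CTDIvol produced by one tube current
#'
#' Standard helical dose scaling: CTDIvol = k · mA · T / pitch, with T the
#' rotation time and k the family's dose coefficient (mGy per mA·s at pitch
#' 1). The per-family coefficient absorbs kV-pair, focal-spot and bowtie
#' differences that are not modelled explicitly.
#'
#' @param family A one-row family table with `dose_coeff` set.
#' @param ma Tube current(s) in mA; must be positive.
#' @return CTDIvol in mGy, vectorised over `ma`.
#' @export
#' @examples
#' f <- preset_family("f", "Large Body", "Large", 80, 1, 1,
#'                    ma_grid = c(100, 200), dose_coeff = 0.01)
#' ctdi_for_ma(f, 100)  # 1 mGy
ctdi_for_ma <- function(family, ma) {
  stopifnot(nrow(family) == 1)
  if (!is.finite(family$dose_coeff))
    stop("family '", family$name, "' has no dose_coeff; cannot map mA to CTDIvol",
         call. = FALSE)
  if (any(ma <= 0)) stop("tube current must be > 0", call. = FALSE)
  family$dose_coeff * ma * family$rotation_time_s / family$pitch
}

#' Achievable CTDIvol grid of a preset family
#'
#' The discrete set of CTDIvol values the family can produce: one value per
#' grid current when the current list is known, or a synthetic uniform grid
#' of `n_grid` values spanning `[ctdi_min, ctdi_max]` (endpoints exact) for
#' bounds-only families.
#'
#' @param family A one-row family table.
#' @param n_grid Number of synthetic grid points for bounds-only families
#'   (default 20).
#' @return Sorted numeric vector of class `achievable_doses` with a
#'   `source` attribute naming the family.
#' @export
ctdi_grid <- function(family, n_grid = 20) {
  stopifnot(nrow(family) == 1)
  ma <- family$ma_grid[[1]]
  if (!is.null(ma) && length(ma) > 0 && is.finite(family$dose_coeff)) {
    vals <- sort(ctdi_for_ma(family, ma))
  } else {
    if (family$ctdi_min == family$ctdi_max) n_grid <- 1L
    vals <- seq(family$ctdi_min, family$ctdi_max, length.out = max(1L, n_grid))
  }
  achievable_doses(vals, source = family$name)
}

#' Construct an achievable-dose set
#'
#' @param values Numeric CTDIvol values (mGy); must be non-empty and, after
#'   de-duplication, strictly increasing.
#' @param source Label for provenance (family or profile name).
#' @return Sorted numeric vector with class `achievable_doses`.
#' @export
achievable_doses <- function(values, source = NA_character_) {
  stopifnot(length(values) > 0, all(is.finite(values)))
  values <- sort(unique(as.numeric(values)))
  structure(values, source = source, class = "achievable_doses")
}

#' @export
print.achievable_doses <- function(x, ...) {
  cat(sprintf("<achievable_doses: %d value(s), %.1f-%.1f mGy, source: %s>\n",
              length(x), min(x), max(x), attr(x, "source")))
  invisible(x)
}

#' Clinical constraints used to filter candidate families
#'
#' The restrictions a facility fixes before choosing preset families: the
#' scan field of view and collimation are matched exactly; pitch and
#' rotation time must fall inside the allowed intervals; the XLarge focal
#' spot (higher currents, some resolution cost) is admitted only when
#' `allow_xlarge` is `TRUE`.
#'
#' @param sfov Required scan field of view label.
#' @param collimation_mm Required collimation (mm).
#' @param pitch_max,pitch_min Allowed helical-pitch interval (defaults: no
#'   lower bound, no upper bound).
#' @param rot_min,rot_max Allowed rotation-time interval in seconds
#'   (defaults unbounded).
#' @param allow_xlarge Is the XLarge focal spot acceptable? Default `FALSE`.
#' @return A list of class `profile_constraints`.
#' @export
#' @examples
#' profile_constraints("Large Body", 80, pitch_max = 1.375, allow_xlarge = TRUE)
profile_constraints <- function(sfov, collimation_mm,
                                pitch_max = Inf, pitch_min = 0,
                                rot_min = 0, rot_max = Inf,
                                allow_xlarge = FALSE) {
  stopifnot(pitch_min <= pitch_max, rot_min <= rot_max)
  structure(
    list(sfov = as.character(sfov), collimation_mm = as.numeric(collimation_mm),
         pitch_max = pitch_max, pitch_min = pitch_min,
         rot_min = rot_min, rot_max = rot_max,
         allow_xlarge = isTRUE(allow_xlarge)),
    class = "profile_constraints"
  )
}

#' @export
print.profile_constraints <- function(x, ...) {
  cat(sprintf("<profile_constraints: %s / %g mm, pitch [%g, %g], rot [%g, %g] s, XLarge %s>\n",
              x$sfov, x$collimation_mm, x$pitch_min, x$pitch_max,
              x$rot_min, x$rot_max, if (x$allow_xlarge) "allowed" else "excluded"))
  invisible(x)
}

#' Which families satisfy a constraint set?
#'
#' SFOV and collimation are exact matches; pitch and rotation time are
#' interval checks (inclusive); XLarge-focal families pass only when the
#' constraints allow the XLarge spot.
#'
#' @param families A family table (any number of rows).
#' @param constraints A [profile_constraints()] object.
#' @return Logical vector, one element per row.
#' @export
family_matches <- function(families, constraints) {
  stopifnot(inherits(constraints, "profile_constraints"))
  families$sfov == constraints$sfov &
    families$collimation_mm == constraints$collimation_mm &
    families$pitch >= constraints$pitch_min &
    families$pitch <= constraints$pitch_max &
    families$rotation_time_s >= constraints$rot_min &
    families$rotation_time_s <= constraints$rot_max &
    (families$focal_spot != "XLarge" | constraints$allow_xlarge)
}
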