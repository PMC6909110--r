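# Embedded published preset-family data (Large Body SFOV, 80 mm coverage)
# and reproducible synthetic generators. All doses in mGy at one-decimal
# precision, as printed.

lb80_row <- function(role, focal, rot, pitch, lo, hi) {
  tibble::tibble(role = role,
                 name = sprintf("LB80 %s %.1fs p%.3f", focal, rot, pitch),
                 sfov = "Large Body", focal_spot = focal, collimation_mm = 80,
                 rotation_time_s = rot, pitch = pitch,
                 ctdi_min = lo, ctdi_max = hi,
                 ma_grid = list(NULL), dose_coeff = NA_real_)
}

paper_profile_data <- function() {
  list(
    # clinical liver profile: three Large-focal families, medium primary
    uab_liver = dplyr::bind_rows(
      lb80_row("small",  "Large", 0.5, 1.375, 3.6, 8.6),
      lb80_row("medium", "Large", 0.8, 0.992, 7.3, 18.6),
      lb80_row("large",  "Large", 1.0, 0.508, 17.4, 44.6)
    ),
    # unconstrained pitch and rotation time (abdomen/pelvis, motion not a concern)
    lb80 = dplyr::bind_rows(
      lb80_row("small",  "Large",  0.5, 1.531, 3.1, 7.9),
      lb80_row("medium", "Large",  1.0, 1.375, 6.3, 16.8),
      lb80_row("large",  "Large",  0.8, 0.508, 14.0, 36.8),
      lb80_row("xlarge", "XLarge", 1.0, 0.508, 49.7, 53.7)
    ),
    # pitch capped at 1.375 (helical-artifact concern)
    lb80_pitch_le_1375 = dplyr::bind_rows(
      lb80_row("small",  "Large",  0.5, 1.375, 3.4, 8.8),
      lb80_row("medium", "Large",  0.8, 0.992, 7.1, 18.9),
      lb80_row("large",  "Large",  1.0, 0.508, 17.2, 45.5),
      lb80_row("xlarge", "XLarge", 1.0, 0.508, 49.7, 53.7)
    ),
    # pitch capped at 0.992
    lb80_pitch_le_0992 = dplyr::bind_rows(
      lb80_row("small",  "Large",  0.5, 0.992, 4.7, 12.2),
      lb80_row("medium", "Large",  0.6, 0.508, 10.9, 28.4),
      lb80_row("large",  "Large",  1.0, 0.508, 17.2, 45.5),
      lb80_row("xlarge", "XLarge", 1.0, 0.508, 49.7, 53.7)
    ),
    # fast rotation (<= 0.6 s; chest, motion-limited)
    lb80_rot_le_0.6 = dplyr::bind_rows(
      lb80_row("small",  "Large",  0.5, 1.531, 3.1, 7.9),
      lb80_row("medium", "Large",  0.6, 0.992, 5.6, 14.6),
      lb80_row("large",  "Large",  0.6, 0.508, 10.9, 28.4),
      lb80_row("xlarge", "XLarge", 0.6, 0.508, 31.1, 33.6)
    ),
    # slow rotation (>= 0.8 s; quantitative accuracy prioritised)
    lb80_rot_ge_0.8 = dplyr::bind_rows(
      lb80_row("small",  "Large",  0.8, 1.531, 4.6, 12.2),
      lb80_row("medium", "Large",  1.0, 0.992, 8.8, 23.3),
      lb80_row("large",  "Large",  1.0, 0.508, 17.2, 45.5),
      lb80_row("xlarge", "XLarge", 1.0, 0.508, 49.7, 53.7)
    )
  )
}

#' Published example profiles
#'
#' Profiles transcribed from published Large Body SFOV / 80 mm coverage
#' examples, as bounds-only families (the vendor's per-family current lists
#' are not public). Available names: `"uab_liver"` (the three-family
#' clinical liver profile), `"lb80"` (no pitch/rotation constraint),
#' `"lb80_pitch_le_1375"`, `"lb80_pitch_le_0992"`, `"lb80_rot_le_0.6"`,
#' `"lb80_rot_ge_0.8"`.
#'
#' @param name Profile name (see above), or nothing to list the names.
#' @return A `gsi_profile` (medium family primary), or a character vector
#'   of available names when `name` is missing.
#' @export
#' @examples
#' paper_profile()
#' paper_profile("uab_liver")
paper_profile <- function(name) {
  data <- paper_profile_data()
  if (missing(name)) return(names(data))
  name <- match.arg(name, names(data))
  gsi_profile(name, data[[name]], primary_role = "medium")
}

#' Candidate table of distinct published preset families
#'
#' The de-duplicated set of (rotation time, pitch, focal spot, dose range)
#' preset families appearing across the published Large Body / 80 mm
#' example profiles — 13 distinct families, sorted by ascending minimum
#' CTDIvol. This is the in-package stand-in for a vendor's full preset
#' listing and is sufficient to reproduce the published profile-selection
#' walk-through.
#'
#' @return A family table (13 rows).
#' @export
#' @examples
#' gsi_candidate_table()
gsi_candidate_table <- function() {
  all_rows <- dplyr::bind_rows(paper_profile_data()[-1])  # liver profile uses
  # the same modes at slightly different calibration; the candidate set is
  # defined by the four-family example profiles
  all_rows$role <- NULL
  out <- dplyr::distinct(all_rows,
                         .data$rotation_time_s, .data$pitch, .data$focal_spot,
                         .keep_all = TRUE)
  sort_candidates(as_family_table(out))
}

# deterministic RNG scope that restores the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random preset-family table
#'
#' Reproducible synthetic tables with realistic spreads for testing the
#' profile builder at scale: pitches and rotation times drawn from the
#' scanner's discrete options, mostly Large focal spots, explicit mA grids
#' of 10–40 steps in 5 mA increments, and log-normal dose coefficients
#' centred so typical ranges span a few to a few tens of mGy.
#'
#' @param n_families Number of families (>= 1).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param sfov,collimation_mm SFOV label and collimation for every family.
#' @param pitches,rot_times Discrete option sets sampled from.
#' @param p_xlarge Probability a family uses the XLarge focal spot.
#' @return A validated family table with `ma_grid` and `dose_coeff` set
#'   (and `ctdi_min`/`ctdi_max` filled in from the grid endpoints).
#' @export
#' @examples
#' generate_family_table(5, seed = 1)
generate_family_table <- function(n_families, seed = 1,
                                  sfov = "Large Body", collimation_mm = 80,
                                  pitches = c(0.508, 0.992, 1.375, 1.531),
                                  rot_times = c(0.5, 0.6, 0.8, 1.0),
                                  p_xlarge = 0.2) {
  stopifnot(n_families >= 1)
  with_seed(seed, {
    rows <- purrr::map(seq_len(n_families), function(i) {
      rot <- sample(rot_times, 1)
      pitch <- sample(pitches, 1)
      focal <- if (stats::runif(1) < p_xlarge) "XLarge" else "Large"
      n_ma <- sample(10:40, 1)
      ma_min <- 5 * sample(5:30, 1)
      ma <- seq(ma_min, by = 5, length.out = n_ma)
      k <- stats::rlnorm(1, meanlog = log(0.02), sdlog = 0.35)
      fam <- tibble::tibble(
        name = sprintf("synth%03d %s %.1fs p%.3f", i, focal, rot, pitch),
        sfov = sfov, focal_spot = focal, collimation_mm = collimation_mm,
        rotation_time_s = rot, pitch = pitch,
        ctdi_min = NA_real_, ctdi_max = NA_real_,
        ma_grid = list(ma), dose_coeff = k
      )
      ends <- range(k * ma * rot / pitch)
      fam$ctdi_min <- ends[1]
      fam$ctdi_max <- ends[2]
      fam
    })
    validate_family_table(dplyr::bind_rows(rows))
  })
}

#' Generate a synthetic patient
#'
#' A smooth water-equivalent thickness profile along the scan axis: mean
#' thickness `d_mean`, an optional linear taper of `taper` cm end-to-end
#' (patient size commonly changes by ~5 cm over an abdomen/pelvis scan),
#' and smooth bounded undulation of amplitude `d_sd` (a random-phase
#' low-frequency sinusoid, so |d - trend| never exceeds `d_sd`).
#'
#' @param seed Integer seed.
#' @param length_cm Scan length (cm, default 40).
#' @param d_mean Mean water-equivalent thickness (cm, default 30).
#' @param d_sd Undulation amplitude (cm, default 1).
#' @param taper End-to-end linear thickness change (cm, default 0).
#' @param n Number of axial samples (default 20).
#' @param ... Calibration arguments forwarded to [patient_model()].
#' @return A [patient_model()].
#' @export
#' @examples
#' generate_patient(seed = 1, d_mean = 32, taper = 5)
generate_patient <- function(seed = 1, length_cm = 40, d_mean = 30,
                             d_sd = 1, taper = 0, n = 20, ...) {
  stopifnot(length_cm > 0, d_mean > 0, d_sd >= 0, n >= 2)
  with_seed(seed, {
    z <- seq(0, length_cm, length.out = n)
    u <- z / length_cm
    trend <- d_mean + taper * (u - 0.5)
    wobble <- if (d_sd > 0) {
      freq <- sample(1:3, 1)
      phase <- stats::runif(1, 0, 2 * pi)
      d_sd * sin(2 * pi * freq * u + phase)
    } else 0
    patient_model(z, pmax(trend + wobble, 1), ...)
  })
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` patients with mean thicknesses sampled from a normal
#' distribution (truncated at 10 cm), each realised by
#' [generate_patient()]. Cohort parameters can also be read from a YAML
#' spec via [read_cohort_spec()].
#'
#' @param n Cohort size.
#' @param d_mean,d_sd Population mean and SD of mean thickness (cm).
#' @param taper,within_sd Per-patient taper and undulation amplitude (cm).
#' @param length_cm Scan length (cm).
#' @param seed Integer seed.
#' @param ... Forwarded to [patient_model()] calibration.
#' @return Tibble with `id`, `d_mean`, and a `patient` list-column.
#' @export
generate_cohort <- function(n, d_mean = 30, d_sd = 5, taper = 0,
                            within_sd = 0.5, length_cm = 40, seed = 1, ...) {
  stopifnot(n >= 1)
  with_seed(seed, {
    means <- pmax(stats::rnorm(n, d_mean, d_sd), 10)
    seeds <- sample.int(.Machine$integer.max, n)
    tibble::tibble(
      id = seq_len(n), d_mean = means,
      patient = purrr::map2(means, seeds, function(m, s)
        generate_patient(seed = s, length_cm = length_cm, d_mean = m,
                         d_sd = within_sd, taper = taper, ...))
    )
  })
}

#' Read a cohort specification from YAML
#'
#' Expected keys: `n`, `d_mean`, `d_sd`, `taper`, `within_sd`,
#' `length_cm`, `seed` (missing keys take [generate_cohort()] defaults).
#'
#' @param path YAML file path.
#' @return The cohort tibble from [generate_cohort()].
#' @export
read_cohort_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(spec)[names(spec) == "FALSE"] <- "n"
  allowed <- c("n", "d_mean", "d_sd", "taper", "within_sd", "length_cm", "seed")
  bad <- setdiff(names(spec), allowed)
  if (length(bad) > 0)
    stop("unknown cohort spec keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(generate_cohort, spec)
}
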