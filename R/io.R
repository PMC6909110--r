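# Plain-text serialization: family tables as CSV/JSON, profiles as JSON,
# patients as CSV. Doses are written at one-decimal mGy precision
# (bounds-only tables round-trip bit-exactly); internal arithmetic stays
# full precision.

family_cols <- c("name", "sfov", "focal_spot", "collimation_mm",
                 "rotation_time_s", "pitch", "ctdi_min", "ctdi_max",
                 "ma_grid", "dose_coeff")

serialize_family_df <- function(families) {
  out <- tibble::as_tibble(families)[intersect(c("role", family_cols), names(families))]
  out$ma_grid <- purrr::map_chr(out$ma_grid, function(g)
    if (is.null(g) || length(g) == 0) NA_character_
    else paste(format(g, trim = TRUE, scientific = FALSE), collapse = ";"))
  out
}

deserialize_family_df <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(c("name", "sfov", "focal_spot", "collimation_mm",
                            "rotation_time_s", "pitch"), names(df))
  if (length(missing_cols) > 0)
    stop("family table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if ("ma_grid" %in% names(df) && !is.list(df$ma_grid)) {
    df$ma_grid <- purrr::map(as.character(df$ma_grid), function(s) {
      if (is.na(s) || !nzchar(s)) NULL
      else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  validate_family_table(as_family_table(df))
}

#' Read / write a preset-family table
#'
#' CSV columns: `name,sfov,focal_spot,collimation_mm,rotation_time_s,pitch,`
#' `ctdi_min,ctdi_max[,ma_grid,dose_coeff]`, with `ma_grid` as
#' semicolon-separated currents. The JSON form mirrors the same schema
#' (one object per family, `ma_grid` as an array). The format is chosen by
#' file extension (`.json` vs anything else = CSV).
#'
#' @param path File path.
#' @param families A family table (for writing).
#' @return `read_family_table()` returns a validated family table;
#'   `write_family_table()` returns `path` invisibly.
#' @export
read_family_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- tibble::as_tibble(raw)
    if ("ma_grid" %in% names(df))
      df$ma_grid <- purrr::map(df$ma_grid, function(g)
        if (is.null(g) || all(is.na(g))) NULL else as.numeric(g))
    deserialize_family_df(df)
  } else {
    deserialize_family_df(readr::read_csv(path, show_col_types = FALSE))
  }
}

#' @rdname read_family_table
#' @export
write_family_table <- function(families, path) {
  families <- validate_family_table(families)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- purrr::map(seq_len(nrow(families)), function(i) {
      r <- as.list(tibble::as_tibble(families)[i, setdiff(family_cols, "ma_grid")])
      r <- r[!vapply(r, function(v) is.na(v), logical(1))]
      g <- families$ma_grid[[i]]
      if (!is.null(g) && length(g) > 0) r$ma_grid <- g
      r
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    readr::write_csv(serialize_family_df(families), path)
  }
  invisible(path)
}

#' Read / write a profile as JSON
#'
#' Schema: `{name, primary_role, members: [{role, family: {...}}]}` with
#' members in serialized order (primary first).
#'
#' @param profile A `gsi_profile` (for writing).
#' @param path File path.
#' @return `read_profile()` returns a `gsi_profile`; `write_profile()`
#'   returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "gsi_profile"))
  m <- profile$members
  members <- purrr::map(seq_len(nrow(m)), function(i) {
    fam <- as.list(tibble::as_tibble(m)[i, setdiff(family_cols, "ma_grid")])
    fam <- fam[!vapply(fam, function(v) is.na(v), logical(1))]
    g <- m$ma_grid[[i]]
    if (!is.null(g) && length(g) > 0) fam$ma_grid <- g
    list(role = m$role[i], family = fam)
  })
  jsonlite::write_json(
    list(name = profile$name, primary_role = profile$primary_role,
         members = members),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  members <- purrr::map_dfr(raw$members, function(mm) {
    fam <- mm$family
    tibble::tibble(
      role = mm$role, name = fam$name, sfov = fam$sfov,
      focal_spot = fam$focal_spot,
      collimation_mm = as.numeric(fam$collimation_mm),
      rotation_time_s = as.numeric(fam$rotation_time_s),
      pitch = as.numeric(fam$pitch),
      ctdi_min = as.numeric(fam$ctdi_min %||% NA),
      ctdi_max = as.numeric(fam$ctdi_max %||% NA),
      ma_grid = list(if (is.null(fam$ma_grid)) NULL else as.numeric(unlist(fam$ma_grid))),
      dose_coeff = as.numeric(fam$dose_coeff %||% NA)
    )
  })
  gsi_profile(raw$name, members, primary_role = raw$primary_role)
}

#' Read / write a patient thickness profile as CSV
#'
#' Columns `z_cm,d_cm`; the calibration (`d_ref`, `d_double`, `ctdi_ref`,
#' `ni_ref`) is not stored in the CSV and is supplied on read.
#'
#' @param path File path.
#' @param patient A [patient_model()] (for writing).
#' @param ... Calibration arguments for [patient_model()] on read.
#' @return `read_patient()` returns a [patient_model()]; `write_patient()`
#'   returns `path` invisibly.
#' @export
read_patient <- function(path, ...) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("z_cm", "d_cm") %in% names(df)))
  patient_model(df$z_cm, df$d_cm, ...)
}

#' @rdname read_patient
#' @export
write_patient <- function(patient, path) {
  readr::write_csv(tibble::tibble(z_cm = patient$z_cm, d_cm = patient$d_cm), path)
  invisible(path)
}

#' Write a coverage report as CSV
#'
#' One row per target: `target,nearest,f,covered`.
#'
#' @param report A `dose_match_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(report, path) {
  stopifnot(inherits(report, "dose_match_report"))
  readr::write_csv(report$targets, path)
  invisible(path)
}
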