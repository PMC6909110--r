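#' Canonical ordering of candidate families
#'
#' Vendor preset listings order families by increasing minimum CTDIvol; the
#' greedy selection procedure reads "first" and "last" against this order.
#' The sort is stable: ties on `ctdi_min` break by ascending `ctdi_max`,
#' then by input order.
#'
#' @param families A family table.
#' @return The same tibble, reordered.
#' @export
sort_candidates <- function(families) {
  families <- as_family_table(families)
  families[order(families$ctdi_min, families$ctdi_max), , drop = FALSE]
}

role_levels <- c("small", "medium", "large", "xlarge")

#' Build a profile by greedy dose-range covering
#'
#' Selects up to four preset families whose CTDIvol ranges chain together
#' with overlap but as little redundancy as possible, on the
#' constraint-filtered candidate list in canonical order (ascending
#' `ctdi_min`):
#'
#' * **small** — the first candidate;
#' * **medium** — the *last* Large-focal-spot candidate whose `ctdi_min` is
#'   strictly below the small family's `ctdi_max`;
#' * **large** — the *last* Large-focal-spot candidate whose `ctdi_min` is
#'   strictly below the medium family's `ctdi_max`;
#' * **xlarge** — the candidate (any permitted focal spot) with the highest
#'   `ctdi_max`; ties break toward lower `ctdi_min`, then canonical order.
#'
#' When a search returns the family already holding an earlier role the
#' later role is dropped, so degenerate tables yield profiles with fewer
#' members. The medium family is the primary by default — it is used at
#' scan time unless the operator overrides — but a facility imaging mostly
#' bariatric (or paediatric) patients may designate large (or small)
#' instead via `primary_role`.
#'
#' @param families Candidate family table (any order; sorting is canonical).
#' @param constraints A [profile_constraints()] object.
#' @param name Profile name.
#' @param primary_role Which role is primary; collapsed onto the surviving
#'   role of the same family when that role was dropped.
#' @return A `gsi_profile` object: `name`, `primary_role`, and a `members`
#'   tibble (one row per role, primary first in serialized order).
#' @export
#' @examples
#' fams <- gsi_candidate_table()
#' cons <- profile_constraints("Large Body", 80, pitch_max = 1.375,
#'                             allow_xlarge = TRUE)
#' build_profile(fams, cons, name = "abdomen")
build_profile <- function(families, constraints, name = "profile",
                          primary_role = "medium") {
  primary_role <- match.arg(primary_role, role_levels)
  families <- validate_family_table(families)
  cand <- sort_candidates(families)
  keep <- family_matches(cand, constraints)
  if (!any(keep)) {
    stop("no preset family matches the constraints (sfov=", constraints$sfov,
         ", collimation=", constraints$collimation_mm,
         " mm, pitch in [", constraints$pitch_min, ", ", constraints$pitch_max,
         "], rotation time in [", constraints$rot_min, ", ", constraints$rot_max,
         "] s, XLarge ", if (constraints$allow_xlarge) "allowed" else "excluded", ")",
         call. = FALSE)
  }
  cand <- cand[keep, , drop = FALSE]
  large_focal <- cand$focal_spot == "Large"

  pick_last <- function(ok) if (any(ok)) max(which(ok)) else NA_integer_

  i_small <- 1L
  i_medium <- pick_last(large_focal & cand$ctdi_min < cand$ctdi_max[i_small])
  if (is.na(i_medium)) i_medium <- i_small
  i_large <- pick_last(large_focal & cand$ctdi_min < cand$ctdi_max[i_medium])
  if (is.na(i_large)) i_large <- i_medium
  ord <- order(-cand$ctdi_max, cand$ctdi_min)
  i_xlarge <- ord[1L]

  idx <- c(small = i_small, medium = i_medium, large = i_large, xlarge = i_xlarge)
  # collapse later roles that landed on an already-used family
  keep_role <- !duplicated(idx)
  roles <- names(idx)[keep_role]
  members <- cand[idx[keep_role], , drop = FALSE]
  members <- tibble::add_column(members, role = roles, .before = 1)

  if (!primary_role %in% roles) {
    primary_role <- members$role[match(idx[[primary_role]], idx[keep_role])]
  }
  new_gsi_profile(name, primary_role, members)
}

new_gsi_profile <- function(name, primary_role, members) {
  stopifnot(primary_role %in% members$role, !anyDuplicated(members$role),
            nrow(members) >= 1, nrow(members) <= 4)
  # serialized order: primary first, remaining roles by ascending ctdi_min
  rest <- members[members$role != primary_role, , drop = FALSE]
  rest <- rest[order(rest$ctdi_min), , drop = FALSE]
  members <- dplyr::bind_rows(members[members$role == primary_role, ], rest)
  structure(list(name = name, primary_role = primary_role,
                 members = as_family_table(members)),
            class = "gsi_profile")
}

#' Assemble a profile from an explicit role/family table
#'
#' Lower-level companion to [build_profile()] for profiles whose members are
#' already known (e.g. transcribed from a scanner or publication).
#'
#' @param name Profile name.
#' @param members Family table with a `role` column
#'   (small/medium/large/xlarge, unique).
#' @param primary_role The primary role (default `"medium"`, falling back to
#'   the first listed role when absent).
#' @return A `gsi_profile` object.
#' @export
gsi_profile <- function(name, members, primary_role = NULL) {
  members <- validate_family_table(members)
  stopifnot("role" %in% names(members), all(members$role %in% role_levels))
  if (is.null(primary_role))
    primary_role <- if ("medium" %in% members$role) "medium" else members$role[1]
  new_gsi_profile(name, primary_role, members)
}

#' @export
print.gsi_profile <- function(x, ...) {
  cat(sprintf("<gsi_profile '%s': %d member(s), primary = %s>\n",
              x$name, nrow(x$members), x$primary_role))
  m <- x$members
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-6s %s  %.1f-%.1f mGy  (%s, %g s, pitch %g%s)\n",
                m$role[i], m$focal_spot[i], m$ctdi_min[i], m$ctdi_max[i],
                m$sfov[i], m$rotation_time_s[i], m$pitch[i],
                if (m$role[i] == x$primary_role) ", primary" else ""))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a profile into its member table
#'
#' @param x A `gsi_profile`.
#' @param ... Unused.
#' @return Tibble with one row per member family (primary first) and a
#'   logical `primary` column.
#' @export
tidy.gsi_profile <- function(x, ...) {
  out <- tibble::as_tibble(x$members)
  out$primary <- out$role == x$primary_role
  out
}

#' One-row profile summary
#'
#' @param x A `gsi_profile`.
#' @param ... Unused.
#' @return Tibble with the member count, primary role, and the extremes of
#'   the union achievable-dose range.
#' @export
glance.gsi_profile <- function(x, ...) {
  tibble::tibble(name = x$name, n_members = nrow(x$members),
                 primary_role = x$primary_role,
                 union_min = min(x$members$ctdi_min),
                 union_max = max(x$members$ctdi_max))
}

#' Diagnose gaps and overlap in a profile's dose ladder
#'
#' The design goal is member ranges that overlap, but only just. For every
#' consecutive pair of members (ascending `ctdi_min`) a `gap` diagnostic is
#' emitted when the next range starts above the previous one's maximum; the
#' overlap fraction (overlap length / union length) summarises redundancy.
#'
#' @param profile A `gsi_profile`.
#' @return Tibble of diagnostics, one row per consecutive pair: roles,
#'   boundary values, `gap` flag and the signed overlap (negative = gap),
#'   with the total overlap fraction in attribute `overlap_fraction`.
#' @export
validate_profile <- function(profile) {
  m <- profile$members[order(profile$members$ctdi_min), , drop = FALSE]
  n <- nrow(m)
  if (n < 2) {
    out <- tibble::tibble(lower_role = character(), upper_role = character(),
                          lower_max = numeric(), upper_min = numeric(),
                          overlap_mgy = numeric(), gap = logical())
    attr(out, "overlap_fraction") <- 0
    return(out)
  }
  i <- seq_len(n - 1)
  out <- tibble::tibble(
    lower_role = m$role[i], upper_role = m$role[i + 1],
    lower_max = m$ctdi_max[i], upper_min = m$ctdi_min[i + 1],
    overlap_mgy = m$ctdi_max[i] - m$ctdi_min[i + 1]
  )
  out$gap <- out$overlap_mgy < 0
  total_overlap <- sum(pmax(out$overlap_mgy, 0))
  union_len <- max(m$ctdi_max) - min(m$ctdi_min)
  attr(out, "overlap_fraction") <- if (union_len > 0) total_overlap / union_len else 0
  out
}
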