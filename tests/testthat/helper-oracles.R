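# Independent oracles, deliberately written as literal re-reads of the
# procedures (loops and explicit comparisons, no shared code with R/).

# linear scan for the closest grid value; strict < keeps the earlier
# (lower) value on exact midpoints
scan_nearest <- function(grid, target) {
  best <- grid[1]
  for (v in grid) {
    if (abs(v - target) < abs(best - target)) best <- v
  }
  best
}

# stable selection sort by (ctdi_min, ctdi_max)
oracle_sort <- function(families) {
  df <- tibble::as_tibble(families)
  n <- nrow(df)
  taken <- rep(FALSE, n)
  out_idx <- integer(0)
  for (k in seq_len(n)) {
    best <- NA_integer_
    for (i in seq_len(n)) {
      if (taken[i]) next
      if (is.na(best)) { best <- i; next }
      if (df$ctdi_min[i] < df$ctdi_min[best] ||
          (df$ctdi_min[i] == df$ctdi_min[best] &&
           df$ctdi_max[i] < df$ctdi_max[best])) best <- i
    }
    taken[best] <- TRUE
    out_idx <- c(out_idx, best)
  }
  df[out_idx, , drop = FALSE]
}

oracle_matches <- function(row, cons) {
  if (row$sfov != cons$sfov) return(FALSE)
  if (row$collimation_mm != cons$collimation_mm) return(FALSE)
  if (row$pitch > cons$pitch_max) return(FALSE)
  if (row$pitch < cons$pitch_min) return(FALSE)
  if (row$rotation_time_s < cons$rot_min) return(FALSE)
  if (row$rotation_time_s > cons$rot_max) return(FALSE)
  if (row$focal_spot == "XLarge" && !cons$allow_xlarge) return(FALSE)
  TRUE
}

# literal step-by-step greedy selection; returns role -> candidate-row index
# after collapsing duplicate assignments
oracle_build_roles <- function(families, cons) {
  sorted <- oracle_sort(families)
  keep <- vapply(seq_len(nrow(sorted)),
                 function(i) oracle_matches(sorted[i, ], cons), logical(1))
  cand <- sorted[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)

  i_small <- 1L

  i_medium <- NA_integer_
  for (i in seq_len(nrow(cand))) {
    if (cand$focal_spot[i] == "Large" &&
        cand$ctdi_min[i] < cand$ctdi_max[i_small]) i_medium <- i
  }
  if (is.na(i_medium)) i_medium <- i_small

  i_large <- NA_integer_
  for (i in seq_len(nrow(cand))) {
    if (cand$focal_spot[i] == "Large" &&
        cand$ctdi_min[i] < cand$ctdi_max[i_medium]) i_large <- i
  }
  if (is.na(i_large)) i_large <- i_medium

  i_xlarge <- 1L
  for (i in seq_len(nrow(cand))) {
    better <- cand$ctdi_max[i] > cand$ctdi_max[i_xlarge] ||
      (cand$ctdi_max[i] == cand$ctdi_max[i_xlarge] &&
       cand$ctdi_min[i] < cand$ctdi_min[i_xlarge])
    if (better) i_xlarge <- i
  }

  idx <- c(small = i_small, medium = i_medium, large = i_large,
           xlarge = i_xlarge)
  roles <- character(0); names_out <- character(0)
  seen <- integer(0)
  for (r in names(idx)) {
    if (!idx[[r]] %in% seen) {
      roles <- c(roles, r)
      names_out <- c(names_out, cand$name[idx[[r]]])
      seen <- c(seen, idx[[r]])
    }
  }
  stats::setNames(names_out, roles)
}

# role -> family-name map from a built profile, in role order
profile_roles <- function(profile) {
  m <- profile$members
  stats::setNames(m$name, m$role)[order(match(m$role, c("small", "medium", "large", "xlarge")))]
}

random_constraints <- function() {
  profile_constraints(
    "Large Body", 80,
    pitch_max = sample(c(0.992, 1.375, 1.531, Inf), 1),
    rot_min = sample(c(0, 0.6, 0.8), 1),
    rot_max = sample(c(1.0, Inf), 1),
    allow_xlarge = sample(c(TRUE, FALSE), 1)
  )
}

constant_patient <- function(d, n = 20, ...) {
  patient_model(seq(0, 40, length.out = n), rep(d, n), ...)
}
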