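test_that("sort_candidates uses the canonical stable (ctdi_min, ctdi_max) order", {
  mk <- function(name, lo, hi)
    preset_family(name, "Large Body", "Large", 80, 0.5, 1.0,
                  ctdi_min = lo, ctdi_max = hi)
  tab <- dplyr::bind_rows(mk("a", 7.1, 18.9), mk("b", 3.4, 8.8), mk("c", 17.2, 45.5))
  expect_equal(sort_candidates(tab)$ctdi_min, c(3.4, 7.1, 17.2))

  # equal keys keep input order (stable)
  ties <- dplyr::bind_rows(mk("first", 5, 10), mk("second", 5, 10))
  expect_equal(sort_candidates(ties)$name, c("first", "second"))

  # random tables match an independently coded selection sort
  set.seed(42)
  for (rep in 1:5) {
    tab <- generate_family_table(50, seed = 1000 + rep)
    expect_equal(sort_candidates(tab)$name, oracle_sort(tab)$name)
  }
})

test_that("build_profile reproduces the published worked example", {
  cons <- profile_constraints("Large Body", 80, pitch_max = 1.375,
                              allow_xlarge = TRUE)
  prof <- build_profile(gsi_candidate_table(), cons, name = "abdomen")
  m <- prof$members[order(match(prof$members$role, c("small", "medium", "large", "xlarge"))), ]
  expect_equal(m$role, c("small", "medium", "large", "xlarge"))
  expect_equal(m$ctdi_min, c(3.4, 7.1, 17.2, 49.7))
  expect_equal(m$ctdi_max, c(8.8, 18.9, 45.5, 53.7))
  expect_equal(prof$primary_role, "medium")
  # serialized order lists the primary first
  expect_equal(prof$members$role[1], "medium")
})

test_that("build_profile handles degenerate and erroring inputs", {
  solo <- preset_family("only", "Large Body", "Large", 80, 0.5, 1.0,
                        ctdi_min = 3, ctdi_max = 9)
  prof <- build_profile(solo, profile_constraints("Large Body", 80))
  expect_equal(nrow(prof$members), 1)
  expect_equal(prof$members$name, "only")

  expect_error(
    build_profile(solo, profile_constraints("Head", 40)),
    "no preset family matches")

  # large collapses onto medium, xlarge onto large, when searches coincide
  two <- dplyr::bind_rows(
    solo,
    preset_family("upper", "Large Body", "Large", 80, 1.0, 0.5,
                  ctdi_min = 8, ctdi_max = 20))
  prof2 <- build_profile(two, profile_constraints("Large Body", 80))
  expect_setequal(prof2$members$role, c("small", "medium"))
  expect_equal(prof2$primary_role, "medium")
})

test_that("primary remaps to the surviving role when its role collapsed", {
  solo <- preset_family("only", "Large Body", "Large", 80, 0.5, 1.0,
                        ctdi_min = 3, ctdi_max = 9)
  prof <- build_profile(solo, profile_constraints("Large Body", 80),
                        primary_role = "medium")
  expect_equal(prof$primary_role, "small")
})

test_that("build_profile agrees with the literal step-by-step oracle on random tables", {
  set.seed(7)
  n_checked <- 0
  for (rep in 1:60) {
    tab <- generate_family_table(sample(3:30, 1), seed = 5000 + rep)
    cons <- random_constraints()
    expected <- oracle_build_roles(tab, cons)
    if (is.null(expected)) {
      expect_error(build_profile(tab, cons), "no preset family matches")
    } else {
      got <- profile_roles(build_profile(tab, cons))
      expect_identical(got, expected)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("build_profile output is invariant under input permutation", {
  set.seed(99)
  tab <- generate_family_table(20, seed = 321)
  cons <- profile_constraints("Large Body", 80, allow_xlarge = TRUE)
  ref <- profile_roles(build_profile(tab, cons))
  for (rep in 1:5) {
    shuffled <- tab[sample(nrow(tab)), ]
    expect_identical(profile_roles(build_profile(shuffled, cons)), ref)
  }
})

test_that("selected roles chain with strict overlap when searches found distinct families", {
  set.seed(17)
  for (rep in 1:40) {
    tab <- generate_family_table(sample(5:30, 1), seed = 9000 + rep)
    cons <- random_constraints()
    prof <- tryCatch(build_profile(tab, cons), error = function(e) NULL)
    if (is.null(prof)) next
    m <- prof$members
    get <- function(role) m[m$role == role, ]
    if (all(c("small", "medium") %in% m$role))
      expect_lt(get("medium")$ctdi_min, get("small")$ctdi_max)
    if (all(c("medium", "large") %in% m$role))
      expect_lt(get("large")$ctdi_min, get("medium")$ctdi_max)
  }
})

test_that("tightening the pitch cap never lowers the small family's range floor", {
  set.seed(31)
  for (rep in 1:20) {
    tab <- generate_family_table(25, seed = 7000 + rep)
    loose <- profile_constraints("Large Body", 80, pitch_max = 1.531,
                                 allow_xlarge = TRUE)
    tight <- profile_constraints("Large Body", 80, pitch_max = 0.992,
                                 allow_xlarge = TRUE)
    p_loose <- tryCatch(build_profile(tab, loose), error = function(e) NULL)
    p_tight <- tryCatch(build_profile(tab, tight), error = function(e) NULL)
    if (is.null(p_loose) || is.null(p_tight)) next
    small_min <- function(p) p$members$ctdi_min[p$members$role == "small"]
    expect_gte(small_min(p_tight), small_min(p_loose))
  }
})

test_that("validate_profile flags gaps between consecutive role ranges", {
  prof <- paper_profile("lb80_pitch_le_1375")
  diag <- validate_profile(prof)
  # the published four-family abdomen profile has exactly one gap: the
  # extra-large family starts at 49.7 mGy, above the large family's 45.5
  expect_equal(sum(diag$gap), 1)
  expect_equal(diag$lower_role[diag$gap], "large")
  expect_equal(diag$upper_role[diag$gap], "xlarge")

  disjoint <- gsi_profile("d", dplyr::bind_rows(
    preset_family("a", "Large Body", "Large", 80, 0.5, 1,
                  ctdi_min = 1, ctdi_max = 2) |> tibble::add_column(role = "small"),
    preset_family("b", "Large Body", "Large", 80, 1, 0.5,
                  ctdi_min = 10, ctdi_max = 20) |> tibble::add_column(role = "medium")))
  expect_equal(sum(validate_profile(disjoint)$gap), 1)

  # overlapping three-family liver profile: no gaps
  expect_equal(sum(validate_profile(paper_profile("uab_liver"))$gap), 0)
})
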