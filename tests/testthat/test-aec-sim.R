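test_that("required_ctdi follows the thickness and noise scaling laws", {
  pat <- constant_patient(30)  # defaults: d_ref 30, d_double 5, ctdi_ref 15, ni_ref 18
  expect_equal(required_ctdi(30, pat, 18), 15)         # calibration point
  expect_equal(required_ctdi(35, pat, 18), 30)         # +5 cm doubles dose
  expect_equal(required_ctdi(25, pat, 18), 7.5)
  expect_equal(required_ctdi(30, pat, 9), 60)          # halving NI quadruples dose
  expect_error(required_ctdi(-1, pat, 18), "must be > 0")
  expect_error(required_ctdi(30, pat, 0), "must be > 0")
})

test_that("target_ctdi aggregates per-slice requirements", {
  flat <- constant_patient(32)
  expect_equal(target_ctdi(flat, 18), required_ctdi(32, flat, 18))

  # two-slab patient: half at reference, half 5 cm thicker -> 1.5x reference
  slab <- patient_model(z = 1:10, d = c(rep(30, 5), rep(35, 5)))
  expect_equal(target_ctdi(slab, 18), 1.5 * 15)
  expect_equal(target_ctdi(slab, 18, aggregate = "max"), 30)

  taper <- patient_model(z = 1:10, d = seq(28, 36, length.out = 10))
  t <- target_ctdi(taper, 18)
  expect_gt(t, required_ctdi(28, taper, 18))
  expect_lt(t, required_ctdi(36, taper, 18))
})

test_that("choose_current clamps to the family range and matches a scan oracle", {
  fam <- preset_family("f", "Large Body", "Large", 80, 0.8, 0.992,
                       ctdi_min = 7.1, ctdi_max = 18.9)
  expect_equal(choose_current(fam, 2)$actual_ctdi, 7.1)
  expect_equal(choose_current(fam, 100)$actual_ctdi, 18.9)

  set.seed(12)
  for (i in 1:50) {
    f <- generate_family_table(1, seed = 300 + i)
    target <- stats::runif(1, 0.2, 80)
    sel <- choose_current(f, target)
    grid <- as.numeric(ctdi_grid(f))
    expect_equal(sel$actual_ctdi, scan_nearest(grid, target))
    # the reported current generates the reported dose
    expect_equal(ctdi_for_ma(f, sel$ma), sel$actual_ctdi)
  }
})

test_that("projected_ni is self-consistent and follows the inverse-square law", {
  pat <- constant_patient(33)
  ni <- 18
  req <- required_ctdi(33, pat, ni)
  self <- projected_ni(pat, req, ni)
  expect_equal(self$avg_pni, ni)
  expect_equal(self$pni_profile$pni_hu, rep(ni, nrow(pat)))
  expect_false(any(self$above_mask))

  quad <- projected_ni(pat, 4 * req, ni)
  expect_equal(quad$pni_profile$pni_hu, rep(ni / 2, nrow(pat)))

  under <- projected_ni(pat, 0.5 * req, ni)
  expect_true(all(under$above_mask))  # every slice flagged noisy
})

test_that("the switching rule is strict at the 2 HU boundaries", {
  expect_equal(technologist_rule(18, 18), "keep_primary")
  expect_equal(technologist_rule(21, 18), "switch_large")
  expect_equal(technologist_rule(15, 18), "switch_small")
  expect_equal(technologist_rule(16, 18), "keep_primary")  # exactly 2 below
  expect_equal(technologist_rule(20, 18), "keep_primary")  # exactly 2 above
  expect_equal(technologist_rule(20.9, 18, threshold = 3), "keep_primary")
})

test_that("simulate_exam ties the pipeline together", {
  prof <- paper_profile("uab_liver")
  ni <- 18

  # patient whose requirement sits mid-range of the primary family: keep
  pat_mid <- constant_patient(30)  # requires 15 mGy, inside 7.3-18.6
  res <- simulate_exam(prof, pat_mid, ni)
  expect_equal(res$recommendation, "keep_primary")
  expect_equal(res$selected_role, "medium")
  expect_equal(nrow(res$per_family), 3)
  expect_equal(res$per_family$role[1], "medium")  # primary listed first

  # avg_pni equals the mean of the stored per-slice profile
  for (i in seq_len(nrow(res$per_family)))
    expect_equal(res$per_family$avg_pni[i],
                 mean(res$per_family$pni_profile[[i]]$pni_hu))
  # flags agree with the prescribed NI
  expect_equal(res$per_family$flag,
               ifelse(res$per_family$avg_pni > ni, "above", "at_or_below"))
  # delivered doses stay within each family's achievable range
  j <- match(res$per_family$role, prof$members$role)
  expect_true(all(res$per_family$actual_ctdi >= prof$members$ctdi_min[j]))
  expect_true(all(res$per_family$actual_ctdi <= prof$members$ctdi_max[j]))

  # very large patient: target far above the primary ceiling -> switch_large
  pat_big <- constant_patient(41)  # requires ~68.6 mGy
  expect_gt(target_ctdi(pat_big, ni), 1.5 * 18.6)
  res_big <- simulate_exam(prof, pat_big, ni)
  expect_gt(res_big$avg_pni_primary, ni)
  expect_equal(res_big$recommendation, "switch_large")
  expect_equal(res_big$selected_role, "large")

  # small patient gets excess dose when the floor exceeds the requirement
  pat_small <- constant_patient(18)
  res_small <- simulate_exam(prof, pat_small, ni)
  floor_small <- min(prof$members$ctdi_min)
  sel <- tidy(res_small)
  expect_gt(sel$actual_ctdi[sel$selected],
            target_ctdi(pat_small, ni))
})

test_that("constant patients satisfy the closed-form AvgPNI identity exactly", {
  prof <- paper_profile("uab_liver")
  ni <- 18
  for (d in seq(18, 42, by = 2)) {
    res <- simulate_exam(prof, constant_patient(d), ni)
    tgt <- res$target_ctdi
    for (i in seq_len(nrow(res$per_family))) {
      closed <- ni * sqrt(tgt / res$per_family$actual_ctdi[i])
      expect_equal(res$per_family$avg_pni[i], closed, tolerance = 1e-12)
    }
  }
})

test_that("recommendations are monotone in patient size for a fixed profile", {
  prof <- paper_profile("uab_liver")
  rank <- c(switch_small = -1, keep_primary = 0, switch_large = 1)
  sizes <- seq(16, 46, by = 1)
  recs <- vapply(sizes, function(d)
    rank[[simulate_exam(prof, constant_patient(d), 18)$recommendation]],
    numeric(1))
  expect_true(all(diff(recs) >= 0))
  expect_equal(min(recs), -1)  # thin patients do trigger the small preset
  expect_equal(max(recs), 1)
})
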