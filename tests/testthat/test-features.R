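sched <- build_protocol()

trapezoid_series <- function(dt = 0.1) {
  t <- seq(0, 80, by = dt)
  y <- ifelse(t <= 10, t, ifelse(t <= 70, 10, pmax(10 - (t - 70), 0)))
  toy_series(t, y)
}

win <- list(trial = 1, pressure_mmHg = 60, onset_s = 0, hold_start_s = 0,
            deflation_s = 70, end_s = 80)

test_that("plateau time of an analytic trapezoid is exact", {
  tf <- extract_trial_features(trapezoid_series(), win, smooth_width = 1)
  expect_equal(tf$hbt_max_uM, 10)
  expect_equal(tf$t_rise_s, 9, tolerance = 1e-9)
  expect_equal(tf$pt_s, 62, tolerance = 1e-9)
  expect_false(tf$censored)
  expect_true(tf$saturation)
})

test_that("plateau time of an analytic triangle is exact", {
  t <- seq(0, 20, by = 0.1)
  y <- ifelse(t <= 10, t, 20 - t)
  w <- list(trial = 1, pressure_mmHg = 60, onset_s = 0, hold_start_s = 0,
            deflation_s = 10, end_s = 20)
  tf <- extract_trial_features(toy_series(t, y), w, smooth_width = 1)
  expect_equal(tf$pt_s, 2, tolerance = 1e-9)
  expect_false(tf$saturation) # only 2 s within 10% of the peak
})

test_that("a noisy simulated curve recovers its generator plateau time", {
  fr <- 2.56 # four-patch acquisition rate
  ser <- simulate_hbt_curve(curve_params(target_pt_s = 30), sched, fr)
  rec <- forward_optics(ser, sched, noise_sd = 0.01, seed = 11)
  rcv <- reconstruct_recording(rec)
  tf <- extract_patch_features(rcv, sched)
  expect_true(all(abs(tf$pt_s - 30) <= 2 / fr))
})

test_that("plateau time is invariant under positive affine rescaling", {
  ser <- trapezoid_series()
  base <- extract_trial_features(ser, win, smooth_width = 1)$pt_s
  for (ab in list(c(3, 0), c(0.5, 7), c(10, -20))) {
    scaled <- toy_series(ser$time_s, ab[1] * ser$dHbT_uM + ab[2])
    expect_equal(extract_trial_features(scaled, win, smooth_width = 1)$pt_s,
                 base, tolerance = 1e-9)
  }
})

test_that("plateau time is stable under resampling to a finer grid", {
  coarse_fr <- 2.56
  for (pt in c(20, 45)) {
    p <- curve_params(target_pt_s = pt)
    pt_coarse <- extract_patch_features(
      simulate_hbt_curve(p, sched, coarse_fr), sched)$pt_s
    pt_fine <- extract_patch_features(
      simulate_hbt_curve(p, sched, 10.24), sched)$pt_s
    expect_true(all(abs(pt_coarse - pt_fine) <= 2 / coarse_fr))
  }
})

test_that("right-censoring clamps the trailing crossing to the window end", {
  # curve still above threshold at the end of the window
  t <- seq(0, 80, by = 0.1)
  y <- pmin(t, 10)
  tf <- extract_trial_features(toy_series(t, y), win, smooth_width = 1)
  expect_true(tf$censored)
  expect_equal(tf$pt_s, 80 - 9, tolerance = 1e-6)
})

test_that("windows with too few frames are rejected", {
  t <- seq(0, 80, by = 20)
  expect_error(extract_trial_features(toy_series(t, t), win),
               class = "dvospt_data_error")
})

test_that("patch plateau time averages the two trials with declared fallbacks", {
  tf <- tibble::tibble(pt_s = c(60, 64), defined = c(TRUE, TRUE))
  expect_equal(patch_pt(tf), 62)
  tf1 <- tibble::tibble(pt_s = c(62, NA), defined = c(TRUE, FALSE))
  expect_warning(v <- patch_pt(tf1), "only one trial")
  expect_equal(v, 62)
  tf0 <- tibble::tibble(pt_s = c(NA_real_, NA_real_), defined = c(FALSE, FALSE))
  expect_true(is.na(patch_pt(tf0)))
  tfe <- tibble::tibble(pt_s = c(55, 55), defined = c(TRUE, TRUE))
  expect_equal(patch_pt(tfe), 55)
})

test_that("Gen and Loc aggregation follow the arterial-tree rules", {
  tree <- angiosome_tree()
  # patch on the ulcer angiosome wins
  a <- gen_loc_aggregate(
    tibble::tibble(angiosome = c("posterior_tibial", "dorsalis_pedis"),
                   pt_s = c(40, 60)),
    "dorsalis_pedis", tree)
  expect_equal(a$gen_pt_s, 50)
  expect_equal(a$loc_pt_s, 60)
  expect_equal(a$loc_rule, "on_ulcer_angiosome")
  # else the mean of the patches below the affected artery
  b <- gen_loc_aggregate(
    tibble::tibble(angiosome = c("medial_plantar", "lateral_plantar"),
                   pt_s = c(30, 50)),
    "posterior_tibial", tree)
  expect_equal(b$loc_pt_s, 40)
  expect_equal(b$loc_rule, "below_affected_artery")
  # else the patch directly above it
  c3 <- gen_loc_aggregate(
    tibble::tibble(angiosome = "anterior_tibial", pt_s = 45),
    "dorsalis_pedis", tree)
  expect_equal(c3$loc_pt_s, 45)
  expect_equal(c3$loc_rule, "above_affected_artery")
  # nothing applicable: explicit missing
  d <- gen_loc_aggregate(
    tibble::tibble(angiosome = "peroneal", pt_s = 33),
    "dorsalis_pedis", tree)
  expect_true(is.na(d$loc_pt_s))
  expect_equal(d$gen_pt_s, 33)

  expect_error(gen_loc_aggregate(tibble::tibble(angiosome = "peroneal", pt_s = 1),
                                 "popliteal", tree),
               class = "dvospt_config_error")
})

test_that("Gen aggregation is permutation-invariant and skips missing patches", {
  pts <- tibble::tibble(
    angiosome = c("peroneal", "dorsalis_pedis", "medial_plantar"),
    pt_s = c(10, 20, NA))
  g1 <- gen_loc_aggregate(pts, "peroneal")$gen_pt_s
  g2 <- gen_loc_aggregate(pts[c(3, 1, 2), ], "peroneal")$gen_pt_s
  expect_equal(g1, 15)
  expect_equal(g1, g2)
})

test_that("difference features subtract later minus earlier and compose", {
  tbl <- tibble::tibble(time_point = c("pre", "post", "fu1"),
                        gen_pt_s = c(10, 55, 61), loc_pt_s = c(10, 55, 61))
  d <- difference_features(tbl)
  expect_equal(d$postpre_gen, 45)
  expect_equal(d$fu1pre_gen, 51)
  expect_equal(d$fu1post_gen, 6)
  expect_equal(d$fu1post_gen, d$fu1pre_gen - d$postpre_gen)

  flat <- tibble::tibble(time_point = c("pre", "post", "fu1"),
                         gen_pt_s = c(30, 30, 30), loc_pt_s = c(30, 30, 30))
  expect_true(all(unlist(difference_features(flat)) == 0))

  partial <- tibble::tibble(time_point = c("pre", "post"),
                            gen_pt_s = c(10, 20), loc_pt_s = c(10, 20))
  dp <- difference_features(partial)
  expect_equal(dp$postpre_gen, 10)
  expect_true(is.na(dp$fu1post_gen) && is.na(dp$fu1pre_gen))
})

test_that("a synthetic patient realizes its drawn feature difference", {
  spec <- cohort_spec(n_positive = 1, n_negative = 1, noise_sd = 0,
                      patch_counts = 2, seed = 31)
  coh <- generate_cohort(spec)
  feats <- patient_features(coh)
  drawn <- tapply(coh$targets$target_pt_s,
                  list(coh$targets$patient_id, coh$targets$time_point), mean)
  for (pid in rownames(drawn)) {
    expected <- drawn[pid, "fu1"] - drawn[pid, "post"]
    realized <- feats$fu1post_gen[feats$patient_id == pid]
    expect_true(abs(realized - expected) <= 1 / 5.12,
                label = sprintf("%s realized FU1-post difference within one frame", pid))
  }
})
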