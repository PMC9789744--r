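test_that("the frame rate is fixed by the number of patches", {
  expect_equal(patch_frame_rate(1:4), c(10.24, 5.12, 3.41, 2.56))
  for (k in c(1L, 3L)) {
    coh <- generate_cohort(cohort_spec(n_positive = 1, n_negative = 1,
                                       patch_counts = k, seed = 2),
                           recordings = FALSE)
    expect_true(all(coh$patients$frame_rate == patch_frame_rate(k)))
    expect_true(all(coh$patients$n_patches == k))
  }
  expect_error(patch_frame_rate(5), class = "dvospt_config_error")
})

test_that("the same seed reproduces a bit-identical cohort and serialization", {
  spec <- tiny_cohort_spec(seed = 17)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$targets, c2$targets)
  expect_identical(c1$panel, c2$panel)
  for (k in seq_len(nrow(c1$recordings))) {
    expect_identical(c1$recordings$recording[[k]]$data,
                     c2$recordings$recording[[k]]$data)
  }
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  f1 <- list.files(d1)
  expect_setequal(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = sprintf("file %s byte-identical", f))
  }
  # different seeds diverge
  c3 <- generate_cohort(cohort_spec(n_positive = 2, n_negative = 2,
                                    patch_counts = 4, seed = 18))
  expect_false(identical(c1$targets$target_pt_s, c3$targets$target_pt_s))
})

test_that("a cohort survives the write/read round trip", {
  coh <- generate_cohort(cohort_spec(n_positive = 1, n_negative = 1,
                                     patch_counts = 2, seed = 5))
  dir <- file.path(withr::local_tempdir(), "coh")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$patients), as.data.frame(coh$patients))
  expect_equal(back$panel$ratio, coh$panel$ratio, tolerance = 1e-12)
  expect_equal(back$schedule$phases$end_s, coh$schedule$phases$end_s)
  k <- nrow(back$recordings)
  expect_equal(as.data.frame(back$recordings$recording[[k]]$data),
               as.data.frame(coh$recordings$recording[[k]]$data),
               tolerance = 1e-9)
  # the reloaded cohort feeds the same feature pipeline
  feats <- patient_features(back)
  expect_equal(nrow(feats), 2)
})

test_that("degenerate zero-SD groups pin every difference at the group mean", {
  spec <- cohort_spec(n_positive = 3, n_negative = 2,
                      diff_sd_s = c(positive = 0, negative = 0),
                      pre_pt_sd_s = 0, post_pt_sd_s = 0,
                      patch_counts = 2, seed = 8)
  coh <- generate_cohort(spec, recordings = FALSE)
  by_tp <- tapply(coh$targets$target_pt_s,
                  list(coh$targets$patient_id, coh$targets$time_point), mean)
  diffs <- by_tp[, "fu1"] - by_tp[, "post"]
  pos <- coh$patients$patient_id[coh$patients$outcome == 1]
  neg <- coh$patients$patient_id[coh$patients$outcome == 0]
  expect_equal(unname(diffs[pos]), rep(6.7, 3), tolerance = 1e-12)
  expect_equal(unname(diffs[neg]), rep(-7.1, 2), tolerance = 1e-12)
})

test_that("drawn group differences sit near the printed generator parameters", {
  coh <- generate_cohort(cohort_spec(seed = 1), recordings = FALSE)
  expect_equal(nrow(coh$patients), 14)
  by_tp <- tapply(coh$targets$target_pt_s,
                  list(coh$targets$patient_id, coh$targets$time_point), mean)
  diffs <- by_tp[, "fu1"] - by_tp[, "post"]
  pos <- diffs[coh$patients$patient_id[coh$patients$outcome == 1]]
  neg <- diffs[coh$patients$patient_id[coh$patients$outcome == 0]]
  expect_lt(abs(mean(pos) - 6.7), 4 * 9.3 / sqrt(9))
  expect_lt(abs(mean(neg) + 7.1), 4 * 4.3 / sqrt(5))
})

test_that("over many cohorts the realized positive-group difference is unbiased", {
  n_cohorts <- 2000
  total <- 0; count <- 0
  for (s in seq_len(n_cohorts)) {
    coh <- generate_cohort(cohort_spec(seed = 1e6 + s), recordings = FALSE)
    by_tp <- tapply(coh$targets$target_pt_s,
                    list(coh$targets$patient_id, coh$targets$time_point), mean)
    diffs <- by_tp[, "fu1"] - by_tp[, "post"]
    pos <- coh$patients$patient_id[coh$patients$outcome == 1]
    total <- total + sum(diffs[pos]); count <- count + length(pos)
  }
  expect_lt(abs(total / count - 6.7), 0.1)
})

test_that("modality panel has explicit missingness and positive ratios", {
  coh <- generate_cohort(cohort_spec(seed = 12), recordings = FALSE)
  panel <- coh$panel
  expect_setequal(unique(panel$modality), c("abi", "adus"))
  expect_setequal(unique(panel$time_point), c("pre", "fu1"))
  obs <- panel$ratio[!is.na(panel$ratio)]
  expect_true(all(obs > 0))
  # missingness is whole-modality per patient/time point
  per <- tapply(is.na(panel$ratio),
                paste(panel$patient_id, panel$time_point, panel$modality),
                function(x) length(unique(x)))
  expect_true(all(per == 1))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_positive = 0), class = "dvospt_config_error")
  expect_error(cohort_spec(diff_sd_s = c(positive = -1, negative = 4.3)),
               class = "dvospt_config_error")
  expect_error(cohort_spec(patch_counts = 5), class = "dvospt_config_error")
  expect_error(cohort_spec(diff_mean_s = c(a = 1, b = 2)),
               class = "dvospt_config_error")
})
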