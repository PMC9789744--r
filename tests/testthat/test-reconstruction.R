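sched <- build_protocol()

make_rec <- function(noise = 0, seed = NULL, params = curve_params(), fr = 2.56) {
  ser <- simulate_hbt_curve(params, sched, fr)
  list(series = ser,
       rec = forward_optics(ser, sched, noise_sd = noise, seed = seed))
}

test_that("constant voltages give identically zero optical density", {
  out <- make_rec(params = curve_params(amplitude_uM = 0))
  od <- compute_delta_od(out$rec)
  for (col in grep("^od_", names(od), value = TRUE)) {
    expect_true(all(od[[col]] == 0))
  }
})

test_that("halving the voltage after baseline gives dOD = log10(2)", {
  out <- make_rec(params = curve_params(amplitude_uM = 0))
  rec <- out$rec
  late <- rec$data$time_s > 100
  for (col in setdiff(names(rec$data), "time_s")) {
    rec$data[[col]][late] <- rec$data[[col]][late] / 2
  }
  od <- compute_delta_od(rec)
  expect_equal(unique(od$od_780[late]), log10(2), tolerance = 1e-12)
  expect_equal(unique(od$od_780[!late]), 0, tolerance = 1e-12)
})

test_that("optical density matches the forward-model exponent on simulator output", {
  out <- make_rec()
  od <- compute_delta_od(out$rec, optical_config())
  ext <- hb_extinction()
  cfg <- optical_config()
  for (k in seq_len(nrow(ext))) {
    expected <- (ext$eps_hbo2_mM_cm[k] * out$series$dHbO2_uM +
                   ext$eps_hb_mM_cm[k] * out$series$dHb_uM) / 1000 *
      cfg$distance_cm * cfg$dpf[[as.character(ext$wavelength_nm[k])]]
    expect_equal(od[[sprintf("od_%d", ext$wavelength_nm[k])]], expected,
                 tolerance = 1e-12)
  }
})

test_that("zero optical density unmixes to zero concentrations", {
  od <- tibble::tibble(time_s = 1:5, od_670 = 0, od_780 = 0, od_808 = 0, od_850 = 0)
  ser <- unmix(od)
  expect_true(all(ser$dHbO2_uM == 0) && all(ser$dHb_uM == 0) && all(ser$dHbT_uM == 0))
})

test_that("a consistent system is recovered exactly, also with a dropped wavelength", {
  cfg <- optical_config()
  ext <- hb_extinction()
  E <- cbind(ext$eps_hbo2_mM_cm, ext$eps_hb_mM_cm) * cfg$distance_cm *
    unname(cfg$dpf) / 1000
  truth <- c(5, -2)
  odv <- as.numeric(E %*% truth)
  od <- tibble::tibble(time_s = 1, od_670 = odv[1], od_780 = odv[2],
                       od_808 = odv[3], od_850 = odv[4])
  ser <- unmix(od, cfg)
  expect_equal(c(ser$dHbO2_uM, ser$dHb_uM), truth, tolerance = 1e-12)
  ser3 <- unmix(od[, c("time_s", "od_670", "od_808", "od_850")], cfg)
  expect_equal(c(ser3$dHbO2_uM, ser3$dHb_uM), truth, tolerance = 1e-12)
})

test_that("unmixing is linear frame-wise", {
  cfg <- optical_config()
  set.seed(42)
  od1 <- tibble::tibble(time_s = 1:20, od_670 = rnorm(20), od_780 = rnorm(20),
                        od_808 = rnorm(20), od_850 = rnorm(20))
  od2 <- tibble::tibble(time_s = 1:20, od_670 = rnorm(20), od_780 = rnorm(20),
                        od_808 = rnorm(20), od_850 = rnorm(20))
  a <- 2.5; b <- -1.25
  comb <- od1
  for (col in c("od_670", "od_780", "od_808", "od_850")) {
    comb[[col]] <- a * od1[[col]] + b * od2[[col]]
  }
  s1 <- unmix(od1, cfg); s2 <- unmix(od2, cfg); sc <- unmix(comb, cfg)
  expect_equal(sc$dHbO2_uM, a * s1$dHbO2_uM + b * s2$dHbO2_uM, tolerance = 1e-10)
  expect_equal(sc$dHb_uM, a * s1$dHb_uM + b * s2$dHb_uM, tolerance = 1e-10)
})

test_that("unmixing equals a brute-force normal-equations solve per frame", {
  cfg <- optical_config()
  ext <- hb_extinction()
  E <- cbind(ext$eps_hbo2_mM_cm, ext$eps_hb_mM_cm) * cfg$distance_cm *
    unname(cfg$dpf) / 1000
  set.seed(7)
  od <- tibble::tibble(time_s = 1:30, od_670 = rnorm(30, sd = 0.05),
                       od_780 = rnorm(30, sd = 0.05), od_808 = rnorm(30, sd = 0.05),
                       od_850 = rnorm(30, sd = 0.05))
  ser <- unmix(od, cfg)
  for (i in c(1, 13, 30)) {
    y <- as.numeric(od[i, c("od_670", "od_780", "od_808", "od_850")])
    beta <- solve(t(E) %*% E) %*% t(E) %*% y
    expect_equal(c(ser$dHbO2_uM[i], ser$dHb_uM[i]), as.numeric(beta),
                 tolerance = 1e-10)
  }
})

test_that("doubling the pathlength halves the recovered concentrations", {
  out <- make_rec()
  cfg1 <- optical_config(dpf = 4)
  cfg2 <- optical_config(dpf = 8)
  s1 <- reconstruct_recording(out$rec, cfg1)
  s2 <- reconstruct_recording(out$rec, cfg2)
  expect_equal(s2$dHbT_uM, s1$dHbT_uM / 2, tolerance = 1e-10)
})

test_that("degenerate inputs raise the declared errors", {
  out <- make_rec()
  ext <- hb_extinction()
  ext$eps_hb_mM_cm <- 2 * ext$eps_hbo2_mM_cm # rank-1 extinction matrix
  expect_error(reconstruct_recording(out$rec, optical_config(extinction = ext)),
               class = "dvospt_config_error")
  rec <- out$rec
  rec$data$v670_far[5] <- -1
  expect_error(compute_delta_od(rec), class = "dvospt_data_error")
  expect_error(
    compute_delta_od(out$rec, optical_config(baseline_window_s = c(-10, 5))),
    class = "dvospt_config_error")
  expect_error(
    compute_delta_od(out$rec, optical_config(baseline_window_s = c(30, 90))),
    class = "dvospt_config_error")
})
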