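#' Hemodynamic curve parameters for one patch recording
#'
#' Parametrises the total-hemoglobin (HbT) response of one tissue patch to a
#' venous-occlusion trial. The curve family is a saturating-exponential rise
#' toward `baseline + amplitude` after inflation onset, followed by an
#' exponential return to baseline after cuff deflation. For a saturating
#' curve the rise time constant (and, for short plateaus, an onset delay) is
#' solved so that the interval spent above 90% of the realized maximum has
#' exactly `target_pt_s` seconds; non-saturating curves are still rising when
#' the cuff deflates, which yields a short realized plateau time.
#'
#' @param baseline_uM Baseline HbT offset in micromolar.
#' @param amplitude_uM Plateau amplitude above baseline in micromolar
#'   (HbTmax); zero gives a flat curve.
#' @param target_pt_s Target plateau time in seconds (interval between the
#'   two 90%-of-maximum crossings). Ignored when `saturating = FALSE`.
#' @param saturating Does the curve plateau within the trial window? If
#'   `FALSE` the curve is still strictly increasing at deflation.
#' @param rise_tau_s Reference rise time constant in seconds (used directly
#'   for short-plateau and non-saturating curves).
#' @param decay_tau_s Post-deflation decay time constant in seconds.
#' @param oxy_fraction Fraction of the HbT change carried by oxyhemoglobin;
#'   venous pooling is mostly venous blood, so the default is 0.7.
#'
#' @return A `curve_params` object (a validated list).
#' @export
curve_params <- function(baseline_uM = 0,
                         amplitude_uM = 10,
                         target_pt_s = 40,
                         saturating = TRUE,
                         rise_tau_s = 4,
                         decay_tau_s = 10,
                         oxy_fraction = 0.7) {
  if (!is_scalar_number(amplitude_uM) || amplitude_uM < 0) {
    abort_config("`amplitude_uM` must be a single non-negative number")
  }
  stopifnot_scalar_positive(rise_tau_s, "rise_tau_s")
  stopifnot_scalar_positive(decay_tau_s, "decay_tau_s")
  if (!is_scalar_number(baseline_uM)) abort_config("`baseline_uM` must be a number")
  if (!is_scalar_number(target_pt_s) || target_pt_s < 0) {
    abort_config("`target_pt_s` must be a single non-negative number of seconds")
  }
  if (!is_scalar_number(oxy_fraction) || oxy_fraction < 0 || oxy_fraction > 1) {
    abort_config("`oxy_fraction` must lie in [0, 1]")
  }
  structure(
    list(baseline_uM = baseline_uM, amplitude_uM = amplitude_uM,
         target_pt_s = target_pt_s, saturating = isTRUE(saturating),
         rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
         oxy_fraction = oxy_fraction),
    class = "curve_params"
  )
}

# Offset (seconds after rise onset) at which a saturating-exponential rise of
# time constant tau, truncated at rise duration L, crosses 90% of its
# realized maximum.
crossing_offset <- function(tau, L) {
  m_frac <- 1 - exp(-L / tau)
  -tau * log(1 - 0.9 * m_frac)
}

# Solve the rise shape (onset delay D and time constant tau) so the interval
# above 90% of the realized maximum lasts exactly target_pt seconds.
# L = inflation duration (onset to deflation). The curve decays with
# decay_tau after deflation, so the trailing 90% crossing sits
# decay_tau*log(1/0.9) seconds past deflation.
solve_trial_shape <- function(params, L) {
  t2_off <- params$decay_tau_s * log(1 / 0.9)
  if (!params$saturating) {
    return(list(delay = 0, tau = 2 * L))
  }
  pt <- params$target_pt_s
  if (pt <= t2_off || pt >= L + t2_off) {
    abort_config(sprintf(
      "target plateau time %.2f s is not realizable: with a %.0f s inflation and %.1f s decay constant the plateau must lie in (%.2f, %.2f) s",
      pt, L, params$decay_tau_s, t2_off, L + t2_off))
  }
  pt_at_zero_delay <- L + t2_off - crossing_offset(params$rise_tau_s, L)
  if (pt > pt_at_zero_delay) {
    # long plateau: no delay, faster rise; solve for tau
    x1 <- L + t2_off - pt
    f <- function(tau) (1 - exp(-x1 / tau)) - 0.9 * (1 - exp(-L / tau))
    tau <- stats::uniroot(f, c(1e-4, 1e7), tol = 1e-12)$root
    list(delay = 0, tau = tau)
  } else {
    # short plateau: keep the reference rise and delay its onset
    tau <- params$rise_tau_s
    g <- function(D) (L + t2_off - D - crossing_offset(tau, L - D)) - pt
    D <- stats::uniroot(g, c(0, L - 1e-9), tol = 1e-12)$root
    list(delay = D, tau = tau)
  }
}

# Contribution of one trial to the HbT time course (vectorised over t).
trial_bump <- function(t, onset, deflation, shape, amplitude, decay_tau) {
  rise_start <- onset + shape$delay
  L_eff <- deflation - rise_start
  m <- amplitude * (1 - exp(-L_eff / shape$tau))
  out <- numeric(length(t))
  rising <- t >= rise_start & t <= deflation
  out[rising] <- amplitude * (1 - exp(-(t[rising] - rise_start) / shape$tau))
  after <- t > deflation
  out[after] <- m * exp(-(t[after] - deflation) / decay_tau)
  out
}

#' Simulate a noiseless chromophore time course for one patch
#'
#' Evaluates the parametric HbT response over the full five-phase protocol at
#' the given frame rate. Both inflation trials share the same curve
#' parameters; the second trial's response superposes on the residual decay
#' of the first. The oxy/deoxy split is a fixed fraction, so
#' `dHbT_uM = dHbO2_uM + dHb_uM` holds exactly at every frame.
#'
#' @param params A [curve_params()] object.
#' @param schedule A [build_protocol()] schedule.
#' @param frame_rate Sampling rate in frames per second.
#' @return A `chromophore_series` tibble with columns `time_s`, `dHbO2_uM`,
#'   `dHb_uM`, `dHbT_uM`.
#' @examples
#' sched <- build_protocol()
#' ser <- simulate_hbt_curve(curve_params(target_pt_s = 62), sched, 10.24)
#' @export
simulate_hbt_curve <- function(params, schedule, frame_rate = 10.24) {
  if (!inherits(params, "curve_params")) abort_config("`params` must be curve_params")
  if (!inherits(schedule, "protocol_schedule")) {
    abort_config("`schedule` must be a protocol_schedule")
  }
  stopifnot_scalar_positive(frame_rate, "frame_rate")
  tw <- trial_windows(schedule)
  if (params$saturating && params$amplitude_uM > 0) {
    win_len <- tw$end_s - tw$onset_s
    if (any(params$target_pt_s > win_len)) {
      abort_config(sprintf("target plateau time %.2f s exceeds the %.0f s trial window",
                           params$target_pt_s, min(win_len)))
    }
  }

  n <- floor(schedule$total_s * frame_rate)
  t <- (seq_len(n) - 1) / frame_rate
  hbt <- rep(params$baseline_uM, n)
  if (params$amplitude_uM > 0) {
    for (k in 1:2) {
      L <- tw$deflation_s[k] - tw$onset_s[k]
      shape <- solve_trial_shape(params, L)
      hbt <- hbt + trial_bump(t, tw$onset_s[k], tw$deflation_s[k], shape,
                              params$amplitude_uM, params$decay_tau_s)
    }
  }
  dhbo2 <- params$oxy_fraction * hbt
  new_chromophore_series(
    time_s = t, dHbO2_uM = dhbo2, dHb_uM = hbt - dhbo2,
    frame_rate = frame_rate, schedule = schedule, source = "simulated"
  )
}

# Shared constructor for chromophore concentration series; guarantees the
# HbT = HbO2 + Hb identity by construction.
new_chromophore_series <- function(time_s, dHbO2_uM, dHb_uM,
                                   patch_id = NA_character_,
                                   detector = NA_character_,
                                   frame_rate = NA_real_,
                                   baseline_window_s = NULL,
                                   schedule = NULL,
                                   source = NA_character_) {
  time_s <- as.numeric(time_s)
  dHbO2_uM <- as.numeric(dHbO2_uM)
  dHb_uM <- as.numeric(dHb_uM)
  out <- tibble::new_tibble(
    list(time_s = time_s, dHbO2_uM = dHbO2_uM, dHb_uM = dHb_uM,
         dHbT_uM = dHbO2_uM + dHb_uM),
    nrow = length(time_s)
  )
  attr(out, "patch_id") <- patch_id
  attr(out, "detector") <- detector
  attr(out, "frame_rate") <- frame_rate
  attr(out, "baseline_window_s") <- baseline_window_s
  attr(out, "schedule") <- schedule
  attr(out, "source") <- source
  class(out) <- c("chromophore_series", class(out))
  out
}

#' Write / read a chromophore series as text
#'
#' Writes the concentration time course as a comma-separated table
#' (`time_s, dHbO_uM, dHb_uM, dHbT_uM`) with a JSON sidecar echoing the
#' provenance (patch, detector, baseline window).
#'
#' @param series A `chromophore_series`.
#' @param path Output CSV path; the sidecar gets the same path with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_chromophore_series <- function(series, path) {
  df <- data.frame(time_s = series$time_s, dHbO_uM = series$dHbO2_uM,
                   dHb_uM = series$dHb_uM, dHbT_uM = series$dHbT_uM)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    patch_id = attr(series, "patch_id"),
    detector = attr(series, "detector"),
    frame_rate = attr(series, "frame_rate"),
    baseline_window_s = attr(series, "baseline_window_s"),
    source = attr(series, "source")
  )
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
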