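#' Hemoglobin extinction coefficients at the device wavelengths
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the four
#' laser-diode wavelengths (670, 780, 808, 850 nm), in per-millimolar per-cm,
#' taken from the standard published compilation of hemoglobin absorption
#' spectra. 808 nm sits near the isosbestic point; 670 nm is strongly
#' deoxy-weighted, 850 nm oxy-weighted, which keeps the unmixing system well
#' conditioned.
#'
#' @return A tibble with columns `wavelength_nm`, `eps_hbo2_mM_cm`,
#'   `eps_hb_mM_cm`.
#' @export
hb_extinction <- function() {
  tibble::tibble(
    wavelength_nm = c(670, 780, 808, 850),
    eps_hbo2_mM_cm = c(0.320, 0.710, 0.866, 1.058),
    eps_hb_mM_cm = c(2.795, 1.075, 0.762, 0.691)
  )
}

dvos_wavelengths <- c(670, 780, 808, 850)
dvos_detectors <- c(near = 1.6, far = 2.5)

#' Patch source--detector geometry
#'
#' @param distances_cm Named source--detector distances in cm; the patch has
#'   a near (1.6 cm) and a far (2.5 cm) silicon photodiode.
#' @param dpf Differential pathlength factor, a single value applied to all
#'   wavelengths or a vector named by wavelength.
#' @param v0 Baseline detector voltage (volts) at zero concentration change.
#' @param extinction Extinction table as from [hb_extinction()].
#' @return An `optical_geometry` list.
#' @export
optical_geometry <- function(distances_cm = c(near = 1.6, far = 2.5),
                             dpf = 4, v0 = 1,
                             extinction = hb_extinction()) {
  if (is.null(names(distances_cm)) || !all(c("near", "far") %in% names(distances_cm))) {
    abort_config("`distances_cm` must be named with 'near' and 'far'")
  }
  if (any(distances_cm <= 0)) abort_config("detector distances must be positive")
  stopifnot_scalar_positive(v0, "v0")
  check_extinction(extinction, dvos_wavelengths)
  structure(
    list(distances_cm = distances_cm,
         dpf = expand_dpf(dpf, extinction$wavelength_nm),
         v0 = v0, extinction = extinction),
    class = "optical_geometry"
  )
}

expand_dpf <- function(dpf, wavelengths) {
  if (length(dpf) == 1L) {
    dpf <- stats::setNames(rep(dpf, length(wavelengths)), wavelengths)
  }
  if (is.null(names(dpf))) names(dpf) <- wavelengths
  if (any(!is.finite(dpf)) || any(dpf <= 0)) abort_config("DPF values must be positive")
  dpf[as.character(wavelengths)]
}

check_extinction <- function(extinction, wavelengths) {
  need <- c("wavelength_nm", "eps_hbo2_mM_cm", "eps_hb_mM_cm")
  if (!all(need %in% names(extinction))) {
    abort_config("extinction table must have columns wavelength_nm, eps_hbo2_mM_cm, eps_hb_mM_cm")
  }
  sub <- extinction[extinction$wavelength_nm %in% wavelengths, ]
  if (nrow(sub) < length(wavelengths) ||
      any(!is.finite(sub$eps_hbo2_mM_cm)) || any(!is.finite(sub$eps_hb_mM_cm))) {
    abort_config(sprintf(
      "extinction table is missing entries for wavelengths {%s} for both chromophores",
      paste(wavelengths, collapse = ", ")))
  }
  invisible(extinction)
}

#' Beer--Lambert forward model: concentrations to detector voltages
#'
#' Maps a chromophore concentration time course to raw detector voltages for
#' all four wavelengths and both detectors via the modified Beer--Lambert
#' law: `V = v0 * 10^(-(eps_HbO2*dHbO2 + eps_Hb*dHb) * d * DPF / 1000)`,
#' optionally multiplied by `(1 + e)` with `e ~ N(0, noise_sd)` i.i.d. per
#' sample (multiplicative detector noise).
#'
#' @param series A `chromophore_series` (concentrations in micromolar).
#' @param schedule The protocol schedule, used to stamp cuff-event markers
#'   into the recording.
#' @param geometry An [optical_geometry()].
#' @param noise_sd Relative (multiplicative) noise standard deviation;
#'   0 for a noiseless recording.
#' @param seed Optional integer seed set before drawing noise.
#' @param patch_id,angiosome Patch identity recorded in the output.
#' @param frame_rate Frames per second; defaults to the series' own rate.
#' @return A `patch_recording` object: voltage tibble (`time_s`,
#'   `v670_near`, `v670_far`, ..., `v850_far`), cuff events, and geometry.
#' @examples
#' sched <- build_protocol()
#' ser <- simulate_hbt_curve(curve_params(), sched, 2.56)
#' rec <- forward_optics(ser, sched, noise_sd = 0, patch_id = "patch1")
#' @export
forward_optics <- function(series, schedule,
                           geometry = optical_geometry(),
                           noise_sd = 0.01, seed = NULL,
                           patch_id = "patch1",
                           angiosome = "dorsalis_pedis",
                           frame_rate = NULL) {
  if (!inherits(geometry, "optical_geometry")) {
    abort_config("`geometry` must be an optical_geometry")
  }
  check_extinction(geometry$extinction, dvos_wavelengths)
  if (!is_scalar_number(noise_sd) || noise_sd < 0 || noise_sd >= 0.3) {
    abort_config("`noise_sd` must be in [0, 0.3)")
  }
  frame_rate <- frame_rate %||% attr(series, "frame_rate")
  if (is.null(frame_rate) || is.na(frame_rate)) {
    dt <- stats::median(diff(series$time_s))
    frame_rate <- 1 / dt
  }
  if (!is.null(seed)) set.seed(seed)

  ext <- geometry$extinction[match(dvos_wavelengths, geometry$extinction$wavelength_nm), ]
  n <- nrow(series)
  # absorption term per wavelength, per cm of geometric path (uM -> mM)
  mu <- outer(series$dHbO2_uM, ext$eps_hbo2_mM_cm) +
    outer(series$dHb_uM, ext$eps_hb_mM_cm) # n x 4, mM*eps units
  mu <- mu / 1000

  cols <- list(time_s = series$time_s)
  for (i in seq_along(dvos_wavelengths)) {
    for (det in c("near", "far")) {
      d <- geometry$distances_cm[[det]]
      dpf_i <- geometry$dpf[[as.character(dvos_wavelengths[i])]]
      v <- geometry$v0 * 10^(-mu[, i] * d * dpf_i)
      if (noise_sd > 0) v <- v * (1 + stats::rnorm(n, 0, noise_sd))
      cols[[sprintf("v%d_%s", dvos_wavelengths[i], det)]] <- v
    }
  }
  data <- tibble::new_tibble(cols, nrow = n)
  new_patch_recording(data, patch_id, angiosome, frame_rate,
                      protocol_events(schedule), geometry)
}

new_patch_recording <- function(data, patch_id, angiosome, frame_rate,
                                events, geometry) {
  vcols <- setdiff(names(data), "time_s")
  if (any(vapply(data[vcols], function(v) any(v <= 0), logical(1)))) {
    abort_data("detector voltages must be strictly positive")
  }
  if (any(diff(data$time_s) <= 0)) abort_data("timestamps must be strictly increasing")
  structure(
    list(data = data, patch_id = patch_id, angiosome = angiosome,
         frame_rate = frame_rate, events = events, geometry = geometry),
    class = "patch_recording"
  )
}

#' @export
print.patch_recording <- function(x, ...) {
  cat(sprintf("<patch_recording> %s on %s, %.2f fps, %d frames, %.0f s span\n",
              x$patch_id, x$angiosome, x$frame_rate, nrow(x$data),
              max(x$data$time_s)))
  invisible(x)
}

#' Frame rate implied by the number of patches in use
#'
#' The acquisition electronics multiplex patches, so the per-patch frame rate
#' is fixed by how many patches record simultaneously: 10.24, 5.12, 3.41 and
#' 2.56 frames per second for 1-4 patches.
#'
#' @param n_patches Integer number of patches (1-4).
#' @return Frames per second.
#' @export
patch_frame_rate <- function(n_patches) {
  rates <- c(10.24, 5.12, 3.41, 2.56)
  if (any(!n_patches %in% 1:4)) abort_config("`n_patches` must be 1, 2, 3 or 4")
  rates[n_patches]
}

#' Write / read a raw patch recording
#'
#' The recording is a comma-separated table (`time_s`, then one voltage
#' column per wavelength and detector) preceded by `#` header lines naming
#' the patch, angiosome and frame rate, plus a JSON sidecar with the
#' cuff-event markers and geometry.
#'
#' @param recording A `patch_recording`.
#' @param path Output CSV path (sidecar written next to it as `.json`).
#' @return `path` (write) or a `patch_recording` (read).
#' @export
write_recording <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# patch_id: %s", recording$patch_id),
    sprintf("# angiosome: %s", recording$angiosome),
    sprintf("# frame_rate: %.2f", recording$frame_rate)
  ), con)
  utils::write.csv(recording$data, con, row.names = FALSE)
  sidecar <- list(
    patch_id = recording$patch_id,
    angiosome = recording$angiosome,
    frame_rate = recording$frame_rate,
    events = recording$events,
    geometry = list(
      distances_cm = as.list(recording$geometry$distances_cm),
      dpf = as.list(recording$geometry$dpf),
      v0 = recording$geometry$v0,
      extinction = recording$geometry$extinction
    )
  )
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  data <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  geometry <- optical_geometry(
    distances_cm = unlist(side$geometry$distances_cm),
    dpf = unlist(side$geometry$dpf),
    v0 = side$geometry$v0,
    extinction = tibble::as_tibble(side$geometry$extinction)
  )
  new_patch_recording(data, side$patch_id, side$angiosome, side$frame_rate,
                      tibble::as_tibble(side$events), geometry)
}
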