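#' Foot angiosomes instrumented by the device
#'
#' @return Character vector of the six angiosome labels.
#' @export
angiosome_labels <- function() {
  c("peroneal", "posterior_tibial", "anterior_tibial",
    "dorsalis_pedis", "lateral_plantar", "medial_plantar")
}

#' Specification of a synthetic patient cohort
#'
#' Defines the study conditions emulated by the generator: group sizes, the
#' outcome-dependent distribution of the follow-up-minus-postintervention
#' plateau-time difference (FU1PostGen), plateau-time levels at the three
#' acquisition time points, patch-level heterogeneity, optical amplitude and
#' detector noise. Defaults reproduce the reported study: 9 positive-outcome
#' and 5 negative-outcome patients with FU1PostGen differences of
#' 6.7 +/- 9.3 s and -7.1 +/- 4.3 s respectively.
#'
#' @param n_positive,n_negative Patients per outcome group (>= 1).
#' @param diff_mean_s,diff_sd_s Named (`positive`, `negative`) mean and SD of
#'   the FU1PostGen plateau-time difference, in seconds. SDs may be zero.
#' @param pre_pt_mean_s,pre_pt_sd_s Preintervention plateau-time level.
#' @param post_pt_mean_s Named postintervention plateau-time means; the
#'   negative group's larger post-pre jump is the default.
#' @param post_pt_sd_s Postintervention plateau-time SD (common).
#' @param patch_offset_sd_s SD of the persistent per-patch plateau-time
#'   offset (the same offset applies at all three time points, so
#'   patch-mean differences equal the patient-level difference exactly).
#' @param patch_counts Optional integer vector (one entry per patient, values
#'   1-4) fixing the number of patches; `NULL` draws 1-4 at random.
#' @param amplitude_uM HbT plateau amplitude in micromolar.
#' @param noise_sd Relative multiplicative detector-noise SD.
#' @param seed Integer seed; per-patient streams are derived from it
#'   deterministically.
#' @param panel Panel model parameters, see [default_panel_model()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_positive = 9, n_negative = 5,
                        diff_mean_s = c(positive = 6.7, negative = -7.1),
                        diff_sd_s = c(positive = 9.3, negative = 4.3),
                        pre_pt_mean_s = 15, pre_pt_sd_s = 4,
                        post_pt_mean_s = c(positive = 35, negative = 45),
                        post_pt_sd_s = 5,
                        patch_offset_sd_s = 1.5,
                        patch_counts = NULL,
                        amplitude_uM = 10,
                        noise_sd = 0.01,
                        seed = 1,
                        panel = default_panel_model()) {
  if (!is_scalar_number(n_positive) || !is_scalar_number(n_negative) ||
      n_positive < 1 || n_negative < 1) {
    abort_config("group sizes must be >= 1")
  }
  n_positive <- as.integer(n_positive); n_negative <- as.integer(n_negative)
  for (v in list(diff_mean_s, diff_sd_s, post_pt_mean_s)) {
    if (!all(c("positive", "negative") %in% names(v))) {
      abort_config("group parameters must be named 'positive' and 'negative'")
    }
  }
  if (any(diff_sd_s < 0) || pre_pt_sd_s < 0 || post_pt_sd_s < 0 ||
      patch_offset_sd_s < 0) {
    abort_config("standard deviations must be non-negative")
  }
  n <- n_positive + n_negative
  if (!is.null(patch_counts)) {
    if (length(patch_counts) == 1L) patch_counts <- rep(patch_counts, n)
    if (length(patch_counts) != n || !all(patch_counts %in% 1:4)) {
      abort_config("`patch_counts` must have one value in 1:4 per patient")
    }
    patch_counts <- as.integer(patch_counts)
  }
  stopifnot_scalar_positive(amplitude_uM, "amplitude_uM")
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    abort_config("`noise_sd` must be non-negative")
  }
  if (!is_scalar_number(seed)) abort_config("`seed` must be a single integer")
  structure(
    list(n_positive = n_positive, n_negative = n_negative,
         diff_mean_s = diff_mean_s, diff_sd_s = diff_sd_s,
         pre_pt_mean_s = pre_pt_mean_s, pre_pt_sd_s = pre_pt_sd_s,
         post_pt_mean_s = post_pt_mean_s, post_pt_sd_s = post_pt_sd_s,
         patch_offset_sd_s = patch_offset_sd_s,
         patch_counts = patch_counts,
         amplitude_uM = amplitude_uM, noise_sd = noise_sd,
         seed = as.integer(seed), panel = panel),
    class = "cohort_spec"
  )
}

#' Default ankle-brachial index and duplex-ultrasound panel model
#'
#' Generator parameters for the comparison modalities. Ratios carry only a
#' weak outcome association (the study found neither modality statistically
#' associated with wound healing) and availability matches the reported
#' counts: preintervention ABI in 5/14 patients, follow-up ABI in 10/14,
#' preintervention duplex in 9/14, follow-up duplex in 11/14.
#'
#' @return A list of panel-model parameters.
#' @export
default_panel_model <- function() {
  list(
    abi_mean = list(pre = c(positive = 0.65, negative = 0.62),
                    fu1 = c(positive = 0.88, negative = 0.78)),
    abi_sd = 0.18, abi_artery_sd = 0.06, abi_floor = 0.2,
    adus_meanlog = list(pre = c(positive = log(2.4), negative = log(2.6)),
                        fu1 = c(positive = log(2.1), negative = log(2.7))),
    adus_sdlog = 0.35, adus_artery_sdlog = 0.15,
    availability = c(abi_pre = 5 / 14, abi_fu1 = 10 / 14,
                     adus_pre = 9 / 14, adus_fu1 = 11 / 14)
  )
}

abi_arteries <- c("posterior_tibial", "dorsalis_pedis")
adus_arteries <- c("peroneal", "posterior_tibial", "anterior_tibial")

# Plateau-time targets realizable by the curve family within the default
# protocol; patient-level levels and patch-level targets are clamped here.
pt_clamp_patient <- c(2, 69)
pt_clamp_patch <- c(1.5, 70)

clamp <- function(x, lim) pmin(pmax(x, lim[1]), lim[2])

#' Generate a seeded synthetic cohort
#'
#' Draws outcome-dependent plateau-time trajectories, simulates the raw
#' multi-wavelength recordings for every patient, time point and patch via
#' the Beer--Lambert forward model, and draws the ABI / duplex-ultrasound
#' modality panel. The per-patient plateau-time targets at the three time
#' points are chosen so that the pipeline-realized FU1PostGen difference
#' equals the drawn group-distributed value (patch offsets are persistent
#' across time points and cancel in differences).
#'
#' @param spec A [cohort_spec()].
#' @param schedule Protocol schedule shared by all recordings.
#' @param geometry Optical geometry shared by all patches.
#' @param recordings If `FALSE`, draw only the outcome labels, plateau-time
#'   targets and modality panel and skip the optical simulation (useful for
#'   distributional studies of the generator itself); the drawn values are
#'   identical to a full run at the same seed.
#' @return A `dvos_cohort` object: `patients` (id, outcome, ulcer angiosome,
#'   patch count, frame rate), `targets` (drawn plateau-time targets),
#'   `recordings` (tibble with a `recording` list-column of
#'   `patch_recording`s), `panel` (long tibble of modality ratios with
#'   explicit `NA` missingness), plus the schedule and spec.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_positive = 2, n_negative = 1, seed = 7,
#'                                    patch_counts = 4))
#' coh$patients
#' @export
generate_cohort <- function(spec, schedule = build_protocol(),
                            geometry = optical_geometry(),
                            recordings = TRUE) {
  if (!inherits(spec, "cohort_spec")) abort_config("`spec` must be a cohort_spec")
  n <- spec$n_positive + spec$n_negative
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    outcome = rep(c(1L, 0L), c(spec$n_positive, spec$n_negative))
  )
  time_points <- c("pre", "post", "fu1")
  angios <- angiosome_labels()

  acc <- list(patient_id = character(0), time_point = character(0),
              patch_id = character(0), angiosome = character(0),
              frame_rate = numeric(0), target_pt_s = numeric(0))
  rec_list <- list()
  panel_rows <- list()
  meta <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(mix_seed(spec$seed, i))
    grp <- if (patients$outcome[i] == 1L) "positive" else "negative"

    n_patch <- if (is.null(spec$patch_counts)) sample(1:4, 1) else spec$patch_counts[i]
    fr <- patch_frame_rate(n_patch)
    ulcer <- sample(angios, 1)
    patch_angios <- c(ulcer, sample(setdiff(angios, ulcer), n_patch - 1))
    offsets <- stats::rnorm(n_patch, 0, spec$patch_offset_sd_s)

    pre <- stats::rnorm(1, spec$pre_pt_mean_s, spec$pre_pt_sd_s)
    post <- stats::rnorm(1, spec$post_pt_mean_s[[grp]], spec$post_pt_sd_s)
    fu1_diff <- stats::rnorm(1, spec$diff_mean_s[[grp]], spec$diff_sd_s[[grp]])
    levels <- clamp(c(pre = pre, post = post, fu1 = post + fu1_diff),
                    pt_clamp_patient)

    meta[[i]] <- tibble::tibble(
      patient_id = patients$patient_id[i], outcome = patients$outcome[i],
      n_patches = n_patch, frame_rate = fr, ulcer_angiosome = ulcer
    )

    # panel drawn before the optical noise stream so targets and panel are
    # identical whether or not recordings are simulated
    panel_rows[[length(panel_rows) + 1L]] <-
      draw_modality_panel(patients$patient_id[i], grp, ulcer, spec$panel)

    for (tp in time_points) {
      for (p in seq_len(n_patch)) {
        target <- clamp(levels[[tp]] + offsets[p], pt_clamp_patch)
        k <- length(acc$patient_id) + 1L
        acc$patient_id[k] <- patients$patient_id[i]
        acc$time_point[k] <- tp
        acc$patch_id[k] <- sprintf("patch%d", p)
        acc$angiosome[k] <- patch_angios[p]
        acc$frame_rate[k] <- fr
        acc$target_pt_s[k] <- target
        if (recordings) {
          params <- curve_params(amplitude_uM = spec$amplitude_uM,
                                 target_pt_s = target)
          series <- simulate_hbt_curve(params, schedule, fr)
          rec_list[[k]] <- forward_optics(series, schedule, geometry,
                                          noise_sd = spec$noise_sd,
                                          patch_id = sprintf("patch%d", p),
                                          angiosome = patch_angios[p])
        }
      }
    }
  }

  n_rec <- length(acc$patient_id)
  targets <- tibble::new_tibble(
    acc[c("patient_id", "time_point", "patch_id", "angiosome", "target_pt_s")],
    nrow = n_rec)
  rec_tbl <- if (recordings) {
    tibble::new_tibble(
      c(acc[c("patient_id", "time_point", "patch_id", "angiosome", "frame_rate")],
        list(recording = rec_list)),
      nrow = n_rec)
  } else {
    NULL
  }
  structure(
    list(
      patients = dplyr::bind_rows(meta),
      targets = targets,
      recordings = rec_tbl,
      panel = dplyr::bind_rows(panel_rows),
      schedule = schedule,
      spec = spec
    ),
    class = "dvos_cohort"
  )
}

# ABI pressure ratios and duplex PSV ratios for one patient. Missingness is
# drawn per patient/time point/modality; when a modality is observed all of
# its arteries are observed. Ratios stay strictly positive.
draw_modality_panel <- function(patient_id, grp, ulcer, panel) {
  rows <- list()
  mk <- function(tp, modality, arteries, ratio) {
    k <- length(arteries)
    tibble::new_tibble(
      list(patient_id = rep(patient_id, k), time_point = rep(tp, k),
           modality = rep(modality, k), artery = arteries, ratio = ratio),
      nrow = k)
  }
  for (tp in c("pre", "fu1")) {
    abi_avail <- stats::runif(1) < panel$availability[[paste0("abi_", tp)]]
    m <- stats::rnorm(1, panel$abi_mean[[tp]][[grp]], panel$abi_sd)
    vals <- pmax(m + stats::rnorm(length(abi_arteries), 0, panel$abi_artery_sd),
                 panel$abi_floor)
    rows[[length(rows) + 1L]] <- mk(tp, "abi", abi_arteries,
                                    if (abi_avail) vals else rep(NA_real_, 2))
    adus_avail <- stats::runif(1) < panel$availability[[paste0("adus_", tp)]]
    ml <- stats::rnorm(1, panel$adus_meanlog[[tp]][[grp]], panel$adus_sdlog)
    vals <- exp(ml + stats::rnorm(length(adus_arteries), 0, panel$adus_artery_sdlog))
    rows[[length(rows) + 1L]] <- mk(tp, "adus", adus_arteries,
                                    if (adus_avail) vals else rep(NA_real_, 3))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.dvos_cohort <- function(x, ...) {
  cat(sprintf("<dvos_cohort> %d patients (%d positive / %d negative), %d recordings, seed %d\n",
              nrow(x$patients), sum(x$patients$outcome == 1),
              sum(x$patients$outcome == 0),
              if (is.null(x$recordings)) 0L else nrow(x$recordings),
              x$spec$seed))
  invisible(x)
}

#' Write / read a cohort to a directory of text files
#'
#' Serialises every patch recording as a commented CSV plus JSON sidecar (see
#' [write_recording()]) and writes a `manifest.json` listing patients, time
#' points, patch files, outcome labels and the modality panel. A cohort
#' generated twice from the same seed serialises to byte-identical files.
#'
#' @param cohort A `dvos_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path (write); a `dvos_cohort` without the spec
#'   (read).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- cohort$recordings
  files <- sprintf("%s_%s_%s.csv", recs$patient_id, recs$time_point, recs$patch_id)
  for (k in seq_len(nrow(recs))) {
    write_recording(recs$recording[[k]], file.path(dir, files[k]))
  }
  manifest <- list(
    patients = cohort$patients,
    recordings = dplyr::mutate(
      recs[, c("patient_id", "time_point", "patch_id", "angiosome", "frame_rate")],
      file = files),
    panel = cohort$panel,
    protocol = list(
      phase_ends_s = cohort$schedule$phases$end_s,
      ramp_s = cohort$schedule$ramp_s,
      pressures_mmHg = cohort$schedule$pressures_mmHg
    ),
    seed = cohort$spec$seed
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  recs <- tibble::as_tibble(manifest$recordings)
  recs$recording <- lapply(file.path(dir, recs$file), read_recording)
  recs$file <- NULL
  ends <- manifest$protocol$phase_ends_s
  durations <- diff(c(0, ends)) - c(0, manifest$protocol$ramp_s, 0,
                                    manifest$protocol$ramp_s, 0)
  schedule <- build_protocol(durations, manifest$protocol$ramp_s,
                             manifest$protocol$pressures_mmHg)
  structure(
    list(patients = tibble::as_tibble(manifest$patients),
         targets = NULL,
         recordings = recs,
         panel = tibble::as_tibble(manifest$panel),
         schedule = schedule,
         spec = NULL),
    class = "dvos_cohort"
  )
}
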