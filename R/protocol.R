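#' Build the five-phase cuff-occlusion protocol schedule
#'
#' The acquisition protocol has five ordered phases: a resting baseline, a
#' thigh-cuff inflation held at 60 mmHg (venous occlusion), a post-deflation
#' recovery, a second inflation held at 100 mmHg (partial arterial
#' involvement), and a final recovery. Each hold lasts about one minute and
#' each inflation is preceded by a ~10 s ramp while the cuff pressurises, so
#' the two occlusion phases span `ramp_s + phase_durations[c(2, 4)]` seconds.
#'
#' @param phase_durations Numeric vector of five phase durations in seconds
#'   (baseline, 60 mmHg hold, recovery, 100 mmHg hold, recovery). The ramp is
#'   added on top of the two hold durations.
#' @param ramp_s Cuff inflation ramp duration in seconds.
#' @param pressures_mmHg Cuff pressures for the two inflation trials, in
#'   order (default 60 then 100 mmHg).
#'
#' @return A `protocol_schedule` object: a list with a `phases` tibble
#'   (`phase`, `label`, `start_s`, `end_s`, `pressure_mmHg`), the ramp, the
#'   trial pressures, and the total duration.
#' @examples
#' sched <- build_protocol()
#' trial_windows(sched)
#' @export
build_protocol <- function(phase_durations = rep(60, 5),
                           ramp_s = 10,
                           pressures_mmHg = c(60, 100)) {
  if (length(phase_durations) != 5L || !is.numeric(phase_durations) ||
      any(!is.finite(phase_durations)) || any(phase_durations <= 0)) {
    abort_config("`phase_durations` must be five positive finite durations in seconds")
  }
  if (!is_scalar_number(ramp_s) || ramp_s < 0) {
    abort_config("`ramp_s` must be a single non-negative number of seconds")
  }
  if (length(pressures_mmHg) != 2L || any(!is.finite(pressures_mmHg)) ||
      any(pressures_mmHg <= 0) || diff(pressures_mmHg) <= 0) {
    abort_config("`pressures_mmHg` must be two increasing positive cuff pressures")
  }

  durations <- phase_durations + c(0, ramp_s, 0, ramp_s, 0)
  ends <- cumsum(durations)
  starts <- c(0, ends[-5])
  phases <- tibble::tibble(
    phase = 1:5,
    label = c("baseline",
              sprintf("occlusion_%gmmHg", pressures_mmHg[1]),
              "recovery",
              sprintf("occlusion_%gmmHg", pressures_mmHg[2]),
              "recovery"),
    start_s = starts,
    end_s = ends,
    pressure_mmHg = c(NA, pressures_mmHg[1], NA, pressures_mmHg[2], NA)
  )
  trials <- tibble::tibble(
    trial = 1:2,
    pressure_mmHg = pressures_mmHg,
    onset_s = phases$start_s[c(2, 4)],
    hold_start_s = phases$start_s[c(2, 4)] + ramp_s,
    deflation_s = phases$end_s[c(2, 4)],
    end_s = phases$end_s[c(3, 5)]
  )
  events <- tibble::tibble(
    trial = rep(trials$trial, each = 3),
    event = rep(c("inflation_start", "inflation_end", "deflation"), 2),
    time_s = as.vector(rbind(trials$onset_s, trials$hold_start_s,
                             trials$deflation_s))
  )
  structure(
    list(phases = phases,
         ramp_s = ramp_s,
         pressures_mmHg = pressures_mmHg,
         total_s = ends[5],
         trials = trials,
         events = events),
    class = "protocol_schedule"
  )
}

#' Trial analysis windows of a protocol schedule
#'
#' Each inflation trial is analysed from its inflation onset through cuff
#' deflation and the following recovery minute, so the plateau and its decay
#' both fall inside the window.
#'
#' @param schedule A `protocol_schedule` from [build_protocol()].
#' @return A tibble with one row per trial: `trial`, `pressure_mmHg`,
#'   `onset_s` (inflation start), `hold_start_s` (ramp end), `deflation_s`,
#'   and `end_s` (end of the post-deflation recovery).
#' @export
trial_windows <- function(schedule) {
  if (!inherits(schedule, "protocol_schedule")) {
    abort_config("`schedule` must be a protocol_schedule")
  }
  schedule$trials
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule> 5 phases, %.0f s total, trials at %g and %g mmHg\n",
              x$total_s, x$pressures_mmHg[1], x$pressures_mmHg[2]))
  print(x$phases)
  invisible(x)
}

# Cuff-event markers emitted alongside recordings.
protocol_events <- function(schedule) {
  schedule$events
}
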