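#' Arterial tree of the foot angiosomes
#'
#' Directed adjacency among the six instrumented angiosomes: the anterior
#' tibial artery feeds the dorsalis pedis, and the posterior tibial feeds the
#' medial and lateral plantar territories; the peroneal stands alone. Used to
#' resolve the "localized" (Loc) feature: the patch on the ulcer's angiosome,
#' else the patch(es) directly below the affected artery, else the patch
#' directly above it.
#'
#' @param edges Optional tibble with `parent` and `child` columns replacing
#'   the default edges; all labels must be angiosome labels and the graph
#'   must be acyclic.
#' @return An `angiosome_tree` tibble of edges with a `nodes` attribute.
#' @export
angiosome_tree <- function(edges = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(
      parent = c("anterior_tibial", "posterior_tibial", "posterior_tibial"),
      child = c("dorsalis_pedis", "medial_plantar", "lateral_plantar")
    )
  }
  nodes <- angiosome_labels()
  if (!all(c(edges$parent, edges$child) %in% nodes)) {
    abort_config("angiosome tree edges must use known angiosome labels")
  }
  if (anyDuplicated(edges$child) > 0) {
    abort_config("each angiosome can have at most one feeding artery")
  }
  # cycle check by repeated leaf stripping
  e <- edges
  while (nrow(e) > 0) {
    leaves <- setdiff(e$child, e$parent)
    if (length(leaves) == 0) abort_config("angiosome tree contains a cycle")
    e <- e[!e$child %in% leaves, , drop = FALSE]
  }
  structure(edges, nodes = nodes, class = c("angiosome_tree", class(edges)))
}

tree_descendants <- function(tree, node) {
  out <- character(0)
  frontier <- node
  while (length(frontier) > 0) {
    kids <- tree$child[tree$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

tree_ancestors <- function(tree, node) {
  out <- character(0)
  cur <- node
  repeat {
    parent <- tree$parent[tree$child == cur]
    if (length(parent) == 0) break
    out <- c(out, parent)
    cur <- parent
  }
  out
}

# Centered moving average with shrinking windows at the edges; width must be
# odd. Width 1 returns the input unchanged.
smooth_ma <- function(x, width = 5) {
  if (width <= 1) return(x)
  if (width %% 2 == 0) abort_config("smoothing width must be odd")
  half <- (width - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Extract plateau-time features from one inflation trial
#'
#' Within the trial window the (optionally smoothed) HbT curve is referenced
#' to its level at inflation onset (the mean of the last few raw frames at or
#' before the window start), `HbTmax` is the maximum excursion above that
#' reference, and the threshold is 90% of it. `t1` is the first upward
#' threshold crossing (linearly interpolated between bracketing frames), `t2`
#' the last time the curve is at or above the threshold (interpolated on the
#' way down, or clamped to the window end with a right-censoring flag if the
#' curve never falls below before the window ends). The plateau time is
#' `PT = t2 - t1` and the rise time is `t1` minus the inflation onset.
#' Because the threshold is relative to the window's own baseline and
#' maximum, the features are invariant under positive affine rescaling of
#' the curve.
#'
#' @param series A `chromophore_series` covering the window.
#' @param window One row of [trial_windows()] (or a list with `onset_s`,
#'   `deflation_s`, `end_s`, `pressure_mmHg`).
#' @param smooth_width Centered moving-average width in frames (odd; 1
#'   disables smoothing).
#' @param min_amplitude_uM Amplitudes at or below this are treated as a flat
#'   curve: the features come back undefined (`NA`) with a diagnostic
#'   `reason`, never silently zero.
#' @param saturation_hold_s Minimum contiguous time (s) within 10% of the
#'   maximum for the trial to count as having reached saturation.
#' @return A one-row tibble: `pressure_mmHg`, `hbt_max_uM`, `t_rise_s`,
#'   `pt_s`, `saturation`, `censored`, `defined`, `reason`.
#' @export
extract_trial_features <- function(series, window, smooth_width = 5,
                                   min_amplitude_uM = 1e-6,
                                   saturation_hold_s = 5) {
  onset <- window$onset_s
  end <- window$end_s
  idx <- which(series$time_s >= onset & series$time_s <= end)
  if (length(idx) < 10) abort_data("trial window contains fewer than 10 frames")
  tt <- series$time_s[idx]
  yy <- smooth_ma(series$dHbT_uM, smooth_width)[idx]

  # Reference level at inflation onset, from the raw frames just before the
  # window so the smoothing window never straddles the onset kink; falls back
  # to the first in-window frame when nothing precedes the window.
  pre_idx <- which(series$time_s <= onset)
  b0 <- if (length(pre_idx) > 0) {
    mean(series$dHbT_uM[utils::tail(pre_idx, 5)])
  } else {
    yy[1]
  }

  row <- function(hbt_max = NA_real_, t_rise = NA_real_, pt = NA_real_,
                  saturation = NA, censored = NA, defined = FALSE,
                  reason = NA_character_) {
    tibble::new_tibble(
      list(pressure_mmHg = window$pressure_mmHg, hbt_max_uM = hbt_max,
           t_rise_s = t_rise, pt_s = pt, saturation = saturation,
           censored = censored, defined = defined, reason = reason),
      nrow = 1L)
  }

  amp <- max(yy) - b0
  if (!is.finite(amp) || amp <= min_amplitude_uM) {
    return(row(reason = "flat curve: non-positive HbT excursion"))
  }
  thr <- b0 + 0.9 * amp
  above <- yy >= thr
  hits <- which(above)

  i1 <- hits[1]
  t1 <- if (i1 == 1) tt[1] else {
    tt[i1 - 1] + (thr - yy[i1 - 1]) / (yy[i1] - yy[i1 - 1]) * (tt[i1] - tt[i1 - 1])
  }
  i2 <- hits[length(hits)]
  censored <- i2 == length(yy)
  t2 <- if (censored) tt[length(tt)] else {
    tt[i2] + (yy[i2] - thr) / (yy[i2] - yy[i2 + 1]) * (tt[i2 + 1] - tt[i2])
  }

  runs <- rle(above)
  dt <- (tt[length(tt)] - tt[1]) / (length(tt) - 1)
  longest <- max(runs$lengths[runs$values]) * dt

  row(hbt_max = amp, t_rise = t1 - onset, pt = t2 - t1,
      saturation = longest >= saturation_hold_s, censored = censored,
      defined = TRUE)
}

#' Trial features for both inflation trials of a recording
#'
#' @param series A `chromophore_series` spanning the whole protocol.
#' @param schedule The protocol schedule defining the two trial windows.
#' @param ... Passed to [extract_trial_features()].
#' @return A two-row tibble (60 and 100 mmHg trials) with a `trial` column.
#' @export
extract_patch_features <- function(series, schedule, ...) {
  tw <- trial_windows(schedule)
  rows <- lapply(seq_len(nrow(tw)), function(k) {
    extract_trial_features(series, lapply(tw, `[[`, k), ...)
  })
  cols <- lapply(names(rows[[1]]), function(cn) {
    unlist(lapply(rows, `[[`, cn), use.names = FALSE)
  })
  names(cols) <- names(rows[[1]])
  tibble::new_tibble(c(list(trial = seq_along(rows)), cols),
                     nrow = length(rows))
}

#' Patch-level plateau time
#'
#' The plateau time of a patch at one time point is the mean over the two
#' inflation trials. If only one trial produced a defined plateau time that
#' value is used with a warning; if neither did, `NA` is propagated.
#'
#' @param trial_features Tibble of trial features (needs `pt_s`, `defined`).
#' @return A single plateau time in seconds, possibly `NA`.
#' @export
patch_pt <- function(trial_features) {
  ok <- trial_features$defined & !is.na(trial_features$pt_s)
  vals <- trial_features$pt_s[ok]
  if (length(vals) == 0) return(NA_real_)
  if (length(vals) < nrow(trial_features)) {
    rlang::warn("plateau time defined for only one trial; using that trial alone")
  }
  mean(vals)
}

#' Aggregate patch plateau times into Gen and Loc features
#'
#' `Gen` is the arithmetic mean over all patches with a defined plateau
#' time. `Loc` follows the arterial tree in preferential order: the patch(es)
#' on the ulcer's own angiosome, else the patch(es) below the affected
#' artery, else the patch on the nearest artery above it; patients with no
#' patch in any of those positions get an explicit `NA`.
#'
#' @param patch_pts Tibble with `angiosome` and `pt_s` per patch.
#' @param ulcer_angiosome The angiosome carrying the ulcer.
#' @param tree An [angiosome_tree()].
#' @return A one-row tibble: `gen_pt_s`, `loc_pt_s`, `loc_rule`.
#' @export
gen_loc_aggregate <- function(patch_pts, ulcer_angiosome, tree = angiosome_tree()) {
  nodes <- attr(tree, "nodes")
  if (!ulcer_angiosome %in% nodes) {
    abort_config(sprintf("ulcer angiosome '%s' is not in the arterial tree", ulcer_angiosome))
  }
  if (!all(patch_pts$angiosome %in% nodes)) {
    abort_config("patch angiosome label not present in the arterial tree")
  }
  ok <- !is.na(patch_pts$pt_s)
  gen <- if (any(ok)) mean(patch_pts$pt_s[ok]) else NA_real_

  pick <- function(angios) {
    sel <- ok & patch_pts$angiosome %in% angios
    if (any(sel)) mean(patch_pts$pt_s[sel]) else NULL
  }
  loc <- pick(ulcer_angiosome); rule <- "on_ulcer_angiosome"
  if (is.null(loc)) {
    loc <- pick(tree_descendants(tree, ulcer_angiosome)); rule <- "below_affected_artery"
  }
  if (is.null(loc)) {
    for (anc in tree_ancestors(tree, ulcer_angiosome)) {
      loc <- pick(anc)
      if (!is.null(loc)) break
    }
    rule <- "above_affected_artery"
  }
  if (is.null(loc)) {
    loc <- NA_real_; rule <- "unresolved"
  }
  tibble::tibble(gen_pt_s = gen, loc_pt_s = loc, loc_rule = rule)
}

#' Time-point difference features
#'
#' Forms the three plateau-time differences (later minus earlier) for the
#' Gen and Loc aggregates: post minus pre, follow-up minus pre, follow-up
#' minus post. A missing time point yields a missing feature.
#'
#' @param pt_by_timepoint Tibble with `time_point` (`"pre"`, `"post"`,
#'   `"fu1"`), `gen_pt_s`, `loc_pt_s`.
#' @return A one-row tibble with `postpre_gen`, `fu1pre_gen`, `fu1post_gen`
#'   and the `_loc` analogues, in seconds.
#' @export
difference_features <- function(pt_by_timepoint) {
  get <- function(col, tp) {
    v <- pt_by_timepoint[[col]][pt_by_timepoint$time_point == tp]
    if (length(v) == 0) NA_real_ else v[1]
  }
  out <- list()
  for (side in c("gen", "loc")) {
    col <- paste0(side, "_pt_s")
    pre <- get(col, "pre"); post <- get(col, "post"); fu1 <- get(col, "fu1")
    out[[paste0("postpre_", side)]] <- post - pre
    out[[paste0("fu1pre_", side)]] <- fu1 - pre
    out[[paste0("fu1post_", side)]] <- fu1 - post
  }
  tibble::as_tibble(out)
}

#' Per-patient feature table from a synthetic cohort
#'
#' Runs the reconstruction and feature-extraction chain over every recording
#' of a cohort: voltages are unmixed to HbT, trial plateau times extracted,
#' averaged over trials per patch, aggregated to Gen/Loc per time point, and
#' differenced across time points.
#'
#' @param cohort A `dvos_cohort`.
#' @param config Reconstruction settings, an [optical_config()].
#' @param tree The [angiosome_tree()] used for the Loc rule.
#' @param smooth_width,saturation_hold_s Passed to feature extraction.
#' @return A tibble with one row per patient: identity and outcome, the Gen
#'   and Loc plateau times at each time point, the six difference features,
#'   and `censored_any` (whether any trial was right-censored).
#' @export
patient_features <- function(cohort, config = optical_config(),
                             tree = angiosome_tree(),
                             smooth_width = 5, saturation_hold_s = 5) {
  if (!inherits(cohort, "dvos_cohort")) abort_data("`cohort` must be a dvos_cohort")
  if (is.null(cohort$recordings)) {
    abort_data("cohort carries no recordings (generated with recordings = FALSE)")
  }
  schedule <- cohort$schedule
  recs <- cohort$recordings
  rows <- vector("list", nrow(cohort$patients))

  for (i in seq_len(nrow(cohort$patients))) {
    pid <- cohort$patients$patient_id[i]
    ulcer <- cohort$patients$ulcer_angiosome[i]
    sub <- recs[recs$patient_id == pid, ]
    censored_any <- FALSE
    tp_rows <- list()
    for (tp in c("pre", "post", "fu1")) {
      sub_tp <- sub[sub$time_point == tp, ]
      if (nrow(sub_tp) == 0) next
      pts <- vapply(seq_len(nrow(sub_tp)), function(k) {
        series <- reconstruct_recording(sub_tp$recording[[k]], config)
        tf <- extract_patch_features(series, schedule,
                                     smooth_width = smooth_width,
                                     saturation_hold_s = saturation_hold_s)
        censored_any <<- censored_any || any(tf$censored, na.rm = TRUE)
        patch_pt(tf)
      }, numeric(1))
      agg <- gen_loc_aggregate(
        tibble::tibble(angiosome = sub_tp$angiosome, pt_s = pts),
        ulcer, tree)
      tp_rows[[tp]] <- dplyr::mutate(agg, time_point = tp)
    }
    by_tp <- dplyr::bind_rows(tp_rows)
    at <- function(col, tp) {
      v <- by_tp[[col]][by_tp$time_point == tp]
      if (length(v) == 0) NA_real_ else v[1]
    }
    wide <- tibble::tibble(
      pt_pre_gen = at("gen_pt_s", "pre"),
      pt_post_gen = at("gen_pt_s", "post"),
      pt_fu1_gen = at("gen_pt_s", "fu1"),
      pt_pre_loc = at("loc_pt_s", "pre"),
      pt_post_loc = at("loc_pt_s", "post"),
      pt_fu1_loc = at("loc_pt_s", "fu1")
    )
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(patient_id = pid, outcome = cohort$patients$outcome[i]),
      wide,
      difference_features(by_tp),
      tibble::tibble(censored_any = censored_any)
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a feature table as CSV
#'
#' @param features Tibble from [patient_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
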