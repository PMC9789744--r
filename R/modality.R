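#' Cutoff rules mapping modality readings to outcome assignments
#'
#' Each modality assigns outcome 0 (predicted non-healing) on its abnormal
#' side of a literature or ROC-derived cutoff: the optical plateau-time
#' difference below -1.3 s, an ankle-brachial index below 0.9, or a duplex
#' peak-systolic-velocity ratio above 2.4. The inequality is strict, so a
#' reading exactly at the cutoff is assigned outcome 1. The direction
#' conventions are isolated here so they can be flipped in configuration.
#'
#' @param modality Label (`"dvos"`, `"abi"`, `"adus"`, or custom).
#' @param cutoff Finite cutoff value.
#' @param abnormal Side of the cutoff mapped to assigned outcome 0:
#'   `"below"` or `"above"`.
#' @return A one-row `cutoff_rule` tibble.
#' @export
cutoff_rule <- function(modality, cutoff, abnormal = c("below", "above")) {
  abnormal <- match.arg(abnormal)
  if (!is_scalar_number(cutoff)) abort_config("`cutoff` must be a finite number")
  out <- tibble::tibble(modality = modality, cutoff = cutoff, abnormal = abnormal)
  class(out) <- c("cutoff_rule", class(out))
  out
}

#' @rdname cutoff_rule
#' @export
default_cutoff_rules <- function() {
  dplyr::bind_rows(
    cutoff_rule("dvos", -1.3, "below"),
    cutoff_rule("abi", 0.9, "below"),
    cutoff_rule("adus", 2.4, "above")
  )
}

#' Assign outcomes from modality readings
#'
#' @param values Numeric readings; `NA` stays `NA` (missing in, missing
#'   out).
#' @param rule A one-row [cutoff_rule()].
#' @return Integer vector in `{0, 1, NA}`.
#' @examples
#' assign_outcome(c(-7.1, 6.7, NA), cutoff_rule("dvos", -1.3, "below"))
#' @export
assign_outcome <- function(values, rule) {
  if (nrow(rule) != 1) abort_config("`rule` must be a single cutoff rule")
  abn <- if (rule$abnormal == "below") values < rule$cutoff else values > rule$cutoff
  ifelse(is.na(values), NA_integer_, as.integer(!abn))
}

#' Read the bundled clinical truth table
#'
#' Parses the per-patient comparison table of clinical outcome (`co`),
#' optical outcome (`oo`) and the ABI / duplex assignments at follow-up
#' (general and localized), with `X` entries read as explicit missing
#' values. The packaged file transcribes the published 14-patient
#' comparison.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A `truth_table` tibble with agreement columns, via
#'   [build_truth_table()].
#' @export
read_truth_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "clinical_truth_table.csv",
                                package = "dvospt", mustWork = TRUE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("patient", "co", "oo", "abi_gen", "abi_loc", "adus_gen", "adus_loc")
  if (!all(need %in% names(raw))) {
    abort_data(sprintf("truth table must have columns: %s", paste(need, collapse = ", ")))
  }
  parse01 <- function(x, col) {
    x[x %in% c("X", "x", "")] <- NA
    bad <- !is.na(x) & !x %in% c("0", "1")
    if (any(bad)) {
      abort_data(sprintf("malformed truth-table value '%s' in column '%s' (row %d)",
                         x[bad][1], col, which(bad)[1] + 1L))
    }
    as.integer(x)
  }
  tbl <- tibble::tibble(
    patient = raw$patient,
    co = parse01(raw$co, "co"),
    oo = parse01(raw$oo, "oo"),
    abi_gen = parse01(raw$abi_gen, "abi_gen"),
    abi_loc = parse01(raw$abi_loc, "abi_loc"),
    adus_gen = parse01(raw$adus_gen, "adus_gen"),
    adus_loc = parse01(raw$adus_loc, "adus_loc")
  )
  build_truth_table(tbl)
}

modality_columns <- c("oo", "abi_gen", "abi_loc", "adus_gen", "adus_loc")

#' Build a truth table from per-patient assignments
#'
#' Validates the assignment table (unique patients, clinical outcome never
#' missing, binary entries) and adds per-modality agreement indicators
#' (`agree_<modality>` = 1 when the assignment matches the clinical outcome,
#' missing when the assignment is missing).
#'
#' @param assignments Tibble with `patient`, `co`, and any of the modality
#'   columns `oo`, `abi_gen`, `abi_loc`, `adus_gen`, `adus_loc`.
#' @return A `truth_table` tibble.
#' @export
build_truth_table <- function(assignments) {
  if (!all(c("patient", "co") %in% names(assignments))) {
    abort_data("assignments need `patient` and `co` columns")
  }
  if (anyDuplicated(assignments$patient) > 0) abort_data("duplicate patient ids")
  if (anyNA(assignments$co) || !all(assignments$co %in% c(0, 1))) {
    abort_data("clinical outcome `co` must be 0/1 and never missing")
  }
  mods <- intersect(modality_columns, names(assignments))
  if (length(mods) == 0) abort_data("no modality assignment columns present")
  out <- assignments
  for (m in mods) {
    if (!all(out[[m]] %in% c(0L, 1L, NA))) {
      abort_data(sprintf("assignments in '%s' must be 0, 1 or missing", m))
    }
    out[[paste0("agree_", m)]] <- ifelse(is.na(out[[m]]), NA_integer_,
                                         as.integer(out[[m]] == out$co))
  }
  class(out) <- c("truth_table", setdiff(class(out), "truth_table"))
  out
}

#' Truth table for a synthetic cohort
#'
#' Applies the modality cutoff rules to a cohort's realized features and
#' modality panel: the optical assignment uses the follow-up minus
#' postintervention patch-mean plateau-time difference; the ABI and duplex
#' assignments use the follow-up ratios, either averaged over the measured
#' arteries (general) or from the artery nearest the ulcer (localized).
#'
#' @param cohort A `dvos_cohort` (for the panel and ulcer angiosomes).
#' @param features Feature table from [patient_features()].
#' @param rules Cutoff rules, see [default_cutoff_rules()].
#' @return A `truth_table` tibble.
#' @export
truth_table_from_cohort <- function(cohort, features, rules = default_cutoff_rules()) {
  rule_of <- function(mod) rules[rules$modality == mod, ]
  pts <- cohort$patients
  panel <- cohort$panel

  # nearest measured artery per ulcer angiosome, per modality
  abi_loc_map <- c(peroneal = "posterior_tibial", posterior_tibial = "posterior_tibial",
                   anterior_tibial = "dorsalis_pedis", dorsalis_pedis = "dorsalis_pedis",
                   lateral_plantar = "posterior_tibial", medial_plantar = "posterior_tibial")
  adus_loc_map <- c(peroneal = "peroneal", posterior_tibial = "posterior_tibial",
                    anterior_tibial = "anterior_tibial", dorsalis_pedis = "anterior_tibial",
                    lateral_plantar = "posterior_tibial", medial_plantar = "posterior_tibial")

  value_of <- function(pid, mod, artery = NULL) {
    sub <- panel[panel$patient_id == pid & panel$time_point == "fu1" &
                   panel$modality == mod, ]
    if (!is.null(artery)) sub <- sub[sub$artery == artery, ]
    if (nrow(sub) == 0 || anyNA(sub$ratio)) NA_real_ else mean(sub$ratio)
  }

  feats <- features[match(pts$patient_id, features$patient_id), ]
  rows <- tibble::tibble(
    patient = pts$patient_id,
    co = pts$outcome,
    oo = assign_outcome(feats$fu1post_gen, rule_of("dvos")),
    abi_gen = assign_outcome(
      vapply(pts$patient_id, value_of, numeric(1), mod = "abi",
             USE.NAMES = FALSE), rule_of("abi")),
    abi_loc = assign_outcome(
      vapply(seq_len(nrow(pts)), function(i) {
        value_of(pts$patient_id[i], "abi", abi_loc_map[[pts$ulcer_angiosome[i]]])
      }, numeric(1)), rule_of("abi")),
    adus_gen = assign_outcome(
      vapply(pts$patient_id, value_of, numeric(1), mod = "adus",
             USE.NAMES = FALSE), rule_of("adus")),
    adus_loc = assign_outcome(
      vapply(seq_len(nrow(pts)), function(i) {
        value_of(pts$patient_id[i], "adus", adus_loc_map[[pts$ulcer_angiosome[i]]])
      }, numeric(1)), rule_of("adus"))
  )
  build_truth_table(rows)
}

#' Score each modality against the clinical outcome
#'
#' Confusion metrics per modality over the patients with that modality
#' available; subset sizes are reported alongside so the modalities'
#' differing availability stays visible.
#'
#' @param table A `truth_table`.
#' @param modalities Modality columns to score (those present by default).
#' @return A tibble with one row per modality: `n_available`,
#'   `n_misclassified`, the confusion counts and the four rates (proportions
#'   and rounded percentages).
#' @export
score_modalities <- function(table, modalities = NULL) {
  modalities <- modalities %||% intersect(modality_columns, names(table))
  rows <- lapply(modalities, function(m) {
    ok <- !is.na(table[[m]])
    if (!any(ok)) {
      return(tibble::tibble(modality = m, n_available = 0L))
    }
    cm <- confusion_metrics(table[[m]][ok], table$co[ok])
    dplyr::mutate(tidy(cm), modality = m, n_available = sum(ok), .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Availability accounting for a truth table
#'
#' @param table A `truth_table`.
#' @return A list with the clinical outcome counts (`n_positive`,
#'   `n_negative`) and a tibble of per-modality availability.
#' @export
availability_counts <- function(table) {
  mods <- intersect(modality_columns, names(table))
  list(
    n_positive = sum(table$co == 1),
    n_negative = sum(table$co == 0),
    by_modality = tibble::tibble(
      modality = mods,
      n_available = vapply(mods, function(m) sum(!is.na(table[[m]])), integer(1),
                           USE.NAMES = FALSE)
    )
  )
}
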