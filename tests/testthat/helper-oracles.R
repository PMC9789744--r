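# Independent oracles used across tests. These are deliberately naive
# implementations (dense grids, exhaustive enumeration) kept separate from
# the package's own code paths.

# Read the two 90%-of-max crossings off a (dense) time/value grid by linear
# interpolation, referenced to the first value in the window.
oracle_pt <- function(time_s, hbt, onset, end) {
  keep <- time_s >= onset & time_s <= end
  t <- time_s[keep]
  y <- hbt[keep] - hbt[keep][1]
  thr <- 0.9 * max(y)
  up <- which(y >= thr)
  i1 <- up[1]
  i2 <- up[length(up)]
  t1 <- if (i1 == 1) t[1] else {
    t[i1 - 1] + (thr - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * (t[i1] - t[i1 - 1])
  }
  t2 <- if (i2 == length(y)) t[length(t)] else {
    t[i2] + (y[i2] - thr) / (y[i2] - y[i2 + 1]) * (t[i2 + 1] - t[i2])
  }
  t2 - t1
}

# AUC by exhaustive pair counting (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Youden-optimal cutoff by exhaustive search over midpoint thresholds, with
# the same declared tie-break chain: max J, then closest to (0, 1), then the
# larger cutoff.
oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  best <- NULL
  for (ct in thr) {
    se <- mean(scores[labels == 1] >= ct)
    sp <- mean(scores[labels == 0] < ct)
    j <- se + sp - 1
    d <- (1 - sp)^2 + (1 - se)^2
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && d < best$d - 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(d - best$d) <= 1e-12 && ct > best$ct)) {
      best <- list(ct = ct, j = j, d = d, se = se, sp = sp)
    }
  }
  best
}

# Spearman coefficient as Pearson on hand-built ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Plain tibble that quacks like a chromophore series for feature extraction.
toy_series <- function(time_s, hbt) {
  tibble::tibble(time_s = time_s, dHbT_uM = hbt)
}

# Small, fast cohort spec used where the exact study size is not the point.
tiny_cohort_spec <- function(seed, ...) {
  cohort_spec(n_positive = 2, n_negative = 2, patch_counts = 4, seed = seed, ...)
}
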