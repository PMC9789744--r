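# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn
NULL

# Percentages in reports are rounded half-up (8/9 -> 89%), not to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic sub-stream seeds derived from a single run seed, kept inside
# the 32-bit integer range R requires.
mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) {
    s <- (s * 69069 + (abs(p) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(s)
}

abort_config <- function(msg) rlang::abort(msg, class = "dvospt_config_error")
abort_data <- function(msg) rlang::abort(msg, class = "dvospt_data_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort_config(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}
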