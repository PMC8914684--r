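# internal helpers

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    .stopf("`%s` must be a single positive finite number", name)
  invisible(x)
}

.assert_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("`%s` must be a single finite number", name)
  invisible(x)
}

# clamp a scalar to [lo, hi], warning when it had to move
.clamp_warn <- function(x, lo, hi, name) {
  if (x < lo || x > hi) {
    .warnf("`%s` = %g outside [%g, %g]; clamped", name, x, lo, hi)
    x <- min(max(x, lo), hi)
  }
  x
}

.match_mode <- function(mode) match.arg(mode, c("pregnant", "postpartum"))
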