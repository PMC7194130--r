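# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop <- function(...) stop(..., call. = FALSE)

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) .stop(...)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
}

# Aspect labels are a closed set; anything else is rejected rather than
# guessed (no mapping of "NE", lowercase, degrees, ...).
ASPECTS <- c("N", "S", "E", "W")

.check_aspect <- function(x) {
  bad <- setdiff(unique(as.character(x)), ASPECTS)
  .assert(length(bad) == 0L,
          "invalid aspect label(s): ", paste(bad, collapse = ", "),
          " (allowed: N, S, E, W)")
  invisible(TRUE)
}

# Tiny polynomial string hash, used only to fingerprint run configurations
# in output metadata headers (keeps outputs byte-identical across reruns,
# unlike a timestamp).
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Standard error of the mean.
.se <- function(x) stats::sd(x) / sqrt(length(x))
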