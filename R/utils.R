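#' @keywords internal
"_PACKAGE"

# Round half away from zero (round() in R rounds half to even, which is not
# reproducible across languages for .5 ties).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a stream of child seeds from one master seed without touching the
# global RNG state outside the call.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# Polynomial rolling hash (mod 2^31 - 1) of a character string; used to
# fingerprint run configurations inside output JSON.
config_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  m <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% m
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
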