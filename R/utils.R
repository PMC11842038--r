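# small shared helpers: dB bookkeeping, windows, seed plumbing

#' Convert dB (re 1 microvolt) to microvolt
#'
#' Inverse of the `20*log10` transformation with 1 uV as the reference, as used
#' when reanalysing EFR growth data reported on a dB scale.
#'
#' @param db numeric vector of levels in dB re 1 uV.
#' @return amplitude(s) in uV.
#' @examples
#' db_to_microvolt(c(0, -20, 6.0206))
#' @export
db_to_microvolt <- function(db) 10^(db / 20)

#' @rdname db_to_microvolt
#' @param uv amplitude(s) in uV.
#' @export
microvolt_to_db <- function(uv) 20 * log10(uv)

#' Tapered-cosine (Tukey) window
#'
#' Raised-cosine ramps over the first and last `fraction/2` of the samples,
#' flat (exactly 1) in between. `fraction = 0` gives a rectangular window,
#' `fraction = 1` a full raised-cosine (Hann-shaped) window. Ramp endpoints
#' are exactly 0.
#'
#' @param n window length in samples.
#' @param fraction total fraction of samples tapered, in \[0, 1\].
#' @return numeric vector of length `n`.
#' @export
tukey_window <- function(n, fraction) {
  stopifnot(n >= 1, fraction >= 0, fraction <= 1)
  w <- rep(1, n)
  m <- round(fraction * n / 2)
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * (0:(m - 1)) / m))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
  }
  w
}

# derive a bounded child seed from a user seed and a stage offset
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

# tiny FNV-1a checksum used to stamp configs in run manifests
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
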