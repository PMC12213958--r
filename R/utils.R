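#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit seed for subject `idx` under master seed `master`.
# Knuth-style multiplicative mix; exact in double precision (< 2^53).
derive_seed <- function(master, idx) {
  m <- as.numeric(master) %% 2147483647
  s <- (m * 48271 + as.numeric(idx) * 69621 + 11) %% 2147483629
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Average-reference centering matrix H = I - 11'/n.
centering_matrix <- function(n) {
  diag(n) - matrix(1 / n, n, n)
}

# Row-wise unit normalisation of an n x 3 matrix.
unit_rows <- function(x) {
  nr <- sqrt(rowSums(x^2))
  if (any(nr == 0)) stopf("cannot normalise a zero vector")
  x / nr
}

vec_norm <- function(x) sqrt(sum(x^2))

# ms <-> sample index for an epoch starting at t0_ms sampled at fs_hz.
# Sample 1 corresponds to t0_ms.
ms_to_sample <- function(ms, fs_hz, t0_ms) {
  as.integer(round((ms - t0_ms) * fs_hz / 1000)) + 1L
}

sample_to_ms <- function(i, fs_hz, t0_ms) {
  t0_ms + (i - 1) * 1000 / fs_hz
}

epoch_times_ms <- function(fs_hz, t0_ms, n_samples) {
  t0_ms + (seq_len(n_samples) - 1) * 1000 / fs_hz
}
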