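# Orthogonal discrete wavelet transform used for denoising. The signal is
# symmetrically extended to a multiple of 2^level, a periodized pyramid with
# the 8-tap Daubechies-4 filters is applied (exact reconstruction), selected
# bands are zeroed, and the extension is stripped on the way out.

# db4 decomposition low-pass filter (8 taps, 4 vanishing moments)
db4_dec_lo <- function() {
  c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
    -0.187034811718881140, -0.027983769416983850, 0.630880767929590400,
    0.714846570552541500, 0.230377813308855230)
}

wavelet_filters <- function(wavelet = "db4") {
  if (!identical(wavelet, "db4")) stop("unsupported wavelet: ", wavelet)
  h <- db4_dec_lo()
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)   # quadrature mirror high-pass
  list(h = h, g = g)
}

# one periodized analysis step: x (even length) -> list(a, d) of half length
dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n %/% 2
  k2 <- 2 * (seq_len(half) - 1)
  a <- numeric(half); d <- numeric(half)
  for (m in seq_along(h)) {
    xm <- x[(k2 + m - 1) %% n + 1]
    a <- a + h[m] * xm
    d <- d + g[m] * xm
  }
  list(a = a, d = d)
}

# inverse of dwt_step
idwt_step <- function(a, d, h, g) {
  n <- 2 * length(a)
  x <- numeric(n)
  k2 <- 2 * (seq_along(a) - 1)
  for (m in seq_along(h)) {
    j <- (k2 + m - 1) %% n + 1
    contrib <- h[m] * a + g[m] * d
    # j values are distinct within one m (stride 2 shifts), safe to accumulate
    x[j] <- x[j] + contrib
  }
  x
}

# symmetric (half-point) extension of x to length n_target
extend_symmetric <- function(x, n_target) {
  n <- length(x)
  if (n >= n_target) return(x[seq_len(n_target)])
  period <- c(x, rev(x))
  rep_len(period, n_target)
}

#' Multi-level discrete wavelet decomposition
#'
#' Decomposes a signal into `level` detail bands plus a final approximation,
#' using the Daubechies-4 filter pair on a symmetric extension of the signal
#' to the next multiple of `2^level` (periodized at that length, so the
#' transform is exactly invertible by [dwt_inverse()]).
#'
#' @param x numeric signal (finite values)
#' @param level decomposition depth
#' @param wavelet only "db4"
#' @return list with `a` (deepest approximation), `d` (list of detail bands,
#'   element 1 = finest), `n` (original length), `level`, `wavelet`.
#' @export
dwt_decompose <- function(x, level, wavelet = "db4") {
  if (any(!is.finite(x))) stop("signal contains non-finite samples")
  flt <- wavelet_filters(wavelet)
  n <- length(x)
  block <- 2^level
  n_pad <- ceiling(max(n, 8) / block) * block
  a <- extend_symmetric(x, n_pad)
  d <- vector("list", level)
  for (j in seq_len(level)) {
    s <- dwt_step(a, flt$h, flt$g)
    a <- s$a
    d[[j]] <- s$d
  }
  list(a = a, d = d, n = n, level = level, wavelet = wavelet)
}

#' @rdname dwt_decompose
#' @param dec a decomposition from [dwt_decompose()], possibly with bands
#'   zeroed
#' @export
dwt_inverse <- function(dec) {
  flt <- wavelet_filters(dec$wavelet)
  a <- dec$a
  for (j in rev(seq_len(dec$level))) {
    a <- idwt_step(a, dec$d[[j]], flt$h, flt$g)
  }
  a[seq_len(dec$n)]
}

#' Remove baseline wander by wavelet decomposition
#'
#' Level-9 Daubechies-4 decomposition; the deepest approximation band (which
#' at 360 Hz covers roughly 0-0.35 Hz, where baseline drift lives) is zeroed
#' before reconstruction, so slow wander is subtracted while the QRS
#' morphology passes through.
#'
#' @param signal numeric ECG signal in mV
#' @param fs sampling rate in Hz (documentation of band edges; the band
#'   split itself is dyadic in `fs`)
#' @param level decomposition depth (default 9)
#' @param wavelet mother wavelet name
#' @return The drift-free signal, same length as the input.
#' @export
remove_baseline <- function(signal, fs, level = 9, wavelet = "db4") {
  dec <- dwt_decompose(signal, level, wavelet)
  dec$a[] <- 0
  dwt_inverse(dec)
}

#' Remove high-frequency noise by wavelet decomposition
#'
#' Level-6 Daubechies-4 decomposition; every detail band whose upper edge
#' `fs / 2^j` reaches `cut_hz` is zeroed. At 360 Hz with the default 45 Hz
#' cut this removes the three finest bands (nominally 22.5-45, 45-90 and
#' 90-180 Hz). The nominally sub-45 band must go too: db4's band edges are
#' soft, so a mains-frequency tone leaks substantially into it and would
#' otherwise survive. The zeroed-band reconstruction is an orthogonal
#' projection, hence exactly idempotent.
#'
#' @inheritParams remove_baseline
#' @param cut_hz frequency above which content is suppressed (default 45)
#' @return The filtered signal, same length as the input.
#' @export
remove_highfreq <- function(signal, fs, level = 6, wavelet = "db4",
                            cut_hz = 45) {
  zero <- which(fs / 2^seq_len(level) >= cut_hz)
  if (length(zero) == 0) return(signal + 0)
  # bands deeper than the deepest zeroed one pass through unchanged, so the
  # pyramid only needs to reach that depth; this keeps the operator an exact
  # orthogonal projection (idempotent) whenever 2^depth divides the length
  depth <- max(zero)
  dec <- dwt_decompose(signal, depth, wavelet)
  for (j in zero) dec$d[[j]][] <- 0
  dwt_inverse(dec)
}
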