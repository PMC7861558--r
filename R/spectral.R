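# Stationary-fluctuation analysis: Welch power spectral density of the
# pole difference A1 - A2 and the coherence-resonance metric.

#' Welch power spectral density
#'
#' Averaged-periodogram estimate from overlapping, Hann-tapered segments
#' (50% overlap by default), one-sided, with density normalization: the
#' integral of the PSD over frequency equals the series mean power (its
#' variance when `detrend = "constant"`), up to windowing leakage.
#'
#' By default segments are *not* demeaned, so the zero-frequency bin
#' carries the DC power of the series. This matters for the
#' coherence-resonance metric: the polarity fluctuation A1 - A2 of a
#' polarized cell has a large mean, and the peak-to-zero-frequency ratio is
#' defined against that total zero-frequency power.
#'
#' @param x uniformly sampled series.
#' @param dt sampling interval, min.
#' @param segment_length samples per segment (default 2^14).
#' @param overlap fractional overlap between segments.
#' @param detrend `"none"` (default) or `"constant"` (demean each segment).
#' @return data frame with columns `freq` (cycles/min) and `psd`
#'   (power per cycles/min).
#' @export
welch_psd <- function(x, dt, segment_length = 2^14, overlap = 0.5,
                      detrend = c("none", "constant")) {
  detrend <- match.arg(detrend)
  n <- length(x)
  L <- as.integer(segment_length)
  if (n < L) stop("series shorter than one segment")
  hop <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / L))  # periodic Hann
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    if (detrend == "constant") seg <- seg - mean(seg)
    seg <- seg * w
    sp <- abs(fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / length(starts) * dt / U
  # one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2L == 0L) dbl[nf] <- 1
  psd <- psd * dbl
  data.frame(freq = (seq_len(nf) - 1L) / (L * dt), psd = psd)
}

#' Coherence-resonance metric of a PSD
#'
#' Ratio of the maximal power density over nonzero frequencies to the power
#' at zero frequency. Values above 1 indicate a finite-frequency peak: the
#' stochastic dynamics has a preferred switching frequency. Plotted against
#' the noise level this ratio is non-monotonic, with an interior maximum at
#' intermediate noise (coherence resonance).
#'
#' @param psd data frame from [welch_psd()], including the zero-frequency
#'   bin.
#' @return scalar ratio (>= 0), or `NA` with a warning if the power at zero
#'   frequency is zero.
#' @export
coherence_metric <- function(psd) {
  stopifnot(is.data.frame(psd), psd$freq[1] == 0)
  p0 <- psd$psd[1]
  if (p0 == 0) {
    warning("zero power at zero frequency; coherence metric undefined")
    return(NA_real_)
  }
  max(psd$psd[-1]) / p0
}

#' PSD of the polarity fluctuation of a trajectory
#'
#' Convenience wrapper: Welch PSD of A1(t) - A2(t).
#'
#' @param traj a `polarity_trajectory` sampled at uniform intervals.
#' @param segment_length samples per segment.
#' @param detrend passed to [welch_psd()].
#' @return as [welch_psd()].
#' @export
polarity_psd <- function(traj, segment_length = 2^14, detrend = "none") {
  dt <- stats::median(diff(traj$time))
  welch_psd(traj$A1 - traj$A2, dt = dt, segment_length = segment_length,
            detrend = detrend)
}

#' Coherence metric across noise levels
#'
#' Simulates one no-signal stochastic trajectory per noise level from the
#' polarized state and computes the peak-to-zero-frequency PSD ratio of
#' A1 - A2 for each.
#'
#' @param params a `polarity_params` vector.
#' @param N_levels numeric vector of copy-number parameters.
#' @param T_trace trajectory length per level, min.
#' @param seed base seed (level i uses seed + i).
#' @param segment_length Welch segment length in samples (sampling interval
#'   0.01 min).
#' @return data frame with columns `N` and `ratio`.
#' @export
coherence_sweep <- function(params, N_levels, T_trace = 2000, seed = 1L,
                            segment_length = 2^14) {
  initial <- relax_to_polarized(params, orientation = "pole1")
  rows <- lapply(seq_along(N_levels), function(i) {
    nc <- noise_config(N = N_levels[i], seed = seed + i)
    traj <- simulate_stochastic(initial, params, scenario = NULL,
                                t_span = c(0, T_trace), noise = nc)
    psd <- polarity_psd(traj, segment_length = segment_length)
    data.frame(N = N_levels[i], ratio = coherence_metric(psd))
  })
  do.call(rbind, rows)
}
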