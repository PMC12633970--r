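#' Specification of the 1/f^beta background synaptic current
#'
#' The background synaptic bombardment is modelled as an additive current
#' whose power spectrum falls off as 1/f^beta over a frequency band
#' \[f_min, f_max\]; beta = 0 is white noise, beta = 1 pink, beta = 2
#' Brownian-like.  The series is built in the frequency domain (spectrum
#' magnitude times a uniformly random phase), inverse-Fourier transformed,
#' standardised to unit variance and scaled by the total noise intensity
#' \code{sigma_eta}.
#'
#' @param beta spectral exponent (>= 0).
#' @param sigma_eta total noise intensity (standard deviation of the
#'   resulting current, uA/cm^2).
#' @param duration series duration (s).
#' @param sample_rate sampling rate (Hz).
#' @param seed integer seed.
#' @param f_min,f_max band limits (Hz); power outside the band (including
#'   DC) is zero.  \code{f_min} defaults to 1/duration.
#' @return an object of class \code{noise_spec}.
#' @export
noise_spec <- function(beta = 1, sigma_eta = 1, duration = 5,
                       sample_rate = 10000, seed = 1,
                       f_min = NULL, f_max = NULL) {
  f_min <- f_min %||% (1 / duration)
  f_max <- f_max %||% (sample_rate / 2)
  check(is_number(duration) && duration > 0, "duration must be > 0")
  check(is_number(sample_rate) && sample_rate > 0, "sample_rate must be > 0")
  check(is_number(sigma_eta) && sigma_eta >= 0, "sigma_eta must be >= 0")
  check(is_number(beta) && beta >= 0, "beta must be >= 0")
  check(f_min < f_max && f_max <= sample_rate / 2,
        "band must satisfy f_min < f_max <= sample_rate/2")
  structure(list(beta = beta, sigma_eta = sigma_eta, duration = duration,
                 sample_rate = sample_rate, seed = seed,
                 f_min = f_min, f_max = f_max),
            class = "noise_spec")
}

#' Synthesise a 1/f^beta noise current
#'
#' Random-phase spectral synthesis: the one-sided spectrum magnitude is
#' set to f^(-beta/2) inside the band and 0 outside, multiplied by
#' exp(i phi) with phi uniform on \[0, 2 pi), mirrored to a Hermitian
#' spectrum and inverse-transformed.  The real series is standardised and
#' scaled so that its sample standard deviation is exactly
#' \code{sigma_eta} (scaling is linear in \code{sigma_eta} for a fixed
#' seed).
#'
#' @param spec a \code{noise_spec}.
#' @return numeric vector of length \code{duration * sample_rate}.
#' @export
synthesize_noise <- function(spec) {
  check(inherits(spec, "noise_spec"), "spec must be a noise_spec")
  n <- round(spec$duration * spec$sample_rate)
  if (spec$sigma_eta == 0) return(numeric(n))
  freqs <- seq(0, n %/% 2) / spec$duration
  amp <- numeric(length(freqs))
  inband <- freqs >= spec$f_min & freqs <= spec$f_max & freqs > 0
  amp[inband] <- freqs[inband]^(-spec$beta / 2)
  phases <- withr_seed(spec$seed, runif(length(freqs), 0, 2 * pi))
  half <- amp * exp(1i * phases)
  half[1] <- 0                       # zero mean by construction
  # Hermitian mirror (drop Nyquist duplicate for even n)
  full <- c(half, Conj(rev(half[2:(n - length(half) + 1)])))
  x <- Re(fft(full, inverse = TRUE))
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s * spec$sigma_eta
}

#' Welch-style log-log spectral slope of a series
#'
#' Averages periodograms over non-overlapping segments and regresses
#' log power on log frequency inside a band; used to audit the spectral
#' exponent of synthesised noise (slope approximately -beta).
#'
#' @param x numeric series.
#' @param sample_rate Hz.
#' @param f_min,f_max regression band (Hz).
#' @param n_seg number of segments to average.
#' @return fitted slope (dimensionless).
#' @export
psd_slope <- function(x, sample_rate, f_min = 1, f_max = sample_rate / 4,
                      n_seg = 8) {
  seg_len <- floor(length(x) / n_seg)
  check(seg_len >= 16, "series too short for the requested segmentation")
  nf <- seg_len %/% 2
  freqs <- seq_len(nf) * sample_rate / seg_len
  pxx <- rowMeans(vapply(seq_len(n_seg), function(i) {
    seg <- x[((i - 1) * seg_len + 1):(i * seg_len)]
    p <- Mod(fft(seg - mean(seg)))^2 / seg_len
    p[2:(nf + 1)]
  }, numeric(nf)))
  sel <- freqs >= f_min & freqs <= f_max & pxx > 0
  check(sum(sel) >= 8, "too few in-band frequencies")
  unname(coef(lm(log(pxx[sel]) ~ log(freqs[sel])))[2])
}

#' Export a noise series to CSV
#'
#' Columns \code{t_s} and \code{I_syn}.
#' @param x series from \code{\link{synthesize_noise}}.
#' @param spec the \code{noise_spec} that produced it.
#' @param path file to write.
#' @export
write_noise_csv <- function(x, spec, path) {
  write.csv(data.frame(t_s = (seq_along(x) - 1) / spec$sample_rate,
                       I_syn = x), path, row.names = FALSE)
  invisible(path)
}
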