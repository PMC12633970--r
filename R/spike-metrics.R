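#' Construct a spike train
#'
#' @param spike_times spike times (s), strictly increasing, within
#'   \[0, duration\].
#' @param duration recording duration (s).
#' @param source "recording" or "simulation".
#' @return an object of class \code{spike_train}.
#' @export
spike_train <- function(spike_times, duration, source = "simulation") {
  check(is_number(duration) && duration > 0, "duration must be > 0")
  check(all(diff(spike_times) > 0), "spike times must be strictly increasing")
  check(all(spike_times >= 0 & spike_times <= duration),
        "spike times must lie in [0, duration]")
  structure(list(spike_times = as.numeric(spike_times), duration = duration,
                 source = source), class = "spike_train")
}

#' Threshold-based spike detection
#'
#' Spikes are placed at the local maxima of threshold-exceeding
#' excursions of the voltage trace.  The default threshold of -30 mV (in
#' absolute trace units) is the detection level used for intracellular
#' data and the biophysical model, whose baseline sits near -70 mV; use
#' \code{threshold = 0} for the dimensionless Hindmarsh-Rose voltage.
#' For traces with an unusual resting level, \code{baseline_relative =
#' TRUE} re-interprets \code{threshold} as a positive excursion above the
#' trace median (e.g. 40 mV), which transfers across cells.  Detections
#' closer than \code{min_separation} (default 1 ms) are merged keeping
#' the larger peak, suppressing double counts on noisy peaks.
#'
#' @param trace data frame with columns \code{t_s} (uniform sampling) and
#'   \code{v}.
#' @param threshold detection threshold in trace units (a positive
#'   excursion above the median when \code{baseline_relative}).
#' @param min_separation minimum inter-detection separation (s).
#' @param baseline_relative interpret \code{threshold} as an excursion
#'   above the trace median.
#' @return a \code{spike_train} (possibly empty).
#' @export
detect_spikes <- function(trace, threshold = -30, min_separation = 0.001,
                          baseline_relative = FALSE) {
  check(is.data.frame(trace) && all(c("t_s", "v") %in% names(trace)),
        "trace must have columns t_s and v")
  check(nrow(trace) > 0, "empty trace")
  v <- trace$v; t <- trace$t_s
  thr <- if (baseline_relative) median(v) + threshold else threshold
  above <- v > thr
  if (!any(above))
    return(spike_train(numeric(0), duration = t[length(t)]))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peaks <- vapply(which(r$values), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(v[seg])]
  }, integer(1))
  # merge peaks closer than min_separation, keeping the larger
  if (length(peaks) > 1) {
    keep <- peaks[1]
    for (pk in peaks[-1]) {
      last <- keep[length(keep)]
      if (t[pk] - t[last] < min_separation) {
        if (v[pk] > v[last]) keep[length(keep)] <- pk
      } else keep <- c(keep, pk)
    }
    peaks <- keep
  }
  spike_train(t[peaks], duration = t[length(t)])
}

#' Action-potential waveform features
#'
#' Isolates a window (default +/- 4 ms) around each spike peak and
#' extracts: the spike threshold (voltage where dV/dt first exceeds an
#' onset criterion on the rising phase), the peak voltage, the post-peak
#' trough (window minimum after the peak), the voltages at 50% amplitude
#' of the upstroke (threshold-to-peak) and downstroke (peak-to-trough)
#' phases, and the afterdepolarisation voltage \code{adp_v} (post-trough
#' local maximum; NA when the post-trough segment is monotone, and such
#' spikes are excluded from ADP statistics downstream).  Spikes whose
#' window would be clipped at a trace boundary are excluded.
#'
#' @param trace data frame with \code{t_s}, \code{v}.
#' @param spikes a \code{spike_train} from \code{\link{detect_spikes}}.
#' @param window half-window around each peak (s).
#' @param dvdt_threshold onset criterion for the spike threshold (V/s).
#' @return data frame of class \code{ap_feature_table}: one row per
#'   unclipped spike with columns \code{spike_time}, \code{threshold_v},
#'   \code{upstroke_v}, \code{peak_v}, \code{downstroke_v},
#'   \code{trough_v}, \code{adp_v}.
#' @export
extract_ap_features <- function(trace, spikes, window = 0.004,
                                dvdt_threshold = 20) {
  check(nrow(trace) >= 3, "trace too short")
  dt <- trace$t_s[2] - trace$t_s[1]
  check(window > dt, "window must exceed one sample step")
  check(window < (trace$t_s[nrow(trace)] - trace$t_s[1]) / 2,
        "window larger than trace")
  half <- round(window / dt)
  n <- nrow(trace)
  rows <- lapply(spikes$spike_times, function(ts) {
    i <- which.min(abs(trace$t_s - ts))
    if (i - half < 1 || i + half > n) return(NULL)   # clipped
    seg <- trace$v[(i - half):(i + half)]
    pk <- half + 1
    # local peak refinement inside the window
    pk <- which.max(seg[max(1, pk - 3):min(length(seg), pk + 3)]) +
      max(1, pk - 3) - 1
    dvdt <- c(NA, diff(seg)) / dt            # V units per second
    thr_idx <- NA
    for (j in seq(pk, 2)) {
      if (!is.na(dvdt[j]) && dvdt[j] < dvdt_threshold * 1000) {
        thr_idx <- j; break
      }
    }
    if (is.na(thr_idx)) thr_idx <- 1
    threshold_v <- seg[thr_idx]
    peak_v <- seg[pk]
    post <- seg[pk:length(seg)]
    tr_rel <- which.min(post)
    trough_v <- post[tr_rel]
    after <- post[tr_rel:length(post)]
    adp_v <- NA_real_
    if (length(after) >= 3) {
      da <- diff(after)
      rises <- which(da > 0)
      if (length(rises)) {
        # local maximum after the first rise
        fall_after <- which(da < 0 & seq_along(da) > rises[1])
        j <- if (length(fall_after)) fall_after[1] else length(after)
        if (after[j] > trough_v + 1e-12) adp_v <- after[j]
      }
    }
    data.frame(spike_time = ts,
               threshold_v = threshold_v,
               upstroke_v = (threshold_v + peak_v) / 2,
               peak_v = peak_v,
               downstroke_v = (peak_v + trough_v) / 2,
               trough_v = trough_v,
               adp_v = adp_v)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(spike_time = numeric(0), threshold_v = numeric(0),
                      upstroke_v = numeric(0), peak_v = numeric(0),
                      downstroke_v = numeric(0), trough_v = numeric(0),
                      adp_v = numeric(0))
  class(out) <- c("ap_feature_table", "data.frame")
  out
}

#' Scott's-rule bandwidth
#'
#' h = sigma-hat n^(-1/5) for a Gaussian kernel in one dimension.
#' @param x numeric sample.
#' @return bandwidth.
#' @export
bw_scott <- function(x) sd(x) * length(x)^(-1 / 5)

#' Interspike-interval distribution estimate
#'
#' Histogram (2 ms bins by default), Gaussian kernel density estimate
#' with Scott's-rule bandwidth, and a bootstrap error band: the KDE is
#' recomputed on \code{n_boot} random sub-segments (default 50 resamples
#' of 4-s segments) and the variance around the mean KDE forms the band.
#'
#' @param spikes a \code{spike_train} with at least 2 spikes.
#' @param bin_width histogram bin width (s).
#' @param n_boot number of bootstrap resamples.
#' @param segment bootstrap segment length (s); capped at the recording
#'   duration.
#' @param seed seed for the bootstrap segment draws.
#' @return list with \code{isis}, \code{breaks}, \code{counts},
#'   \code{kde} (data frame x, y), \code{kde_sd} (bootstrap standard
#'   deviation on the same grid), \code{bw}.
#' @export
isi_distribution <- function(spikes, bin_width = 0.002, n_boot = 50,
                             segment = 4, seed = 1) {
  isis <- diff(spikes$spike_times)
  check(length(isis) >= 1, "need at least 2 spikes for an ISI distribution")
  breaks <- seq(0, max(isis) + bin_width, by = bin_width)
  counts <- graphics::hist(isis, breaks = breaks, plot = FALSE)$counts
  bw <- if (length(isis) > 1 && sd(isis) > 0) bw_scott(isis) else bin_width
  grid_to <- max(isis) + 4 * bw
  kde <- density(isis, bw = bw, kernel = "gaussian", from = 0, to = grid_to,
                 n = 512)
  kde_sd <- rep(NA_real_, 512)
  seg <- min(segment, spikes$duration)
  if (n_boot > 0 && spikes$duration > 0) {
    mats <- withr_seed(seed, {
      lapply(seq_len(n_boot), function(b) {
        t0 <- runif(1, 0, max(0, spikes$duration - seg))
        sel <- spikes$spike_times[spikes$spike_times >= t0 &
                                  spikes$spike_times <= t0 + seg]
        bi <- diff(sel)
        if (length(bi) < 2 || sd(bi) == 0) return(NULL)
        density(bi, bw = bw, from = 0, to = grid_to, n = 512)$y
      })
    })
    mats <- Filter(Negate(is.null), mats)
    if (length(mats) >= 2)
      kde_sd <- apply(do.call(cbind, mats), 1, sd)
  }
  list(isis = isis, breaks = breaks, counts = counts,
       kde = data.frame(x = kde$x, y = kde$y), kde_sd = kde_sd, bw = bw)
}

#' Partition spikes into bursts and isolated spikes
#'
#' A burst is a maximal run of two or more spikes in which every
#' consecutive interspike interval falls below the threshold (default
#' 12 ms, the conventional separator of intra-burst from isolated spikes
#' in ELL pyramidal cells).  The burst fraction is the ratio of spikes
#' inside bursts to the total spike count.
#'
#' @param spikes a \code{spike_train}.
#' @param isi_threshold burst ISI threshold (s), > 0.
#' @return list with \code{labels} ("burst"/"isolated" per spike),
#'   \code{bursts} (list of spike-index vectors), \code{burst_fraction},
#'   \code{burst_sizes}.
#' @export
burst_partition <- function(spikes, isi_threshold = 0.012) {
  check(is_number(isi_threshold) && isi_threshold > 0,
        "isi_threshold must be > 0")
  n <- length(spikes$spike_times)
  if (n == 0)
    return(list(labels = character(0), bursts = list(),
                burst_fraction = 0, burst_sizes = integer(0)))
  labels <- rep("isolated", n)
  bursts <- list()
  if (n >= 2) {
    short <- diff(spikes$spike_times) < isi_threshold
    r <- rle(short)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      idx <- starts[i]:(ends[i] + 1)        # ISI run -> spike run
      bursts[[length(bursts) + 1]] <- idx
      labels[idx] <- "burst"
    }
  }
  list(labels = labels, bursts = bursts,
       burst_fraction = sum(labels == "burst") / n,
       burst_sizes = vapply(bursts, length, integer(1)))
}

#' Estimate a per-cell burst threshold from the ISI density
#'
#' Locates the local minimum of the ISI KDE between its two largest
#' modes; falls back to the fixed default when the density is unimodal.
#'
#' @param spikes a \code{spike_train}.
#' @param default fallback threshold (s).
#' @return threshold (s).
#' @export
estimate_burst_threshold <- function(spikes, default = 0.012) {
  if (length(spikes$spike_times) < 10) return(default)
  d <- isi_distribution(spikes, n_boot = 0)
  y <- d$kde$y; x <- d$kde$x
  pk <- which(diff(sign(diff(y))) == -2) + 1
  if (length(pk) < 2) return(default)
  pk <- pk[order(y[pk], decreasing = TRUE)][1:2]
  lo <- min(pk); hi <- max(pk)
  x[lo + which.min(y[lo:hi]) - 1]
}

#' Summary statistics of a spike train
#'
#' Mean firing rate (count/duration), ISI mean, median, standard
#' deviation (sample, n-1 denominator) and coefficient of variation, and
#' the burst fraction at the given threshold.
#'
#' @param spikes a \code{spike_train}.
#' @param isi_threshold burst ISI threshold (s).
#' @return object of class \code{spike_train_stats}: named list with
#'   \code{mean_fr}, \code{burst_fraction}, \code{mean_isi},
#'   \code{median_isi}, \code{std_isi}, \code{cv_isi}, \code{n_spikes}.
#' @export
spike_summary <- function(spikes, isi_threshold = 0.012) {
  check(spikes$duration > 0, "zero-duration spike train")
  n <- length(spikes$spike_times)
  isis <- diff(spikes$spike_times)
  bp <- burst_partition(spikes, isi_threshold)
  structure(list(
    mean_fr = n / spikes$duration,
    burst_fraction = bp$burst_fraction,
    mean_isi = if (length(isis)) mean(isis) else NA_real_,
    median_isi = if (length(isis)) median(isis) else NA_real_,
    std_isi = if (length(isis) > 1) sd(isis) else NA_real_,
    cv_isi = if (length(isis) > 1 && mean(isis) > 0)
      sd(isis) / mean(isis) else NA_real_,
    n_spikes = n), class = "spike_train_stats")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |F_x - F_y| over the pooled sample with the asymptotic
#' p-value; used as the distribution-agreement gate when accepting fitted
#' parameter sets (fits must not differ significantly from the target ISI
#' sample, p > 0.05).
#'
#' @param x,y numeric samples (non-empty).
#' @return list with \code{D} and \code{p_value}.
#' @export
ks_two_sample <- function(x, y) {
  check(length(x) > 0 && length(y) > 0, "samples must be non-empty")
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p_value = unname(res$p.value))
}
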