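#' Generate a reference recording with known ground truth
#'
#' Stands in for an intracellular recording: simulates the chosen model
#' with its stochastic drive, records 5 s of membrane voltage at 10 kHz
#' (the recording protocol of the emulated dataset) and stores the
#' generating parameters together with the spike train and statistics
#' recomputed from the trace by the same analysis pipeline applied to
#' real data.  These are synthetic stand-ins, not recordings.
#'
#' @param model "hr_modified", "hr_classic" or "biophys".
#' @param params parameter object for the model.
#' @param seed integer seed; the trace is reproducible per seed.
#' @param duration recording length (s).
#' @return object of class \code{reference_recording}: list with
#'   \code{trace} (t_s, v), \code{params}, \code{seed}, \code{spikes},
#'   \code{stats}, \code{model}.
#' @export
generate_reference_recording <- function(model, params, seed,
                                         duration = 5) {
  is_hr <- model %in% c("hr_modified", "hr_classic")
  if (is_hr) {
    tr <- simulate_hr(params, duration = duration, seed = seed)
    trace <- trace_df(tr, "V")
    spikes <- detect_spikes(trace, threshold = 0, baseline_relative = FALSE)
  } else {
    tr <- simulate_biophys(params, duration = duration, seed = seed)
    trace <- trace_df(tr, "V_S")
    spikes <- detect_spikes(trace, threshold = -30, baseline_relative = FALSE)
  }
  structure(list(trace = trace, params = params, seed = seed,
                 spikes = spikes, stats = spike_summary(spikes),
                 model = model),
            class = "reference_recording")
}

#' Locations of the ISI density modes
#'
#' Local maxima of the Scott-bandwidth ISI KDE, ordered by height; used
#' to assess bimodality (a burst-firing cell shows a short intra-burst
#' mode below ~12 ms and a long inter-burst mode near ~100 ms).
#'
#' @param spikes a \code{spike_train} with >= 3 spikes.
#' @return numeric vector of mode locations (s), tallest first.
#' @export
isi_modes <- function(spikes) {
  if (length(spikes$spike_times) < 3) return(numeric(0))
  d <- isi_distribution(spikes, n_boot = 0)
  y <- d$kde$y; x <- d$kde$x
  pk <- which(diff(sign(diff(y))) == -2) + 1
  if (y[1] > y[2]) pk <- c(1L, pk)
  x[pk[order(y[pk], decreasing = TRUE)]]
}

#' Synthetic population of reference recordings
#'
#' Draws parameter sets for the modified Hindmarsh-Rose model around its
#' calibrated defaults (applied current, slow-adaptation decay and noise
#' intensities varied across cells), simulates each and keeps draws
#' whose mean firing rate lies inside \code{rate_range} and whose burst
#' fraction is strictly inside (0, 1) - the statistical envelope of the
#' recorded in vivo population (rates 5-60 Hz, coexisting burst and
#' isolated spikes, bimodal ISI distributions with the intra-burst mode
#' below ~12 ms).
#'
#' @param n number of recordings to produce.
#' @param seed integer master seed.
#' @param duration recording length (s).
#' @param rate_range admissible mean-rate interval (Hz).
#' @param max_draws rejection-sampling cap.
#' @return list of \code{reference_recording} objects of length
#'   \code{n}.
#' @export
population_preset <- function(n = 32, seed = 1, duration = 5,
                              rate_range = c(5, 60), max_draws = 40 * n) {
  out <- vector("list", n)
  got <- 0L
  for (d in seq_len(max_draws)) {
    ds <- derive_seed(seed, d)
    draw <- withr_seed(ds, {
      list(I_app = runif(1, 2.0, 3.2),
           gamma_d = runif(1, 0.07, 0.13),
           sigma_V = runif(1, 0.1, 0.4),
           sigma_u = runif(1, 0, 0.02))
    })
    p <- do.call(hr_params, draw)
    rec <- tryCatch(
      generate_reference_recording("hr_modified", p, seed = ds,
                                   duration = duration),
      error = function(e) NULL)
    if (is.null(rec)) next
    fr <- rec$stats$mean_fr; bf <- rec$stats$burst_fraction
    if (fr >= rate_range[1] && fr <= rate_range[2] && bf > 0 && bf < 1) {
      got <- got + 1L
      out[[got]] <- rec
      if (got == n) break
    }
  }
  check(got == n, "rejection sampling exhausted after ", max_draws,
        " draws (got ", got, "/", n, ")")
  out
}
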