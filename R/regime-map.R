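#' Classify the firing regime of a deterministic trajectory
#'
#' Rules applied to the post-transient spike train:
#' \itemize{
#'   \item \code{quiescent}: no spikes and mean voltage below the spike
#'     threshold;
#'   \item \code{depolarization_block}: no spikes and mean voltage above
#'     threshold (the cell sits depolarised but cannot fire);
#'   \item \code{tonic}: regular firing (CV of ISIs < \code{cv_tol}) with
#'     no intra-burst-range ISI;
#'   \item \code{doublet}: every burst has exactly two spikes and bursts
#'     recur periodically (CV of inter-burst intervals < \code{cv_tol});
#'   \item \code{burst}: any other pattern with a positive burst
#'     fraction; irregular ISI dispersion within this label is the
#'     signature of chaotic ghostbursting.
#' }
#'
#' @param tr a \code{trajectory} from a deterministic run.
#' @param var voltage variable name (default first recorded).
#' @param threshold spike threshold in trace units.
#' @param baseline_relative see \code{\link{detect_spikes}}.
#' @param burst_threshold burst ISI threshold (s).
#' @param cv_tol regularity cutoff for tonic/doublet classification.
#' @param min_expected_isis minimum analysable window in units of the
#'   observed mean ISI.
#' @return list of class \code{regime_label}: \code{label} plus
#'   diagnostics (\code{mean_fr}, \code{cv_isi}, \code{burst_sizes},
#'   \code{mean_v}, \code{n_spikes}).
#' @export
classify_regime <- function(tr, var = names(tr$values)[1], threshold = 0,
                            baseline_relative = FALSE,
                            burst_threshold = 0.012, cv_tol = 0.05,
                            min_expected_isis = 10) {
  trace <- trace_df(tr, var)
  spikes <- detect_spikes(trace, threshold = threshold,
                          baseline_relative = baseline_relative)
  mean_v <- mean(trace$v)
  n <- length(spikes$spike_times)
  thr_abs <- if (baseline_relative) median(trace$v) + threshold else threshold
  diag0 <- list(mean_fr = n / spikes$duration, cv_isi = NA_real_,
                burst_sizes = integer(0), mean_v = mean_v, n_spikes = n)
  if (n < 2) {
    # at most a lone transient spike over the window: not sustained firing
    lab <- if (mean_v < thr_abs) "quiescent" else "depolarization_block"
    return(structure(c(list(label = lab), diag0), class = "regime_label"))
  }
  isis <- diff(spikes$spike_times)
  if (spikes$duration < min_expected_isis * mean(isis))
    stop_invalid("window shorter than ", min_expected_isis, " expected ISIs")
  cv <- sd(isis) / mean(isis)
  bp <- burst_partition(spikes, burst_threshold)
  diag <- list(mean_fr = n / spikes$duration, cv_isi = cv,
               burst_sizes = bp$burst_sizes, mean_v = mean_v, n_spikes = n)
  lab <- if (cv < cv_tol && all(isis >= burst_threshold)) {
    "tonic"
  } else if (length(bp$bursts) >= 2 && all(bp$burst_sizes == 2)) {
    firsts <- vapply(bp$bursts, function(i) spikes$spike_times[i[1]],
                     numeric(1))
    ibi <- diff(firsts)
    if (length(ibi) >= 2 && sd(ibi) / mean(ibi) < cv_tol) "doublet"
    else "burst"
  } else if (bp$burst_fraction > 0) {
    "burst"
  } else if (cv < cv_tol) "tonic" else "tonic_irregular"
  structure(c(list(label = lab), diag), class = "regime_label")
}

#' One-dimensional firing-regime sweep
#'
#' Brute-force regime cartography: one deterministic simulation per grid
#' point of a single parameter, classification of each trajectory and a
#' firing-rate map.  Warm starts (continuation-style: each run starts
#' from the end state of the previous grid point) follow an attractor
#' branch; cold starts (the same initial state everywhere) expose
#' multistability when the two modes disagree.
#'
#' @param model "hr_modified", "hr_classic" or "biophys".
#' @param params base parameter object (\code{hr_params} or
#'   \code{biophys_params}).
#' @param param_name name of the swept parameter ("I_app", "g_SK",
#'   "g_NMDA", ...).
#' @param grid sorted numeric grid of parameter values.
#' @param duration analysis window per point (s), after \code{burn_in}.
#' @param burn_in discarded transient per point (s).
#' @param warm_start follow the previous grid point's end state.
#' @param frozen_glu for the biophysical model: drive every grid point
#'   with one and the same pre-drawn glutamate release train (a frozen,
#'   hence deterministic, input), so the NMDA/SK pathway participates in
#'   the map; FALSE shuts glutamate release off entirely.
#' @param ... passed to \code{\link{classify_regime}}.
#' @return data frame of class \code{regime_map}: one row per grid point
#'   with \code{value}, \code{label}, \code{mean_fr}, \code{cv_isi},
#'   \code{mean_v}, \code{failed}.
#' @export
sweep_1d <- function(model, params, param_name, grid, duration = 20,
                     burn_in = 2, warm_start = TRUE, frozen_glu = TRUE, ...) {
  check(!is.unsorted(grid), "grid must be sorted")
  is_hr <- model %in% c("hr_modified", "hr_classic")
  state <- NULL
  glu_train <- FALSE
  if (!is_hr && isTRUE(frozen_glu))
    glu_train <- sample_release_times(params$noise$lambda_glu,
                                      duration + burn_in, seed = 1,
                                      A_glu = params$noise$A_glu,
                                      tau_d = params$noise$tau_d_glu)
  rows <- lapply(seq_along(grid), function(i) {
    val <- grid[i]
    res <- tryCatch({
      if (is_hr) {
        p <- modifyList(params, setNames(list(val), param_name))
        p <- modifyList(p, list(sigma_V = 0, sigma_y = 0, sigma_z = 0,
                                sigma_u = 0))
        p <- validate_hr_params(p)
        st <- if (warm_start && !is.null(state)) state else hr_state()
        tr <- simulate_hr(p, duration = duration + burn_in,
                          burn_in = burn_in, seed = 1, state0 = st)
        if (warm_start)
          state <<- hr_state(V = tail(tr$values$V, 1),
                             y = tail(tr$values$y, 1),
                             z = tail(tr$values$z, 1),
                             u = tail(tr$values$u, 1))
        classify_regime(tr, var = "V", threshold = 0,
                        baseline_relative = FALSE, ...)
      } else {
        ov <- setNames(list(val), param_name)
        p <- do.call(biophys_params, modifyList(as.list(unclass(params)), ov))
        p$noise$sigma_eta <- 0
        st <- if (warm_start && !is.null(state)) state
          else biophys_state(params = p)
        tr <- simulate_biophys(p, duration = duration + burn_in,
                               burn_in = burn_in, seed = 1, state0 = st,
                               stochastic_glu = glu_train,
                               record_vars = NULL)
        if (warm_start) {
          last <- vapply(tr$values, function(x) tail(x, 1), numeric(1))
          state <<- structure(last, class = "biophys_state")
        }
        classify_regime(tr, var = "V_S", threshold = -30,
                        baseline_relative = FALSE, ...)
      }
    }, error = function(e) e)
    if (inherits(res, "error"))
      data.frame(value = val, label = NA_character_, mean_fr = NA_real_,
                 cv_isi = NA_real_, mean_v = NA_real_, failed = TRUE)
    else
      data.frame(value = val, label = res$label, mean_fr = res$mean_fr,
                 cv_isi = res$cv_isi, mean_v = res$mean_v, failed = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "param_name") <- param_name
  class(out) <- c("regime_map", "data.frame")
  out
}

#' Probe for coexisting attractors at fixed parameters
#'
#' Simulates each initial state deterministically and groups the
#' asymptotic outcomes into \code{rest} (no spikes, settles at
#' equilibrium), \code{single_spike} (exactly one transient spike before
#' rest) and \code{sustained} (ongoing firing).  Two or more coexisting
#' classes at fixed parameters witness bistability, the hallmark of the
#' region below the firing onset where the quiescent state coexists with
#' spiking/bursting orbits.
#'
#' @param model "hr_modified", "hr_classic" or "biophys".
#' @param params parameter object.
#' @param I_app applied current to probe at.
#' @param initial_states list of initial states.
#' @param duration simulated time per probe (s).
#' @return list with \code{outcomes} (character per initial state),
#'   \code{classes} (unique outcomes), \code{bistable} (>= 2 classes).
#' @export
bistability_probe <- function(model, params, I_app, initial_states,
                              duration = 2) {
  is_hr <- model %in% c("hr_modified", "hr_classic")
  outcomes <- vapply(initial_states, function(st) {
    if (is_hr) {
      p <- validate_hr_params(modifyList(params, list(
        I_app = I_app, sigma_V = 0, sigma_y = 0, sigma_z = 0, sigma_u = 0)))
      tr <- simulate_hr(p, duration = duration, seed = 1, state0 = st)
      spikes <- detect_spikes(trace_df(tr, "V"), threshold = 0,
                              baseline_relative = FALSE)
    } else {
      p <- do.call(biophys_params,
                   modifyList(as.list(unclass(params)), list(I_app = I_app)))
      p$noise$sigma_eta <- 0
      tr <- simulate_biophys(p, duration = duration, seed = 1, state0 = st,
                             stochastic_glu = FALSE)
      spikes <- detect_spikes(trace_df(tr, "V_S"), threshold = -30,
                              baseline_relative = FALSE)
    }
    n <- length(spikes$spike_times)
    late <- sum(spikes$spike_times > duration / 2)
    if (n == 0) "rest"
    else if (late == 0 && n == 1) "single_spike"
    else if (late == 0) "transient"
    else "sustained"
  }, character(1))
  list(outcomes = outcomes, classes = sort(unique(outcomes)),
       bistable = length(unique(outcomes)) >= 2)
}

#' Export a regime map to long-format CSV
#' @param map a \code{regime_map}.
#' @param path file to write.
#' @export
write_regime_map_csv <- function(map, path) {
  df <- as.data.frame(map)
  df$param <- attr(map, "param_name")
  write.csv(df[, c("param", "value", "label", "mean_fr", "cv_isi",
                   "mean_v", "failed")], path, row.names = FALSE)
  invisible(path)
}
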