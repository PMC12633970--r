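#' Feature target for model fitting
#'
#' A named set of scalar features with per-feature weights and
#' normalisation scales.  Spike-train features (mean_fr, burst_fraction,
#' mean_isi, median_isi, std_isi, cv_isi) apply to both models; waveform
#' features (threshold_v, upstroke_v, peak_v, downstroke_v, trough_v,
#' adp_v) are used for the biophysical model only, consistent with the
#' phenomenological nature of the Hindmarsh-Rose formulation.
#'
#' Scales default to |target value| (relative error) with an absolute
#' floor for near-zero targets; weights default to equal and are
#' normalised to sum to one inside the loss.
#'
#' @param features named numeric vector of target values.
#' @param weights named numeric vector (subset of features); >= 0, not
#'   all zero.
#' @param scales named numeric vector of normalisation scales (> 0).
#' @param scale_floor absolute floor for auto-derived scales.
#' @param isi_sample optional numeric vector of target ISIs (s) enabling
#'   the Kolmogorov-Smirnov acceptance gate.
#' @return an object of class \code{feature_target}.
#' @export
feature_target <- function(features, weights = NULL, scales = NULL,
                           scale_floor = 1e-3, isi_sample = NULL) {
  check(length(features) > 0 && !is.null(names(features)),
        "features must be a named vector")
  w <- setNames(rep(1, length(features)), names(features))
  if (!is.null(weights)) {
    check(all(names(weights) %in% names(features)), "unknown weight names")
    w[names(weights)] <- weights
  }
  check(all(w >= 0) && any(w > 0), "weights must be >= 0 and not all zero")
  s <- pmax(abs(features), scale_floor)
  if (!is.null(scales)) {
    check(all(names(scales) %in% names(features)), "unknown scale names")
    s[names(scales)] <- scales
  }
  check(all(s > 0), "scales must be > 0")
  structure(list(features = features, weights = w, scales = s,
                 isi_sample = isi_sample), class = "feature_target")
}

#' Weighted normalised-RMSE loss
#'
#' Per-feature normalised error |sim - target| / scale, aggregated with
#' weights normalised to sum to one.  With equal weights a total loss
#' below 0.1 corresponds to less than 10% normalised error across all
#' features, the criterion used to accept fits.  Features missing (NA)
#' in the simulation or the target (e.g. an absent ADP) are excluded and
#' the remaining weights renormalised.
#'
#' @param simulated named numeric vector of simulated features.
#' @param target a \code{feature_target}.
#' @return list with \code{total} and \code{per_feature} (named vector).
#' @export
fit_loss <- function(simulated, target) {
  nm <- names(target$features)
  sim <- simulated[nm]
  ok <- !is.na(sim) & !is.na(target$features) & target$weights > 0
  check(any(ok), "no overlapping finite features between simulation and target")
  err <- abs(sim[ok] - target$features[ok]) / target$scales[ok]
  w <- target$weights[ok] / sum(target$weights[ok])
  list(total = sum(w * err), per_feature = setNames(err, nm[ok]))
}

#' Spike-train (and optionally waveform) features of a voltage trace
#'
#' Runs the full analysis pipeline (spike detection, burst partition,
#' ISI statistics, optionally AP waveform features averaged across
#' spikes) and returns the named feature vector consumed by
#' \code{\link{fit_loss}}.
#'
#' @param trace data frame with \code{t_s}, \code{v}.
#' @param threshold,baseline_relative spike-detection settings.
#' @param burst_threshold burst ISI threshold (s).
#' @param waveform include averaged AP waveform features.
#' @return named numeric vector (NA for unavailable features); the ISI
#'   vector is attached as attribute \code{"isis"}.
#' @export
trace_features <- function(trace, threshold = -30, baseline_relative = FALSE,
                           burst_threshold = 0.012, waveform = FALSE) {
  spikes <- detect_spikes(trace, threshold = threshold,
                          baseline_relative = baseline_relative)
  st <- spike_summary(spikes, burst_threshold)
  out <- c(mean_fr = st$mean_fr, burst_fraction = st$burst_fraction,
           mean_isi = st$mean_isi, median_isi = st$median_isi,
           std_isi = st$std_isi, cv_isi = st$cv_isi)
  if (waveform) {
    ft <- extract_ap_features(trace, spikes)
    wf <- c(threshold_v = NA_real_, upstroke_v = NA_real_, peak_v = NA_real_,
            downstroke_v = NA_real_, trough_v = NA_real_, adp_v = NA_real_)
    if (nrow(ft) > 0) {
      wf["threshold_v"] <- mean(ft$threshold_v)
      wf["upstroke_v"] <- mean(ft$upstroke_v)
      wf["peak_v"] <- mean(ft$peak_v)
      wf["downstroke_v"] <- mean(ft$downstroke_v)
      wf["trough_v"] <- mean(ft$trough_v)
      adp <- ft$adp_v[!is.na(ft$adp_v)]
      if (length(adp)) wf["adp_v"] <- mean(adp)
    }
    out <- c(out, wf)
  }
  attr(out, "isis") <- diff(spikes$spike_times)
  out
}

#' Fit a model to feature targets with NSGA-II
#'
#' Multi-objective search over box bounds: each per-feature normalised
#' error is one objective, minimised jointly by NSGA-II; the reported
#' solution is the archive member with the smallest total (weighted)
#' loss.  Each trial simulates with a fixed seed per trial index (common
#' random numbers), which stabilises the ranking of stochastic
#' objectives.  A fit is accepted when total loss < \code{loss_threshold}
#' and, if the target carries an ISI sample, the simulated ISI
#' distribution does not differ from it significantly
#' (Kolmogorov-Smirnov p > 0.05).
#'
#' @param model "hr_modified", "hr_classic" or "biophys".
#' @param base_params parameter object supplying every non-fitted value.
#' @param bounds named list of c(lower, upper) per fitted parameter
#'   (top-level scalar parameters of the model).
#' @param target a \code{feature_target}.
#' @param budget total evaluation budget (>= pop_size).
#' @param pop_size NSGA-II population size.
#' @param seed integer master seed.
#' @param duration simulated seconds per trial.
#' @param loss_threshold acceptance threshold on the total loss.
#' @param waveform include waveform features (biophysical fits).
#' @return an object of class \code{fit_result}: \code{par} (named best
#'   parameters), \code{loss}, \code{per_feature}, \code{accepted},
#'   \code{ks} (D, p_value or NULL), \code{archive} (data frame of all
#'   trials: parameters, loss), \code{seed}.
#' @export
fit_model <- function(model, base_params, bounds, target, budget = 500,
                      pop_size = 50, seed = 1, duration = 5,
                      loss_threshold = 0.1, waveform = FALSE) {
  check(budget >= pop_size, "budget must be at least pop_size")
  pn <- names(bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  is_hr <- model %in% c("hr_modified", "hr_classic")
  sim_seed <- derive_seed(seed, 7L)
  simulate_features <- function(x) {
    ov <- setNames(as.list(x), pn)
    if (is_hr) {
      p <- validate_hr_params(modifyList(base_params, ov))
      tr <- simulate_hr(p, duration = duration, seed = sim_seed)
      trc <- trace_df(tr, "V")
      trace_features(trc, threshold = 0, baseline_relative = FALSE,
                     waveform = FALSE)
    } else {
      p <- do.call(biophys_params, modifyList(as.list(unclass(base_params)), ov))
      tr <- simulate_biophys(p, duration = duration, seed = sim_seed)
      trc <- trace_df(tr, "V_S")
      trace_features(trc, threshold = -30, baseline_relative = FALSE,
                     waveform = waveform)
    }
  }
  nm <- names(target$features)
  objective <- function(x) {
    f <- simulate_features(x)
    err <- abs(f[nm] - target$features) / target$scales
    err[is.na(err)] <- 10   # missing feature: heavily penalised objective
    unname(err)
  }
  n_gen <- max(1L, as.integer(ceiling(budget / pop_size)) - 1L)
  res <- nsga2(objective, lower, upper, pop_size = pop_size,
               n_gen = n_gen, seed = seed)
  w <- target$weights / sum(target$weights)
  totals <- as.vector(res$F %*% w)
  totals[apply(res$F, 1, function(r) any(is.na(r)))] <- NA
  check(any(!is.na(totals)), "all trials failed to simulate")
  best <- which.min(totals)
  best_par <- setNames(res$X[best, ], pn)
  best_feats <- simulate_features(best_par)
  loss <- fit_loss(best_feats, target)
  ks <- NULL
  if (!is.null(target$isi_sample) && length(attr(best_feats, "isis")) > 0)
    ks <- ks_two_sample(attr(best_feats, "isis"), target$isi_sample)
  accepted <- loss$total < loss_threshold &&
    (is.null(ks) || ks$p_value > 0.05)
  archive <- as.data.frame(res$X)
  names(archive) <- pn
  archive$loss <- totals
  structure(list(par = best_par, loss = loss$total,
                 per_feature = loss$per_feature, features = best_feats,
                 accepted = accepted, ks = ks, archive = archive,
                 seed = seed, model = model),
            class = "fit_result")
}

#' First-order Sobol indices from a fit archive
#'
#' Retains the archive trials whose loss is below the threshold
#' (discarding implausible dynamics), then decomposes the variance of
#' the loss over the retained sample: var_i is the variance of the
#' binned conditional expectation E\[loss | x_i\] (ANOVA-style
#' estimator) and S_i = var_i / var_total.
#'
#' @param archive data frame with one column per parameter plus
#'   \code{loss}.
#' @param loss_threshold retain trials with loss below this (default
#'   0.1); use \code{Inf} to retain all.
#' @param n_bins number of equal-frequency bins per parameter.
#' @param min_trials minimum retained trials required.
#' @return object of class \code{sobol_result}: data frame with columns
#'   \code{parameter}, \code{S}, \code{var_i}; attributes
#'   \code{var_total}, \code{method}.
#' @export
sobol_fit_archive <- function(archive, loss_threshold = 0.1, n_bins = 8,
                              min_trials = 30) {
  check("loss" %in% names(archive), "archive must have a loss column")
  keep <- !is.na(archive$loss) & archive$loss < loss_threshold
  check(sum(keep) >= min_trials,
        "insufficient successful trials (", sum(keep), " < ", min_trials, ")")
  arch <- archive[keep, , drop = FALSE]
  y <- arch$loss
  var_total <- var(y)
  check(var_total > 0, "zero loss variance among retained trials")
  pn <- setdiff(names(arch), "loss")
  rows <- lapply(pn, function(nm) {
    x <- arch[[nm]]
    nb <- min(n_bins, max(2, floor(length(x) / 10)))
    br <- unique(quantile(x, probs = seq(0, 1, length.out = nb + 1)))
    if (length(br) < 3) return(data.frame(parameter = nm, S = 0, var_i = 0))
    bins <- cut(x, br, include.lowest = TRUE)
    cm <- tapply(y, bins, mean)
    cn <- tapply(y, bins, length)
    ok <- !is.na(cm)
    gm <- sum(cn[ok] * cm[ok]) / sum(cn[ok])
    var_i <- sum(cn[ok] * (cm[ok] - gm)^2) / sum(cn[ok])
    data.frame(parameter = nm, S = var_i / var_total, var_i = var_i)
  })
  out <- do.call(rbind, rows)
  attr(out, "var_total") <- var_total
  attr(out, "method") <- "fit-archive-ratio"
  class(out) <- c("sobol_result", "data.frame")
  out
}

#' First-order Sobol indices of a model output by Saltelli sampling
#'
#' Latin-hypercube A and B matrices with the radial A_B^(i) design and
#' the Saltelli 2010 first-order estimator
#' S_i = mean(f(B) (f(AB_i) - f(A))) / Var(f).
#'
#' @param fn function(x) -> scalar output, x a numeric vector in the
#'   given ranges.
#' @param ranges named list of c(lower, upper) per parameter.
#' @param n_samples base sample size (total evaluations
#'   n_samples * (k + 2)).
#' @param seed integer seed.
#' @return a \code{sobol_result} data frame (parameter, S, var_i).
#' @export
sobol_model <- function(fn, ranges, n_samples = 1024, seed = 1) {
  k <- length(ranges)
  pn <- names(ranges)
  lower <- vapply(ranges, `[`, numeric(1), 1)
  upper <- vapply(ranges, `[`, numeric(1), 2)
  check(all(upper > lower), "ranges must have upper > lower")
  AB <- withr_seed(seed, lhs::randomLHS(n_samples, 2 * k))
  scale_mat <- function(U) sweep(sweep(U, 2, upper - lower, `*`), 2, lower, `+`)
  A <- scale_mat(AB[, 1:k, drop = FALSE])
  B <- scale_mat(AB[, (k + 1):(2 * k), drop = FALSE])
  fA <- apply(A, 1, fn); fB <- apply(B, 1, fn)
  V <- var(c(fA, fB))
  check(is.finite(V) && V > 0, "zero-variance (constant) model output")
  rows <- lapply(seq_len(k), function(i) {
    ABi <- A; ABi[, i] <- B[, i]
    fABi <- apply(ABi, 1, fn)
    var_i <- mean(fB * (fABi - fA))
    data.frame(parameter = pn[i], S = var_i / V, var_i = var_i)
  })
  out <- do.call(rbind, rows)
  attr(out, "var_total") <- V
  attr(out, "method") <- "saltelli"
  class(out) <- c("sobol_result", "data.frame")
  out
}

#' Ishigami benchmark function
#'
#' f(x) = sin x1 + a sin^2 x2 + b x3^4 sin x1 on \[-pi, pi\]^3; the
#' standard validation case for Sobol estimators, with closed-form
#' first-order indices.
#'
#' @param x numeric vector of length 3.
#' @param a,b coefficients (defaults 7 and 0.1).
#' @return scalar function value.
#' @export
ishigami <- function(x, a = 7, b = 0.1)
  sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1])

#' Closed-form first-order Sobol indices of the Ishigami function
#' @param a,b Ishigami coefficients.
#' @return named vector (x1, x2, x3).
#' @export
ishigami_indices <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V <- 0.5 + a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18
  c(x1 = V1 / V, x2 = V2 / V, x3 = 0)
}
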