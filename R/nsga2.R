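# Elitist non-dominated sorting genetic algorithm (NSGA-II) with
# simulated-binary crossover and polynomial mutation, on a box-bounded
# continuous search space.  Written against the canonical algorithm
# description; no NSGA-II implementation is exported by the package's
# dependencies.

# fast non-dominated sort: returns front index per row of the objective
# matrix (minimisation)
nds_fronts <- function(F) {
  n <- nrow(F)
  dominates <- function(i, j)
    all(F[i, ] <= F[j, ]) && any(F[i, ] < F[j, ])
  S <- vector("list", n); cnt <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) S[[i]] <- c(S[[i]], j)
      else if (dominates(j, i)) cnt[i] <- cnt[i] + 1
    }
  }
  front <- integer(n)
  cur <- which(cnt == 0); f <- 1L
  while (length(cur)) {
    front[cur] <- f
    nxt <- integer(0)
    for (i in cur) for (j in S[[i]]) {
      cnt[j] <- cnt[j] - 1
      if (cnt[j] == 0) nxt <- c(nxt, j)
    }
    cur <- unique(nxt); f <- f + 1L
  }
  front
}

crowding_distance <- function(F) {
  n <- nrow(F); m <- ncol(F)
  d <- numeric(n)
  for (k in seq_len(m)) {
    o <- order(F[, k])
    d[o[1]] <- d[o[n]] <- Inf
    rng <- F[o[n], k] - F[o[1], k]
    if (rng > 0 && n > 2)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], k] - F[o[1:(n - 2)], k]) / rng
  }
  d
}

sbx_crossover <- function(p1, p2, lower, upper, eta = 15, pc = 0.9) {
  if (runif(1) > pc) return(list(p1, p2))
  u <- runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutation <- function(x, lower, upper, eta = 20, pm = NULL) {
  pm <- pm %||% (1 / length(x))
  for (j in seq_along(x)) {
    if (runif(1) < pm && upper[j] > lower[j]) {
      u <- runif(1)
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
               else 1 - (2 * (1 - u))^(1 / (eta + 1))
      x[j] <- min(max(x[j] + delta * (upper[j] - lower[j]), lower[j]),
                  upper[j])
    }
  }
  x
}

#' Multi-objective minimisation with NSGA-II
#'
#' @param fn function(x) returning a numeric vector of objectives
#'   (minimised); may return NA objectives for failed evaluations (these
#'   are pushed to the last front).
#' @param lower,upper box bounds.
#' @param pop_size population size.
#' @param n_gen number of generations.
#' @param seed integer seed.
#' @return list with \code{X} (all evaluated points, row per evaluation),
#'   \code{F} (their objectives), \code{pareto_X}, \code{pareto_F}
#'   (final non-dominated set).
#' @export
nsga2 <- function(fn, lower, upper, pop_size = 50, n_gen = 10, seed = 1) {
  check(length(lower) == length(upper) && all(upper >= lower),
        "invalid bounds")
  d <- length(lower)
  evaluate <- function(X) {
    res <- lapply(seq_len(nrow(X)), function(i)
      tryCatch(fn(X[i, ]), error = function(e) NULL))
    m <- max(1L, vapply(res, length, integer(1)))
    t(vapply(res, function(f) {
      if (is.null(f) || length(f) != m || any(!is.finite(f)))
        rep(NA_real_, m)
      else as.numeric(f)
    }, numeric(m)))
  }
  withr_seed(seed, {
    span <- upper - lower
    P <- sweep(sweep(matrix(runif(pop_size * d), pop_size, d), 2, span, `*`),
               2, lower, `+`)
    if (any(span == 0)) P[, span == 0] <- matrix(rep(lower[span == 0],
                                                     each = pop_size),
                                                 pop_size)
    FP <- evaluate(P)
    allX <- P; allF <- FP
    for (gen in seq_len(n_gen)) {
      penal <- FP
      bad <- apply(FP, 1, function(r) any(is.na(r)))
      if (any(bad)) penal[bad, ] <- max(FP[!bad, ], 0, na.rm = TRUE) * 10 + 1
      fr <- nds_fronts(penal)
      cd <- numeric(nrow(P))
      for (f in unique(fr)) {
        sel <- fr == f
        cd[sel] <- if (sum(sel) > 1) crowding_distance(penal[sel, , drop = FALSE]) else Inf
      }
      tournament <- function() {
        ij <- sample.int(nrow(P), 2)
        i <- ij[1]; j <- ij[2]
        if (fr[i] < fr[j]) i
        else if (fr[j] < fr[i]) j
        else if (cd[i] >= cd[j]) i else j
      }
      Q <- matrix(NA_real_, pop_size, d)
      k <- 1
      while (k <= pop_size) {
        ch <- sbx_crossover(P[tournament(), ], P[tournament(), ],
                            lower, upper)
        for (c1 in ch) {
          if (k > pop_size) break
          Q[k, ] <- poly_mutation(c1, lower, upper)
          k <- k + 1
        }
      }
      FQ <- evaluate(Q)
      allX <- rbind(allX, Q); allF <- rbind(allF, FQ)
      R <- rbind(P, Q); FR <- rbind(FP, FQ)
      penal <- FR
      bad <- apply(FR, 1, function(r) any(is.na(r)))
      if (any(bad)) penal[bad, ] <- max(FR[!bad, ], 0, na.rm = TRUE) * 10 + 1
      fr <- nds_fronts(penal)
      keep <- integer(0)
      for (f in sort(unique(fr))) {
        idx <- which(fr == f)
        if (length(keep) + length(idx) <= pop_size) keep <- c(keep, idx)
        else {
          cdf <- crowding_distance(penal[idx, , drop = FALSE])
          keep <- c(keep, idx[order(cdf, decreasing = TRUE)[
            seq_len(pop_size - length(keep))]])
          break
        }
      }
      P <- R[keep, , drop = FALSE]; FP <- FR[keep, , drop = FALSE]
    }
    penal <- FP
    bad <- apply(FP, 1, function(r) any(is.na(r)))
    if (any(bad)) penal[bad, ] <- max(FP[!bad, ], 0, na.rm = TRUE) * 10 + 1
    fr <- nds_fronts(penal)
    list(X = allX, F = allF,
         pareto_X = P[fr == 1, , drop = FALSE],
         pareto_F = FP[fr == 1, , drop = FALSE])
  })
}
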