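#' @keywords internal
"_PACKAGE"

#' @useDynLib ghostburst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rexp sd median var density fft ks.test
#'   quantile approx lm coef setNames
#' @importFrom utils read.csv write.csv modifyList head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("ghostburst_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check <- function(cond, ...) if (!isTRUE(cond)) stop_invalid(...)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic components of the package draw their randomness through
#' seeds derived deterministically from one master seed, so that a whole
#' pipeline is reproducible from a single integer.
#'
#' @param seed master seed (integer).
#' @param index stream index (non-negative integer).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, index = 0L) {
  check(is_number(seed), "seed must be a single finite number")
  # affine hash mod a prime below 2^31; avoids correlated consecutive seeds
  as.integer((abs(seed) * 2654435761 + index * 40503 + 12345) %% 2147483587)
}
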