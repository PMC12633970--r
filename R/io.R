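#' Read a membrane-voltage trace from CSV
#'
#' Expects two columns: time in seconds and voltage, with a header row
#' (any names; the first two columns are used).  The sampling grid must
#' be uniform.
#'
#' @param path CSV file.
#' @return data frame with columns \code{t_s}, \code{v}.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  check(ncol(df) >= 2, "trace CSV needs at least two columns (time, voltage)")
  out <- data.frame(t_s = as.numeric(df[[1]]), v = as.numeric(df[[2]]))
  dt <- diff(out$t_s)
  check(all(abs(dt - dt[1]) < 1e-9), "trace must be uniformly sampled")
  out
}

#' Write a membrane-voltage trace to CSV
#'
#' Columns \code{t_s}, \code{v} at full double precision so a written
#' trace reads back bit-exactly.
#'
#' @param trace data frame with \code{t_s}, \code{v}.
#' @param path file to write.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(t_s = sprintf("%.17g", trace$t_s),
                   v = sprintf("%.17g", trace$v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write spike-train statistics to JSON
#'
#' @param stats a \code{spike_train_stats}.
#' @param path file to write.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read spike-train statistics from JSON
#' @param path JSON file from \code{\link{write_stats_json}}.
#' @return a \code{spike_train_stats}.
#' @export
read_stats_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "spike_train_stats")
}

#' Write Hindmarsh-Rose parameters to a JSON document
#' @param p an \code{hr_params}.
#' @param path file to write.
#' @export
write_hr_params_json <- function(p, path) {
  doc <- list(model = p$model,
              params = unclass(p)[setdiff(names(p), "model")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run manifest
#'
#' Every pipeline output can be reproduced from its manifest: model,
#' seed, configuration and a digest of the parameter document.
#'
#' @param model model selector.
#' @param seed master seed.
#' @param config list of configuration values.
#' @param params parameter object (serialised inline).
#' @param path file to write.
#' @export
write_manifest <- function(model, seed, config, params, path) {
  doc <- list(package = "ghostburst",
              version = as.character(utils::packageVersion("ghostburst")),
              model = model, seed = seed, config = config,
              params = unclass(params))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
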