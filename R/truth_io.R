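# Ground-truth serialization for simulated cohorts (JSON, so downstream
# scorers need not be written in R).

#' Write or read simulation ground truth
#'
#' @param truth A [synthetic_truth()].
#' @param path JSON file.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(
    list(effects = truth$effects, baseline_mean = truth$baseline_mean,
         noise_sd = truth$noise_sd, seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop_input("truth file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  effects <- x$effects
  if (is.null(effects) || length(effects) == 0L) {
    effects <- NULL
  } else {
    effects <- as.data.frame(effects)
  }
  synthetic_truth(effects = effects, baseline_mean = x$baseline_mean,
                  noise_sd = x$noise_sd, seed = x$seed)
}
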