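#' Read / write an analysis run configuration
#'
#' A run configuration collects, in one YAML document, everything needed
#' to reproduce an analysis: file paths, sampling rate, basis parameters,
#' boosting step and fold count, the full-model feature set together
#' with the reduced models (one per feature under investigation), the
#' group-statistics parameters (smoothing sigma, TFCE E/H/dh, permutation
#' count) and the seeds. Validation enforces that every reduced model's
#' features are a strict subset of the full model's and that only defined
#' features are named (see [feature_registry()]). Configurations
#' round-trip through serialization unchanged.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: a validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a `run_config` (or plain list with the same fields).
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  config <- as.list(config)
  defaults <- list(fs = 100,
                   basis = list(tmin_ms = -100, tmax_ms = 1000,
                                width_ms = 50, stride_ms = 10),
                   step = 0.005, k = 4,
                   features = c("word_onset", "phoneme_onset",
                                "sublexical_surprisal"),
                   reduced_models = list(),
                   stats = list(sigma = 1, E = 0.5, H = 2, dh = 0.1,
                                n_perm = 10000),
                   seed = 1)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  reg <- feature_registry()
  bad <- setdiff(unlist(c(config$features, config$reduced_models)),
                 reg$name)
  if (length(bad))
    stop("unknown feature(s) in config: ", paste(bad, collapse = ", "))
  undef <- intersect(unlist(c(config$features, config$reduced_models)),
                     reg$name[!reg$defined])
  if (length(undef))
    stop("feature(s) not defined: ", paste(undef, collapse = ", "))
  for (nm in names(config$reduced_models)) {
    r <- config$reduced_models[[nm]]
    if (!all(r %in% config$features) || setequal(r, config$features))
      stop("reduced model '", nm,
           "' must be a strict subset of the full feature set")
  }
  if (config$fs <= 0) stop("config: fs must be > 0")
  if (config$step <= 0) stop("config: step must be > 0")
  if (config$k < 3) stop("config: need k >= 3 folds")
  class(config) <- "run_config"
  config
}
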