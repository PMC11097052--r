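# Detector registry: uniform dispatch for the CLI, the optimizer and the
# validation harness.

detector_registry <- function() {
  list(
    paraschiv2019 = detect_paraschiv2019,
    paraschiv2020 = detect_paraschiv2020,
    iluz          = detect_iluz,
    gu            = detect_gu,
    karas         = detect_karas,
    hickey        = detect_hickey,
    kheirkhahan   = detect_kheirkhahan
  )
}

#' Names of the registered gait-detection algorithms
#' @return character vector of registry keys.
#' @export
gsd_algorithms <- function() names(detector_registry())

#' Load the shipped parameter banks
#'
#' Reads the YAML parameter bank (default and wrist-optimized parameter sets
#' per algorithm, values as published) shipped with the package, or a
#' user-supplied file in the same layout.
#'
#' @param path optional path to a YAML file; defaults to the shipped bank.
#' @return nested list: algorithm -> bank -> parameters.
#' @export
load_parameter_banks <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("params", "parameter_banks.yaml", package = "wristgsd")
  yaml::read_yaml(path)
}

#' Look up a detector's parameters
#'
#' @param name registry key.
#' @param bank `"default"` or `"optimized"`.
#' @param banks optional bank list from [load_parameter_banks()].
#' @return named list of parameters.
#' @export
detector_params <- function(name, bank = c("default", "optimized"),
                            banks = NULL) {
  bank <- match.arg(bank)
  if (is.null(banks)) banks <- load_parameter_banks()
  if (is.null(banks[[name]]))
    stop(sprintf("unknown algorithm '%s'; registry: %s", name,
                 paste(gsd_algorithms(), collapse = ", ")))
  banks[[name]][[bank]]
}

#' Run a registered detector on a recording
#'
#' Dispatches by registry key with the requested parameter bank, applying
#' explicit overrides on top. The parameters actually used are attached to
#' the result as the `"params"` attribute and logged at message level when
#' `verbose = TRUE`.
#'
#' @param name registry key; see [gsd_algorithms()].
#' @param recording a `gsd_recording`.
#' @param bank `"default"` or `"optimized"`.
#' @param params_override named list of parameter overrides.
#' @param verbose log the dispatch.
#' @return a `gs_list` with a `"params"` attribute.
#' @export
run_algorithm <- function(name, recording, bank = "default",
                          params_override = list(), verbose = FALSE) {
  reg <- detector_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown algorithm '%s'; registry: %s", name,
                 paste(names(reg), collapse = ", ")))
  params <- detector_params(name, bank)
  params[names(params_override)] <- params_override
  if (verbose)
    message(sprintf("[wristgsd] %s (%s bank): %s", name, bank,
                    paste(names(params), unlist(params), sep = "=", collapse = " ")))
  out <- do.call(reg[[name]], c(list(recording = recording), params))
  attr(out, "params") <- params
  attr(out, "bank") <- bank
  out
}
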