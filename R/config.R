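#' Default hierarchical configuration
#'
#' Every constant of the model — the map geometry, the stimulus equation, the
#' lateral-connectivity equations, the rostral-caudal gradients, both AdEx
#' parameter sets and the decoder — collected in one nested list, suitable for
#' serialization to YAML. [model_from_config()] turns such a list back into a
#' calibrated model.
#'
#' @return nested named list with sections \code{map}, \code{stimulus},
#'   \code{network}, \code{adex_input}, \code{adex_sc}, \code{decoder} and
#'   \code{simulation}.
#' @export
default_config <- function() {
  strip <- function(p) p[setdiff(names(p), "layer")]
  list(
    map = list(n_neurons = 200L, length_mm = 5.0, A_deg = 3.0, B_u_mm = 1.4),
    stimulus = list(I0 = 3.0, sigma_pop = 0.5, beta = 0.03, gamma = 1.8,
                    T_deg = 15, t_end = 400),
    network = unclass(network_config()),
    adex_input = strip(unclass(adex_params("input"))),
    adex_sc = strip(unclass(adex_params("sc"))),
    decoder = list(N_ref = 500, target_rate_sps = 550),
    simulation = list(dt = 0.05)
  )
}

#' Read a configuration file
#'
#' YAML-format configuration; missing keys fall back to [default_config()].
#'
#' @param path file path, or \code{NULL} for the defaults.
#' @return nested list as in [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_config: the 'yaml' package is required to read config files")
  }
  user <- yaml::read_yaml(path)
  for (sec in intersect(names(user), names(cfg))) {
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

#' Write a configuration file
#'
#' @param cfg nested list as in [default_config()].
#' @param path destination file.
#' @export
write_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("write_config: the 'yaml' package is required to write config files")
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build and calibrate a model from a configuration
#'
#' @param cfg nested list as in [default_config()].
#' @return a calibrated \code{sc_model} (see [calibrate_model()]).
#' @export
model_from_config <- function(cfg = default_config()) {
  net_cfg <- do.call(network_config,
                     cfg$network[setdiff(names(cfg$network), character(0))])
  grid <- map_grid(cfg$map$n_neurons, cfg$map$length_mm)
  calibrate_model(
    cfg = net_cfg, grid = grid,
    input_params = do.call(adex_params, c(list(layer = "input"), cfg$adex_input)),
    sc_params = do.call(adex_params, c(list(layer = "sc"), cfg$adex_sc)),
    target_rate_sps = cfg$decoder$target_rate_sps,
    T_deg = cfg$stimulus$T_deg, N_ref = cfg$decoder$N_ref,
    dt = cfg$simulation$dt
  )
}
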