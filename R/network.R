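#' Network configuration
#'
#' Constants of the two-layer topology: the Mexican-hat lateral connectivity
#' of the SC layer (short-range excitation, width \code{sigma_exc}; long-range
#' inhibition, width \code{sigma_inh}), and the three rostral-caudal gradients
#' obtained from the tuning of the model — the adaptation time constant
#' \code{tau_q(u) = 60 - 12 u}, the feedforward projection strength
#' \code{w_FS(u) = 10 - 1.2 u}, and the lateral gain \code{S(u) = 1 - 0.04 u^2}
#' that scales the outgoing lateral weights of each neuron.
#'
#' @param W_exc_bar excitatory lateral weight scale, nS.
#' @param W_inh_bar inhibitory lateral depth, nS.
#' @param sigma_exc,sigma_inh Gaussian widths of the lateral profiles, mm.
#' @param tau_q_intercept,tau_q_slope adaptation gradient (ms, ms/mm).
#' @param wFS_intercept,wFS_slope feedforward gradient (nS, nS/mm).
#' @param S_coeff quadratic coefficient of the lateral gain, 1/mm^2.
#' @param scale_side whether the lateral gain S is evaluated at the
#'   \code{"source"} (default: outgoing weights scale with the presynaptic
#'   neuron's site) or the \code{"target"} neuron (sensitivity tests).
#' @param I_sat saturation scale of the input-layer rate cap, pA.
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(W_exc_bar = 0.16, W_inh_bar = 1.15,
                           sigma_exc = 0.2, sigma_inh = 0.7,
                           tau_q_intercept = 60, tau_q_slope = -12,
                           wFS_intercept = 10, wFS_slope = -1.2,
                           S_coeff = 0.04,
                           scale_side = c("source", "target"),
                           I_sat = 15) {
  scale_side <- match.arg(scale_side)
  stopifnot(sigma_exc > 0, sigma_inh > 0, W_exc_bar >= 0, W_inh_bar >= 0,
            I_sat >= 0)
  if (sigma_exc >= sigma_inh) {
    stop("network_config: sigma_exc must be smaller than sigma_inh ",
         "(short-range excitation, long-range inhibition)")
  }
  structure(
    list(W_exc_bar = W_exc_bar, W_inh_bar = W_inh_bar,
         sigma_exc = sigma_exc, sigma_inh = sigma_inh,
         tau_q_intercept = tau_q_intercept, tau_q_slope = tau_q_slope,
         wFS_intercept = wFS_intercept, wFS_slope = wFS_slope,
         S_coeff = S_coeff, scale_side = scale_side, I_sat = I_sat),
    class = "network_config"
  )
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    paste0("<network_config> W_exc = %.3g nS (sigma %.3g mm), ",
           "W_inh = %.3g nS (sigma %.3g mm), S at %s\n"),
    x$W_exc_bar, x$sigma_exc, x$W_inh_bar, x$sigma_inh, x$scale_side))
  invisible(x)
}

#' Location-dependent SC parameters
#'
#' Evaluates the three rostral-caudal gradients at a map position:
#' adaptation time constant \code{tau_q}, feedforward weight \code{w_FS} and
#' lateral gain \code{S}.
#'
#' @param u_mm map position(s) in \code{[0, 5]} mm.
#' @param cfg a [network_config()].
#' @return list with fields \code{tau_q} (ms), \code{w_FS} (nS) and \code{S}
#'   (dimensionless).
#' @examples
#' location_params(2.5)  # tau_q = 30 ms, w_FS = 7 nS, S = 0.75
#' @export
location_params <- function(u_mm, cfg = network_config()) {
  if (any(u_mm < 0) || any(u_mm > 5)) {
    stop("location_params: u must lie within [0, 5] mm")
  }
  list(
    tau_q = cfg$tau_q_intercept + cfg$tau_q_slope * u_mm,
    w_FS = cfg$wFS_intercept + cfg$wFS_slope * u_mm,
    S = 1 - cfg$S_coeff * u_mm^2
  )
}

#' Lateral connection weights between two SC neurons
#'
#' The Mexican-hat pair for a directed connection from the neuron at
#' \code{u_source} to the one at \code{u_target}:
#' \deqn{w_{exc} = S \bar W_{exc} e^{-d^2 / 2\sigma_{exc}^2}, \qquad
#'       w_{inh} = S (1 - \bar W_{inh} e^{-d^2 / 2\sigma_{inh}^2}),}
#' with \code{d} the anatomical distance and \code{S} the site-dependent gain
#' (evaluated at the source neuron by default). At short range \code{w_inh}
#' is negative — net disinhibition — which [route_signed_weights()] resolves
#' into physical, non-negative conductance increments.
#'
#' @param u_source,u_target map positions, mm (must differ: no
#'   self-connection).
#' @param cfg a [network_config()].
#' @return list with fields \code{w_exc} and \code{w_inh} (nS; \code{w_inh}
#'   may be negative at short range).
#' @export
lateral_weight <- function(u_source, u_target, cfg = network_config()) {
  if (any(u_source == u_target)) {
    stop("lateral_weight: self-connections are not defined (u_source == u_target)")
  }
  d2 <- (u_source - u_target)^2
  S <- location_params(if (cfg$scale_side == "source") u_source else u_target,
                       cfg)$S
  list(
    w_exc = S * cfg$W_exc_bar * exp(-d2 / (2 * cfg$sigma_exc^2)),
    w_inh = S * (1 - cfg$W_inh_bar * exp(-d2 / (2 * cfg$sigma_inh^2)))
  )
}

#' Route signed lateral weights onto physical conductances
#'
#' The short-range limb of the inhibitory profile is negative (net
#' disinhibition). Conductances cannot be negative, so the negative part is
#' routed onto the excitatory synapse: the excitatory increment is
#' \code{w_exc + max(0, -w_inh)} and the inhibitory increment
#' \code{max(0, w_inh)}. The net drive \code{w_exc - w_inh} is preserved in
#' sign, and approximately in magnitude near the resting potential.
#'
#' @param w_exc,w_inh signed weight pair(s), nS.
#' @return list with non-negative fields \code{exc} and \code{inh}, nS.
#' @export
route_signed_weights <- function(w_exc, w_inh) {
  list(exc = w_exc + pmax(-w_inh, 0), inh = pmax(w_inh, 0))
}

#' Build the two-layer SC network
#'
#' Assembles the full model: an input layer with no recurrent synapses,
#' one-to-one topography-preserving feedforward projections with the gradient
#' weight \code{w_FS(u)} (strong rostrally, weak caudally), and all-to-all
#' (minus self) lateral connectivity in the SC layer with the routed
#' Mexican-hat weights. The SC adaptation time constant follows the
#' \code{tau_q(u)} gradient.
#'
#' @param cfg a [network_config()].
#' @param grid a [map_grid()].
#' @param input_params,sc_params [adex_params()] for the two layers.
#' @return An object of class \code{sc_network}.
#' @export
build_network <- function(cfg = network_config(), grid = map_grid(),
                          input_params = adex_params("input"),
                          sc_params = adex_params("sc")) {
  stopifnot(inherits(cfg, "network_config"), inherits(grid, "map_grid"))
  u <- grid$positions
  loc <- location_params(u, cfg)
  if (any(loc$tau_q <= 0)) stop("build_network: tau_q gradient non-positive on the grid")
  if (any(loc$w_FS <= 0)) stop("build_network: w_FS gradient non-positive on the grid")
  if (any(loc$S < 0)) stop("build_network: lateral gain S negative on the grid")

  n <- grid$n_neurons
  d2 <- outer(u, u, function(a, b) (a - b)^2)
  S_row <- if (cfg$scale_side == "source") loc$S else rep(1, n)
  S_col <- if (cfg$scale_side == "target") loc$S else rep(1, n)
  Smat <- outer(S_row, S_col)   # one factor is all-ones
  w_exc <- Smat * cfg$W_exc_bar * exp(-d2 / (2 * cfg$sigma_exc^2))
  w_inh <- Smat * (1 - cfg$W_inh_bar * exp(-d2 / (2 * cfg$sigma_inh^2)))
  routed <- route_signed_weights(w_exc, w_inh)
  diag(routed$exc) <- 0
  diag(routed$inh) <- 0

  structure(
    list(
      cfg = cfg, grid = grid,
      input_params = input_params, sc_params = sc_params,
      w_FS = loc$w_FS, tau_q = loc$tau_q, S = loc$S,
      W_exc_routed = routed$exc, W_inh_routed = routed$inh,
      par_input = adex_param_matrix(input_params, n),
      par_sc = adex_param_matrix(sc_params, n, tau_q = loc$tau_q)
    ),
    class = "sc_network"
  )
}

#' @export
print.sc_network <- function(x, ...) {
  cat(sprintf(
    "<sc_network> 2 x %d AdEx neurons on [0, %g] mm; feedforward w_FS in [%.3g, %.3g] nS\n",
    x$grid$n_neurons, x$grid$length_mm, min(x$w_FS), max(x$w_FS)))
  invisible(x)
}

#' Simulate the network for one stimulus
#'
#' Runs the compiled two-layer AdEx integrator for the duration of the
#' stimulus spec. The model has no noise source, so identical parameters and
#' stimulus give bit-identical spike trains. Spikes are delivered within the
#' step in which they occur (zero axonal delay).
#'
#' @param network an [build_network()] object.
#' @param spec a [stimulus_spec()].
#' @param dt integration step, ms (0 < dt <= 0.1; default 0.05).
#' @param monitor_sc integer indices (1-based) of SC neurons whose membrane
#'   potential should be recorded.
#' @return list with elements \code{input} and \code{sc}, each a
#'   \code{spike_record}, plus \code{V_sc} (matrix, one column per monitored
#'   neuron) when requested.
#' @export
simulate_network <- function(network, spec, dt = 0.05, monitor_sc = integer(0)) {
  stopifnot(inherits(network, "sc_network"), inherits(spec, "stimulus_spec"),
            dt > 0, dt <= 0.1)
  if (spec$t_end < spec$gamma / spec$beta) {
    stop("simulate_network: t_end shorter than the stimulus rise (gamma/beta)")
  }
  u <- network$grid$positions
  n_steps <- as.integer(ceiling(spec$t_end / dt))
  t_steps <- (seq_len(n_steps) - 1) * dt
  spatial <- spec$I0 * exp(-(u - spec$u_T)^2 / (2 * spec$sigma_pop^2))
  temporal <- gamma_profile(t_steps, spec$beta, spec$gamma)

  raw <- simulate_network_cpp(
    network$par_input, network$par_sc, spatial, temporal,
    network$cfg$I_sat, network$w_FS,
    network$W_exc_routed, network$W_inh_routed,
    dt, as.integer(monitor_sc)
  )
  out <- list(
    input = spike_record("input", raw$input_neuron, raw$input_t,
                         network$grid, dt, spec$t_end),
    sc = spike_record("sc", raw$sc_neuron, raw$sc_t,
                      network$grid, dt, spec$t_end)
  )
  if (length(monitor_sc)) {
    out$V_sc <- raw$V_sc
    attr(out$V_sc, "t_ms") <- t_steps
    colnames(out$V_sc) <- paste0("n", monitor_sc)
  }
  out
}

#' Spike record of one layer
#'
#' Per-neuron spike times for one simulated layer, stored as a long-format
#' data.frame. Neuron indices are 1-based; the anatomical position of neuron
#' \code{i} is \code{positions[i]}.
#'
#' @param layer layer tag (\code{"input"} or \code{"sc"}).
#' @param neuron integer vector of spiking neuron indices (1-based).
#' @param t_ms spike times, ms.
#' @param grid the [map_grid()] of the network.
#' @param dt integration step used, ms.
#' @param t_end simulated duration, ms.
#' @return An object of class \code{spike_record}: list with \code{layer},
#'   \code{n_neurons}, \code{positions}, \code{dt}, \code{t_end} and
#'   \code{spikes} (data.frame with columns \code{neuron}, \code{u_mm},
#'   \code{t_ms}).
#' @export
spike_record <- function(layer, neuron, t_ms, grid, dt, t_end) {
  neuron <- as.integer(neuron)
  stopifnot(length(neuron) == length(t_ms),
            all(neuron >= 1), all(neuron <= grid$n_neurons),
            all(t_ms >= 0), all(t_ms <= t_end))
  structure(
    list(layer = layer, n_neurons = grid$n_neurons,
         positions = grid$positions, dt = dt, t_end = t_end,
         spikes = data.frame(neuron = neuron,
                             u_mm = grid$positions[neuron],
                             t_ms = as.numeric(t_ms))),
    class = "spike_record"
  )
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> layer %s: %d spikes from %d/%d neurons over %g ms\n",
              x$layer, nrow(x$spikes), length(unique(x$spikes$neuron)),
              x$n_neurons, x$t_end))
  invisible(x)
}

#' Per-neuron spike counts
#'
#' @param record a [spike_record()].
#' @return integer vector of length \code{n_neurons}.
#' @export
spike_counts <- function(record) {
  stopifnot(inherits(record, "spike_record"))
  tabulate(record$spikes$neuron, nbins = record$n_neurons)
}

#' Write / read a spike record as tabular text
#'
#' Plain TSV with header \code{layer, neuron, u_mm, t_ms}; the companion
#' reader restores a \code{spike_record} given the grid it was simulated on.
#'
#' @param record a [spike_record()].
#' @param path file path.
#' @export
write_spike_record <- function(record, path) {
  stopifnot(inherits(record, "spike_record"))
  df <- cbind(layer = record$layer, record$spikes)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_record
#' @param grid the [map_grid()] the record refers to.
#' @param dt,t_end simulation step and duration (ms) to annotate the record
#'   with; \code{t_end} defaults to the latest spike time.
#' @export
read_spike_record <- function(path, grid = map_grid(), dt = 0.05, t_end = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("layer", "neuron", "t_ms") %in% names(df)))
  if (is.null(t_end)) t_end <- if (nrow(df)) max(df$t_ms) else 0
  spike_record(df$layer[1] %||% "sc", df$neuron, df$t_ms, grid, dt, t_end)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
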