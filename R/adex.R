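#' AdEx neuron parameters
#'
#' Biophysical constants of one adaptive exponential integrate-and-fire
#' neuron with conductance-based synapses. Units follow the
#' (mV, ms, pA, pF, nS) system, so all equations balance without conversion
#' factors. Two default sets are provided, one per layer:
#' \describe{
#'   \item{input}{a fast, non-adapting cell whose firing rate follows the
#'     external current near-linearly up to the 400 spikes/s cap enforced by
#'     the 2.5 ms refractory period;}
#'   \item{sc}{an adapting cell (spike-triggered increment \code{b}) whose
#'     adaptation time constant \code{tau_q} is later overridden per neuron by
#'     the rostral-caudal gradient.}
#' }
#' The membrane scale (\code{C}, \code{g_L}) is deliberately small so that the
#' pA-scale input currents of the stimulus protocols are suprathreshold;
#' [calibrate_model()] can rescale the pair jointly without changing the
#' membrane time constant.
#'
#' @param layer \code{"input"} or \code{"sc"}, selecting the default set.
#' @param ... named overrides of individual constants (see Details).
#' @details Fields: \code{C} (pF), \code{g_L} (nS), \code{E_L}, \code{V_T},
#'   \code{Delta_T}, \code{V_reset}, \code{V_cut}, \code{E_exc}, \code{E_inh}
#'   (mV), \code{a} (nS), \code{b} (pA), \code{tau_q}, \code{t_ref},
#'   \code{tau_syn_exc}, \code{tau_syn_inh} (ms).
#' @return An object of class \code{adex_params} (named list).
#' @export
adex_params <- function(layer = c("input", "sc"), ...) {
  layer <- match.arg(layer)
  p <- switch(layer,
    input = list(
      C = 0.048, g_L = 0.015, E_L = -70, V_T = -50, Delta_T = 2,
      a = 0, b = 0, tau_q = 100, V_reset = -70, V_cut = -30, t_ref = 2.5,
      E_exc = 0, E_inh = -75, tau_syn_exc = 1, tau_syn_inh = 1,
      tau_syn_ff = 1
    ),
    sc = list(
      C = 12.6, g_L = 2.1, E_L = -70, V_T = -55, Delta_T = 2,
      a = 0, b = 9.2, tau_q = 30, V_reset = -60, V_cut = -30, t_ref = 1,
      E_exc = 0, E_inh = -75, tau_syn_exc = 2.73, tau_syn_inh = 32,
      tau_syn_ff = 0.3
    )
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) stop("adex_params: unknown fields ",
                              paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_adex_params(p)
  structure(c(p, list(layer = layer)), class = "adex_params")
}

validate_adex_params <- function(p) {
  stopifnot(p$C > 0, p$g_L > 0, p$Delta_T > 0, p$tau_q > 0,
            p$tau_syn_exc > 0, p$tau_syn_inh > 0, p$tau_syn_ff > 0,
            p$t_ref >= 0,
            p$E_inh < p$E_L, p$E_L < p$E_exc,
            p$V_reset <= p$V_T, p$V_T < p$V_cut)
  invisible(p)
}

#' @export
print.adex_params <- function(x, ...) {
  cat(sprintf("<adex_params> layer = %s\n", x$layer))
  flds <- setdiff(names(x), "layer")
  cat(paste(sprintf("  %s = %g", flds, unlist(x[flds])), collapse = "\n"), "\n")
  invisible(x)
}

#' AdEx dynamic state
#'
#' @param params an [adex_params()] object (supplies the resting potential).
#' @param V membrane potential (mV); defaults to the leak reversal.
#' @param q adaptation current (pA).
#' @param g_exc,g_inh synaptic conductances (nS, >= 0).
#' @param t_last_spike time of the last spike (ms; \code{-Inf} if none).
#' @return An object of class \code{adex_state}.
#' @export
adex_state <- function(params, V = params$E_L, q = 0,
                       g_exc = 0, g_inh = 0, t_last_spike = -Inf) {
  stopifnot(g_exc >= 0, g_inh >= 0)
  structure(list(V = V, q = q, g_exc = g_exc, g_inh = g_inh,
                 t_last_spike = t_last_spike),
            class = "adex_state")
}

#' Advance one AdEx neuron by one time step
#'
#' Reference single-neuron integrator, identical in semantics to the compiled
#' network loop: linearized exponential-Euler on the membrane potential (the
#' leak and synaptic conductance terms are integrated exactly over the step,
#' the spike-initiation exponential is explicit with its argument clamped at
#' +10 slope factors), forward Euler on the adaptation current, exponential
#' decay of the synaptic conductances, refractory clamp at \code{V_reset}, and
#' the spike stamped at the start of the step in which the potential crossed
#' \code{V_cut}.
#'
#' @param state an [adex_state()].
#' @param params an [adex_params()].
#' @param I_ext external current during the step, pA.
#' @param dt step, ms (0 < dt <= 0.1).
#' @param t current time (ms), used for the refractory clock.
#' @return list with fields \code{state} (updated) and \code{spiked} (logical).
#' @export
adex_step <- function(state, params, I_ext, dt, t = 0) {
  stopifnot(dt > 0, dt <= 0.1)
  p <- params; s <- state
  spiked <- FALSE
  if (t - s$t_last_spike < p$t_ref - 1e-12) {
    s$V <- p$V_reset
    s$q <- s$q + dt * (p$a * (s$V - p$E_L) - s$q) / p$tau_q
  } else {
    expo <- min((s$V - p$V_T) / p$Delta_T, 10)
    G <- p$g_L + s$g_exc + s$g_inh
    A <- p$g_L * p$E_L + p$g_L * p$Delta_T * exp(expo) +
      s$g_exc * p$E_exc + s$g_inh * p$E_inh - s$q + I_ext
    V_inf <- A / G
    dq <- (p$a * (s$V - p$E_L) - s$q) / p$tau_q
    s$V <- V_inf + (s$V - V_inf) * exp(-G * dt / p$C)
    s$q <- s$q + dt * dq
    if (!is.finite(s$V) || !is.finite(s$q)) stop("adex_step: non-finite state")
    if (s$V >= p$V_cut) {
      s$V <- p$V_reset
      s$q <- s$q + p$b
      s$t_last_spike <- t
      spiked <- TRUE
    }
  }
  s$g_exc <- s$g_exc * exp(-dt / p$tau_syn_exc)
  s$g_inh <- s$g_inh * exp(-dt / p$tau_syn_inh)
  list(state = s, spiked = spiked)
}

#' Deliver a presynaptic spike to a neuron
#'
#' Increments the excitatory or inhibitory synaptic conductance by a
#' non-negative routed weight (signed lateral weights are resolved upstream by
#' [route_signed_weights()]).
#'
#' @param state an [adex_state()].
#' @param weight conductance increment, nS (>= 0 after routing).
#' @param polarity \code{"excitatory"} or \code{"inhibitory"}.
#' @return the updated state.
#' @export
deliver_spike <- function(state, weight, polarity = c("excitatory", "inhibitory")) {
  polarity <- match.arg(polarity)
  if (weight < 0) stop("deliver_spike: routed weight must be >= 0")
  if (polarity == "excitatory") state$g_exc <- state$g_exc + weight
  else state$g_inh <- state$g_inh + weight
  state
}

#' Saturating input-output cap on the external drive
#'
#' Smooth sigmoidal compression \code{I_sat * tanh(drive / I_sat)} applied to
#' the external current of input-layer neurons, so that evoked firing rates
#' saturate instead of growing without bound; at or below the default peak
#' current (3 pA) the transfer is identity-like (within 2% for the default
#' \code{I_sat}). A 2.5 ms refractory period in the input layer makes the
#' 400 spikes/s ceiling a hard guarantee.
#'
#' @param drive external current, pA.
#' @param I_sat saturation scale, pA; \code{I_sat = 0} disables the cap.
#' @return effective drive, pA.
#' @export
rate_cap_transfer <- function(drive, I_sat = 15) {
  stopifnot(I_sat >= 0)
  if (I_sat == 0) return(drive)
  I_sat * tanh(drive / I_sat)
}

# per-neuron parameter matrix for the compiled loop (column order fixed by
# the enum in src/adex_network.cpp)
adex_param_matrix <- function(params, n, tau_q = NULL) {
  cols <- c("C", "g_L", "E_L", "V_T", "Delta_T", "a", "b", "tau_q",
            "V_reset", "V_cut", "t_ref", "E_exc", "E_inh",
            "tau_syn_exc", "tau_syn_inh", "tau_syn_ff")
  m <- matrix(rep(unlist(params[cols]), each = n), nrow = n,
              dimnames = list(NULL, cols))
  if (!is.null(tau_q)) {
    stopifnot(length(tau_q) == n, all(tau_q > 0))
    m[, "tau_q"] <- tau_q
  }
  m
}
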