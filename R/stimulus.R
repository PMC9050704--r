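#' External input current specification
#'
#' Parameters of the separable spatial-temporal cortical input current that
#' drives the input layer. The spatial factor is a Gaussian of width
#' \code{sigma_pop} centred on the image point \code{u_T}; the temporal factor
#' is a gamma-shaped burst \code{t^gamma * exp(-beta * t)}, normalized to unit
#' peak so that \code{I0} is the maximum current anywhere (attained at
#' \code{u = u_T}, \code{t = gamma / beta}). Time is in ms and \code{beta} in
#' 1/ms, which places the default current peak at 60 ms and gives input bursts
#' of order 150-300 ms over the swept \code{beta} range.
#'
#' @param I0 peak current amplitude, pA (>= 0).
#' @param sigma_pop spatial width of the recruited input population, mm (> 0).
#' @param beta inverse-duration parameter of the gamma profile, 1/ms (> 0).
#' @param gamma skewness (shape) of the gamma profile, dimensionless (> 0).
#' @param u_T centre of stimulation on the map, mm.
#' @param t_end simulated duration, ms.
#' @return An object of class \code{stimulus_spec}.
#' @examples
#' sp <- stimulus_spec()             # the default (control) stimulation
#' external_current(sp$u_T, 60, sp)  # peak current = I0 = 3 pA
#' @export
stimulus_spec <- function(I0 = 3.0, sigma_pop = 0.5, beta = 0.03,
                          gamma = 1.8, u_T = afferent_map(15), t_end = 400) {
  stopifnot(I0 >= 0, sigma_pop > 0, beta > 0, gamma > 0,
            u_T >= 0, u_T <= 5, t_end > 0)
  structure(
    list(I0 = I0, sigma_pop = sigma_pop, beta = beta, gamma = gamma,
         u_T = u_T, t_end = t_end),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> I0 = %.3g pA, sigma_pop = %.3g mm, beta = %.4g /ms, gamma = %.3g, u_T = %.4g mm, t_end = %g ms\n",
    x$I0, x$sigma_pop, x$beta, x$gamma, x$u_T, x$t_end
  ))
  invisible(x)
}

# unit-peak gamma burst profile; peak value 1 at t = gamma/beta
gamma_profile <- function(t, beta, gamma) {
  peak <- (gamma / beta)^gamma * exp(-gamma)
  ifelse(t <= 0, ifelse(t < 0, NA_real_, 0), t^gamma * exp(-beta * t) / peak)
}

#' Evaluate the external input current
#'
#' \code{I_ext(u, t) = I0 * exp(-(u - u_T)^2 / (2 sigma_pop^2)) * g(t)}, with
#' \code{g} the unit-peak gamma profile of the spec. Separable by construction:
#' the spatial factor depends only on \code{u}, the temporal one only on
#' \code{t}.
#'
#' @param u_mm map position(s), mm.
#' @param t_ms time(s) since stimulus onset, ms (>= 0).
#' @param spec a [stimulus_spec()].
#' @return current in pA (vector recycling rules of \code{*} apply).
#' @export
external_current <- function(u_mm, t_ms, spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (any(t_ms < 0)) stop("external_current: t must be >= 0")
  spatial <- exp(-(u_mm - spec$u_T)^2 / (2 * spec$sigma_pop^2))
  spec$I0 * spatial * gamma_profile(t_ms, spec$beta, spec$gamma)
}

#' Stimulus set for the spatial input-variation protocol
#'
#' Sweeps the recruited input population size over
#' \code{sigma_pop = 0.05-1.0 mm} at fixed temporal parameters
#' (\code{beta = 0.03}, \code{gamma = 1.8}). The current amplitude ramps
#' linearly from 2.0 pA at \code{sigma_pop = 0.05} to 3.0 pA at 0.5 mm and is
#' held at 3.0 pA for larger populations, mimicking microstimulation at
#' graded current strengths.
#'
#' @param sigma_grid population sizes to sweep, mm.
#' @param T_deg stimulation site (target eccentricity), deg.
#' @param t_end simulated duration per condition, ms.
#' @return list of [stimulus_spec()] objects, one per \code{sigma_grid} entry.
#' @export
spatial_sweep_specs <- function(sigma_grid = c(0.05, 0.1, 0.15, 0.2, 0.25,
                                               0.3, 0.4, 0.5, 0.6, 0.7,
                                               0.85, 1.0),
                                T_deg = 15, t_end = 400) {
  stopifnot(all(sigma_grid >= 0.05 - 1e-12), all(sigma_grid <= 1.0 + 1e-12))
  u_T <- afferent_map(T_deg)
  lapply(sigma_grid, function(s) {
    I0 <- if (s < 0.5) 2.0 + (s - 0.05) / (0.5 - 0.05) else 3.0
    stimulus_spec(I0 = I0, sigma_pop = s, u_T = u_T, t_end = t_end)
  })
}

#' Stimulus set for the temporal input-variation protocol
#'
#' Sweeps the input burst duration via \code{beta} in \code{[0.019, 0.030]}
#' 1/ms at fixed population size (\code{sigma_pop = 0.5} mm). For every
#' \code{beta}, the amplitude \code{I0} is found by bisection on a full network
#' simulation so that either
#' \describe{
#'   \item{\code{"fixed_output_spikes"}}{the total number of SC-layer spikes
#'     matches the default run's count (scenario i; \code{I0} searched in
#'     0.2-3.0 pA), or}
#'   \item{\code{"fixed_input_spikes"}}{the total number of input-layer spikes
#'     matches the default run's count (scenario ii; \code{I0} searched in
#'     1.2-3.0 pA).}
#' }
#' Calibration succeeds when the spike count is within \code{tol_frac} of the
#' default; a bracket failure is reported in the calibration record, never
#' silently clipped.
#'
#' @param scenario \code{"fixed_output_spikes"} or \code{"fixed_input_spikes"}.
#' @param network a network built by [build_network()].
#' @param beta_grid values of beta to sweep, 1/ms.
#' @param T_deg stimulation site, deg.
#' @param tol_frac relative tolerance on the matched spike count.
#' @param max_iter maximum bisection iterations per beta.
#' @param dt integration step, ms.
#' @return list with elements \code{specs} (list of [stimulus_spec()]) and
#'   \code{calibration} (data.frame: beta, I0, input_spikes, sc_spikes,
#'   converged).
#' @export
temporal_sweep_specs <- function(scenario = c("fixed_output_spikes",
                                              "fixed_input_spikes"),
                                 network,
                                 beta_grid = seq(0.019, 0.030, by = 0.001),
                                 T_deg = 15, tol_frac = 0.01,
                                 max_iter = 40, dt = 0.05) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(network, "sc_network"))
  u_T <- afferent_map(T_deg)
  I0_range <- if (scenario == "fixed_output_spikes") c(0.2, 3.0) else c(1.2, 3.0)

  count_spikes <- function(spec) {
    rec <- simulate_network(network, spec, dt = dt)
    c(input = nrow(rec$input$spikes), sc = nrow(rec$sc$spikes))
  }
  layer <- if (scenario == "fixed_output_spikes") "sc" else "input"
  default_spec <- stimulus_spec(u_T = u_T)
  target <- count_spikes(default_spec)[[layer]]

  specs <- vector("list", length(beta_grid))
  cal <- data.frame(beta = beta_grid, I0 = NA_real_,
                    input_spikes = NA_integer_, sc_spikes = NA_integer_,
                    converged = FALSE)
  for (k in seq_along(beta_grid)) {
    b <- beta_grid[k]
    make <- function(I0) stimulus_spec(I0 = I0, beta = b, u_T = u_T)
    lo <- I0_range[1]; hi <- I0_range[2]
    n_hi <- count_spikes(make(hi))[[layer]]
    if (abs(n_hi - target) <= tol_frac * target) {
      # the upper bound (the default amplitude) is its own calibration point
      specs[[k]] <- make(hi)
      cal[k, c("I0", "input_spikes", "sc_spikes", "converged")] <- {
        n <- count_spikes(make(hi))
        list(hi, n[["input"]], n[["sc"]], TRUE)
      }
      next
    }
    n_lo <- count_spikes(make(lo))[[layer]]
    # spike counts increase with I0; require the target inside the bracket
    if (n_lo > target * (1 + tol_frac) || n_hi < target * (1 - tol_frac)) {
      best <- if (abs(n_lo - target) < abs(n_hi - target)) lo else hi
      n <- count_spikes(make(best))
      specs[[k]] <- make(best)
      cal[k, c("I0", "input_spikes", "sc_spikes", "converged")] <-
        list(best, n[["input"]], n[["sc"]], FALSE)
      warning(sprintf(
        "temporal_sweep_specs: no I0 bracket for beta = %.4g (counts %d..%d, target %d)",
        b, n_lo, n_hi, target))
      next
    }
    mid <- hi; n_mid <- n_hi
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      n_mid <- count_spikes(make(mid))[[layer]]
      if (abs(n_mid - target) <= tol_frac * target) break
      if (n_mid < target) lo <- mid else hi <- mid
    }
    n <- count_spikes(make(mid))
    specs[[k]] <- make(mid)
    cal[k, c("I0", "input_spikes", "sc_spikes", "converged")] <-
      list(mid, n[["input"]], n[["sc"]],
           abs(n_mid - target) <= tol_frac * target)
  }
  list(specs = specs, calibration = cal, scenario = scenario, target = target)
}
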