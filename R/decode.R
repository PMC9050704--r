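#' Decode SC spike trains into an eye trajectory
#'
#' Linear ensemble decoding: every spike of SC neuron \code{n} adds its spike
#' vector \code{m_n = zeta * R(u_n) / N_ref} to the eye displacement, so
#' \code{S(t)} is the running weighted cumulative spike count of the
#' population. The final amplitude equals \code{sum(m_n * N_spk(n))} exactly,
#' independent of spike timing; no smoothing is applied to position.
#'
#' @param record a [spike_record()] from the SC layer.
#' @param zeta global decoder gain.
#' @param N_ref reference total spike count.
#' @param dt output time base, ms (default 1).
#' @param A_deg,B_u_mm efferent-map constants (see [efferent_map()]).
#' @return An object of class \code{saccade_trajectory}: data.frame with
#'   columns \code{t_ms} and \code{S_deg}, starting at \code{S(0) = 0}.
#' @export
decode_trajectory <- function(record, zeta = 1.0, N_ref = 500, dt = 1,
                              A_deg = 3.0, B_u_mm = 1.4) {
  stopifnot(inherits(record, "spike_record"), dt > 0)
  if (record$layer != "sc") {
    stop("decode_trajectory: expects spikes from the SC layer, got '",
         record$layer, "'")
  }
  t_grid <- seq(0, record$t_end, by = dt)
  S <- numeric(length(t_grid))
  if (nrow(record$spikes)) {
    m <- spike_vector(record$spikes$u_mm, zeta = zeta, N_ref = N_ref,
                      A_deg = A_deg, B_u_mm = B_u_mm,
                      length_mm = record$positions[record$n_neurons] + 1e-9)
    # bin each spike into the first grid point at or after its time
    bin <- pmin(findInterval(record$spikes$t_ms, t_grid, left.open = TRUE) + 1,
                length(t_grid))
    inc <- vapply(split(m, factor(bin, levels = seq_along(t_grid))), sum, 0)
    S <- cumsum(inc)
  }
  structure(data.frame(t_ms = t_grid, S_deg = S),
            class = c("saccade_trajectory", "data.frame"),
            dt = dt, zeta = zeta, N_ref = N_ref)
}

#' Instantaneous eye velocity via Savitzky-Golay differentiation
#'
#' Fits a local polynomial of the given order in a sliding window and returns
#' its first derivative, in deg/s. Polynomials up to the filter order are
#' differentiated exactly, so a linear ramp yields its slope to numerical
#' precision.
#'
#' @param traj a [decode_trajectory()] result.
#' @param window filter window length in samples (odd).
#' @param order polynomial order (< window).
#' @return the trajectory with an added \code{V_degs} column (deg/s).
#' @export
eye_velocity <- function(traj, window = 21, order = 3) {
  stopifnot(inherits(traj, "saccade_trajectory"),
            window %% 2 == 1, order < window)
  if (nrow(traj) < window) {
    stop("eye_velocity: trajectory shorter than the filter window")
  }
  dt <- attr(traj, "dt")
  # first-derivative Savitzky-Golay filter; ts = dt in ms, so scale to deg/s
  v <- signal::sgolayfilt(traj$S_deg, p = order, n = window, m = 1, ts = dt)
  traj$V_degs <- v * 1000
  traj
}

#' Saccade metrics from a decoded trajectory
#'
#' Onset and offset are the first and last crossings of 5% of the peak
#' velocity (a relative criterion that still works for the slow, small
#' near-threshold movements); amplitude is the displacement between them.
#'
#' @param traj a trajectory with a velocity column (see [eye_velocity()]).
#' @param onset_frac velocity threshold as a fraction of the peak.
#' @return An object of class \code{saccade_metrics}: list with \code{R_deg},
#'   \code{V_peak_degs}, \code{D_ms}, \code{onset_ms}, \code{offset_ms} and
#'   \code{flagged} (TRUE when no movement was detected and the duration is
#'   undefined).
#' @export
saccade_metrics <- function(traj, onset_frac = 0.05) {
  stopifnot(inherits(traj, "saccade_trajectory"),
            !is.null(traj$V_degs), onset_frac > 0, onset_frac < 1)
  V_peak <- max(traj$V_degs)
  if (!is.finite(V_peak) || V_peak <= 0) {
    return(structure(list(R_deg = 0, V_peak_degs = 0, D_ms = NA_real_,
                          onset_ms = NA_real_, offset_ms = NA_real_,
                          flagged = TRUE),
                     class = "saccade_metrics"))
  }
  above <- which(traj$V_degs >= onset_frac * V_peak)
  onset <- traj$t_ms[above[1]]
  offset <- traj$t_ms[above[length(above)]]
  structure(
    list(R_deg = traj$S_deg[above[length(above)]] - traj$S_deg[above[1]],
         V_peak_degs = V_peak, D_ms = offset - onset,
         onset_ms = onset, offset_ms = offset, flagged = FALSE),
    class = "saccade_metrics"
  )
}

#' @export
print.saccade_metrics <- function(x, ...) {
  if (x$flagged) cat("<saccade_metrics> no movement detected\n")
  else cat(sprintf(
    "<saccade_metrics> R = %.2f deg, V_peak = %.0f deg/s, D = %g ms (onset %g, offset %g)\n",
    x$R_deg, x$V_peak_degs, x$D_ms, x$onset_ms, x$offset_ms))
  invisible(x)
}

#' Spike density function of one spike train
#'
#' Gaussian-kernel rate estimate. Each spike's kernel is renormalized by its
#' analytic mass inside the evaluated interval, so the integral of the trace
#' equals the spike count regardless of edge effects.
#'
#' @param spike_times_ms spike times of one neuron, ms.
#' @param t_end end of the evaluation interval, ms.
#' @param dt evaluation step, ms.
#' @param sigma_ms kernel standard deviation, ms (> 0).
#' @return data.frame with columns \code{t_ms} and \code{rate_sps} (spikes/s).
#' @export
spike_density <- function(spike_times_ms, t_end, dt = 1, sigma_ms = 4) {
  stopifnot(sigma_ms > 0, dt > 0, t_end > 0)
  t_grid <- seq(0, t_end, by = dt)
  rate <- numeric(length(t_grid))
  for (ts in spike_times_ms) {
    mass <- stats::pnorm(t_end + dt / 2, ts, sigma_ms) -
      stats::pnorm(-dt / 2, ts, sigma_ms)
    rate <- rate + stats::dnorm(t_grid, ts, sigma_ms) / mass
  }
  data.frame(t_ms = t_grid, rate_sps = rate * 1000)
}

#' Central cell of a population burst
#'
#' The neuron with the maximal spike count; ties are broken toward the neuron
#' nearest the stimulation centre.
#'
#' @param record a [spike_record()].
#' @param u_T stimulation centre, mm.
#' @return 1-based neuron index.
#' @export
central_cell <- function(record, u_T) {
  counts <- spike_counts(record)
  top <- which(counts == max(counts))
  top[which.min(abs(record$positions[top] - u_T))]
}

#' Fit the saturating main-sequence relation
#'
#' Least-squares fit of \code{V_peak = V0 * (1 - exp(-alpha * R))} to
#' amplitude-peak-velocity pairs. The small-amplitude slope of the fitted
#' curve is \code{V0 * alpha}.
#'
#' @param R_deg saccade amplitudes, deg (> 0, length >= 3).
#' @param V_peak_degs peak velocities, deg/s.
#' @return An object of class \code{main_sequence_fit}: list with \code{V0},
#'   \code{alpha}, \code{residuals} and the \code{fit} object.
#' @export
fit_main_sequence <- function(R_deg, V_peak_degs) {
  stopifnot(length(R_deg) >= 3, length(R_deg) == length(V_peak_degs),
            all(R_deg > 0))
  df <- data.frame(R = R_deg, V = V_peak_degs)
  start <- list(V0 = max(df$V) * 1.2, alpha = 1 / stats::median(df$R))
  fit <- minpack.lm::nlsLM(V ~ V0 * (1 - exp(-alpha * R)), data = df,
                           start = start,
                           lower = c(V0 = 0, alpha = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(list(V0 = unname(est["V0"]), alpha = unname(est["alpha"]),
                 residuals = stats::residuals(fit), fit = fit),
            class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf(
    "<main_sequence_fit> V_peak = V0 (1 - exp(-alpha R)): V0 = %.4g deg/s, alpha = %.4g 1/deg (RMS resid %.3g)\n",
    x$V0, x$alpha, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Fit the linear kinematic relation V_peak * D = k * R
#'
#' Zero-intercept least squares for the dimensionless slope \code{k}. For
#' triangular velocity profiles \code{k = 2} exactly.
#'
#' @param R_deg amplitudes, deg (not all zero, length >= 2).
#' @param VD_deg products \code{V_peak * D}, deg (with D in s), same length.
#' @return An object of class \code{kinematic_fit}: list with \code{k},
#'   \code{residuals} and the \code{fit} object.
#' @export
fit_kinematic_slope <- function(R_deg, VD_deg) {
  stopifnot(length(R_deg) >= 2, length(R_deg) == length(VD_deg))
  if (all(R_deg == 0)) stop("fit_kinematic_slope: all amplitudes are zero")
  fit <- stats::lm(VD_deg ~ 0 + R_deg)
  structure(list(k = unname(stats::coef(fit)[1]),
                 residuals = stats::residuals(fit), fit = fit),
            class = "kinematic_fit")
}

#' @export
print.kinematic_fit <- function(x, ...) {
  cat(sprintf("<kinematic_fit> V_peak * D = k R: k = %.3f (RMS resid %.3g)\n",
              x$k, sqrt(mean(x$residuals^2))))
  invisible(x)
}
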