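#' Anatomical lattice of the motor map
#'
#' Builds the one-dimensional lattice of neuron positions on the rostral-caudal
#' axis of the SC motor map. Both layers of the network share this lattice
#' (one-to-one feedforward topology), so a single grid describes the whole
#' model. Positions start at 0 mm and are uniformly spaced by
#' \code{length_mm / n_neurons}, so with the defaults neuron index 100
#' (0-based) sits at exactly 2.5 mm.
#'
#' @param n_neurons number of neurons per layer.
#' @param length_mm extent of the map in mm.
#' @return An object of class \code{map_grid} with fields \code{n_neurons},
#'   \code{length_mm} and \code{positions} (mm, 0-based index order).
#' @examples
#' g <- map_grid()
#' g$positions[101]   # neuron nr. 100 sits at 2.5 mm
#' @export
map_grid <- function(n_neurons = 200L, length_mm = 5.0) {
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 2L, length_mm > 0)
  grid <- structure(
    list(
      n_neurons = n_neurons,
      length_mm = length_mm,
      positions = (seq_len(n_neurons) - 1L) * (length_mm / n_neurons)
    ),
    class = "map_grid"
  )
  grid
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf(
    "<map_grid> %d neurons on [0, %.3g] mm (spacing %.4g mm)\n",
    x$n_neurons, x$length_mm, x$length_mm / x$n_neurons
  ))
  invisible(x)
}

#' Afferent mapping: target eccentricity to map coordinate
#'
#' Logarithmic magnification of visual eccentricity onto the anatomical
#' rostral-caudal axis, \code{u = B_u * log((T + A) / A)}. With the default
#' constants (\code{A = 3} deg, \code{B_u = 1.4} mm) a 15-deg target lands at
#' the 2.5 mm site, the conventional anchor for the horizontal meridian.
#'
#' @param T_deg target eccentricity in degrees (scalar or vector, >= 0).
#' @param A_deg mapping offset in degrees.
#' @param B_u_mm mapping scale in mm.
#' @return map coordinate(s) u in mm.
#' @seealso [efferent_map()] for the exact inverse.
#' @export
afferent_map <- function(T_deg, A_deg = 3.0, B_u_mm = 1.4) {
  stopifnot(A_deg > 0, B_u_mm > 0)
  if (any(T_deg < 0)) stop("afferent_map: eccentricity T must be >= 0")
  B_u_mm * log((T_deg + A_deg) / A_deg)
}

#' Efferent mapping: map coordinate to saccade eccentricity
#'
#' Exact inverse of [afferent_map()]: \code{R(u) = A * (exp(u / B_u) - 1)} deg.
#'
#' @param u_mm map coordinate(s) in mm, within \code{[0, length_mm]}.
#' @param A_deg,B_u_mm mapping constants, as in [afferent_map()].
#' @param length_mm upper bound of the admissible map coordinate.
#' @return eccentricity in degrees.
#' @export
efferent_map <- function(u_mm, A_deg = 3.0, B_u_mm = 1.4, length_mm = 5.0) {
  stopifnot(A_deg > 0, B_u_mm > 0)
  if (any(u_mm < 0) || any(u_mm > length_mm)) {
    stop("efferent_map: u must lie within [0, ", length_mm, "] mm")
  }
  A_deg * (exp(u_mm / B_u_mm) - 1)
}

#' Per-spike movement contribution (spike vector)
#'
#' Every spike of an SC neuron adds a fixed miniature displacement to the eye
#' trajectory, determined solely by the neuron's map position: rostral cells
#' contribute small vectors, caudal cells large ones. The contribution is
#' \code{m(u) = zeta * R(u) / N_ref}, where \code{R(u)} is the efferent
#' mapping, \code{N_ref} the fixed total SC spike budget of a saccade, and
#' \code{zeta} a dimensionless global gain calibrated once so that the default
#' stimulation at T = 15 deg decodes to a 15-deg saccade.
#'
#' @param u_mm map coordinate(s) in mm.
#' @param zeta global decoder gain (> 0).
#' @param N_ref reference total spike count (> 0).
#' @param A_deg,B_u_mm,length_mm efferent-map constants.
#' @return displacement per spike, in degrees.
#' @export
spike_vector <- function(u_mm, zeta = 1.0, N_ref = 500,
                         A_deg = 3.0, B_u_mm = 1.4, length_mm = 5.0) {
  stopifnot(zeta > 0, N_ref > 0)
  zeta * efferent_map(u_mm, A_deg, B_u_mm, length_mm) / N_ref
}
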