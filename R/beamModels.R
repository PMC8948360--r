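#' Construct a doughnut beam profile
#'
#' The doughnut (ring) radius defaults to the diffraction-limited scale
#' \eqn{R = \lambda / (2\,NA)}, so longer multiphoton wavelengths produce
#' proportionally larger patterns. Pass `doughnutRadius` to override.
#'
#' @param wavelength excitation wavelength in nm (> 0).
#' @param numericalAperture objective numerical aperture, in (0, 1.7].
#' @param doughnutRadius optional override of the ring radius in nm.
#' @return a [BeamProfile-class].
#' @examples
#' b <- makeBeamProfile(647, 1.4)
#' doughnutRadius(b)        # 231.07 nm
#' doughnutIntensity(b, c(0, 0))                 # exact zero on axis
#' doughnutIntensity(b, c(doughnutRadius(b), 0)) # 1 at the ring
#' @export
makeBeamProfile <- function(wavelength, numericalAperture = 1.4,
                            doughnutRadius = NULL) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      !is.finite(wavelength) || wavelength <= 0)
    stop("invalid parameter: wavelength must be a positive number (nm)")
  if (!is.numeric(numericalAperture) || length(numericalAperture) != 1L ||
      !is.finite(numericalAperture) || numericalAperture <= 0 ||
      numericalAperture > 1.7)
    stop("invalid parameter: numericalAperture must lie in (0, 1.7]")
  R <- if (is.null(doughnutRadius)) wavelength / (2 * numericalAperture)
       else doughnutRadius
  new("BeamProfile", wavelength = wavelength,
      numericalAperture = numericalAperture, doughnutRadius = R)
}

#' @describeIn makeBeamProfile ring radius accessor (nm).
#' @param x a `BeamProfile`.
#' @export
setMethod("doughnutRadius", "BeamProfile", function(x) x@doughnutRadius)

# Core radial profile on squared radius; u = rho^2 / R^2.
# Peak-normalized: e * u * exp(-u) is 0 at u = 0 and 1 at u = 1 (rho = R).
.doughnut <- function(rho2, R) {
  u <- rho2 / (R * R)
  exp(1) * u * exp(-u)
}

.asDisplacementMatrix <- function(displacement) {
  if (is.matrix(displacement)) {
    if (ncol(displacement) != 2L)
      stop("displacement matrix must have 2 columns (x, y in nm)")
    displacement
  } else {
    if (length(displacement) != 2L)
      stop("displacement must be a length-2 vector or an n x 2 matrix")
    matrix(displacement, ncol = 2L)
  }
}

#' Doughnut intensity at a lateral displacement
#'
#' Evaluates the peak-normalized doughnut profile
#' \eqn{I(\rho) = e\,(\rho^2/R^2)\exp(-\rho^2/R^2)} at the given
#' displacement(s) from the beam axis. Radially symmetric, exactly 0 on
#' axis, maximum 1 at \eqn{\rho = R}.
#'
#' @param beam a [BeamProfile-class].
#' @param displacement length-2 vector or n-by-2 matrix of displacements (nm).
#' @return relative intensity in \[0, 1\], one value per displacement row.
#' @export
doughnutIntensity <- function(beam, displacement) {
  stopifnot(is(beam, "BeamProfile"))
  d <- .asDisplacementMatrix(displacement)
  .doughnut(d[, 1]^2 + d[, 2]^2, beam@doughnutRadius)
}

#' Effective multiphoton excitation rate
#'
#' The fluorescence rate under order-c excitation is proportional to the
#' c-th power of the excitation intensity: linear (c = 1), two-photon
#' (c = 2), three-photon (c = 3), or fractional c >= 1 for effective
#' superlinear schemes. Raising to c preserves the intensity zero and
#' sharpens the minimum.
#'
#' @inheritParams doughnutIntensity
#' @param order excitation order c (finite real >= 1).
#' @return relative excitation rate in \[0, 1\], one value per row.
#' @export
effectiveExcitation <- function(beam, displacement, order) {
  if (!is.numeric(order) || length(order) != 1L || !is.finite(order) ||
      order < 1)
    stop("invalid parameter: order must be a finite real >= 1")
  doughnutIntensity(beam, displacement)^order
}

setMethod("show", "BeamProfile", function(object) {
  cat("BeamProfile: lambda =", object@wavelength, "nm, NA =",
      object@numericalAperture, ", doughnut radius =",
      format(object@doughnutRadius, digits = 6), "nm\n")
})
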