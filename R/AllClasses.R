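#' @import methods
NULL

#' Doughnut excitation beam profile
#'
#' Parametric model of a focused beam with an on-axis intensity zero and a
#' ring-shaped maximum ("minimum of light"). The radial profile is the
#' peak-normalized paraxial doughnut
#' \deqn{I(\rho) = e \, (\rho^2/R^2) \, \exp(-\rho^2/R^2),}
#' which is exactly 0 at \eqn{\rho = 0} and exactly 1 at the ring radius
#' \eqn{\rho = R}. Absolute intensity units are irrelevant downstream
#' (exposure probabilities are scale-invariant), so peak normalization just
#' fixes a reproducible convention.
#'
#' @slot wavelength excitation wavelength in nm.
#' @slot numericalAperture objective numerical aperture (dimensionless).
#' @slot doughnutRadius radial position of the intensity maximum in nm;
#'   defaults to the diffraction-limited scale \eqn{\lambda / (2\,NA)}.
#'
#' @seealso [makeBeamProfile()], [doughnutIntensity()], [effectiveExcitation()]
#' @export
setClass("BeamProfile",
  representation(
    wavelength = "numeric",
    numericalAperture = "numeric",
    doughnutRadius = "numeric"
  )
)

setValidity("BeamProfile", function(object) {
  msg <- character()
  if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive finite number (nm)")
  if (length(object@numericalAperture) != 1L ||
      !is.finite(object@numericalAperture) ||
      object@numericalAperture <= 0 || object@numericalAperture > 1.7)
    msg <- c(msg, "numericalAperture must lie in (0, 1.7]")
  if (length(object@doughnutRadius) != 1L || !is.finite(object@doughnutRadius) ||
      object@doughnutRadius <= 0)
    msg <- c(msg, "doughnutRadius must be a single positive finite number (nm)")
  if (length(msg)) msg else TRUE
})

#' Ordered sequence of excitation-pattern center positions
#'
#' The set of positions \eqn{r_i} at which the beam's intensity minimum is
#' placed during one localization event. Two geometries are supported:
#' MINFLUX (vertices of an equilateral triangle of circumradius L/2 plus a
#' final exposure at the pattern center, K = 4) and RASTMIN (a regular m-by-m
#' raster of minima spanning the field of view, K = m^2).
#'
#' @slot method `"minflux"` or `"rastmin"`.
#' @slot L pattern size in nm: diameter of the MINFLUX circumcircle, or the
#'   full span of the raster.
#' @slot positions K-by-2 numeric matrix of pattern-center positions in nm,
#'   in exposure order.
#'
#' @seealso [minfluxSequence()], [rastminSequence()]
#' @export
setClass("ExcitationSequence",
  representation(
    method = "character",
    L = "numeric",
    positions = "matrix"
  )
)

setValidity("ExcitationSequence", function(object) {
  msg <- character()
  if (!(length(object@method) == 1L && object@method %in% c("minflux", "rastmin")))
    msg <- c(msg, "method must be \"minflux\" or \"rastmin\"")
  if (length(object@L) != 1L || !is.finite(object@L) || object@L <= 0)
    msg <- c(msg, "L must be a single positive finite number (nm)")
  P <- object@positions
  if (!is.numeric(P) || ncol(P) != 2L || any(!is.finite(P)))
    msg <- c(msg, "positions must be a finite numeric K x 2 matrix")
  else {
    half <- object@L / 2 + 1e-9
    if (any(abs(P) > half))
      msg <- c(msg, "all positions must lie within [-L/2, L/2]^2")
    if (identical(object@method, "minflux")) {
      if (nrow(P) != 4L)
        msg <- c(msg, "minflux sequences have exactly K = 4 exposures")
      else if (max(abs(colMeans(P))) > 1e-9)
        msg <- c(msg, "minflux positions must have their centroid at the origin")
    }
    if (identical(object@method, "rastmin")) {
      m <- sqrt(nrow(P))
      if (m != round(m) || m < 2)
        msg <- c(msg, "rastmin sequences have K = m^2 exposures with m >= 2")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Full forward-model scenario
#'
#' Binds a beam, an excitation sequence, the excitation order c, the photon
#' budget N, the signal-to-background ratio, and an emitter position into one
#' validated object. Every downstream quantity (exposure probabilities,
#' Fisher information, \eqn{\sigma_{CRB}}, simulated counts) is a function of
#' a Scenario.
#'
#' @slot beam a [BeamProfile-class].
#' @slot sequence an [ExcitationSequence-class].
#' @slot order excitation order c (1 = linear, 2 = two-photon, 3 =
#'   three-photon; fractional values >= 1 model effective superlinear
#'   schemes).
#' @slot N total detected photon budget per localization event.
#' @slot SBR signal-to-background ratio (> 0; `Inf` for no background).
#' @slot emitterPosition emitter position \eqn{r_E} in nm (length-2).
#'
#' @seealso [makeScenario()], [exposureProbabilities()], [crbSigma()]
#' @export
setClass("Scenario",
  representation(
    beam = "BeamProfile",
    sequence = "ExcitationSequence",
    order = "numeric",
    N = "numeric",
    SBR = "numeric",
    emitterPosition = "numeric"
  )
)

setValidity("Scenario", function(object) {
  msg <- character()
  if (length(object@order) != 1L || !is.finite(object@order) || object@order < 1)
    msg <- c(msg, "order must be a single finite number >= 1")
  if (length(object@N) != 1L || !is.finite(object@N) || object@N < 1 ||
      object@N != round(object@N))
    msg <- c(msg, "N must be a single integer >= 1")
  if (length(object@SBR) != 1L || is.na(object@SBR) || object@SBR <= 0)
    msg <- c(msg, "SBR must be a single positive number (Inf allowed)")
  if (length(object@emitterPosition) != 2L || any(!is.finite(object@emitterPosition)))
    msg <- c(msg, "emitterPosition must be a finite length-2 numeric vector (nm)")
  if (length(msg)) msg else TRUE
})

#' Photon-count record for one localization event
#'
#' Nonnegative integer photon counts, one per exposure of the sequence.
#' Records generated by [sampleCounts()] are multinomial draws conditioned on
#' the total photon budget, so their counts sum to N.
#'
#' @slot counts nonnegative integer vector of length K.
#' @seealso [sampleCounts()], [mleLocalize()]
#' @export
setClass("CountRecord", representation(counts = "numeric"))

setValidity("CountRecord", function(object) {
  n <- object@counts
  if (length(n) < 1L || any(!is.finite(n)) || any(n < 0) || any(n != round(n)))
    return("counts must be nonnegative integers")
  TRUE
})

#' Map of the localization precision bound over the field of view
#'
#' \eqn{\sigma_{CRB}} evaluated on a regular g-by-g lattice of emitter
#' positions covering the square \eqn{[-L/2, L/2]^2}. The fingerprint slot
#' records the scenario parameters (without the emitter position) that
#' produced the map.
#'
#' @slot coordinates the g lattice coordinates (nm), shared by both axes.
#' @slot sigma g-by-g matrix of \eqn{\sigma_{CRB}} in nm; rows index x,
#'   columns index y.
#' @slot fingerprint named list of generating parameters.
#' @seealso [precisionMap()], [mapSummary()]
#' @export
setClass("PrecisionMap",
  representation(
    coordinates = "numeric",
    sigma = "matrix",
    fingerprint = "list"
  )
)

setValidity("PrecisionMap", function(object) {
  g <- length(object@coordinates)
  if (g < 3L) return("grid side must be >= 3")
  if (!all(dim(object@sigma) == c(g, g)))
    return("sigma must be a g x g matrix matching the coordinates")
  if (any(!is.finite(object@sigma)) || any(object@sigma <= 0))
    return("sigma values must be strictly positive and finite")
  TRUE
})

#' Result of one maximum-likelihood localization
#'
#' @slot estimate position estimate in nm (length-2).
#' @slot logLik multinomial log-likelihood at the optimum.
#' @slot converged logical convergence flag; `FALSE` flags refinement
#'   failure or an optimum escaping the search margin (never an exception).
#' @slot iterations number of function evaluations spent in refinement.
#' @seealso [mleLocalize()]
#' @export
setClass("LocalizationResult",
  representation(
    estimate = "numeric",
    logLik = "numeric",
    converged = "logical",
    iterations = "numeric"
  )
)

#' Monte-Carlo precision summary for an estimator
#'
#' Empirical spread of repeated maximum-likelihood localizations at a fixed
#' true position, next to the Cramer-Rao bound at that position.
#'
#' @slot sigmaAxis empirical standard deviation per axis (nm, length-2).
#' @slot sigmaPooled pooled isotropic sigma, \eqn{\sqrt{(s_x^2+s_y^2)/2}} (nm).
#' @slot bias mean estimate minus truth (nm, length-2).
#' @slot repeats number of repeats that entered the summary.
#' @slot nExcluded localizations excluded for failed convergence.
#' @slot sigmaCRB \eqn{\sigma_{CRB}} at the true position (nm).
#' @slot identifiable `FALSE` when the model carried (numerically) no
#'   position information at the true position and no localization was run.
#' @seealso [monteCarloPrecision()]
#' @export
setClass("PrecisionSummary",
  representation(
    sigmaAxis = "numeric",
    sigmaPooled = "numeric",
    bias = "numeric",
    repeats = "numeric",
    nExcluded = "numeric",
    sigmaCRB = "numeric",
    identifiable = "logical"
  )
)

#' Validated run configuration
#'
#' Holder for one reproducible run: method and pattern geometry, beam
#' parameters, excitation order, photon budget, SBR, map grid, master seed
#' and output directory. Built by [loadConfig()] or [makeRunConfig()].
#'
#' @slot method `"minflux"` or `"rastmin"`.
#' @slot L pattern size (nm).
#' @slot m rastmin grid side (ignored for minflux).
#' @slot wavelength excitation wavelength (nm).
#' @slot numericalAperture objective NA.
#' @slot order excitation order c.
#' @slot N photon budget.
#' @slot SBR signal-to-background ratio (1e6 encodes the no-background
#'   limit, see [loadConfig()]).
#' @slot mapGrid precision-map grid side g.
#' @slot seed master seed for all randomness.
#' @slot outputDir output directory for run artifacts.
#' @slot configHash md5 of the source file, or `""` when built in code.
#' @export
setClass("RunConfig",
  representation(
    method = "character",
    L = "numeric",
    m = "numeric",
    wavelength = "numeric",
    numericalAperture = "numeric",
    order = "numeric",
    N = "numeric",
    SBR = "numeric",
    mapGrid = "numeric",
    seed = "numeric",
    outputDir = "character",
    configHash = "character"
  )
)
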