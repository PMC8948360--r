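#' Gradients of the exposure probabilities
#'
#' Closed-form \eqn{\partial p_i / \partial (x, y)} at the scenario's emitter
#' position, by the chain rule through the order-c excitation weights. Rows
#' sum to the zero vector because the probabilities sum to 1.
#'
#' @param scenario a [Scenario-class].
#' @return K-by-2 matrix (1/nm).
#' @export
probabilityGradients <- function(scenario) {
  stopifnot(is(scenario, "Scenario"))
  G <- .probGradsAt(scenario@emitterPosition, scenario@sequence@positions,
                    scenario@beam@doughnutRadius, scenario@order,
                    scenario@SBR)
  colnames(G) <- c("d_dx", "d_dy")
  G
}

#' Fisher information for the emitter position
#'
#' Under the multinomial forward model,
#' \deqn{F(r_E) = N \sum_i \frac{1}{p_i} \nabla p_i \nabla p_i^T,}
#' a symmetric positive-semidefinite 2-by-2 matrix, exactly linear in N.
#' At `SBR = Inf`, exposures with zero probability and non-vanishing
#' gradient make the model singular and raise an error suggesting a finite
#' SBR (the interior limit).
#'
#' @param scenario a [Scenario-class].
#' @return 2-by-2 matrix in nm^-2.
#' @export
fisherInformation <- function(scenario) {
  stopifnot(is(scenario, "Scenario"))
  .fisherAt(scenario@emitterPosition, scenario@sequence@positions,
            scenario@beam@doughnutRadius, scenario@order, scenario@SBR,
            scenario@N)
}

#' Cramer-Rao precision bound at one position
#'
#' The scalar bound \eqn{\sigma_{CRB} = \sqrt{(\Sigma_{xx}+\Sigma_{yy})/2}}
#' with \eqn{\Sigma = F^{-1}}: the root-mean per-axis standard deviation
#' that no unbiased estimator can beat. Inherits \eqn{\sigma \propto
#' 1/\sqrt{N}} exactly from the linearity of F in N.
#'
#' @param scenario a [Scenario-class].
#' @return \eqn{\sigma_{CRB}} in nm.
#' @export
crbSigma <- function(scenario) {
  stopifnot(is(scenario, "Scenario"))
  .sigmaAt(scenario@emitterPosition, scenario@sequence@positions,
           scenario@beam@doughnutRadius, scenario@order, scenario@SBR,
           scenario@N)
}

#' Precision map over the field of view
#'
#' Evaluates \eqn{\sigma_{CRB}} on a regular g-by-g lattice covering
#' \eqn{[-L/2, L/2]^2}. Deterministic; the emitter position of `scenario`
#' is ignored (the lattice nodes are the probed positions).
#'
#' @param scenario a [Scenario-class] (or a [RunConfig-class], converted via
#'   [scenarioFromConfig()]).
#' @param gridSide lattice side g (>= 3; odd values place a node at the
#'   exact center).
#' @return a [PrecisionMap-class].
#' @export
precisionMap <- function(scenario, gridSide = 41) {
  if (is(scenario, "RunConfig")) {
    if (missing(gridSide)) gridSide <- scenario@mapGrid
    scenario <- scenarioFromConfig(scenario)
  }
  stopifnot(is(scenario, "Scenario"))
  if (!is.numeric(gridSide) || length(gridSide) != 1L || gridSide < 3 ||
      gridSide != round(gridSide))
    stop("invalid parameter: gridSide must be an integer >= 3")
  L <- scenario@sequence@L
  coords <- seq(-L / 2, L / 2, length.out = gridSide)
  P <- scenario@sequence@positions
  R <- scenario@beam@doughnutRadius
  sig <- matrix(NA_real_, gridSide, gridSide)
  for (j in seq_len(gridSide))
    for (i in seq_len(gridSide))
      sig[i, j] <- .sigmaAt(c(coords[i], coords[j]), P, R,
                            scenario@order, scenario@SBR, scenario@N)
  new("PrecisionMap", coordinates = coords, sigma = sig,
      fingerprint = list(
        method = scenario@sequence@method,
        L_nm = L,
        K = nrow(P),
        wavelength_nm = scenario@beam@wavelength,
        numerical_aperture = scenario@beam@numericalAperture,
        doughnut_radius_nm = R,
        order = scenario@order,
        N = scenario@N,
        SBR = scenario@SBR,
        grid_side = gridSide
      ))
}

#' @describeIn precisionMap sigma matrix accessor (nm).
#' @param x a `PrecisionMap`.
#' @export
setMethod("sigmaValues", "PrecisionMap", function(x) x@sigma)

#' @rdname mapSummary
#' @export
setMethod("mapSummary", "PrecisionMap", function(x) {
  v <- x@sigma
  g <- length(x@coordinates)
  ctr <- v[(g + 1) %/% 2, (g + 1) %/% 2]
  list(min = min(v), max = max(v), center = ctr, mean = mean(v),
       cv = stats::sd(v) / mean(v), dynamicRange = max(v) / ctr)
})

setMethod("show", "PrecisionMap", function(object) {
  s <- mapSummary(object)
  cat(sprintf(
    "PrecisionMap: %s, c = %g, %d x %d over [%g, %g] nm\n",
    object@fingerprint$method, object@fingerprint$order,
    length(object@coordinates), length(object@coordinates),
    min(object@coordinates), max(object@coordinates)))
  cat(sprintf(
    "  sigma_CRB [nm]: center %.3f | mean %.3f | range %.3f-%.3f | CV %.3f\n",
    s$center, s$mean, s$min, s$max, s$cv))
})

# no-background limit used for cross-order comparisons: large finite SBR
# avoids the singular zero-probability center exposure of literal Inf,
# with < 1e-3 relative effect on center sigma
.NO_BACKGROUND_SBR <- 1e6

#' Center precision improvement between excitation orders
#'
#' \eqn{\sigma_{CRB}(c = orderA) / \sigma_{CRB}(c = orderB)} at the pattern
#' center, with the same beam for both orders and the background removed
#' (SBR set to the no-background limit 1e6). For a MINFLUX pattern this
#' ratio equals orderB/orderA exactly in the no-background limit: at the
#' symmetric center the relative gradients of the order-c weights scale
#' exactly by c.
#'
#' @param scenario a [Scenario-class] or [RunConfig-class]; its order and
#'   SBR are overridden.
#' @param orderA,orderB excitation orders to compare (>= 1).
#' @return dimensionless ratio (> 1 when orderB localizes better).
#' @export
centerImprovementRatio <- function(scenario, orderA = 1, orderB = 2) {
  if (is(scenario, "RunConfig")) scenario <- scenarioFromConfig(scenario)
  stopifnot(is(scenario, "Scenario"))
  base <- .withEmitter(scenario, c(0, 0))
  base@SBR <- .NO_BACKGROUND_SBR
  a <- base; a@order <- as.numeric(orderA); validObject(a)
  b <- base; b@order <- as.numeric(orderB); validObject(b)
  crbSigma(a) / crbSigma(b)
}

#' Photon budgets equalizing center precision across orders
#'
#' The ratio \eqn{N_b / N_a} at which order-b excitation reaches the same
#' center \eqn{\sigma_{CRB}} as order-a. By the exact \eqn{1/\sqrt{N}} law
#' this is \eqn{(\sigma_b(N_a)/\sigma_a(N_a))^2} =
#' 1 / centerImprovementRatio^2.
#'
#' @inheritParams centerImprovementRatio
#' @return dimensionless photon-budget ratio (< 1 when orderB is more
#'   photon-efficient).
#' @export
photonEquivalence <- function(scenario, orderA = 1, orderB = 2) {
  1 / centerImprovementRatio(scenario, orderA, orderB)^2
}
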