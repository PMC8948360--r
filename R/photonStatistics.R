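#' Build a forward-model scenario
#'
#' @param beam a [BeamProfile-class].
#' @param sequence an [ExcitationSequence-class].
#' @param order excitation order c (>= 1).
#' @param N total detected photon budget (integer >= 1).
#' @param SBR signal-to-background ratio (> 0; `Inf` = no background).
#' @param emitterPosition emitter position in nm (length-2).
#' @return a validated [Scenario-class].
#' @examples
#' sc <- makeScenario(makeBeamProfile(647), minfluxSequence(100),
#'                    order = 1, N = 500, SBR = 4)
#' exposureProbabilities(sc)
#' @export
makeScenario <- function(beam, sequence, order = 1, N = 500, SBR = 4,
                         emitterPosition = c(0, 0)) {
  new("Scenario", beam = beam, sequence = sequence, order = order,
      N = as.numeric(N), SBR = SBR,
      emitterPosition = as.numeric(emitterPosition))
}

# same scenario probing a different emitter position (internal)
.withEmitter <- function(scenario, rE) {
  scenario@emitterPosition <- as.numeric(rE)
  scenario
}

#' Exposure probabilities of the forward model
#'
#' Probability that a detected photon arrives during exposure i:
#' \deqn{p_i = \frac{SBR}{SBR+1}\,\frac{I^c(r_E - r_i)}{\sum_j I^c(r_E - r_j)}
#'       + \frac{1}{K\,(SBR+1)},}
#' i.e. a fraction SBR/(SBR+1) of the photon budget follows the normalized
#' order-c excitation weights and the rest is uniform background. SBR is the
#' total signal over total background across the sequence. With `SBR = Inf`
#' the background term vanishes.
#'
#' @param scenario a [Scenario-class].
#' @return probability vector of length K summing to 1.
#' @export
exposureProbabilities <- function(scenario) {
  stopifnot(is(scenario, "Scenario"))
  .probsAt(scenario@emitterPosition, scenario@sequence@positions,
           scenario@beam@doughnutRadius, scenario@order, scenario@SBR)
}

#' Expected photon counts per exposure
#'
#' @param scenario a [Scenario-class].
#' @return \eqn{\lambda_i = N p_i}, summing to N.
#' @export
expectedCounts <- function(scenario) {
  scenario@N * exposureProbabilities(scenario)
}

#' Sample one photon-count record
#'
#' One multinomial draw of N photons over the K exposures. Conditioning the
#' per-exposure Poisson counts on their observed total is exactly
#' multinomial, and matches the fixed-photon-budget convention in which maps
#' and bounds are stated.
#'
#' @param p probability vector (must sum to 1 within 1e-9).
#' @param N total photons (integer >= 1).
#' @param seed integer seed making the draw reproducible.
#' @return a [CountRecord-class] whose counts sum to N.
#' @export
sampleCounts <- function(p, N, seed) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) || any(p < 0))
    stop("invalid parameter: p must be a nonnegative probability vector")
  if (abs(sum(p) - 1) > 1e-9)
    stop("invalid parameter: p must sum to 1 (within 1e-9)")
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("invalid parameter: N must be an integer >= 1")
  set.seed(as.integer(seed))
  new("CountRecord", counts = as.vector(stats::rmultinom(1, N, p)))
}

#' @describeIn sampleCounts count vector accessor.
#' @param x a `CountRecord`.
#' @export
setMethod("photonCounts", "CountRecord", function(x) x@counts)

setMethod("show", "CountRecord", function(object) {
  cat("CountRecord:", paste(object@counts, collapse = " "),
      "| total", sum(object@counts), "\n")
})

# per-record substream: record j under master seed s draws with seed
# (s + 1000003 * j) mod 2147483647, so any record is reproducible on its own
.recordSeed <- function(masterSeed, recordIndex) {
  (as.numeric(masterSeed) + 1000003 * as.numeric(recordIndex)) %% 2147483647
}

#' Generate a table of synthetic count records
#'
#' Draws `repeats` multinomial count records at each true emitter position,
#' using a stated per-record seeding scheme so that any single record can be
#' regenerated independently of the rest of the table.
#'
#' @param config a [RunConfig-class] (emitter positions come from
#'   `truePositions`, not the config).
#' @param truePositions n-by-2 matrix of true emitter positions (nm).
#' @param repeats records per position (>= 1).
#' @param seed master seed; defaults to the config's seed.
#' @return data.frame with columns `true_x_nm`, `true_y_nm`, `repeat`,
#'   `n_1` ... `n_K`, `seed` (the per-record substream seed).
#' @export
generateFixtureDataset <- function(config, truePositions, repeats = 1,
                                   seed = config@seed) {
  stopifnot(is(config, "RunConfig"))
  if (!is.numeric(repeats) || length(repeats) != 1L || repeats < 1 ||
      repeats != round(repeats))
    stop("invalid parameter: repeats must be an integer >= 1")
  pos <- .asDisplacementMatrix(truePositions)
  sc <- scenarioFromConfig(config)
  P <- sc@sequence@positions
  K <- nrow(P)
  rows <- nrow(pos) * repeats
  counts <- matrix(0L, rows, K)
  seeds <- numeric(rows)
  idx <- 0L
  for (i in seq_len(nrow(pos))) {
    p <- .probsAt(pos[i, ], P, sc@beam@doughnutRadius, sc@order, sc@SBR)
    for (r in seq_len(repeats)) {
      idx <- idx + 1L
      seeds[idx] <- .recordSeed(seed, idx)
      set.seed(as.integer(seeds[idx]))
      counts[idx, ] <- as.vector(stats::rmultinom(1, sc@N, p))
    }
  }
  out <- data.frame(
    true_x_nm = rep(pos[, 1], each = repeats),
    true_y_nm = rep(pos[, 2], each = repeats),
    rep = rep(seq_len(repeats), times = nrow(pos))
  )
  names(out)[3] <- "repeat"
  cn <- paste0("n_", seq_len(K))
  out[cn] <- as.data.frame(counts)
  out$seed <- seeds
  out
}

setMethod("show", "Scenario", function(object) {
  cat(sprintf(
    "Scenario: %s L = %g nm, c = %g, N = %g, SBR = %s, emitter (%g, %g) nm\n",
    object@sequence@method, object@sequence@L, object@order, object@N,
    format(object@SBR), object@emitterPosition[1], object@emitterPosition[2]))
})
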