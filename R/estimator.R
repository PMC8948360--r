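# Coarse-grid setup shared by single and batch localization. The likelihood
# can be multimodal at low N, so the arg-max is first bracketed on a regular
# grid (default 1 nm pitch) spanning the FOV plus a margin, then refined.
.mleGridSetup <- function(scenario, coarsePitch = 1, marginFraction = 0.2) {
  L <- scenario@sequence@L
  margin <- marginFraction * L
  half <- L / 2 + margin
  ax <- seq(-half, half, by = coarsePitch)
  if (ax[length(ax)] < half) ax <- c(ax, half)
  pts <- cbind(rep(ax, times = length(ax)), rep(ax, each = length(ax)))
  P <- scenario@sequence@positions
  R <- scenario@beam@doughnutRadius
  logP <- matrix(NA_real_, nrow(pts), nrow(P))
  for (g in seq_len(nrow(pts)))
    logP[g, ] <- log(pmax(.probsAt(pts[g, ], P, R, scenario@order,
                                   scenario@SBR), 1e-300))
  list(pts = pts, logP = logP, half = half, norm2 = pts[, 1]^2 + pts[, 2]^2)
}

# coarse arg-max with ties broken toward the smallest |r|
.coarseArgmax <- function(ll, setup) {
  best <- max(ll)
  cand <- which(ll >= best - 1e-9)
  cand[which.min(setup$norm2[cand])]
}

.negLogLik <- function(r, n, scenario) {
  p <- .probsAt(r, scenario@sequence@positions,
                scenario@beam@doughnutRadius, scenario@order, scenario@SBR)
  -sum(n * log(pmax(p, 1e-300)))
}

.refineOne <- function(n, start, scenario, setup) {
  opt <- stats::optim(start, .negLogLik, n = n, scenario = scenario,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  inside <- all(abs(opt$par) <= setup$half + 1e-9)
  new("LocalizationResult",
      estimate = as.numeric(opt$par),
      logLik = -opt$value,
      converged = (opt$convergence == 0) && inside,
      iterations = as.numeric(opt$counts[["function"]]))
}

#' Maximum-likelihood localization of one count record
#'
#' Maximizes the multinomial log-likelihood
#' \eqn{\ell(r) = \sum_i n_i \ln p_i(r)} over the field of view plus a
#' margin, by coarse grid evaluation (ties broken toward the smallest
#' \eqn{|r|}) followed by derivative-free Nelder-Mead refinement.
#' Deterministic for fixed inputs. Estimates are not clipped: optima
#' escaping the margin are returned with `converged = FALSE`.
#'
#' @param counts a [CountRecord-class] or nonnegative integer vector of
#'   length K with positive sum.
#' @param scenario a [Scenario-class] defining the likelihood model (its
#'   emitter position is ignored).
#' @param coarsePitch coarse grid pitch in nm.
#' @param marginFraction margin beyond the FOV as a fraction of L.
#' @return a [LocalizationResult-class].
#' @examples
#' sc <- makeScenario(makeBeamProfile(647), minfluxSequence(100), SBR = 4)
#' mleLocalize(c(150, 170, 160, 20), sc)
#' @export
mleLocalize <- function(counts, scenario, coarsePitch = 1,
                        marginFraction = 0.2) {
  if (is(counts, "CountRecord")) counts <- counts@counts
  stopifnot(is(scenario, "Scenario"))
  K <- nrow(scenario@sequence@positions)
  if (!is.numeric(counts) || length(counts) != K || any(counts < 0) ||
      any(counts != round(counts)))
    stop("invalid input: counts must be ", K, " nonnegative integers")
  if (sum(counts) < 1)
    stop("invalid input: all-zero count record carries no information")
  setup <- .mleGridSetup(scenario, coarsePitch, marginFraction)
  ll <- as.vector(setup$logP %*% counts)
  start <- setup$pts[.coarseArgmax(ll, setup), ]
  .refineOne(counts, start, scenario, setup)
}

#' Monte-Carlo estimator precision at a fixed true position
#'
#' Draws seeded count records at the true position, localizes each by
#' maximum likelihood, and summarizes the empirical spread next to
#' \eqn{\sigma_{CRB}} at that position. Records whose refinement fails are
#' excluded and counted. If the model carries (numerically) no position
#' information at the truth — probability concentrated on one exposure, or
#' a singular Fisher information — the summary is returned flagged
#' non-identifiable instead of crashing.
#'
#' @param truePosition emitter position in nm (length-2).
#' @param scenario a [Scenario-class].
#' @param repeats number of records (>= 100 for a meaningful sigma).
#' @param seed master seed; per-record substreams as in
#'   [generateFixtureDataset()].
#' @return a [PrecisionSummary-class].
#' @export
monteCarloPrecision <- function(truePosition, scenario, repeats = 1000,
                                seed = 1) {
  stopifnot(is(scenario, "Scenario"))
  if (!is.numeric(repeats) || length(repeats) != 1L || repeats < 100)
    stop("invalid parameter: repeats must be >= 100 for a meaningful sigma")
  truePosition <- as.numeric(truePosition)
  P <- scenario@sequence@positions
  R <- scenario@beam@doughnutRadius
  p <- .probsAt(truePosition, P, R, scenario@order, scenario@SBR)
  sigmaCRB <- tryCatch(
    .sigmaAt(truePosition, P, R, scenario@order, scenario@SBR, scenario@N),
    error = function(e) NA_real_)
  if (max(p) > 1 - 1e-9 || !is.finite(sigmaCRB))
    return(new("PrecisionSummary", sigmaAxis = c(NA_real_, NA_real_),
               sigmaPooled = NA_real_, bias = c(NA_real_, NA_real_),
               repeats = 0, nExcluded = 0, sigmaCRB = sigmaCRB,
               identifiable = FALSE))
  K <- nrow(P)
  counts <- matrix(0, repeats, K)
  for (j in seq_len(repeats)) {
    set.seed(as.integer(.recordSeed(seed, j)))
    counts[j, ] <- as.vector(stats::rmultinom(1, scenario@N, p))
  }
  setup <- .mleGridSetup(scenario)
  ll <- setup$logP %*% t(counts)          # coarse pass, all records at once
  est <- matrix(NA_real_, repeats, 2)
  ok <- logical(repeats)
  for (j in seq_len(repeats)) {
    start <- setup$pts[.coarseArgmax(ll[, j], setup), ]
    res <- .refineOne(counts[j, ], start, scenario, setup)
    est[j, ] <- res@estimate
    ok[j] <- res@converged
  }
  used <- est[ok, , drop = FALSE]
  sax <- apply(used, 2, stats::sd)
  new("PrecisionSummary",
      sigmaAxis = sax,
      sigmaPooled = sqrt(mean(sax^2)),
      bias = colMeans(used) - truePosition,
      repeats = nrow(used),
      nExcluded = sum(!ok),
      sigmaCRB = sigmaCRB,
      identifiable = TRUE)
}

setMethod("show", "PrecisionSummary", function(object) {
  if (!object@identifiable) {
    cat("PrecisionSummary: non-identifiable model (no position information)\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    paste0("PrecisionSummary: pooled sigma %.3f nm vs sigma_CRB %.3f nm ",
           "(ratio %.3f)\n  per-axis (%.3f, %.3f) nm, bias (%.3f, %.3f) nm, ",
           "%d repeats, %d excluded\n"),
    object@sigmaPooled, object@sigmaCRB,
    object@sigmaPooled / object@sigmaCRB,
    object@sigmaAxis[1], object@sigmaAxis[2],
    object@bias[1], object@bias[2], object@repeats, object@nExcluded))
})

#' Batch localization of a fixture table
#'
#' Localizes every record of a table in the [generateFixtureDataset()]
#' layout (columns `n_1` ... `n_K`) under the model defined by `config`.
#'
#' @param fixture data.frame or path to a CSV written from one.
#' @param config a [RunConfig-class] or [Scenario-class].
#' @return data.frame with columns `true_x`, `true_y`, `est_x`, `est_y`,
#'   `loglik`, `converged`.
#' @export
batchLocalize <- function(fixture, config) {
  if (is.character(fixture))
    fixture <- utils::read.csv(fixture, check.names = FALSE)
  sc <- if (is(config, "RunConfig")) scenarioFromConfig(config) else config
  stopifnot(is(sc, "Scenario"))
  K <- nrow(sc@sequence@positions)
  cn <- paste0("n_", seq_len(K))
  if (!all(cn %in% names(fixture)))
    stop("fixture table lacks count columns ", paste(cn, collapse = ", "))
  counts <- as.matrix(fixture[cn])
  setup <- .mleGridSetup(sc)
  ll <- setup$logP %*% t(counts)
  out <- data.frame(
    true_x = if ("true_x_nm" %in% names(fixture)) fixture$true_x_nm else NA,
    true_y = if ("true_y_nm" %in% names(fixture)) fixture$true_y_nm else NA,
    est_x = NA_real_, est_y = NA_real_, loglik = NA_real_, converged = NA)
  for (j in seq_len(nrow(counts))) {
    start <- setup$pts[.coarseArgmax(ll[, j], setup), ]
    res <- .refineOne(counts[j, ], start, sc, setup)
    out$est_x[j] <- res@estimate[1]
    out$est_y[j] <- res@estimate[2]
    out$loglik[j] <- res@logLik
    out$converged[j] <- res@converged
  }
  out
}
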