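# Shared builders for the reference configuration used throughout the suite:
# L = 100 nm, N = 500, SBR = 4, lambda = 647 nm, NA 1.4 (the package's reference map conditions).

refBeam <- function(wavelength = 647) makeBeamProfile(wavelength, 1.4)

refScenario <- function(order = 1, method = c("minflux", "rastmin"),
                         SBR = 4, N = 500, L = 100, wavelength = 647,
                         m = 4, emitter = c(0, 0)) {
  method <- match.arg(method)
  seqn <- if (method == "minflux") minfluxSequence(L) else rastminSequence(L, m)
  makeScenario(refBeam(wavelength), seqn, order = order, N = N, SBR = SBR,
               emitterPosition = emitter)
}

NO_BG <- 1e6  # no-background limit convention

# independent brute-force oracle for the multinomial log-likelihood surface:
# recomputes the forward model from the formulas (doughnut ^ c, SBR mixing)
# without calling the package's probability code
oracleLogLik <- function(counts, gridXY, seqPositions, R, order, SBR) {
  K <- nrow(seqPositions)
  W <- matrix(0, nrow(gridXY), K)
  for (i in seq_len(K)) {
    u <- ((gridXY[, 1] - seqPositions[i, 1])^2 +
          (gridXY[, 2] - seqPositions[i, 2])^2) / R^2
    W[, i] <- (exp(1) * u * exp(-u))^order
  }
  S <- rowSums(W)
  p <- (SBR / (SBR + 1)) * W / S + 1 / (K * (SBR + 1))
  as.vector(log(pmax(p, 1e-300)) %*% counts)
}

rotate2 <- function(xy, angleDeg) {
  a <- angleDeg * pi / 180
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  if (is.matrix(xy)) xy %*% t(Rm) else as.vector(Rm %*% xy)
}
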