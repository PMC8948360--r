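# Internal numeric core shared by the photon-statistics and CRB layers.
# All functions work on plain numerics: emitter position rE (length 2),
# exposure positions P (K x 2, nm), ring radius R (nm), order c, SBR, N.

# order-c excitation weights w_i = I^c(rE - r_i), in closed form:
# w = e^c u^c exp(-c u) with u = |rE - r_i|^2 / R^2
.weightsAt <- function(rE, P, R, order) {
  u <- ((rE[1] - P[, 1])^2 + (rE[2] - P[, 2])^2) / (R * R)
  exp(order) * u^order * exp(-order * u)
}

# mixing of signal and uniform background:
# p_i = (SBR/(SBR+1)) w_i / sum(w) + 1 / (K (SBR+1));  SBR = Inf drops the
# background term. A zero total signal (emitter on every minimum at once)
# falls back to uniform signal weights to keep the model total.
.probsAt <- function(rE, P, R, order, SBR) {
  w <- .weightsAt(rE, P, R, order)
  K <- nrow(P)
  S <- sum(w)
  sig <- if (S > 0) w / S else rep(1 / K, K)
  if (is.infinite(SBR)) sig
  else (SBR / (SBR + 1)) * sig + 1 / (K * (SBR + 1))
}

# analytic gradients dp_i/d(x, y), K x 2. Chain rule through w:
# dw/dr = e^c c u^(c-1) (1 - u) exp(-c u) * 2 (rE - r_i) / R^2
# (u^(c-1) -> 0 as u -> 0 for c > 1; the c = 1 limit is finite; the
# displacement factor kills the u = 0 point for every c >= 1).
.probGradsAt <- function(rE, P, R, order, SBR) {
  dx <- rE[1] - P[, 1]
  dy <- rE[2] - P[, 2]
  u <- (dx * dx + dy * dy) / (R * R)
  w <- exp(order) * u^order * exp(-order * u)
  upow <- ifelse(u == 0, if (order > 1) 0 else 1, u^(order - 1))
  fac <- exp(order) * order * upow * (1 - u) * exp(-order * u) * 2 / (R * R)
  dwx <- fac * dx
  dwy <- fac * dy
  S <- sum(w)
  K <- nrow(P)
  if (S <= 0) return(matrix(0, K, 2))          # degenerate-guard branch
  a <- if (is.infinite(SBR)) 1 else SBR / (SBR + 1)
  cbind(a * (dwx * S - w * sum(dwx)) / S^2,
        a * (dwy * S - w * sum(dwy)) / S^2)
}

# multinomial Fisher information for position, F = N sum_i (1/p_i) g_i g_i^T.
# Exposures with p_i = 0 and vanishing gradient carry no information and are
# dropped; p_i = 0 with a non-vanishing gradient makes the model singular
# (possible only at SBR = Inf).
.fisherAt <- function(rE, P, R, order, SBR, N) {
  p <- .probsAt(rE, P, R, order, SBR)
  G <- .probGradsAt(rE, P, R, order, SBR)
  zero <- p == 0
  if (any(zero)) {
    if (any(abs(G[zero, , drop = FALSE]) > 1e-12))
      stop("singular model: an exposure has zero probability but non-zero ",
           "gradient; use a finite SBR (e.g. 1e6) for the interior limit")
    p <- p[!zero]
    G <- G[!zero, , drop = FALSE]
  }
  N * crossprod(G / sqrt(p))
}

# sqrt(mean per-axis variance) from the 2x2 information matrix, with a
# condition-number guard on the closed-form inverse.
.sigmaFromFisher <- function(F) {
  a <- F[1, 1]; b <- F[1, 2]; d <- F[2, 2]
  tr <- a + d
  disc <- sqrt(max((a - d)^2 + 4 * b * b, 0))
  lmin <- (tr - disc) / 2
  lmax <- (tr + disc) / 2
  if (!is.finite(lmin) || lmin <= 0 || lmax / lmin > 1e12)
    stop("singular model: Fisher information is (near-)singular at this ",
         "position (condition number > 1e12)")
  det <- a * d - b * b
  sqrt((a + d) / (2 * det))
}

.sigmaAt <- function(rE, P, R, order, SBR, N) {
  .sigmaFromFisher(.fisherAt(rE, P, R, order, SBR, N))
}
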