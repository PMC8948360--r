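#' MINFLUX excitation sequence
#'
#' Four exposures: the vertices of an equilateral triangle of circumradius
#' L/2 centered at the origin (first vertex on the +y axis, counterclockwise)
#' followed by a final exposure at the pattern center. L is the diameter of
#' the circumcircle and defines the field of view.
#'
#' @param L pattern size in nm (> 0).
#' @return an [ExcitationSequence-class] with K = 4.
#' @examples
#' s <- minfluxSequence(100)
#' exposurePositions(s)
#' @export
minfluxSequence <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("invalid parameter: L must be a positive number (nm)")
  ang <- pi / 2 + 2 * pi * (0:2) / 3
  P <- rbind(cbind((L / 2) * cos(ang), (L / 2) * sin(ang)),
             c(0, 0))
  # snap exact zeros (cos(pi/2) is ~6e-17) so the stated geometry is exact
  P[abs(P) < 1e-12] <- 0
  dimnames(P) <- list(NULL, c("x", "y"))
  new("ExcitationSequence", method = "minflux", L = L, positions = P)
}

#' RASTMIN excitation sequence
#'
#' A regular m-by-m raster of minima spanning the field of view, with
#' corner exposures at (+-L/2, +-L/2), visited in row-major order (y fixed
#' per row, x advancing).
#'
#' @param L raster span in nm (> 0).
#' @param m grid side (integer >= 2); K = m^2 exposures.
#' @return an [ExcitationSequence-class].
#' @export
rastminSequence <- function(L, m = 4) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("invalid parameter: L must be a positive number (nm)")
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) ||
      m != round(m) || m < 2)
    stop("invalid parameter: m must be an integer >= 2")
  s <- seq(-L / 2, L / 2, length.out = m)
  P <- cbind(x = rep(s, times = m), y = rep(s, each = m))
  new("ExcitationSequence", method = "rastmin", L = L, positions = P)
}

#' @describeIn minfluxSequence exposure positions, a K-by-2 matrix (nm).
#' @param x an `ExcitationSequence`.
#' @export
setMethod("exposurePositions", "ExcitationSequence", function(x) x@positions)

#' @describeIn minfluxSequence number of exposures K.
#' @export
setMethod("numExposures", "ExcitationSequence", function(x) nrow(x@positions))

#' @describeIn minfluxSequence pattern size L (nm).
#' @export
setMethod("patternSize", "ExcitationSequence", function(x) x@L)

setMethod("show", "ExcitationSequence", function(object) {
  cat(sprintf("ExcitationSequence: %s, L = %g nm, K = %d exposures\n",
              object@method, object@L, nrow(object@positions)))
})

#' Export an excitation sequence as a table
#'
#' @param x an [ExcitationSequence-class].
#' @return data.frame with columns `index`, `x_nm`, `y_nm`.
#' @export
sequenceTable <- function(x) {
  stopifnot(is(x, "ExcitationSequence"))
  P <- x@positions
  data.frame(index = seq_len(nrow(P)), x_nm = P[, 1], y_nm = P[, 2])
}
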