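# Small shared numerics.

# Min-max rescale to [0, 1]; a constant vector maps to all-ones so that
# weighting degenerates gracefully to the unweighted case.
minMaxRescale <- function(w) {
  r <- range(w)
  if (r[1] == r[2]) return(rep(1, length(w)))
  (w - r[1]) / (r[2] - r[1])
}

#' Rescale differential co-expression Z-scores to dysregulation weights
#'
#' Takes per-gene (or per-term) Z-score-normalized dC values, uses their
#' absolute magnitude (dysregulation strength, not direction) and min-max
#' rescales to \[0, 1\] within the disease.  A constant input maps to
#' all-ones, i.e. unweighted.
#'
#' @param z numeric vector of Z-scored dC values (may be negative).
#' @return numeric weights in \[0, 1\].
#' @export
normalizeDcWeights <- function(z) {
  stopifnot(is.numeric(z), !anyNA(z))
  minMaxRescale(abs(z))
}

upperTriValues <- function(m) m[upper.tri(m)]

# Hurwitz zeta(s, q) = sum_{k>=0} (q+k)^(-s), s > 1, via Euler-Maclaurin.
hurwitzZeta <- function(s, q, nterms = 1000L) {
  stopifnot(s > 1, q > 0)
  k <- 0:(nterms - 1L)
  a <- q + nterms
  sum((q + k)^(-s)) + a^(1 - s) / (s - 1) + 0.5 * a^(-s) +
    s / 12 * a^(-s - 1)
}
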