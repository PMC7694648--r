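## Mass isotopomer distribution (MID) primitives.
##
## An MID is a numeric vector indexed by mass shift: entry k+1 is the M+k
## fraction. MIDs are kept normalized; tiny negative round-off (>= -1e-12)
## is clipped to zero, anything more negative is treated as an error.

mid_check <- function(x, clip = 1e-12) {
  x <- as.numeric(x)
  if (any(x < -clip))
    stop(sprintf("MID has negative fraction %.3e", min(x)))
  x[x < 0] <- 0
  s <- sum(x)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("MID sums to %.8f, not 1", s))
  x / s
}

#' Convolve two MIDs
#'
#' The MID of two molecule fragments joined in a condensation reaction is
#' the convolution of the fragment MIDs: the fragments combine independently,
#' so `result[k] = sum_j a[j] * b[k - j]`.
#'
#' @param a,b Numeric MID vectors (entry k+1 = M+k fraction).
#' @return Normalized MID of length `length(a) + length(b) - 1`.
#' @export
mid_convolve <- function(a, b) {
  la <- length(a); lb <- length(b)
  out <- numeric(la + lb - 1L)
  for (i in seq_len(la))
    out[i:(i + lb - 1L)] <- out[i:(i + lb - 1L)] + a[i] * b
  mid_check(out)
}

#' Average isotopic enrichment of an MID
#'
#' The per-atom labeled fraction: `sum_k (k/n) * mid[k]` for an n-atom EMU.
#' The enrichment of a condensation product is the atom-count-weighted
#' average of the substrate enrichments.
#'
#' @param mid Numeric MID vector.
#' @return Enrichment in `[0, 1]`.
#' @export
enrichment <- function(mid) {
  n <- length(mid) - 1L
  if (n == 0L) return(0)
  sum(seq(0L, n) * mid) / n
}
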