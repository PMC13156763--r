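#' Maximum-entropy (Kapur) threshold of a 256-bin histogram
#'
#' Returns the gray level `T` in 0-254 maximizing the sum of Shannon
#' entropies of the two classes `{0..T}` and `{T+1..255}` (the Kapur
#' criterion, as in the ImageJ MaxEntropy plugin). Pixels at or below the
#' returned level form the dark class. Deterministic: the smallest argmax is
#' returned on exact ties.
#'
#' @param counts Integer vector of 256 histogram counts.
#' @return Threshold level in 0-254.
#' @export
max_entropy_threshold <- function(counts) {
  if (length(counts) != 256) stop("need a 256-bin histogram")
  if (any(counts < 0) || sum(counts) <= 0) stop("invalid histogram")
  if (sum(counts > 0) < 2)
    stop("histogram has a single occupied bin; no split possible")
  p <- counts / sum(counts)
  P <- cumsum(p)
  ## class entropies for every cut, vectorized via cumulative p*log(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  cum_plogp <- cumsum(plogp)
  tot_plogp <- cum_plogp[256]
  Tcand <- 0:254
  w0 <- P[Tcand + 1]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  H <- rep(-Inf, 255)
  h0 <- -cum_plogp[Tcand + 1] / w0 + log(w0)
  h1 <- -(tot_plogp - cum_plogp[Tcand + 1]) / w1 + log(w1)
  H[valid] <- (h0 + h1)[valid]
  Tcand[which.max(H)]
}
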