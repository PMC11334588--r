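# Independent brute-force oracle: exhaustive enumeration over all ordered
# Bernoulli failure sequences of length n_G.  Deliberately shares no code
# with the package's convolution recursion.

oracle_stagewise <- function(n, r, a = NULL, p) {
  G <- length(n)
  nG <- n[G]
  stopifnot(nG <= 20)
  if (is.null(a)) a <- rep(-1L, G)
  fut <- numeric(G)
  eff <- numeric(G)
  no_stop <- 0
  for (bits in 0:(2^nG - 1)) {
    fail <- as.integer(intToBits(bits))[seq_len(nG)]
    prob <- prod(ifelse(fail == 1L, p, 1 - p))
    stopped <- FALSE
    for (g in seq_len(G)) {
      f <- sum(fail[seq_len(n[g])])
      if (f >= r[g]) {
        fut[g] <- fut[g] + prob
        stopped <- TRUE
        break
      }
      if (a[g] >= 0L && f <= a[g]) {
        eff[g] <- eff[g] + prob
        stopped <- TRUE
        break
      }
    }
    if (!stopped) no_stop <- no_stop + prob
  }
  list(stop_futility = fut, stop_efficacy = eff, no_stop = no_stop)
}

oracle_expected_n <- function(n, r, a = NULL, p) {
  o <- oracle_stagewise(n, r, a, p)
  G <- length(n)
  sum(n * (o$stop_futility + o$stop_efficacy)) + n[G] * o$no_stop
}
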