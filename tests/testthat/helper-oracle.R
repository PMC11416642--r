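# Independent brute-force oracle for the five-hypothesis colocalization
# enumeration: a direct double loop over all M x M causal-variant
# configurations on the raw (non-log) Bayes-factor scale, with no log-space
# shortcuts. Only usable for small M.
bruteColoc <- function(lbfA, lbfB, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  bfA <- exp(lbfA)
  bfB <- exp(lbfB)
  M <- length(bfA)
  w0 <- 1
  w1 <- 0
  for (i in seq_len(M)) w1 <- w1 + p1 * bfA[i]
  w2 <- 0
  for (j in seq_len(M)) w2 <- w2 + p2 * bfB[j]
  w3 <- 0
  w4 <- 0
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) {
        w4 <- w4 + p12 * bfA[i] * bfB[j]
      } else {
        w3 <- w3 + p1 * p2 * bfA[i] * bfB[j]
      }
    }
  }
  w <- c(w0, w1, w2, w3, w4)
  setNames(w / sum(w), paste0("PP", 0:4))
}
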