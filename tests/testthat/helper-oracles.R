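# Brute-force oracle: probability of a run of `run` successes within `n`
# Bernoulli(p) trials, by exhaustive enumeration over all 2^n sequences.
enumerate_pass_probability <- function(run, p, n) {
  total <- 0
  for (i in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(i))[seq_len(n)]
    r <- rle(bits)
    if (any(r$values == 1L & r$lengths >= run)) {
      k <- sum(bits)
      total <- total + p^k * (1 - p)^(n - k)
    }
  }
  total
}

# A small complete score matrix with known structure, used across tests.
toy_scores <- function() {
  m <- matrix(
    c(6, 10, 8,
      12, 25, 15,
      30, 60, 40,
      45, 80, 70,
      90, 120, 100,
      20, 35, 22,
      55, 95, 60,
      8, 14, 12),
    ncol = 3, byrow = TRUE,
    dimnames = list(sprintf("B%02d", 1:8),
                    c("associative", "reversal", "inhibitory"))
  )
  m
}
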