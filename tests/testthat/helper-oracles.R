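# Independent oracles, written as literal double loops so they share no code
# path with the package implementation.

# Brute-force sample-entropy match fractions: for every ordered pair (i, j),
# j != i, compare templates of length m and m + 1 under the Chebyshev metric.
sampen_oracle <- function(x, m = 1, r = 0.4, sd_type = "population") {
  n <- length(x)
  sdx <- if (sd_type == "population") sqrt(mean((x - mean(x))^2)) else sd(x)
  tol <- r * sdx
  nt <- n - m
  b_i <- numeric(nt)
  a_i <- numeric(nt)
  for (i in seq_len(nt)) {
    bi <- 0L
    ai <- 0L
    for (j in seq_len(nt)) {
      if (j == i) next
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= tol) bi <- bi + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= tol) ai <- ai + 1L
    }
    b_i[i] <- bi / (n - m - 1L)
    a_i[i] <- ai / (n - m - 1L)
  }
  list(b_mean = mean(b_i), a_mean = mean(a_i))
}

# All-pairs concordance probability (ties count one half).
auc_oracle <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}
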