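# Independent brute-force oracles, deliberately written without reference to
# the implementations they check.

# Affine-gap local alignment score by direct Gotoh dynamic programming.
# Gap of length L costs `open + L * extend` (matching the package's
# convention). Pure R, O(n*m); intended for short sequences only.
oracle_sw_score <- function(a, b, mat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)     # best ending in match/mismatch or fresh
  E <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
  F <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - open - extend, E[i - 1, j] - extend)
      F[i, j] <- max(H[i, j - 1] - open - extend, F[i, j - 1] - extend)
      s <- mat[av[i - 1], bv[j - 1]]
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, summing hypergeometric probabilities <= the observed
# table's probability.
oracle_fisher_p <- function(tab) {
  m <- matrix(as.numeric(tab), 2, byrow = TRUE)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  hyper <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
  }
  as <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(as, hyper, 0)
  p_obs <- hyper(m[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Paired Wilcoxon signed-rank p by enumerating all 2^n sign assignments of
# the nonzero differences (midranks for ties), n <= ~15.
oracle_signrank_p <- function(a, b, alternative = "two_sided") {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  p <- switch(alternative,
    greater = mean(Ws >= W - 1e-9),
    less = mean(Ws <= W + 1e-9),
    two_sided = mean(abs(Ws - mu) >= abs(W - mu) - 1e-9),
    one_tailed = mean(Ws >= W - 1e-9))
  p
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
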