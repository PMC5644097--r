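# Shared fixtures and independent brute-force oracles.

# one planted tanh-link triplet with exact standard-normal marginals
draw_planted_triplet <- function(theta, m) {
  z <- rnorm(m); w <- rnorm(m); e <- rnorm(m)
  rho <- tanh(theta * z)
  list(x = w, y = rho * w + sqrt(1 - rho^2) * e, z = z)
}

# scalar-loop LA oracle, written independently of la_score
oracle_la <- function(x, y, z) {
  acc <- 0
  for (i in seq_along(x)) acc <- acc + x[i] * y[i] * z[i]
  acc / length(x)
}

# brute-force MLA oracle: explicit equal-size binning by sorted order
oracle_mla <- function(x1, x2, x3, n_bins = 3L) {
  m <- length(x3)
  ord <- order(x3)
  sizes <- rep(m %/% n_bins, n_bins)
  rem <- m %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  acc <- 0
  for (i in seq_len(n_bins)) {
    idx <- ord[starts[i]:stops[i]]
    acc <- acc + cor(x1[idx], x2[idx]) * mean(x3[idx])
  }
  acc / n_bins
}

# canonical key of an unordered triplet, for matching planted ground truth
triplet_key <- function(a, b, c) {
  apply(cbind(a, b, c), 1L, function(r) paste(sort(r), collapse = "|"))
}

# small expression matrix of i.i.d. noise with identifiers
noise_matrix <- function(g, m, seed = 1L) {
  set.seed(seed)
  mat <- matrix(rnorm(g * m), nrow = g,
                dimnames = list(sprintf("g%03d", seq_len(g)),
                                sprintf("s%03d", seq_len(m))))
  mat
}
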