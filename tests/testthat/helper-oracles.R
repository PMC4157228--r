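# Independent oracles used against the package implementations.

# Exact-rational two-tailed Fisher p for small tables. Every term
# C(c1, k) * C(c2, r1 - k) is an integer bounded by C(N, r1) <= C(30, 15),
# so for N <= 30 all arithmetic below is exact in double precision; the
# single division at the end is the only rounding step.
oracle_fisher_exact <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  terms <- choose(c1, ks) * choose(r2 + r1 - c1, r1 - ks) # C(c1,k) C(c2,r1-k)
  # reparametrize: draw r1 items, k from column 1 (size c1), rest from column 2
  obs <- terms[ks == a]
  sum(terms[terms <= obs * (1 + 1e-7)]) / choose(r1 + r2, r1)
}

# Enumeration oracle for large tables, using the independent saddle-point
# hypergeometric pmf from base R (Loader's algorithm, not log-choose).
oracle_fisher_dhyper <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  pmf <- stats::dhyper(ks, c1, r1 + r2 - c1, r1)
  obs <- pmf[ks == a]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

# Naive O(m^2) Benjamini-Hochberg: adj(i) = min(1, min over j with
# rank(j) >= rank(i) of m * p(j) / rank(j)).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(r >= r[i])
    min(1, min(m * p[js] / r[js]))
  }, numeric(1))
}

# Random 2x2 table with total at most n_max (all margins can be zero-ish
# but never the whole table).
random_table <- function(n_max) {
  repeat {
    cells <- as.integer(rmultinom(1, sample.int(n_max, 1), runif(4)))
    if (sum(cells) > 0) {
      return(cells)
    }
  }
}
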