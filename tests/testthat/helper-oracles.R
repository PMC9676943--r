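# Independent oracle implementations used to cross-check package routines.
# These deliberately re-derive each quantity from its definition and never
# share code with the implementation under test.

# strand odds ratio, written straight from the definition
oracle_sor <- function(ref_fw, ref_rv, alt_fw, alt_rv) {
  r1 <- ref_fw + 1; r2 <- ref_rv + 1; a1 <- alt_fw + 1; a2 <- alt_rv + 1
  ratio <- (r1 * a2) / (r2 * a1)
  sym <- ratio + 1 / ratio
  log(sym) + log(min(r1, r2) / max(r1, r2)) - log(min(a1, a2) / max(a1, a2))
}

# brute-force Benjamini-Hochberg: q_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration:
# sum of probabilities of all tables (with the observed margins) whose
# probability does not exceed the observed table's
oracle_fisher <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # col 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p for tiny samples by full enumeration of
# rank assignments
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_obs <- sum(vapply(x, function(xi) sum(xi > y), numeric(1)))
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(vapply(xs, function(xi) sum(xi > ys), numeric(1)))
  })
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# small deterministic call table builder
make_calls <- function(position, alt, hf, ref_fw = 500, ref_rv = 500,
                       sample_id = "S1") {
  n <- length(position)
  depth <- ref_fw + ref_rv
  alt_n <- round(hf * depth / (1 - hf))
  data.frame(
    sample_id = sample_id, position = as.integer(position),
    ref_allele = rep("A", n), alt_allele = alt,
    ref_fw = rep_len(ref_fw, n), ref_rv = rep_len(ref_rv, n),
    alt_fw = ceiling(alt_n / 2), alt_rv = alt_n - ceiling(alt_n / 2),
    mean_base_quality = 33, mean_mapping_quality = 50,
    callers = "A,B,C",
    heteroplasmy_fraction = hf,
    stringsAsFactors = FALSE)
}

# minimal fast simulation config for tests
test_config <- function(...) {
  simulation_config(n_families = 12, mean_coverage = 5000, seed = 101, ...)
}
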