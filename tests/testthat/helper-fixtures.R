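# Small deterministic fixtures shared across tests.

tiny_beta <- function(vals = c(0.1, 0.5, 0.9, 0.5), nr = 2, nc = 2) {
  beta_matrix(matrix(vals, nr, nc),
              probe_ids = sprintf("cg%02d", seq_len(nr)),
              sample_ids = sprintf("S%02d", seq_len(nc)))
}

# independent two-sample pooled t computed directly from first principles
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# exhaustive label-enumeration p-value for a single probe row,
# independent of the package's permutation machinery
oracle_exhaustive_p <- function(row, g) {
  n <- length(row)
  n2 <- sum(g == "IR")
  combos <- combn(n, n2)
  obs <- abs(oracle_pooled_t(row[g == "IS"], row[g == "IR"]))
  nulls <- apply(combos, 2, function(ix)
    abs(oracle_pooled_t(row[-ix], row[ix])))
  (1 + sum(nulls >= obs - 1e-9)) / (1 + ncol(combos))
}

# enumeration oracle for the two-sided Mann-Whitney p-value
oracle_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_of <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  combos <- combn(length(pool), n1)
  dev_obs <- abs(u_of(x, y) - mu)
  devs <- apply(combos, 2, function(ix) abs(u_of(pool[ix], pool[-ix]) - mu))
  mean(devs >= dev_obs - 1e-12)
}
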