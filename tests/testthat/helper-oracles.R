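# Independent reference implementations used as oracles: deliberately written
# at the definition level (explicit loops / enumeration), not sharing code
# with the package internals.

# Checkerboard units by exhaustive enumeration of site pairs: count ordered
# patterns where species i occurs alone at one site and j alone at another.
brute_cu_pair <- function(x, y) {
  n <- length(x)
  cnt <- 0L
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b && x[a] == 1 && y[a] == 0 && x[b] == 0 && y[b] == 1) cnt <- cnt + 1L
    }
  }
  cnt
}

# Total CU by the naive double loop over species pairs.
naive_cu_total <- function(m) {
  tot <- 0
  for (i in seq_len(ncol(m) - 1L)) {
    for (j in (i + 1L):ncol(m)) {
      si <- sum(m[, i]); sj <- sum(m[, j]); q <- sum(m[, i] * m[, j])
      tot <- tot + (si - q) * (sj - q)
    }
  }
  tot
}

# NODF straight from the definition, explicit loops over ordered unit pairs.
enum_nodf <- function(m) {
  m <- m[order(rowSums(m), decreasing = TRUE), , drop = FALSE]
  m <- m[, order(colSums(m), decreasing = TRUE), drop = FALSE]
  pair_sum <- function(units) {    # units: list of binary vectors, sorted
    tot <- 0; npairs <- 0L
    for (u in seq_along(units)[-length(units)]) {
      for (v in (u + 1L):length(units)) {
        npairs <- npairs + 1L
        fu <- sum(units[[u]]); fv <- sum(units[[v]])
        if (fu > fv && fv > 0) {
          tot <- tot + 100 * sum(units[[u]] * units[[v]]) / fv
        }
      }
    }
    c(tot, npairs)
  }
  rows <- pair_sum(split(m, row(m)))
  cols <- pair_sum(split(t(m), row(t(m))))
  (rows[1] + cols[1]) / (rows[2] + cols[2])
}

# All binary matrices with the given row and column sums, keyed by their
# cell pattern, found by brute force over all 2^(r*c) matrices.
enumerate_margin_class <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  keys <- character(0)
  for (code in 0:(2^(nr * nc) - 1L)) {
    bits <- as.integer(intToBits(code)[seq_len(nr * nc)])
    m <- matrix(bits, nr, nc)
    if (all(rowSums(m) == row_sums) && all(colSums(m) == col_sums)) {
      keys <- c(keys, paste(bits, collapse = ""))
    }
  }
  keys
}

# Constrained fraction of a distance matrix regressed on predictors, from
# first principles: Gower double-centering, eigendecomposition, coordinates
# on positive axes, least-squares projection on the predictor space.
pcoa_constrained_fraction <- function(D, X) {
  D <- as.matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > 1e-10
  Y <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
  Xc <- cbind(1, as.matrix(X))
  H <- Xc %*% solve(crossprod(Xc), t(Xc))
  fitted <- H %*% Y
  sum(fitted^2) / sum(Y^2)
}

# Small random binary matrix with no empty rows or columns.
random_community <- function(n_sites, n_species, p = 0.4) {
  repeat {
    m <- matrix(rbinom(n_sites * n_species, 1, p), n_sites, n_species)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
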