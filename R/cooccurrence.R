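#' Checkerboard units for one species pair
#'
#' The number of checkerboard units CU for species i and j equals
#' (S_i - q)(S_j - q), where S_i and S_j are the two species' occurrence
#' counts and q the number of sites holding both. This is the count of site
#' pairs (a, b) where i occurs without j at a and j occurs without i at b —
#' the perfect 2x2 checkerboard submatrices (patterns 10/01 or 01/10).
#'
#' @param occ_i,occ_j binary site vectors of equal length.
#' @return nonnegative count of checkerboard units.
#' @export
checkerboard_units <- function(occ_i, occ_j) {
  if (length(occ_i) != length(occ_j)) stop("occurrence vectors differ in length")
  occ_i <- as.numeric(occ_i > 0)
  occ_j <- as.numeric(occ_j > 0)
  q <- sum(occ_i * occ_j)
  (sum(occ_i) - q) * (sum(occ_j) - q)
}

# Pairwise CU matrix (species x species, upper structure symmetric, zero diag),
# computed through the species co-occurrence count matrix Q = t(M) M.
cu_matrix <- function(M) {
  m <- unclass(M)
  storage.mode(m) <- "double"
  q <- crossprod(m)           # q[i, j] = sites where both i and j occur
  s <- diag(q)                # q[i, i] = S_i
  # (S_i - q_ij) * (S_j - q_ij)
  cu <- (matrix(s, length(s), length(s)) - q) *
        (matrix(s, length(s), length(s), byrow = TRUE) - q)
  diag(cu) <- 0
  cu
}

#' Total checkerboard units of a community matrix
#'
#' Sum of checkerboard units over all unordered species pairs, computed from
#' the species co-occurrence count matrix (bit-identical to looping over
#' pairs, but O(n^2 m) via one matrix product).
#'
#' @param M community matrix with at least two species.
#' @return nonnegative total.
#' @export
cu_total <- function(M) {
  if (ncol(M) < 2L) stop("need at least two species")
  sum(cu_matrix(M)[upper.tri(diag(ncol(M)))])
}

#' C-score: average checkerboard units per species pair
#'
#' Total checkerboard units divided by a species-pair count. The default
#' `"ordered_pairs"` convention divides by n(n-1); the `"stone_roberts"`
#' convention divides by the number of unordered pairs n(n-1)/2 and is exactly
#' twice as large. Both are computed so either reporting convention can be
#' matched; the default is the ordered-pair denominator.
#'
#' @param M community matrix.
#' @param denominator `"ordered_pairs"` (n(n-1), default) or
#'   `"stone_roberts"` (n(n-1)/2).
#' @return nonnegative average.
#' @export
c_score <- function(M, denominator = c("ordered_pairs", "stone_roberts")) {
  denominator <- match.arg(denominator)
  n <- ncol(M)
  tot <- cu_total(M)
  switch(denominator,
         ordered_pairs = tot / (n * (n - 1)),
         stone_roberts = tot / (n * (n - 1) / 2))
}

#' Checkerboard units partitioned by species groups
#'
#' Sums checkerboard units separately for every unordered pair of group
#' labels (e.g. motile-motile, low-high), plus `within` (both species share a
#' label), `between` (labels differ) and `total` aggregates. The disjoint
#' label-pair sums always add up exactly to the total.
#'
#' @param M community matrix.
#' @param G named character vector of group labels covering every species.
#' @return data frame with columns `pair`, `cu`, and attributes none; rows
#'   include every observed label pair plus `within`, `between`, `total`.
#' @export
cu_by_groups <- function(M, G) {
  if (is.null(names(G))) stop("group map must be named by species")
  miss <- setdiff(colnames(M), names(G))
  if (length(miss)) stop("unlabeled species: ", paste(miss, collapse = ", "))
  G <- as.character(G[colnames(M)])
  cu <- cu_matrix(M)
  ut <- upper.tri(cu)
  labs <- sort(unique(G))
  i_lab <- matrix(G, length(G), length(G))
  j_lab <- matrix(G, length(G), length(G), byrow = TRUE)
  key <- ifelse(i_lab <= j_lab, paste(i_lab, j_lab, sep = "-"),
                paste(j_lab, i_lab, sep = "-"))
  pair_sum <- tapply(cu[ut], key[ut], sum)
  within <- sum(cu[ut & i_lab == j_lab])
  total <- sum(cu[ut])
  out <- data.frame(pair = c(names(pair_sum), "within", "between", "total"),
                    cu = c(as.numeric(pair_sum), within, total - within, total),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$pair
  out
}

#' Checkerboard over/under-estimation index F
#'
#' Elementwise ratio F = CU_model / CU_real for matching group-pair keys.
#' F > 1 means the null model over-estimates segregation for that pair of
#' groups; F < 1 means it under-estimates it. Keys with CU_real == 0 are
#' undefined and reported as `NA`.
#'
#' @param cu_model,cu_real data frames as returned by [cu_by_groups()] with
#'   identical `pair` key sets.
#' @return data frame with columns `pair` and `f`.
#' @export
f_index <- function(cu_model, cu_real) {
  if (!setequal(cu_model$pair, cu_real$pair)) stop("group-pair key sets differ")
  cu_real <- cu_real[match(cu_model$pair, cu_real$pair), ]
  f <- ifelse(cu_real$cu > 0, cu_model$cu / cu_real$cu, NA_real_)
  data.frame(pair = cu_model$pair, f = f, stringsAsFactors = FALSE)
}

#' NODF nestedness of a binary matrix
#'
#' Nestedness metric based on overlap and decreasing fill, on the 0-100
#' scale. Rows and columns are sorted by decreasing marginal totals (ties
#' keep original order); for every ordered pair (u before v) with a strictly
#' larger marginal total, the paired contribution is 100 * overlap(u, v) /
#' fill(v), and 0 when the totals are equal. NODF is the mean over all row
#' pairs and column pairs together; row-wise and column-wise component means
#' are also returned. Computed unweighted on incidence data.
#'
#' @param M binary matrix with at least 2 rows and 2 columns.
#' @return list with components `nodf`, `rows`, `cols` (all in \[0, 100\]).
#' @export
nodf <- function(M) {
  m <- unclass(M)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least a 2 x 2 matrix")
  if (sum(m) == 0) stop("degenerate all-zero matrix")
  m <- m[order(rowSums(m), decreasing = TRUE), , drop = FALSE]
  m <- m[, order(colSums(m), decreasing = TRUE), drop = FALSE]
  paired <- function(x) {                 # x: units-in-rows matrix, sorted
    fill <- rowSums(x)
    ov <- tcrossprod(x)                   # ov[u, v] = shared presences
    n <- nrow(x)
    fu <- matrix(fill, n, n)              # fill of the earlier (row) unit
    fv <- matrix(fill, n, n, byrow = TRUE)
    contrib <- ifelse(fu > fv & fv > 0, 100 * ov / fv, 0)
    sum(contrib[upper.tri(contrib)])
  }
  np_rows <- paired(m)
  np_cols <- paired(t(m))
  nr <- nrow(m); nc <- ncol(m)
  pairs_r <- nr * (nr - 1) / 2
  pairs_c <- nc * (nc - 1) / 2
  list(nodf = (np_rows + np_cols) / (pairs_r + pairs_c),
       rows = np_rows / pairs_r,
       cols = np_cols / pairs_c)
}
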