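test_that("checkerboard units match the closed form and brute enumeration", {
  expect_equal(checkerboard_units(c(1, 0), c(0, 1)), 1)
  v <- c(1, 0, 1, 0, 1)
  expect_equal(checkerboard_units(v, v), 0)
  # S_i = 2, S_j = 3, disjoint over 6 sites: (2 - 0)(3 - 0)
  expect_equal(checkerboard_units(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 1, 0)), 6)
  expect_error(checkerboard_units(c(1, 0), c(1, 0, 1)), "length")
  set.seed(11)
  for (r in 1:20) {
    x <- rbinom(12, 1, 0.5); y <- rbinom(12, 1, 0.5)
    expect_equal(checkerboard_units(x, y), brute_cu_pair(x, y))
  }
})

test_that("cu_total equals the naive pairwise loop and handles edge matrices", {
  expect_equal(cu_total(as_community_matrix(diag(2))), 1)
  expect_equal(cu_total(as_community_matrix(matrix(1, 4, 5))), 0)
  expect_error(cu_total(as_community_matrix(matrix(1, 4, 1))), "two species")
  set.seed(21)
  for (r in 1:10) {
    m <- random_community(10, 15)
    expect_equal(cu_total(as_community_matrix(m)), naive_cu_total(m))
  }
})

test_that("cu_total is invariant under row and column permutations", {
  set.seed(31)
  m <- random_community(8, 9)
  ref <- cu_total(as_community_matrix(m))
  for (r in 1:5) {
    p <- m[sample(8), sample(9)]
    expect_equal(cu_total(as_community_matrix(p)), ref)
  }
})

test_that("the two C-score denominators differ exactly by a factor of two", {
  M <- as_community_matrix(diag(2))
  expect_equal(c_score(M, "ordered_pairs"), 0.5)
  expect_equal(c_score(M, "stone_roberts"), 1.0)
  set.seed(41)
  for (r in 1:5) {
    M <- as_community_matrix(random_community(9, 7))
    expect_equal(c_score(M, "ordered_pairs"),
                 c_score(M, "stone_roberts") / 2)
  }
})

test_that("C-score (unordered-pair convention) agrees with vegan", {
  set.seed(43)
  m <- random_community(12, 10)
  expect_equal(c_score(as_community_matrix(m), "stone_roberts"),
               unname(vegan::nestedchecker(m)$C.score))
})

test_that("group-partitioned checkerboard sums add up to the total", {
  set.seed(51)
  m <- random_community(12, 10)
  dimnames(m) <- list(paste0("t", 1:12), paste0("sp", 1:10))
  M <- as_community_matrix(m)
  # single group: within == total, between == 0
  g1 <- setNames(rep("only", 10), colnames(m))
  cu1 <- cu_by_groups(M, g1)
  expect_equal(cu1["within", "cu"], cu1["total", "cu"])
  expect_equal(cu1["between", "cu"], 0)
  # two species in singleton groups: no within pairs
  m2 <- m[, 1:2]
  cu2 <- cu_by_groups(as_community_matrix(m2),
                      setNames(c("a", "b"), colnames(m2)))
  expect_equal(cu2["within", "cu"], 0)
  # arbitrary 3-group labelings: disjoint pair sums == total == cu_total
  for (r in 1:5) {
    g <- setNames(sample(c("x", "y", "z"), 10, replace = TRUE), colnames(m))
    cu <- cu_by_groups(M, g)
    pair_rows <- !cu$pair %in% c("within", "between", "total")
    expect_equal(sum(cu$cu[pair_rows]), cu["total", "cu"])
    expect_equal(cu["within", "cu"] + cu["between", "cu"], cu["total", "cu"])
    expect_equal(cu["total", "cu"], cu_total(M))
  }
  expect_error(cu_by_groups(M, g1[-1]), "unlabeled")
})

test_that("F-index is the elementwise CU ratio with undefined zero keys", {
  real <- data.frame(pair = c("a-a", "a-b", "total"), cu = c(10, 0, 10))
  same <- f_index(real, real)
  expect_equal(same$f[same$pair == "a-a"], 1)
  expect_true(is.na(same$f[same$pair == "a-b"]))
  doubled <- real; doubled$cu <- doubled$cu * 2
  expect_equal(f_index(doubled, real)$f[1], 2)
  expect_error(f_index(real[1:2, ], real), "key sets differ")
})

test_that("NODF hits its extremes and matches definition-level enumeration", {
  tri <- matrix(0, 4, 4); tri[lower.tri(tri, diag = TRUE)] <- 1
  expect_equal(nodf(tri)$nodf, 100)
  expect_equal(nodf(matrix(c(1, 0, 0, 1), 2, 2))$nodf, 0)
  expect_error(nodf(matrix(0, 3, 3)), "all-zero")
  set.seed(61)
  for (r in 1:10) {
    m <- random_community(8, 8, p = 0.45)
    got <- nodf(m)
    expect_equal(got$nodf, enum_nodf(m))
    ref <- vegan::nestednodf(m)$statistic
    expect_equal(got$nodf, unname(ref["NODF"]))
    expect_equal(got$rows, unname(ref["N.rows"]))
    expect_equal(got$cols, unname(ref["N.columns"]))
  }
})

test_that("NODF is invariant under row/column permutations (internal sorting)", {
  set.seed(71)
  m <- random_community(7, 9)
  ref <- nodf(m)$nodf
  for (r in 1:5) {
    expect_equal(nodf(m[sample(7), sample(9)])$nodf, ref)
  }
})

test_that("nesting a matrix lowers checkerboard units and raises NODF", {
  # pack the presences of each species into the richest sites: maximally
  # nested rearrangement with identical column sums
  set.seed(81)
  m <- random_community(10, 12, p = 0.35)
  ord <- order(rowSums(m), decreasing = TRUE)
  nested <- matrix(0L, 10, 12)
  for (j in 1:12) nested[ord[seq_len(sum(m[, j]))], j] <- 1L
  expect_gt(nodf(nested)$nodf, nodf(m)$nodf)
  expect_lt(cu_total(as_community_matrix(nested)),
            cu_total(as_community_matrix(m)))
})
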