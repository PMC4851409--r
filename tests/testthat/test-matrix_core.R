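test_that("abundance inputs are binarized and marginals are consistent", {
  x <- matrix(c(0, 1, 2, 0, 5, 1), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  M <- as_community_matrix(x)
  expect_true(all(M %in% c(0L, 1L)))
  expect_equal(matrix_fill(M), 4)
  expect_equal(sum(species_occurrences(M)), sum(site_richness(M)))
  expect_error(as_community_matrix(matrix(c(1, NA), 1, 2)), "missing")
  dup <- x; rownames(dup) <- c("a", "a", "c")
  expect_error(as_community_matrix(dup), "duplicate site")
})

test_that("write -> read round-trip is the identity and counts are binarized", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(42)
  m <- random_community(6, 4)
  dimnames(m) <- list(paste0("site", 1:6), paste0("sp", 1:4))
  M <- as_community_matrix(m)
  write_community_matrix(M, path)
  expect_message(M2 <- read_community_matrix(path), "6 sites x 4 species")
  expect_equal(unclass(M2), unclass(M))

  # counts above one map to presence
  writeLines(c("id,sp1,sp2", "a,0,2", "b,1,0", "c,0,1"), path)
  M3 <- suppressMessages(read_community_matrix(path))
  expect_equal(matrix_fill(M3), 3)
  expect_equal(unname(unclass(M3)["a", "sp2"]), 1L)
})

test_that("loader rejects empty or non-numeric files naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  expect_error(read_community_matrix(path), "empty")
  writeLines(c("id,sp1,sp2", "a,1,x", "b,0,1"), path)
  expect_error(suppressMessages(read_community_matrix(path)), "sp2")
})

test_that("semicolon-delimited tables are autodetected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id;sp1;sp2", "a;1;0", "b;0;1"), path)
  M <- suppressMessages(read_community_matrix(path))
  expect_equal(dim(M), c(2L, 2L))
  expect_equal(matrix_fill(M), 2)
})

test_that("rare-species filter keeps species at or above the threshold only", {
  # occurrence counts 1, 2, 5, 6, 10 over 10 sites
  m <- matrix(0L, 10, 5, dimnames = list(paste0("t", 1:10), paste0("sp", 1:5)))
  s <- c(1, 2, 5, 6, 10)
  for (j in 1:5) m[seq_len(s[j]), j] <- 1L
  M <- as_community_matrix(m)
  kept <- filter_rare_species(M, 5)
  expect_equal(colnames(kept), c("sp3", "sp4", "sp5"))
  # a species seen 4 times falls below a threshold of five samples
  expect_false("sp2" %in% colnames(filter_rare_species(M, 5)))
  # threshold one is the identity
  expect_equal(unclass(filter_rare_species(M, 1)), unclass(M))
  # idempotent at the same threshold
  expect_equal(unclass(filter_rare_species(kept, 5)), unclass(kept))
  expect_error(filter_rare_species(M, 11), "no species left")
  expect_equal(nrow(kept), 10L)   # sites are never dropped
})

test_that("filtering retains emptied sites with a warning", {
  m <- matrix(0L, 4, 2, dimnames = list(paste0("t", 1:4), c("common", "rare")))
  m[, 1] <- c(1L, 1L, 1L, 0L)
  m[4, 2] <- 1L
  expect_warning(kept <- filter_rare_species(as_community_matrix(m), 3),
                 "zero richness")
  expect_equal(nrow(kept), 4L)
  expect_equal(unname(site_richness(kept)["t4"]), 0)
})

test_that("alignment restricts and reorders all inputs to common identifiers", {
  set.seed(7)
  m <- random_community(5, 3)
  dimnames(m) <- list(paste0("site", 1:5), paste0("sp", 1:3))
  M <- as_community_matrix(m)
  E <- data.frame(x = rnorm(6), y = rnorm(6),
                  row.names = paste0("site", c(3, 1, 2, 5, 4, 6)))
  G <- setNames(c("a", "b", "a"), paste0("sp", c(2, 1, 3)))
  expect_warning(al <- align_inputs(M, E, G), "site6")
  expect_equal(rownames(al$E), rownames(al$M))
  expect_equal(names(al$G), colnames(al$M))
  expect_equal(al$E["site3", "x"], E["site3", "x"])
  # a species without a label is an error naming it
  expect_error(align_inputs(M, E[1:5, ], G[c("sp1", "sp2")]), "sp3")
  E_disjoint <- data.frame(x = 1:2, row.names = c("p", "q"))
  expect_error(align_inputs(M, E_disjoint), "no common sites")
})

test_that("environmental missing values fail by default and impute on request", {
  E <- data.frame(a = c(1, NA, 3), b = c(4, 5, 6), row.names = c("x", "y", "z"))
  expect_error(validate_environment_table(E), "a")
  E2 <- validate_environment_table(E, impute = TRUE)
  expect_equal(E2$a[2], 2)   # column median of 1 and 3
  expect_error(validate_environment_table(data.frame(a = letters[1:3])),
               "non-numeric")
})
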