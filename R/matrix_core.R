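#' Coerce and validate a binary community matrix
#'
#' A community matrix is a sites-by-species incidence matrix: rows are sites,
#' columns are species, cells record presence (1) or absence (0). Abundance
#' inputs are binarized at >= 1; the analyses in this package are
#' incidence-based throughout.
#'
#' @param x a numeric matrix or data frame with unique row (site) and column
#'   (species) names; any positive cell value is mapped to presence.
#' @return an integer matrix of 0/1 with dimnames, of class
#'   `c("community_matrix", "matrix")`.
#' @export
as_community_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("community matrix must be a numeric matrix or data frame")
  }
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column %d", bad[1L], bad[2L]))
  }
  if (any(x < 0)) stop("negative cell values are not valid incidence data")
  if (is.null(rownames(x))) rownames(x) <- paste0("site_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sp_", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate site identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate species identifiers")
  m <- matrix(as.integer(x > 0), nrow(x), ncol(x), dimnames = dimnames(x))
  class(m) <- c("community_matrix", class(m))
  m
}

#' Per-species occurrence counts (column sums)
#' @param M community matrix.
#' @return named integer vector, one entry per species.
#' @export
species_occurrences <- function(M) colSums(unclass(M))

#' Per-site richness (row sums)
#' @param M community matrix.
#' @return named integer vector, one entry per site.
#' @export
site_richness <- function(M) rowSums(unclass(M))

#' Total number of presences in the matrix
#' @param M community matrix.
#' @return scalar fill.
#' @export
matrix_fill <- function(M) sum(unclass(M))

#' Read a community matrix from a delimited text file
#'
#' Expects a rectangular table, site identifiers in the first column, species
#' identifiers in the header. The delimiter (comma or semicolon) is
#' autodetected from the header line. Any positive count is binarized to
#' presence.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) autodetects "," vs ";".
#' @return a validated community matrix.
#' @export
read_community_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) stop("empty file: ", path)
  if (is.null(sep)) {
    sep <- if (lengths(gregexpr(";", header, fixed = TRUE)) >
              lengths(gregexpr(",", header, fixed = TRUE))) ";" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  num <- vapply(tab, is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric cells in column(s): ",
         paste(names(tab)[!num], collapse = ", "))
  }
  M <- as_community_matrix(tab)
  message(sprintf("community matrix: %d sites x %d species, fill %d",
                  nrow(M), ncol(M), matrix_fill(M)))
  M
}

#' Write a community matrix to CSV
#' @param M community matrix.
#' @param path output file path.
#' @export
write_community_matrix <- function(M, path) {
  utils::write.csv(as.data.frame(unclass(M)), path, row.names = TRUE)
  invisible(path)
}

#' Read a site-by-variable environmental table
#'
#' First column holds site identifiers; remaining columns must be numeric.
#' Missing values fail by default; `impute = TRUE` replaces them with the
#' column median.
#'
#' @param path file path.
#' @param sep delimiter, autodetected when `NULL`.
#' @param impute replace missing values by column medians instead of failing.
#' @return a data frame with sites as row names, all columns numeric and finite.
#' @export
read_environment_table <- function(path, sep = NULL, impute = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) stop("empty file: ", path)
  if (is.null(sep)) {
    sep <- if (lengths(gregexpr(";", header, fixed = TRUE)) >
              lengths(gregexpr(",", header, fixed = TRUE))) ";" else ","
  }
  E <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  validate_environment_table(E, impute = impute)
}

#' Validate (and optionally impute) an environmental table
#' @param E data frame of numeric site variables, sites as row names.
#' @param impute replace missing values by column medians.
#' @return the validated data frame.
#' @export
validate_environment_table <- function(E, impute = FALSE) {
  num <- vapply(E, is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric environmental column(s): ",
         paste(names(E)[!num], collapse = ", "))
  }
  if (anyNA(E) || any(!vapply(E, function(v) all(is.finite(v) | is.na(v)), logical(1L)))) {
    if (!impute) {
      bad <- names(E)[vapply(E, function(v) anyNA(v) || any(!is.finite(v)), logical(1L))]
      stop("missing/non-finite environmental values in: ",
           paste(bad, collapse = ", "), " (set impute = TRUE for column medians)")
    }
    E[] <- lapply(E, function(v) {
      v[!is.finite(v)] <- NA
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      v
    })
  }
  if (anyDuplicated(rownames(E))) stop("duplicate site identifiers in environment table")
  E
}

#' Read a species-to-group map
#'
#' Two columns: species identifier and categorical label (e.g. growth-form
#' guild `low`/`high`/`motile`/`unknown`, or genus name).
#'
#' @param path CSV path with columns `species` and `label` (names flexible:
#'   first column species, second label).
#' @return named character vector of labels, names are species identifiers.
#' @export
read_group_map <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group map needs two columns: species, label")
  g <- as.character(tab[[2L]])
  names(g) <- as.character(tab[[1L]])
  if (anyDuplicated(names(g))) stop("duplicate species in group map")
  g
}

#' Drop species observed in fewer than a minimum number of sites
#'
#' Rarely observed species carry little co-occurrence information and are
#' removed before analysis; sites are never dropped, so a site may end up with
#' zero richness (fixed-richness null models and NODF handle empty rows, and
#' silently removing sites would change the fixed-richness constraints).
#'
#' @param M community matrix.
#' @param min_occurrences keep species present in at least this many sites
#'   (default 5: species present in less than five samples are excluded).
#' @return the filtered community matrix.
#' @export
filter_rare_species <- function(M, min_occurrences = 5L) {
  stopifnot(min_occurrences >= 1L)
  keep <- species_occurrences(M) >= min_occurrences
  if (!any(keep)) stop("no species left after rare-species filtering")
  out <- unclass(M)[, keep, drop = FALSE]
  empty <- rowSums(out) == 0L
  if (any(empty)) {
    warning(sprintf("%d site(s) have zero richness after filtering (kept): %s",
                    sum(empty), paste(rownames(out)[empty], collapse = ", ")))
  }
  as_community_matrix(out)
}

#' Align a community matrix, environmental table and group map
#'
#' Restricts and reorders all three objects to their common site and species
#' sets. Extra sites/species in the environment table or group map are dropped
#' with a warning; species of the community matrix missing from the group map
#' are an error (every species must carry exactly one label).
#'
#' @param M community matrix.
#' @param E environmental table (data frame, sites as row names), or `NULL`.
#' @param G named character vector of species labels, or `NULL`.
#' @return list with elements `M`, `E`, `G` aligned to common identifiers.
#' @export
align_inputs <- function(M, E = NULL, G = NULL) {
  M <- as_community_matrix(M)
  if (!is.null(E)) {
    common <- intersect(rownames(M), rownames(E))
    if (length(common) == 0L) stop("no common sites between community matrix and environment table")
    drop_m <- setdiff(rownames(M), common)
    drop_e <- setdiff(rownames(E), common)
    if (length(drop_m)) warning("sites dropped from community matrix (no environment): ",
                                paste(drop_m, collapse = ", "))
    if (length(drop_e)) warning("sites dropped from environment table (no community data): ",
                                paste(drop_e, collapse = ", "))
    M <- as_community_matrix(unclass(M)[common, , drop = FALSE])
    E <- E[common, , drop = FALSE]
  }
  if (!is.null(G)) {
    missing_sp <- setdiff(colnames(M), names(G))
    if (length(missing_sp)) {
      stop("species missing from group map: ", paste(missing_sp, collapse = ", "))
    }
    extra <- setdiff(names(G), colnames(M))
    if (length(extra)) warning(length(extra), " group-map species absent from matrix dropped")
    G <- G[colnames(M)]
  }
  list(M = M, E = E, G = G)
}
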