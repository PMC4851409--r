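#' Is a 2x2 binary submatrix a perfect checkerboard?
#'
#' A perfect checkerboard is the pattern (1,0; 0,1) or (0,1; 1,0): each
#' species occurs at exactly one of the two sites, exclusively. These are the
#' only submatrices the trial-swap chain may flip.
#'
#' @param sub a 2x2 matrix of 0/1.
#' @return `TRUE` iff the submatrix is one of the two checkerboard states.
#' @export
is_checkerboard <- function(sub) {
  if (!is.matrix(sub) || any(dim(sub) != 2L)) stop("need a 2 x 2 matrix")
  if (!all(sub %in% c(0L, 1L))) stop("submatrix must be binary")
  (sub[1, 1] == 1 && sub[2, 2] == 1 && sub[1, 2] == 0 && sub[2, 1] == 0) ||
  (sub[1, 1] == 0 && sub[2, 2] == 0 && sub[1, 2] == 1 && sub[2, 1] == 1)
}

#' One fixed-occurrences / equiprobable-sites randomization (FE)
#'
#' Redistributes each species' presences over sites uniformly and
#' independently of the other species: column sums (species occurrence
#' counts) are preserved exactly, row sums (site richness) are free.
#'
#' @param M community matrix.
#' @return one randomized matrix with the same dimnames.
#' @export
nullmod_fe <- function(M) {
  m <- unclass(M)
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  s <- colSums(m)
  for (j in seq_len(ncol(m))) {
    if (s[j] > 0L) out[sample.int(nrow(m), s[j]), j] <- 1L
  }
  as_community_matrix(out)
}

#' Sequential fixed-fixed trial-swap chain (FF)
#'
#' Markov chain over the set of binary matrices with the same row and column
#' sums as `M`. One trial draws a random 2x2 submatrix (two distinct sites,
#' two distinct species) and swaps it iff it is a perfect checkerboard
#' ([is_checkerboard()]); trial-swap counting makes all matrices of the
#' margin class equiprobable in the stationary distribution. The chain is
#' burnt in for `burnin_factor` times the per-replicate budget, then emits a
#' replicate every `thin_factor * fill` steps. Steps are counted as trials by
#' default (the chain's natural unit); `unit = "swaps"` counts successful
#' swaps instead.
#'
#' @param M community matrix (>= 2 sites and >= 2 species).
#' @param n_replicates number of matrices to emit.
#' @param thin_factor per-replicate step budget as a multiple of the matrix
#'   fill (default 10).
#' @param burnin_factor burn-in as a multiple of the per-replicate budget
#'   (default 2).
#' @param unit count `"trials"` (default) or successful `"swaps"`.
#' @param fun optional function applied to each replicate; when supplied only
#'   the results are kept (replicates are streamed, never stored together).
#' @return list of `n_replicates` matrices, or of `fun` results.
#' @export
nullmod_ff <- function(M, n_replicates, thin_factor = 10, burnin_factor = 2,
                       unit = c("trials", "swaps"), fun = NULL) {
  unit <- match.arg(unit)
  m <- unclass(as_community_matrix(M))
  if (cu_total(M) == 0 && matrix_fill(M) > 0) {
    warning("margins admit no swap: all replicates identical to the input")
  }
  budget <- thin_factor * matrix_fill(M)
  count_swaps <- unit == "swaps"
  state <- trial_swap_cpp(m, burnin_factor * budget, count_swaps)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    state <- trial_swap_cpp(state, budget, count_swaps)
    rep_m <- state
    dimnames(rep_m) <- dimnames(m)
    rep_m <- as_community_matrix(rep_m)
    out[[r]] <- if (is.null(fun)) rep_m else fun(rep_m)
  }
  out
}

#' Stream an ensemble of standard null-model replicates through a statistic
#'
#' @param M community matrix.
#' @param model `"NullModFE"` or `"NullModFF"`.
#' @param n_replicates ensemble size.
#' @param fun function applied to each replicate matrix; must return a named
#'   numeric vector (or scalar).
#' @param ... passed to [nullmod_ff()] for the FF chain.
#' @return data frame, one row per replicate, columns from `fun`.
#' @export
standard_ensemble <- function(M, model = c("NullModFE", "NullModFF"),
                              n_replicates, fun, ...) {
  model <- match.arg(model)
  vals <- switch(model,
    NullModFE = lapply(seq_len(n_replicates), function(r) fun(nullmod_fe(M))),
    NullModFF = nullmod_ff(M, n_replicates, fun = fun, ...))
  as.data.frame(do.call(rbind, lapply(vals, rbind)))
}
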