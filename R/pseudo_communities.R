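#' Draw one fixed-richness pseudo-community (PF scheme)
#'
#' For each site, draws exactly as many species as the supplied richness, by
#' successive weighted draws without replacement with weights proportional to
#' the site's pseudo-probabilities. Row sums match `richness` exactly; column
#' sums are free. Weights are floored at 1e-9 before drawing so a site
#' demanding more species than have positive probability remains feasible.
#'
#' @param P pseudo-probability matrix (sites x species, values in \[0, 1\]).
#' @param richness integer vector of per-site presence counts (usually the
#'   observed site richness).
#' @return a community matrix with the requested row sums.
#' @export
draw_fixed_richness <- function(P, richness) {
  stopifnot(length(richness) == nrow(P), all(richness >= 0),
            all(richness <= ncol(P)))
  out <- matrix(0L, nrow(P), ncol(P), dimnames = dimnames(P))
  ns <- ncol(P)
  for (s in seq_len(nrow(P))) {
    r <- richness[s]
    if (r == 0L) next
    if (r == ns) { out[s, ] <- 1L; next }
    w <- pmax(P[s, ], 1e-9)
    out[s, sample.int(ns, r, prob = w)] <- 1L
  }
  as_community_matrix(out)
}

#' Draw one proportional pseudo-community (PP scheme)
#'
#' Each cell independently compares its pseudo-probability with a uniform
#' draw on \[0, 1\]: the cell is a presence iff the pseudo-probability
#' exceeds the uniform score, i.e. cellwise Bernoulli(P). Both margins are
#' free.
#'
#' @param P pseudo-probability matrix.
#' @return a community matrix.
#' @export
draw_proportional <- function(P) {
  u <- matrix(stats::runif(length(P)), nrow(P), ncol(P))
  out <- matrix(as.integer(P > u), nrow(P), ncol(P), dimnames = dimnames(P))
  as_community_matrix(out)
}

#' Stream an ensemble of environmentally constrained pseudo-communities
#'
#' Generates `n_replicates` pseudo-community matrices from a
#' pseudo-probability matrix under the PF (fixed per-site richness, weighted
#' sampling without replacement) or PP (cellwise Bernoulli) scheme, applying
#' `fun` to each so that replicates never need simultaneous residence.
#'
#' @param P pseudo-probability matrix.
#' @param scheme `"PF"` or `"PP"`.
#' @param n_replicates ensemble size.
#' @param fun function applied to each replicate; must return a named numeric
#'   vector (or scalar). `NULL` returns the matrices themselves.
#' @param M_real real community matrix (required by PF for its richness
#'   vector).
#' @return data frame of `fun` results (one row per replicate), or a list of
#'   matrices when `fun` is `NULL`.
#' @export
pseudo_ensemble <- function(P, scheme = c("PF", "PP"), n_replicates,
                            fun = NULL, M_real = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "PF") {
    if (is.null(M_real)) stop("PF scheme needs the real matrix for its richness vector")
    richness <- site_richness(M_real)
  }
  one <- function() {
    if (scheme == "PF") draw_fixed_richness(P, richness) else draw_proportional(P)
  }
  if (is.null(fun)) return(lapply(seq_len(n_replicates), function(r) one()))
  vals <- lapply(seq_len(n_replicates), function(r) fun(one()))
  as.data.frame(do.call(rbind, lapply(vals, rbind)))
}
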