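#' Jaccard dissimilarity between sites of a binary community matrix
#'
#' d(a, b) = 1 - |A intersect B| / |A union B| on the presence sets of the
#' two sites. Pairs involving a zero-richness site have no defined Jaccard
#' ratio; by convention they get dissimilarity 1 (and 0 between two empty
#' sites, whose compositions are identical), with a warning.
#'
#' @param M community matrix.
#' @return a `dist` object over sites (symmetric, zero diagonal).
#' @export
jaccard_dissimilarity <- function(M) {
  m <- unclass(M)
  storage.mode(m) <- "double"
  empty <- rowSums(m) == 0
  D <- if (any(empty)) {
    suppressWarnings(vegan::vegdist(m, method = "jaccard", binary = TRUE))
  } else {
    vegan::vegdist(m, method = "jaccard", binary = TRUE)
  }
  if (any(empty)) {
    warning(sum(empty), " zero-richness site(s): dissimilarity 1 to non-empty sites by convention")
    Dm <- as.matrix(D)
    Dm[empty, ] <- 1
    Dm[, empty] <- 1
    Dm[empty, empty] <- 0
    diag(Dm) <- 0
    D <- stats::as.dist(Dm)
  }
  D
}

#' Distance-based redundancy analysis of a dissimilarity matrix
#'
#' Constrained principal-coordinates analysis: the dissimilarity matrix is
#' double-centered and eigendecomposed, and the site coordinates on the
#' positive-eigenvalue axes are regressed on the environmental predictors
#' (least-squares projection). Negative eigenvalues are excluded from the
#' constrained analysis (no Lingoes/Cailliez correction) and dissimilarities
#' are not square-root transformed. Backed by `vegan::capscale`.
#'
#' @param D site dissimilarities (`dist`), e.g. from
#'   [jaccard_dissimilarity()].
#' @param E environmental data frame aligned to the sites of `D`.
#' @param vars predictor subset (default: all columns of `E`).
#' @return an object of class `dbrda_result`: list with `ordination` (the
#'   capscale fit), `eigenvalues` (constrained then unconstrained, each
#'   decreasing), `constrained_inertia`, `unconstrained_inertia`,
#'   `total_inertia`, `constrained_fraction`, `site_scores`,
#'   `biplot_scores`, and `vars`.
#' @export
dbrda_fit <- function(D, E, vars = names(E)) {
  stopifnot(inherits(D, "dist"), all(vars %in% names(E)))
  dat <- E[, vars, drop = FALSE]
  env <- new.env(parent = environment())
  assign("D", D, envir = env)
  assign("dat", dat, envir = env)
  fml <- stats::as.formula("D ~ .", env = env)
  ord <- vegan::capscale(fml, data = dat)
  eig_c <- if (!is.null(ord$CCA)) ord$CCA$eig else numeric(0)
  eig_u <- ord$CA$eig[ord$CA$eig > 0]
  chi_c <- if (!is.null(ord$CCA)) ord$CCA$tot.chi else 0
  chi_u <- ord$CA$tot.chi
  res <- list(
    ordination = ord,
    eigenvalues = list(constrained = sort(eig_c, decreasing = TRUE),
                       unconstrained = sort(eig_u, decreasing = TRUE)),
    constrained_inertia = chi_c,
    unconstrained_inertia = chi_u,
    total_inertia = chi_c + chi_u,     # positive-eigenvalue inertia only
    constrained_fraction = chi_c / (chi_c + chi_u),
    site_scores = tryCatch(
      vegan::scores(ord, display = "sites",
                    choices = seq_len(max(1L, length(eig_c)))),
      error = function(e) NULL),
    biplot_scores = ord$CCA$biplot,
    vars = vars)
  class(res) <- "dbrda_result"
  res
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("dbRDA: %d predictors; constrained inertia %.3f of %.3f total (%.1f%%)\n",
              length(x$vars), x$constrained_inertia, x$total_inertia,
              100 * x$constrained_fraction))
  invisible(x)
}

#' Permutation tests for dbRDA axes and variables
#'
#' ANOVA-like permutation tests on the pseudo-F statistic: site rows of the
#' predictor table are permuted freely, the statistic recomputed, and
#' p = (number of permuted statistics >= observed + 1) / (n_perm + 1).
#' `by = "margin"` tests each variable with all others retained
#' (variable-importance table); `by = "axis"` tests the constrained axes
#' sequentially; `by = "onedf"`/`"terms"` give sequential terms.
#'
#' @param fit a `dbrda_result`.
#' @param by `"margin"`, `"axis"`, or `"terms"`.
#' @param n_perm number of permutations (default 999).
#' @return data frame with sums of squares, pseudo-F and permutation
#'   p-values per term or axis (residual row last).
#' @export
dbrda_permutation_tests <- function(fit, by = c("margin", "axis", "terms"),
                                    n_perm = 999) {
  by <- match.arg(by)
  an <- stats::anova(fit$ordination, by = by, permutations = n_perm)
  out <- as.data.frame(an)
  names(out) <- c("df", "sum_of_squares", "pseudo_f", "p_value")[seq_len(ncol(out))]
  out$term <- rownames(an)
  rownames(out) <- NULL
  out[, c("term", setdiff(names(out), "term"))]
}

#' Stepwise AIC-style variable selection for dbRDA
#'
#' Bidirectional stepwise search over predictors starting from the full
#' model, scored by the AIC analog for constrained ordination
#' (n * log(residual inertia / n) penalized by the number of predictors;
#' no closed-form likelihood exists for dbRDA, so the score is the standard
#' deviance-style heuristic). Strongly collinear predictors cost parameters
#' for almost no residual-inertia gain, so at most one of such a pair
#' survives.
#'
#' @param D site dissimilarities (`dist`).
#' @param E environmental data frame.
#' @return character vector of selected variable names.
#' @export
stepwise_select_dbrda <- function(D, E) {
  env <- new.env(parent = environment())
  assign("D", D, envir = env)
  assign("E", E, envir = env)
  full <- eval(quote(vegan::capscale(D ~ ., data = E)), envir = env)
  lower <- eval(quote(vegan::capscale(D ~ 1, data = E)), envir = env)
  sel <- stats::step(full,
                     scope = list(lower = stats::formula(lower),
                                  upper = stats::formula(full)),
                     direction = "both", trace = 0)
  labels(stats::terms(stats::formula(sel)))
}
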