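#' Simulate an environmental table structured by a few latent gradients
#'
#' Sites receive standard-normal scores on a small number of latent
#' gradients; observed variables are random linear mixtures of the gradients
#' plus independent noise, so that (as in real physico-chemical survey data)
#' variables are correlated in blocks. Optionally, near-collinear duplicates
#' of existing variables are appended with a target squared correlation —
#' mimicking measurement pairs such as alkalinity vs hydrogen carbonates.
#'
#' @param n_sites number of sites.
#' @param n_gradients number of latent gradients (>= 1).
#' @param n_vars number of observed mixture variables (before duplicates).
#' @param collinear_r2 numeric vector of target R-squared values; for each,
#'   one extra variable collinear with an existing one is appended.
#' @param noise_sd independent noise standard deviation on each variable.
#' @param seed optional integer seed for exact reproducibility.
#' @return data frame (`site_1`, ... as row names) of numeric variables
#'   `env_1..env_k` plus `dup_1..` for collinear duplicates.
#' @export
generate_environment <- function(n_sites, n_gradients = 2, n_vars = 6,
                                 collinear_r2 = numeric(0), noise_sd = 0.3,
                                 seed = NULL) {
  stopifnot(n_gradients >= 1, n_vars >= 1)
  if (any(collinear_r2 >= 1 | collinear_r2 <= 0)) {
    stop("collinear target R-squared must lie in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(stats::rnorm(n_sites * n_gradients), n_sites, n_gradients)
  L <- matrix(stats::runif(n_vars * n_gradients, -1, 1), n_vars, n_gradients)
  V <- G %*% t(L) + noise_sd * matrix(stats::rnorm(n_sites * n_vars), n_sites, n_vars)
  colnames(V) <- paste0("env_", seq_len(n_vars))
  for (i in seq_along(collinear_r2)) {
    base <- V[, 1 + (i - 1) %% n_vars]
    extra_sd <- stats::sd(base) * sqrt(1 / collinear_r2[i] - 1)
    V <- cbind(V, stats::rnorm(n_sites, base, extra_sd))
    colnames(V)[ncol(V)] <- paste0("dup_", i)
  }
  E <- as.data.frame(V)
  rownames(E) <- paste0("site_", seq_len(n_sites))
  E
}

#' Define the true niche structure of a synthetic metacommunity
#'
#' Each species gets a logistic niche: a baseline intercept drawn from a
#' normal distribution on the logit scale (so that commonness — the
#' prevalence profile — is right-skewed, as in survey data) and slopes on a
#' subset of the environmental variables. A mass-effect strength m in
#' \[0, 1\] controls how much aggregation is injected beyond the niche
#' predictions when realizing communities.
#'
#' @param n_species number of species.
#' @param env_vars names of the environmental variables the niches respond
#'   to.
#' @param intercept_mu,intercept_sd logit-scale intercept distribution
#'   (defaults -1 and 1: median prevalence around 0.27 with a right-skewed
#'   commonness profile).
#' @param slope_sd standard deviation of the nonzero niche slopes.
#' @param n_active_vars how many of `env_vars` each species responds to.
#' @param mass_effect m in \[0, 1\]: probability that an absent cell whose
#'   richer neighbor site holds the species flips to presence.
#' @param seed optional integer seed.
#' @return list of class `synthetic_truth` with `intercepts`, `slopes`
#'   (species x variables, zero where inactive), `env_vars`, `mass_effect`.
#' @export
synthetic_truth <- function(n_species, env_vars, intercept_mu = -1,
                            intercept_sd = 1, slope_sd = 1.5,
                            n_active_vars = min(2L, length(env_vars)),
                            mass_effect = 0, seed = NULL) {
  stopifnot(mass_effect >= 0, mass_effect <= 1, length(env_vars) >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- stats::rnorm(n_species, intercept_mu, intercept_sd)
  B <- matrix(0, n_species, length(env_vars),
              dimnames = list(paste0("sp_", seq_len(n_species)), env_vars))
  for (k in seq_len(n_species)) {
    active <- sample(seq_along(env_vars), n_active_vars)
    B[k, active] <- stats::rnorm(n_active_vars, 0, slope_sd)
  }
  names(a) <- rownames(B)
  structure(list(intercepts = a, slopes = B, env_vars = env_vars,
                 mass_effect = mass_effect),
            class = "synthetic_truth")
}

#' Realize a synthetic metacommunity from an environment and a niche truth
#'
#' True presence probability for species k at site s is
#' `plogis(a_k + sum(b_k * E_s))`; baseline presences are independent
#' Bernoulli draws from these probabilities (pure species sorting). With
#' mass-effect strength m > 0, sites are then ranked by realized richness
#' and each absent cell whose immediately richer neighbor site holds the
#' species is converted to a presence with probability m — a propagule-influx
#' mechanism that injects aggregation and nestedness beyond what the niches
#' predict, without any explicit spatial structure.
#'
#' @param E environmental data frame containing the truth's `env_vars`.
#' @param truth a `synthetic_truth`.
#' @param seed optional integer seed.
#' @return list with `M` (realized community matrix), `P_true` (niche
#'   probabilities before the mass-effect step), and `truth`.
#' @export
generate_metacommunity <- function(E, truth, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            all(truth$env_vars %in% names(E)))
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(E[, truth$env_vars, drop = FALSE])
  eta <- sweep(X %*% t(truth$slopes), 2, truth$intercepts, "+")
  P <- stats::plogis(eta)
  dimnames(P) <- list(rownames(E), names(truth$intercepts))
  m0 <- matrix(as.integer(stats::runif(length(P)) < P), nrow(P), ncol(P),
               dimnames = dimnames(P))
  m <- truth$mass_effect
  if (m > 0) {
    ord <- order(rowSums(m0), decreasing = TRUE)
    for (idx in seq_along(ord)[-1L]) {
      s <- ord[idx]
      donor <- ord[idx - 1L]
      candidates <- which(m0[s, ] == 0L & m0[donor, ] == 1L)
      if (length(candidates)) {
        flip <- candidates[stats::runif(length(candidates)) < m]
        m0[s, flip] <- 1L
      }
    }
  }
  fill <- sum(m0)
  if (fill == 0L || fill == length(m0)) {
    stop(sprintf("degenerate synthetic matrix (fill %d of %d cells); adjust intercepts/slopes",
                 fill, length(m0)))
  }
  list(M = as_community_matrix(m0), P_true = P, truth = truth)
}

#' Assign species to groups for partitioned co-occurrence statistics
#'
#' The random scheme labels species uniformly at random (an exchangeable
#' grouping); the niche-similarity scheme clusters species by their niche
#' coefficients (k-means on intercept + slopes) so that species sharing a
#' label respond similarly to the environment — the synthetic analogue of
#' growth-form guilds or genera.
#'
#' @param truth a `synthetic_truth`.
#' @param scheme `"random"` or `"niche-similarity"`.
#' @param n_groups number of labels.
#' @param seed optional integer seed.
#' @return named character vector of labels (`g1`, `g2`, ...).
#' @export
make_group_map <- function(truth, scheme = c("random", "niche-similarity"),
                           n_groups = 3, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  sp <- names(truth$intercepts)
  if (scheme == "random") {
    g <- paste0("g", sample.int(n_groups, length(sp), replace = TRUE))
  } else {
    feats <- cbind(truth$intercepts, truth$slopes)
    km <- stats::kmeans(feats, centers = n_groups, nstart = 10)
    g <- paste0("g", km$cluster)
  }
  names(g) <- sp
  g
}
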