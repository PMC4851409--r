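#' Per-replicate co-occurrence statistic function
#'
#' Builds the statistic evaluated on every ensemble replicate: C-score and
#' NODF, plus (when a group map is given) the group-partitioned checkerboard
#' unit sums, named `cu.<pair>`.
#'
#' @param G optional named character vector of species group labels.
#' @param denominator C-score convention, see [c_score()].
#' @return function mapping a community matrix to a named numeric vector.
#' @export
replicate_stat <- function(G = NULL, denominator = "ordered_pairs") {
  force(G); force(denominator)
  function(m) {
    out <- c(cscore = c_score(m, denominator), nodf = nodf(m)$nodf)
    if (!is.null(G)) {
      cu <- cu_by_groups(m, G)
      out <- c(out, stats::setNames(cu$cu, paste0("cu.", cu$pair)))
    }
    out
  }
}

#' Generate co-occurrence statistics for a set of null-model ensembles
#'
#' Runs any subset of the six null models — NullModFE, NullModFF (standard),
#' LogitPF, LogitPP, RandForPF, RandForPP (environmentally constrained) —
#' streaming every replicate matrix through [replicate_stat()], so matrices
#' are never stored.
#'
#' @param M real community matrix.
#' @param models character vector of model names to run.
#' @param n_replicates replicates per model.
#' @param P_logit,P_randfor pseudo-probability matrices (needed for the
#'   corresponding environmentally constrained models); see
#'   [build_prob_matrix()].
#' @param G optional species group map for partitioned checkerboard sums.
#' @param denominator C-score convention.
#' @param ... passed to [nullmod_ff()] (chain thinning/burn-in).
#' @return data frame with a `model` column, a `replicate` index, and one
#'   column per statistic.
#' @export
run_null_ensembles <- function(M, models = c("NullModFE", "NullModFF"),
                               n_replicates = 1000,
                               P_logit = NULL, P_randfor = NULL, G = NULL,
                               denominator = "ordered_pairs", ...) {
  known <- c("NullModFE", "NullModFF", "LogitPF", "LogitPP",
             "RandForPF", "RandForPP")
  stopifnot(all(models %in% known))
  stat <- replicate_stat(G, denominator)
  pieces <- lapply(models, function(mod) {
    vals <- switch(mod,
      NullModFE = ,
      NullModFF = standard_ensemble(M, mod, n_replicates, fun = stat, ...),
      LogitPF   = pseudo_ensemble(need_P(P_logit, mod), "PF", n_replicates,
                                  fun = stat, M_real = M),
      LogitPP   = pseudo_ensemble(need_P(P_logit, mod), "PP", n_replicates,
                                  fun = stat),
      RandForPF = pseudo_ensemble(need_P(P_randfor, mod), "PF", n_replicates,
                                  fun = stat, M_real = M),
      RandForPP = pseudo_ensemble(need_P(P_randfor, mod), "PP", n_replicates,
                                  fun = stat))
    cbind(model = mod, replicate = seq_len(nrow(vals)), vals)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

need_P <- function(P, model) {
  if (is.null(P)) stop("model ", model, " needs a pseudo-probability matrix")
  P
}

#' Summarize an ensemble statistic against its observed value
#'
#' Reports the 2.5/50/97.5 percent quantiles of the replicate values, mean
#' and standard error, the observed value, its position relative to the
#' central 95 percent interval (`below` / `within` / `above`), and a
#' two-sided permutation-style p-value.
#'
#' @param values numeric replicate values.
#' @param observed observed (real-matrix) value of the same statistic.
#' @return one-row data frame.
#' @export
ensemble_summary <- function(values, observed) {
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), names = FALSE)
  position <- if (observed < q[1]) "below" else if (observed > q[3]) "above" else "within"
  n <- length(values)
  p_two <- 2 * min(sum(values <= observed) + 1, sum(values >= observed) + 1) / (n + 1)
  data.frame(q025 = q[1], median = q[2], q975 = q[3],
             mean = mean(values), sem = stats::sd(values) / sqrt(n),
             observed = observed, position = position,
             p_value = min(1, p_two))
}

#' Compare the observed C-score with null-model ensembles
#'
#' The central comparison: where does the real matrix's segregation level sit
#' relative to each null model's C-score distribution? `position = "below"`
#' means the real communities are more aggregated than the model predicts
#' (the model over-estimates segregation), `"above"` means more segregated.
#'
#' @param ensembles data frame from [run_null_ensembles()].
#' @param M real community matrix.
#' @param denominator C-score convention (must match the ensembles).
#' @return data frame, one row per model, from [ensemble_summary()].
#' @export
run_cscore_comparison <- function(ensembles, M,
                                  denominator = "ordered_pairs") {
  observed <- c_score(M, denominator)
  out <- do.call(rbind, lapply(split(ensembles, ensembles$model), function(d) {
    cbind(model = d$model[1], ensemble_summary(d$cscore, observed))
  }))
  rownames(out) <- NULL
  out
}

#' Group-partitioned F-index tables
#'
#' For every model and group pair, the mean and standard error (over
#' replicates) of F = CU_model / CU_real: F > 1 flags over-estimation of
#' segregation between those groups, F < 1 under-estimation. Pairs with
#' CU_real == 0 are undefined (`NA`).
#'
#' @param ensembles data frame from [run_null_ensembles()] run with a group
#'   map `G`.
#' @param M real community matrix.
#' @param G the same group map used for the ensembles.
#' @return data frame with columns `model`, `pair`, `f_mean`, `f_sem`,
#'   `direction` (`over` / `under` / `undefined`).
#' @export
run_f_tables <- function(ensembles, M, G) {
  cu_real <- cu_by_groups(M, G)
  cu_cols <- grep("^cu\\.", names(ensembles), value = TRUE)
  if (length(cu_cols) == 0L) stop("ensembles carry no cu.<pair> columns; rerun with a group map")
  pairs <- sub("^cu\\.", "", cu_cols)
  if (!setequal(pairs, cu_real$pair)) stop("group-pair keys of ensembles and real matrix differ")
  out <- do.call(rbind, lapply(split(ensembles, ensembles$model), function(d) {
    do.call(rbind, lapply(seq_along(cu_cols), function(i) {
      real <- cu_real$cu[match(pairs[i], cu_real$pair)]
      if (real > 0) {
        f <- d[[cu_cols[i]]] / real
        data.frame(model = d$model[1], pair = pairs[i], f_mean = mean(f),
                   f_sem = stats::sd(f) / sqrt(length(f)),
                   direction = if (mean(f) > 1) "over" else "under")
      } else {
        data.frame(model = d$model[1], pair = pairs[i], f_mean = NA_real_,
                   f_sem = NA_real_, direction = "undefined")
      }
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Regression of C-score on NODF across pooled pseudo-communities
#'
#' Ordinary least squares of the replicate C-scores on the replicate NODF
#' values over all models pooled; the fitted line predicts the C-score that
#' the real matrix's nestedness level implies, with a 95 percent prediction
#' interval, and flags whether the observed C-score falls inside it.
#'
#' @param ensembles data frame from [run_null_ensembles()] (two or more
#'   models recommended).
#' @param M real community matrix.
#' @param denominator C-score convention (must match the ensembles).
#' @return list with `fit` (the `lm`), `slope`, `r_squared`,
#'   `observed_nodf`, `observed_cscore`, `predicted_cscore`,
#'   `prediction_interval` (length-2), and `observed_inside` (logical).
#' @export
run_nodf_cscore_regression <- function(ensembles, M,
                                       denominator = "ordered_pairs") {
  if (stats::sd(ensembles$nodf) == 0) stop("degenerate: constant NODF across replicates")
  fit <- stats::lm(cscore ~ nodf, data = ensembles)
  obs_nodf <- nodf(M)$nodf
  obs_c <- c_score(M, denominator)
  pred <- stats::predict(fit, newdata = data.frame(nodf = obs_nodf),
                         interval = "prediction", level = 0.95)
  list(fit = fit,
       slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       observed_nodf = obs_nodf,
       observed_cscore = obs_c,
       predicted_cscore = unname(pred[1, "fit"]),
       prediction_interval = unname(pred[1, c("lwr", "upr")]),
       observed_inside = obs_c >= pred[1, "lwr"] && obs_c <= pred[1, "upr"])
}

#' Run one synthetic-world calibration experiment
#'
#' Generates a metacommunity with known niche structure (and optional mass
#' effect), applies the full analysis pipeline — rare-species filter, niche
#' modeling, environmentally constrained ensembles — and reports where the
#' realized matrix's C-score falls within each ensemble. With a pure
#' species-sorting world (mass effect 0) a well-calibrated proportional
#' ensemble should cover the observed C-score; with a strong mass effect the
#' observed C-score should drop below the environmentally constrained
#' ensembles, which cannot see the aggregation mechanism.
#'
#' @param seed integer seed controlling the world and all ensembles.
#' @param n_sites,n_species world dimensions.
#' @param mass_effect m in \[0, 1\], see [synthetic_truth()].
#' @param models environmentally constrained models to run.
#' @param n_replicates replicates per ensemble.
#' @param n_trees trees per random forest.
#' @param min_occurrences rare-species filter threshold.
#' @return list with `M` (filtered matrix), `comparison` (per-model
#'   [run_cscore_comparison()] rows), `ensembles` (replicate statistics),
#'   and the probability matrices used.
#' @export
run_world_calibration <- function(seed, n_sites = 60, n_species = 40,
                                  mass_effect = 0,
                                  models = c("LogitPF", "LogitPP",
                                             "RandForPF", "RandForPP"),
                                  n_replicates = 200, n_trees = 100,
                                  min_occurrences = 5) {
  E <- generate_environment(n_sites, n_gradients = 2, n_vars = 4, seed = seed)
  truth <- synthetic_truth(n_species, paste0("env_", 1:4),
                           mass_effect = mass_effect, seed = seed + 1)
  world <- generate_metacommunity(E, truth, seed = seed + 2)
  M <- suppressWarnings(filter_rare_species(world$M, min_occurrences))
  set.seed(seed + 3)
  P_logit <- if (any(grepl("^Logit", models))) {
    suppressWarnings(build_prob_matrix(M, E, "logit"))
  }
  P_randfor <- if (any(grepl("^RandFor", models))) {
    suppressWarnings(build_prob_matrix(M, E, "randfor", n_trees = n_trees))
  }
  ens <- run_null_ensembles(M, models, n_replicates,
                            P_logit = P_logit, P_randfor = P_randfor)
  list(M = M, comparison = run_cscore_comparison(ens, M), ensembles = ens,
       P_logit = P_logit, P_randfor = P_randfor, truth = truth, E = E)
}
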