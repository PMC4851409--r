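PROB_EPS <- 1e-6

# Fit a binomial glm and record whether it converged cleanly (no separation /
# non-convergence warning).
glm_clean <- function(formula, data) {
  ok <- TRUE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  list(fit = fit, ok = ok && fit$converged)
}

#' Stepwise-AIC variable selection for one species' logistic niche model
#'
#' Bidirectional stepwise search starting from the full additive logistic
#' model of presence/absence on all environmental variables, scored by AIC
#' (deviance + 2 * number of parameters). If the full model fails to
#' converge, a forward search from the intercept-only model is used instead;
#' persistent failure falls back to intercept-only with a warning. Of a pair
#' of strongly collinear predictors at most one survives selection in
#' practice, since the second costs 2 AIC points for almost no deviance.
#'
#' @param y binary presence vector over sites.
#' @param E environmental data frame (rows = sites, numeric columns).
#' @return character vector of selected variable names (possibly empty).
#' @export
stepwise_logistic_select <- function(y, E) {
  stopifnot(length(y) == nrow(E))
  y <- as.integer(y > 0)
  if (sum(y) == 0L || sum(y) == length(y)) stop("constant presence vector")
  dat <- cbind(.y = y, E)
  full_formula <- stats::as.formula(paste(".y ~", paste(names(E), collapse = " + ")))
  res <- glm_clean(full_formula, dat)
  sel <- NULL
  if (res$ok) {
    sel <- tryCatch(
      suppressWarnings(MASS::stepAIC(res$fit, direction = "both", trace = 0)),
      error = function(e) NULL)
  }
  if (is.null(sel)) {
    null_fit <- stats::glm(.y ~ 1, data = dat, family = stats::binomial())
    sel <- tryCatch(
      suppressWarnings(MASS::stepAIC(null_fit, direction = "forward", trace = 0,
                                     scope = list(lower = ~1, upper = full_formula))),
      error = function(e) NULL)
  }
  if (is.null(sel)) {
    warning("stepwise selection failed; intercept-only model used")
    return(character(0))
  }
  setdiff(all.vars(stats::formula(sel)), ".y")
}

# Ridge-penalized logistic fit used when an unpenalized leave-one-out fold
# separates; small fixed L2 penalty, intercept unpenalized.
ridge_logit_predict <- function(X_train, y_train, x_new, lambda = 1e-3) {
  X <- as.matrix(X_train)
  Xs <- scale(X)
  ctr <- attr(Xs, "scaled:center"); scl <- attr(Xs, "scaled:scale")
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  p <- ncol(Xs)
  beta <- rep(0, p + 1)
  for (it in 1:50) {                       # IRLS with L2 penalty on slopes
    eta <- beta[1] + Xs %*% beta[-1]
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y_train - mu) / w
    Xd <- cbind(1, Xs)
    A <- crossprod(Xd, Xd * as.numeric(w)) + diag(c(0, rep(lambda, p)))
    b <- crossprod(Xd, as.numeric(w * z))
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  xs <- (as.numeric(as.matrix(x_new)) - ctr) / scl
  as.numeric(stats::plogis(beta[1] + sum(xs * beta[-1])))
}

#' Leave-one-out logistic predictions with a fixed variable subset
#'
#' For each site s the logistic model with the given variables is refit on
#' all other sites and used to predict the probability of presence at s. The
#' variable subset is selected once on the full data
#' ([stepwise_logistic_select()]) and held fixed across folds; selection is
#' not repeated inside folds. Folds that separate or fail to converge are
#' refit with a small L2 (ridge) penalty. Predictions are clipped to
#' \[1e-6, 1 - 1e-6\].
#'
#' @param y binary presence vector.
#' @param E environmental data frame.
#' @param vars character vector of predictor names (empty = intercept-only,
#'   whose leave-one-out prediction is the fold prevalence).
#' @return numeric vector of leave-one-out presence probabilities.
#' @export
loo_predict_logistic <- function(y, E, vars) {
  stopifnot(length(y) == nrow(E))
  y <- as.integer(y > 0)
  if (sum(y) == 0L || sum(y) == length(y)) stop("constant presence vector")
  n <- length(y)
  if (length(vars) == 0L) {
    p <- (sum(y) - y) / (n - 1)            # fold prevalence, closed form
    return(pmin(pmax(p, PROB_EPS), 1 - PROB_EPS))
  }
  dat <- cbind(.y = y, E[, vars, drop = FALSE])
  fml <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + ")))
  preds <- numeric(n)
  for (s in seq_len(n)) {
    fold <- dat[-s, , drop = FALSE]
    res <- glm_clean(fml, fold)
    if (res$ok) {
      preds[s] <- stats::predict(res$fit, newdata = dat[s, , drop = FALSE],
                                 type = "response")
    } else {
      preds[s] <- ridge_logit_predict(fold[, vars, drop = FALSE], fold$.y,
                                      dat[s, vars, drop = FALSE])
    }
  }
  pmin(pmax(preds, PROB_EPS), 1 - PROB_EPS)
}

#' Leave-one-out random-forest vote fractions
#'
#' For each site s a classification forest is grown on all other sites (no
#' variable pre-selection) and the fraction of trees voting "presence" at s
#' is returned as the pseudo-probability. A degenerate single-class training
#' fold yields probability 0 or 1.
#'
#' @param y binary presence vector.
#' @param E environmental data frame.
#' @param n_trees trees per forest (default 500).
#' @return numeric vector of vote fractions in \[0, 1\].
#' @export
loo_predict_rf <- function(y, E, n_trees = 500) {
  stopifnot(length(y) == nrow(E))
  y <- factor(as.integer(y > 0), levels = c(0L, 1L))
  X <- as.matrix(E)
  n <- length(y)
  preds <- numeric(n)
  for (s in seq_len(n)) {
    y_tr <- droplevels(y[-s])
    if (nlevels(y_tr) < 2L) {
      preds[s] <- as.numeric(as.character(y_tr[1L]))
      next
    }
    rf <- randomForest::randomForest(X[-s, , drop = FALSE], y[-s],
                                     ntree = n_trees)
    preds[s] <- stats::predict(rf, X[s, , drop = FALSE], type = "prob")[, "1"]
  }
  preds
}

#' Build a pseudo-probability matrix from per-species niche models
#'
#' Stacks per-species leave-one-out presence predictions into a matrix of the
#' same dimensions as the community matrix: entry (s, k) is the predicted
#' probability that species k is present at site s, estimated without using
#' the observation at s. `method = "logit"` uses stepwise-selected logistic
#' regression; `method = "randfor"` uses random-forest vote fractions. A
#' species whose model fails entirely falls back to its intercept-only
#' (prevalence) column with a warning.
#'
#' @param M community matrix.
#' @param E aligned environmental data frame.
#' @param method `"logit"` or `"randfor"`.
#' @param n_trees trees per forest (`"randfor"` only, default 500).
#' @return numeric matrix in \[0, 1\] with `M`'s dimnames; attributes
#'   `method` and (for logit) `selected_vars`, a per-species list.
#' @export
build_prob_matrix <- function(M, E, method = c("logit", "randfor"),
                              n_trees = 500) {
  method <- match.arg(method)
  m <- unclass(M)
  stopifnot(nrow(m) == nrow(E))
  P <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  sel_list <- vector("list", ncol(m))
  names(sel_list) <- colnames(m)
  for (k in seq_len(ncol(m))) {
    y <- m[, k]
    P[, k] <- tryCatch({
      if (method == "logit") {
        vars <- stepwise_logistic_select(y, E)
        sel_list[[k]] <- vars
        loo_predict_logistic(y, E, vars)
      } else {
        loo_predict_rf(y, E, n_trees = n_trees)
      }
    }, error = function(e) {
      warning(sprintf("species %s: %s; prevalence fallback used",
                      colnames(m)[k], conditionMessage(e)))
      sel_list[[k]] <- character(0)
      rep(mean(y), nrow(m))
    })
  }
  attr(P, "method") <- method
  if (method == "logit") attr(P, "selected_vars") <- sel_list
  P
}
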