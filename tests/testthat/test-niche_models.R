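make_env <- function(n, k = 4, seed = 1) {
  set.seed(seed)
  E <- as.data.frame(matrix(rnorm(n * k), n, k))
  names(E) <- paste0("x", seq_len(k))
  rownames(E) <- paste0("s", seq_len(n))
  E
}

test_that("stepwise selection keeps a true predictor and drops pure noise", {
  hits_x1 <- 0L; noise_dropped <- 0L
  for (r in 1:10) {
    E <- make_env(200, 4, seed = 200 + r)
    y <- rbinom(200, 1, plogis(2 * E$x1))
    vars <- stepwise_logistic_select(y, E)
    hits_x1 <- hits_x1 + ("x1" %in% vars)
    noise_dropped <- noise_dropped + !("x2" %in% vars)
  }
  expect_gte(hits_x1, 9L)
  expect_gte(noise_dropped, 7L)
})

test_that("stepwise selection mostly returns intercept-only for pure noise", {
  empty <- 0L
  for (r in 1:10) {
    E <- make_env(150, 3, seed = 300 + r)
    y <- rbinom(150, 1, 0.4)
    empty <- empty + (length(stepwise_logistic_select(y, E)) == 0L)
  }
  expect_gte(empty, 6L)
})

test_that("a near-perfectly collinear predictor pair almost never both survive", {
  at_most_one <- 0L
  for (r in 1:10) {
    set.seed(400 + r)
    n <- 200
    x1 <- rnorm(n)
    x2 <- x1 + rnorm(n, sd = sd(x1) * sqrt(1 / 0.995 - 1))  # R^2 ~ 0.995
    E <- data.frame(x1 = x1, x2 = x2, x3 = rnorm(n))
    y <- rbinom(n, 1, plogis(1.5 * x1))
    vars <- stepwise_logistic_select(y, E)
    at_most_one <- at_most_one + (sum(c("x1", "x2") %in% vars) <= 1L)
  }
  # the redundant twin costs 2 AIC points for almost no deviance, so the
  # pair is collapsed in the large majority of runs (not literally always:
  # the twin's noise component can occasionally chase residual deviance)
  expect_gte(at_most_one, 8L)
})

test_that("intercept-only leave-one-out predictions are the fold prevalence", {
  E <- make_env(20, 2, seed = 500)
  y <- c(rep(1, 6), rep(0, 14))
  p <- loo_predict_logistic(y, E, character(0))
  expect_equal(p[1], (6 - 1) / 19)    # presence site
  expect_equal(p[20], 6 / 19)         # absence site
  expect_error(loo_predict_logistic(rep(1, 20), E, character(0)), "constant")
})

test_that("leave-one-out logistic recovers a known sigmoid niche", {
  set.seed(510)
  E <- make_env(200, 3, seed = 510)
  p_true <- plogis(-0.5 + 2 * E$x1)
  y <- rbinom(200, 1, p_true)
  p_hat <- loo_predict_logistic(y, E, "x1")
  expect_lt(mean(abs(p_hat - p_true)), 0.1)
  expect_true(all(p_hat >= 1e-6 & p_hat <= 1 - 1e-6))
})

test_that("separating folds fall back to a penalized fit without failing", {
  set.seed(520)
  n <- 30
  E <- make_env(n, 1, seed = 520)
  y <- as.integer(E$x1 > 0)            # perfectly separable
  p <- loo_predict_logistic(y, E, "x1")
  expect_true(all(is.finite(p)))
  expect_gt(mean(p[y == 1]), mean(p[y == 0]))
})

test_that("random-forest vote fractions track a sharp threshold niche", {
  set.seed(530)
  E <- make_env(120, 3, seed = 530)
  y <- as.integer(E$x1 > 0.2)
  p <- loo_predict_rf(y, E, n_trees = 100)
  expect_true(all(p >= 0 & p <= 1))
  away <- abs(E$x1 - 0.2) > 0.5
  expect_gt(mean(p[y == 1 & away]), 0.8)
  expect_lt(mean(p[y == 0 & away]), 0.2)
})

test_that("random-forest votes on pure noise hover near prevalence", {
  set.seed(540)
  E <- make_env(150, 3, seed = 540)
  y <- rbinom(150, 1, 0.5)
  p <- loo_predict_rf(y, E, n_trees = 100)
  expect_lt(abs(mean(p) - 0.5), 0.05)
})

test_that("the pseudo-probability matrix stacks species predictions", {
  set.seed(550)
  E <- make_env(60, 3, seed = 550)
  n_sp <- 8
  P_true <- sapply(seq_len(n_sp), function(k) plogis(rnorm(1) + rnorm(1) * E$x1))
  m <- matrix(as.integer(runif(60 * n_sp) < P_true), 60, n_sp,
              dimnames = list(rownames(E), paste0("sp", seq_len(n_sp))))
  keep <- colSums(m) >= 5 & colSums(m) <= 55
  m <- m[, keep, drop = FALSE]
  M <- as_community_matrix(m)
  P <- build_prob_matrix(M, E, "logit")
  expect_equal(dim(P), dim(M))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(attr(P, "method"), "logit")
  expect_equal(names(attr(P, "selected_vars")), colnames(M))
  # LOO probabilities beat the prevalence-only baseline on Brier score
  prev <- matrix(colMeans(m), nrow(m), ncol(m), byrow = TRUE)
  expect_lt(mean((P - m)^2), mean((prev - m)^2))
})

test_that("logit predictions are exactly reproducible; forests under a seed", {
  set.seed(560)
  E <- make_env(40, 2, seed = 560)
  y <- rbinom(40, 1, plogis(E$x1))
  if (sum(y) < 5 || sum(y) > 35) y[1:5] <- c(1L, 1L, 1L, 0L, 0L)
  expect_identical(loo_predict_logistic(y, E, "x1"),
                   loo_predict_logistic(y, E, "x1"))
  set.seed(1); a <- loo_predict_rf(y, E, n_trees = 50)
  set.seed(1); b <- loo_predict_rf(y, E, n_trees = 50)
  expect_identical(a, b)
})

test_that("flat-niche predictions converge to prevalence for both methods", {
  set.seed(570)
  n <- 500
  E <- make_env(n, 2, seed = 570)
  prev <- 0.3
  y <- rbinom(n, 1, prev)
  p_logit <- loo_predict_logistic(y, E, stepwise_logistic_select(y, E))
  expect_lt(abs(mean(p_logit) - prev), 0.05)
  p_rf <- loo_predict_rf(y[1:150], E[1:150, ], n_trees = 60)
  expect_lt(abs(mean(p_rf) - prev), 0.08)
})
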