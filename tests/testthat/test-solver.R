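test_that("logistic loss matches closed-form values and limits", {
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  y <- c(1, -1)
  w <- c(0.5, 0.5)
  expect_equal(logistic_loss(c(0, 0), 0, X, y, w), log(2))
  # margins (+1, -1): 0.5 * (log(1+e^-1) + log(1+e^1))
  expect_equal(logistic_loss(c(1, 1), 0, X, y, w),
               0.5 * (log(1 + exp(-1)) + log(1 + exp(1))),
               tolerance = 1e-12)
  expect_equal(logistic_loss(c(1, 1), 0, X, y, w), 0.813262,
               tolerance = 1e-6)
  # a huge correct margin drives the loss to zero without overflow
  expect_equal(logistic_loss(c(5000, 0), 0, matrix(c(1, 0), 1), 1, 1), 0)
  expect_true(is.finite(logistic_loss(c(-5000, 0), 0, matrix(c(1, 0), 1), 1, 1)))
})

test_that("objective adds L1 and weighted group-norm penalties", {
  X <- matrix(0, 2, 2)
  y <- c(1, -1); w <- c(0.5, 0.5)
  gs <- single_group_structure(2, w = sqrt(2))
  L <- logistic_loss(c(3, 4), 0, X, y, w)
  expect_equal(sgl_objective(c(3, 4), 0, X, y, w, 1, 1, gs),
               L + 7 + 5 * sqrt(2))
  expect_equal(sgl_objective(c(3, 4), 0, X, y, w, 0, 0, gs), L)
})

test_that("the closed-form prox matches its definition on hand cases", {
  gs1 <- single_group_structure(1, w = 1)
  expect_equal(prox_sgl(3, 1, 1, gs1), 1)           # soft to 2, scale 1/2
  expect_equal(prox_sgl(3, 0, 0, gs1), 3)           # identity with no penalty
  gs2 <- single_group_structure(2, w = sqrt(2))
  expect_equal(prox_sgl(c(0.5, -0.5), 0.6, 1, gs2), c(0, 0))
  # non-expansiveness on random pairs
  set.seed(1)
  for (i in 1:25) {
    d <- sample(1:4, 1)
    gs <- single_group_structure(d, w = runif(1, 0.5, 2))
    u <- runif(d, -3, 3); v <- runif(d, -3, 3)
    l1 <- runif(1, 0, 1); l2 <- runif(1, 0, 1)
    expect_lte(sqrt(sum((prox_sgl(u, l1, l2, gs) - prox_sgl(v, l1, l2, gs))^2)),
               sqrt(sum((u - v)^2)) + 1e-12)
  }
})

test_that("lambda_max matches a bisection oracle on the fitted path", {
  set.seed(2)
  n <- 8; p <- 6
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  y <- rep(c(1, -1), each = 4)
  w <- rep(1 / n, n)
  gs <- single_group_structure(p, w = sqrt(p))
  l1m <- lambda_max(X, y, w, gs)$lambda1_max
  all_zero_at <- function(l1) {
    opts <- solver_options(lambda_scale = "absolute", group_penalty = FALSE,
                           tol = 1e-12, max_iter = 5000)
    fit <- fit_sgl_logistic(X, y, w, lambda1 = l1, lambda2 = 0,
                            groups = gs, opts = opts)
    all(fit$beta == 0)
  }
  lo <- 0; hi <- 1  # |x| <= 1 and sum(w) = 1 bound every gradient entry by 1
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (all_zero_at(mid)) hi <- mid else lo <- mid
  }
  expect_equal(l1m, hi, tolerance = 1e-3)
})

test_that("lambda fraction 1 collapses to the null model with log-odds intercept", {
  ds <- fixture_dataset(seed = 2)
  cm <- ds$cm
  fit <- fit_sgl_logistic(ds$mf, cm$label, cm$weight, lambda1 = 1, lambda2 = 0.3)
  expect_true(all(fit$beta == 0))
  w <- cm$weight / sum(cm$weight)
  expect_equal(fit$intercept,
               log(sum(w[cm$label == 1]) / sum(w[cm$label == -1])),
               tolerance = 1e-9)
  # group-only penalty at fraction 1 also zeroes every group
  fit2 <- fit_sgl_logistic(ds$mf, cm$label, cm$weight, lambda1 = 0, lambda2 = 1)
  expect_equal(n_selected_groups(fit2), 0L)
})

test_that("fitted models satisfy subgradient optimality and select the planted signal", {
  ds <- fixture_dataset(seed = 4)
  cm <- ds$cm
  fit <- fit_sgl_logistic(ds$mf, cm$label, cm$weight,
                          lambda1 = 0.2, lambda2 = 0.2)
  expect_true(fit$converged)
  # planted bit-columns (pattern identical to the labels) are selected
  planted_ids <- paste0("g3|", ds$fixture$truth$position, "|A")
  expect_true(any(abs(fit$beta[names(fit$beta) %in% planted_ids]) > 0))
  expect_lt(kkt_residual(fit, ds$mf, cm$label, cm$weight), 1e-4)
})

test_that("objective history is non-increasing and nonzeros shrink along the path", {
  ds <- fixture_dataset(seed = 6)
  cm <- ds$cm
  nnz <- integer(0)
  for (l1 in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    fit <- fit_sgl_logistic(ds$mf, cm$label, cm$weight,
                            lambda1 = l1, lambda2 = 0.2)
    expect_true(all(diff(fit$obj_history) <= 1e-12))
    nnz <- c(nnz, sum(fit$beta != 0))
  }
  expect_true(all(diff(nnz) <= 0))
})

test_that("without group penalty the solution matches an independent L1 minimizer", {
  set.seed(7)
  n <- 10; p <- 20
  X <- matrix(rbinom(n * p, 1, 0.4), n, p)
  y <- rep(c(1, -1), each = 5)
  w <- rep(1 / n, n)
  gs <- single_group_structure(p, w = sqrt(p))
  l1 <- 0.3 * lambda_max(X, y, w, gs)$lambda1_max
  fit <- fit_sgl_logistic(X, y, w, lambda1 = l1, lambda2 = 0, groups = gs,
                          opts = solver_options(tol = 1e-13, max_iter = 20000,
                                                lambda_scale = "absolute",
                                                group_penalty = FALSE))
  oracle <- l1_logistic_oracle(X, y, w, l1)
  obj_fit <- sgl_objective(fit$beta, fit$intercept, X, y, w, l1, 0, gs)
  expect_equal(obj_fit, oracle$value, tolerance = 1e-6)
})

test_that("group weights override the square-root default", {
  ds <- fixture_dataset(seed = 9)
  gw <- setNames(rep(1, 5), sprintf("g%d", 1:5))
  gs <- group_structure(ds$mf, weights = gw)
  expect_equal(gs$weight, rep(1, 5))
  gs_def <- group_structure(ds$mf)
  expect_equal(gs_def$weight,
               sqrt(as.numeric(table(ds$mf$features$group)[gs_def$name])))
  expect_error(group_structure(ds$mf, weights = setNames(-1, "g1")), "positive")
})
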