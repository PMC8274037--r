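test_that("the LP solution matches a dense grid oracle on 1-feature problems", {
  set.seed(20)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- runif(n); y <- runif(n)
    lambda <- runif(1, 0.01, 2)
    epsilon <- sample(c(0, 0.05, 0.1), 1)
    fit <- fit_svr_lasso(matrix(x, ncol = 1), y, lambda, epsilon)
    oracle <- grid_oracle_1d(x, y, lambda, epsilon)
    # the LP is exact, the grid is the approximation
    expect_lte(fit$objective, oracle + 1e-9)
    expect_gte(fit$objective, oracle - 1e-4)
  }
})

test_that("the LP agrees with an independent simplex implementation", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:12, 1); p <- sample(1:5, 1)
    X <- matrix(runif(n * p), n, p)
    y <- runif(n) * sample(c(1, 20), 1)
    lambda <- runif(1, 0.005, 2)
    epsilon <- sample(c(0, 0.05, 0.1), 1)
    fit <- fit_svr_lasso(X, y, lambda, epsilon)
    a <- c(rep(lambda, 2 * p), 0, 0, rep(1, n))
    A <- rbind(cbind(-X, X, -1, 1, -diag(n)), cbind(X, -X, 1, -1, -diag(n)))
    b <- c(epsilon - y, epsilon + y)
    neg <- b < 0
    ref <- boot::simplex(a = a, A1 = A[!neg, , drop = FALSE], b1 = b[!neg],
                         A2 = -A[neg, , drop = FALSE], b2 = -b[neg])
    expect_equal(fit$objective, unname(ref$value), tolerance = 1e-6)
  }
})

test_that("an overwhelming penalty zeroes the weights and fits the median", {
  set.seed(22)
  X <- matrix(runif(40), 20, 2)
  y <- rnorm(20, 3, 1)
  fit <- fit_svr_lasso(X, y, lambda = 1e6, epsilon = 0)
  expect_equal(unname(fit$weights), c(0, 0))
  # any median of y minimizes the absolute loss
  med_obj <- sum(abs(y - median(y)))
  expect_equal(sum(abs(y - fit$intercept)), med_obj, tolerance = 1e-8)
})

test_that("the interpolation limit fits square full-rank data exactly", {
  set.seed(23)
  X <- matrix(runif(16), 4, 4) + diag(4)
  y <- runif(4)
  fit <- fit_svr_lasso(X, y, lambda = 1e-9, epsilon = 0)
  resid <- y - drop(X %*% fit$weights) - fit$intercept
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("leave-one-out tuning equals exhaustive enumeration with an independent fitter", {
  boot_fit <- function(X, y, lambda, epsilon) {
    n <- nrow(X); p <- ncol(X)
    a <- c(rep(lambda, 2 * p), 0, 0, rep(1, n))
    A <- rbind(cbind(-X, X, -1, 1, -diag(n)), cbind(X, -X, 1, -1, -diag(n)))
    b <- c(epsilon - y, epsilon + y)
    neg <- b < 0
    s <- boot::simplex(a = a, A1 = A[!neg, , drop = FALSE], b1 = b[!neg],
                       A2 = -A[neg, , drop = FALSE], b2 = -b[neg])
    x <- s$soln
    w <- x[1:p] - x[(p + 1):(2 * p)]
    # same canonical tie-break as the package solver: degenerate optima
    # share the objective but not the vertex
    list(w = w, b = canonical_intercept(y - drop(X %*% w), epsilon))
  }
  set.seed(24)
  for (rep_i in 1:3) {
    n <- 12; p <- 3
    X <- matrix(runif(n * p), n, p)
    y <- drop(X %*% runif(p, -1, 1)) + rnorm(n, 0, 0.2)
    grid <- 10^seq(-2, 1, length.out = 5)
    got <- tune_lambda_loo(X, y, grid, epsilon = 0.05)
    mse <- sapply(sort(grid, decreasing = TRUE), function(lam) {
      mean(sapply(seq_len(n), function(i) {
        f <- boot_fit(X[-i, , drop = FALSE], y[-i], lam, 0.05)
        (y[i] - sum(X[i, ] * f$w) - f$b)^2
      }))
    })
    lam_star <- sort(grid, decreasing = TRUE)[which(mse <= min(mse) + 1e-12)[1]]
    expect_equal(got$lambda, lam_star)
    expect_equal(unname(got$cv_mse), mse, tolerance = 1e-6)
  }
  one <- tune_lambda_loo(matrix(runif(12), 6, 2), runif(6), 0.3)
  expect_equal(one$lambda, 0.3)
  expect_error(tune_lambda_loo(matrix(runif(12), 6, 2), runif(6), numeric(0)),
               "empty")
})

test_that("exact cross-validation ties resolve to the sparser penalty", {
  set.seed(25)
  X <- matrix(runif(20 * 3), 20, 3)
  y <- rnorm(20)
  # both penalties are far beyond the all-zero threshold: identical models,
  # identical LOO errors, so the tie must go to the larger value
  got <- tune_lambda_loo(X, y, c(50, 100), epsilon = 0.1)
  expect_equal(got$lambda, 100)
  expect_equal(unname(diff(got$cv_mse)), 0)
})

test_that("pure-noise outcomes favor heavy regularization in expectation", {
  set.seed(25)
  picks <- replicate(15, {
    X <- matrix(runif(20 * 3), 20, 3)
    y <- rnorm(20)
    tune_lambda_loo(X, y, c(0.01, 0.1, 1, 10, 100), epsilon = 0.1)$lambda
  })
  # the modal choice is the most regularizing grid value
  expect_equal(as.numeric(names(which.max(table(picks)))), 100)
})

test_that("min-max scaling uses train statistics and does not clip", {
  sc <- minmax_scale(matrix(c(2, 4, 6), 3, 1,
                            dimnames = list(NULL, "f")),
                     matrix(8, 1, 1, dimnames = list(NULL, "f")))
  expect_equal(unname(sc$train[, 1]), c(0, 0.5, 1))
  expect_equal(unname(sc$apply_to[1, 1]), 1.5)
  # affine invariance
  tr <- matrix(runif(12), 6, 2); te <- matrix(runif(4), 2, 2)
  s1 <- minmax_scale(tr, te)
  s2 <- minmax_scale(tr * 3 - 1, te * 3 - 1)
  expect_equal(s1$train, s2$train, tolerance = 1e-12)
  expect_equal(s1$apply_to, s2$apply_to, tolerance = 1e-12)
  expect_warning(sc3 <- minmax_scale(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "constant")
  expect_equal(colnames(sc3$train), "b")
})

test_that("feature selection keeps significant and degenerate-certain weights", {
  set.seed(26)
  W <- cbind(zero = rep(0, 10),
             const = rep(0.4, 10),
             sig = rnorm(10, 1, 0.1),
             noise = rnorm(10, 0, 1))
  sel <- select_significant_features(W, alpha = 0.05)
  expect_true(all(c(2, 3) %in% sel))
  expect_false(1 %in% sel)
})

test_that("the stratified split reproduces the 63/28 design", {
  tab <- data.frame(sample_id = sprintf("x%02d", 1:91),
                    sex = c(rep("F", 46), rep("M", 45)),
                    stringsAsFactors = FALSE)
  sp <- split_train_test(tab, fraction = 0.7, stratify_by = "sex", seed = 9)
  expect_length(sp$train, 63)
  expect_length(sp$test, 28)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_train_test(tab, 0.7, "sex", seed = 9))
  expect_error(split_train_test(tab, fraction = 1.0), "empty test set")
})

test_that("prediction evaluation matches the textbook Pearson formula", {
  obs <- c(1, 2, 3, 4)
  expect_equal(evaluate_predictions(obs, obs)$r, 1)
  expect_equal(evaluate_predictions(obs, obs)$mse, 0)
  expect_equal(evaluate_predictions(-obs, obs)$r, -1)
  pred <- c(1.2, 1.9, 3.4, 3.6)
  ev <- evaluate_predictions(pred, obs)
  r_hand <- sum((pred - mean(pred)) * (obs - mean(obs))) /
    sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  expect_equal(ev$r, r_hand, tolerance = 1e-12)
  expect_equal(ev$mse, mean((pred - obs)^2))
  flat <- evaluate_predictions(rep(2, 4), obs)
  expect_true(is.na(flat$r))
  expect_equal(flat$p, 1)
})

test_that("the number of selected weights is non-increasing along the penalty path", {
  set.seed(27)
  n <- 30; p <- 8
  X <- matrix(runif(n * p), n, p)
  y <- drop(X %*% c(2, -1, 1, rep(0, p - 3))) + rnorm(n, 0, 0.3)
  y <- (y - min(y)) / diff(range(y))
  nnz <- sapply(sort(default_lambda_grid(n, 12)), function(l)
    length(fit_svr_lasso(X, y, l, 0.1)$selected))
  expect_true(all(diff(nnz) <= 0))
})

test_that("training on a noiseless linear outcome generalizes almost perfectly", {
  set.seed(28)
  n <- 60
  F <- matrix(runif(n * 5), n, 5,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:5)))
  y <- setNames(drop(F[, 1:3] %*% c(3, -2, 1.5)) + 50, rownames(F))
  tr <- rownames(F)[1:42]; te <- rownames(F)[43:60]
  m <- train_model(F, y, tr, te, "select",
                   lambda_grid = default_lambda_grid(42, 10))
  expect_gte(m$report$test$r, 0.99)
  expect_true(all(paste0("f", 1:3) %in% m$selected_features))
})

test_that("outcomes independent of the features are not significantly predicted", {
  set.seed(29)
  hits <- replicate(20, {
    n <- 40
    F <- matrix(runif(n * 4), n, 4,
                dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:4)))
    y <- setNames(rnorm(n), rownames(F))
    m <- train_model(F, y, rownames(F)[1:28], rownames(F)[29:40], "fixed",
                     lambda_grid = c(0.1, 1, 10))
    !is.na(m$report$test$p) && m$report$test$p < 0.05
  })
  expect_lte(mean(hits), 0.1)
})

test_that("training is reproducible and audits test-set isolation", {
  set.seed(30)
  n <- 40
  F <- matrix(runif(n * 4), n, 4,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:4)))
  y <- setNames(drop(F %*% c(1, -1, 0, 0)) + rnorm(n, 0, 0.2), rownames(F))
  tr <- rownames(F)[1:28]; te <- rownames(F)[29:40]
  m1 <- train_model(F, y, tr, te, "select", lambda_grid = c(0.1, 1, 10))
  m2 <- train_model(F, y, tr, te, "select", lambda_grid = c(0.1, 1, 10))
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  expect_length(intersect(m1$audit$scaling, te), 0)
  expect_length(intersect(m1$audit$tuning, te), 0)
  expect_length(intersect(m1$audit$selection, te), 0)
  expect_error(train_model(F, y, tr, c(te, tr[1]), "fixed"), "overlap")
})
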