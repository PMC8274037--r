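#' @name sparse_svr
#' @title L1-regularized support-vector regression
#' @description
#' Linear epsilon-insensitive regression with an L1 penalty on the weights:
#' minimize `sum_i max(0, |y_i - w.x_i - b| - epsilon) + lambda * ||w||_1`.
#' The convex, piecewise-linear objective is solved exactly as a linear
#' program (positive/negative weight and intercept splits plus one slack per
#' sample, two-phase simplex); vertex solutions carry exact zeros in `w`,
#' which define the selected feature set.
NULL

#' Exact objective of the sparse SVR problem
#'
#' @param w Weight vector.
#' @param b Intercept.
#' @param X Samples x features matrix.
#' @param y Outcome vector.
#' @param lambda L1 penalty.
#' @param epsilon Insensitive-tube half-width.
#' @return Scalar objective value.
#' @export
svr_objective <- function(w, b, X, y, lambda, epsilon) {
  r <- y - drop(X %*% w) - b
  sum(pmax(0, abs(r) - epsilon)) + lambda * sum(abs(w))
}

#' Fit sparse SVR at a fixed penalty
#'
#' Solves the exact linear program: variables are the positive/negative
#' parts of `w` and `b` plus one loss slack per sample, with two residual
#' constraints per sample, minimized by the two-phase simplex of
#' [boot::simplex()].
#'
#' @param X Samples x features matrix (features pre-scaled to \[0, 1\]).
#' @param y Outcome vector, no missing values.
#' @param lambda L1 penalty (must be > 0 for a bounded program; a weight that
#'   is free of charge is unidentifiable under the insensitive loss).
#' @param epsilon Tube half-width (default 0.1, on the scaled-outcome
#'   convention used by [train_model()]).
#' @return List of class `svr_fit`: `weights` (exact zeros mark unselected
#'   features), `intercept`, `lambda`, `epsilon`, `selected` (indices of
#'   nonzero weights), `objective`.
#' @export
fit_svr_lasso <- function(X, y, lambda, epsilon = 0.1) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in the SVR inputs")
  stopifnot(lambda >= 0)
  n <- nrow(X); p <- ncol(X)
  a <- c(rep(lambda, 2 * p), 0, 0, rep(1, n))
  A <- rbind(cbind(-X, X, -1, 1, -diag(n)),
             cbind(X, -X, 1, -1, -diag(n)))
  b <- c(epsilon - y, epsilon + y)
  # the simplex needs non-negative right-hand sides: rows with negative RHS
  # are sign-flipped into >= constraints; each sample's loss-slack column
  # then has a unit coefficient in its flipped row and pivoting it in keeps
  # the RHS non-negative, giving a phase-1-free crash basis
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  xi_col <- rep(2 * p + 2 + c(seq_len(n), seq_len(n)), length.out = 2 * n)
  crash <- ifelse(neg, xi_col - 1L, -1L) # 0-based for the C++ routine
  sol <- .simplex_lp(a, A, b, as.integer(neg), as.integer(crash))
  if (sol$status != 0) { # fall back to the reference simplex
    sol_b <- boot::simplex(a = a,
                           A1 = A[!neg, , drop = FALSE], b1 = b[!neg],
                           A2 = if (any(neg)) A[neg, , drop = FALSE],
                           b2 = if (any(neg)) b[neg])
    if (sol_b$solved < 0) stop("LP solver failed")
    sol <- list(solution = sol_b$soln)
  }
  x <- sol$solution
  w <- x[seq_len(p)] - x[p + seq_len(p)]
  b <- canonical_intercept(y - drop(X %*% w), epsilon)
  structure(list(weights = unname(w), intercept = unname(b), lambda = lambda,
                 epsilon = epsilon, selected = which(w != 0),
                 objective = svr_objective(w, b, X, y, lambda, epsilon)),
            class = "svr_fit")
}

#' Canonical intercept of the insensitive-loss fit
#'
#' Given residuals-without-intercept `r`, the 1-D objective
#' `sum(max(0, |r - b| - epsilon))` is piecewise linear in `b` with a
#' (possibly non-unique) minimizing interval; its midpoint is returned so
#' solutions are deterministic across equivalent LP vertices.
#'
#' @param r Residuals `y - X w`.
#' @param epsilon Tube half-width.
#' @return Scalar intercept.
#' @export
canonical_intercept <- function(r, epsilon) {
  breaks <- sort(unique(c(r - epsilon, r + epsilon)))
  obj <- vapply(breaks, function(b) sum(pmax(abs(r - b) - epsilon, 0)),
                numeric(1))
  opt <- breaks[obj <= min(obj) + 1e-12]
  mean(range(opt))
}

#' Default penalty grid
#'
#' Logarithmically spaced values spanning `[1e-4, 1e2] * n`.
#'
#' @param n Training-set size.
#' @param length Grid length (default 30).
#' @return Increasing numeric vector.
#' @export
default_lambda_grid <- function(n, length = 30) {
  n * 10^seq(-4, 2, length.out = length)
}

#' Tune the penalty by leave-one-out cross-validation
#'
#' For each grid value, `n` leave-one-out fits; the penalty minimizing the
#' mean squared held-out error wins, ties going to the larger (sparser)
#' value.
#'
#' @param X Samples x features matrix.
#' @param y Outcome vector (`n >= 3`).
#' @param lambda_grid Candidate penalties.
#' @param epsilon Tube half-width.
#' @return List: `lambda` (winner), `cv_mse` (named by grid value),
#'   `fold_weights` (n x p weight matrix of the leave-one-out refits at the
#'   winning penalty).
#' @export
tune_lambda_loo <- function(X, y, lambda_grid, epsilon = 0.1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3)
  if (!length(lambda_grid)) stop("empty lambda grid")
  grid <- sort(lambda_grid, decreasing = TRUE)
  cv_mse <- stats::setNames(numeric(length(grid)), format(grid))
  folds <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    lam <- grid[gi]
    W <- matrix(0, n, ncol(X))
    errs <- numeric(n)
    for (i in seq_len(n)) {
      fit <- fit_svr_lasso(X[-i, , drop = FALSE], y[-i], lam, epsilon)
      W[i, ] <- fit$weights
      errs[i] <- (y[i] - drop(X[i, ] %*% fit$weights) - fit$intercept)^2
    }
    cv_mse[gi] <- mean(errs)
    folds[[gi]] <- W
  }
  best <- min(cv_mse)
  winner <- which(cv_mse <= best + 1e-12)[1] # grid is descending: first = largest
  list(lambda = grid[winner], cv_mse = cv_mse,
       fold_weights = folds[[winner]])
}

#' Min-max feature scaling with train-only statistics
#'
#' `(x - min_train) / (max_train - min_train)`; values outside the training
#' range are extrapolated, not clipped. Constant training features are
#' dropped with a warning.
#'
#' @param train Samples x features matrix (training set).
#' @param apply_to Optional matrix to transform with the training statistics.
#' @return List: `train` (scaled), `apply_to` (scaled or `NULL`), `min`,
#'   `max`, `kept` (names/indices of retained features).
#' @export
minmax_scale <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  keep <- maxs > mins
  if (!all(keep)) warning("dropping constant training features: ",
                          paste(colnames(train)[!keep], collapse = ", "))
  sc <- function(M) {
    M <- as.matrix(M)[, keep, drop = FALSE]
    sweep(sweep(M, 2, mins[keep]), 2, maxs[keep] - mins[keep], `/`)
  }
  list(train = sc(train),
       apply_to = if (is.null(apply_to)) NULL else sc(apply_to),
       min = mins[keep], max = maxs[keep],
       kept = which(keep))
}

#' Select features whose fold weights differ from zero
#'
#' Two-sided one-sample t-test of each feature's leave-one-out weights
#' against zero; features with `p < alpha` are kept, in input order. An
#' all-zero weight vector is excluded; a constant nonzero one is kept (the
#' degenerate-certain case).
#'
#' @param fold_weights Folds x features weight matrix.
#' @param alpha Significance level (default 0.05).
#' @return Integer indices of selected features.
#' @export
select_significant_features <- function(fold_weights, alpha = 0.05) {
  keep <- vapply(seq_len(ncol(fold_weights)), function(j) {
    wj <- fold_weights[, j]
    if (all(wj == 0)) return(FALSE)
    if (stats::sd(wj) == 0) return(TRUE)
    stats::t.test(wj)$p.value < alpha
  }, logical(1))
  which(keep)
}

#' Stratified train/test split
#'
#' Deterministic given the seed; `floor(fraction * n)` samples per stratum go
#' to training.
#'
#' @param table Sample table with `sample_id` and the stratification column.
#' @param fraction Training fraction (default 0.7).
#' @param stratify_by Stratification column (default `"sex"`).
#' @param seed Integer seed.
#' @return List with `train` and `test` sample-id vectors.
#' @export
split_train_test <- function(table, fraction = 0.7, stratify_by = "sex",
                             seed = 1) {
  strata <- split(table$sample_id, table[[stratify_by]])
  set.seed(seed)
  train <- unlist(lapply(strata, function(ids) {
    n_tr <- floor(fraction * length(ids))
    if (n_tr < 1) stop("stratum too small for the requested fraction")
    sample(ids, n_tr)
  }), use.names = FALSE)
  test <- setdiff(table$sample_id, train)
  if (!length(test)) stop("empty test set; lower the training fraction")
  list(train = sort(train), test = sort(test))
}

#' Train and evaluate one prediction model
#'
#' Executes the three training steps on the training samples only — penalty
#' tuning by leave-one-out MSE, feature selection from the significance of
#' leave-one-out weights (skipped for fixed-feature models), and a final fit
#' on all training samples with the selected features, whose penalty is
#' re-tuned on the reduced feature set — then evaluates on the hold-out set. Features and the outcome are min-max scaled with
#' training statistics; predictions and MSE are reported on the original
#' outcome scale.
#'
#' @param features Samples x features matrix with sample-id rownames.
#' @param outcome Named outcome vector (original scale).
#' @param train_ids,test_ids Disjoint sample-id sets.
#' @param selection_mode `"select"` or `"fixed"`.
#' @param lambda_grid Penalty grid (default [default_lambda_grid()] on the
#'   training size).
#' @param epsilon Tube half-width on the scaled outcome (default 0.1).
#' @param alpha Feature-selection significance level.
#' @return List of class `svr_model`: `weights` (named, selected features),
#'   `intercept`, `lambda`, `epsilon`, `selected_features`, `scale_min`,
#'   `scale_max`, outcome scaling stats, `report` (train/test r, p, MSE and
#'   prediction vectors) and `audit` (sample ids used at each training step).
#' @export
train_model <- function(features, outcome, train_ids, test_ids,
                        selection_mode = c("select", "fixed"),
                        lambda_grid = NULL, epsilon = 0.1, alpha = 0.05) {
  selection_mode <- match.arg(selection_mode)
  if (length(intersect(train_ids, test_ids)))
    stop("train and test sets overlap")
  stopifnot(all(train_ids %in% rownames(features)),
            all(test_ids %in% rownames(features)))
  outcome <- outcome[c(train_ids, test_ids)]
  if (anyNA(outcome)) stop("outcome missing for some samples")
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(length(train_ids))

  Xtr_raw <- features[train_ids, , drop = FALSE]
  Xte_raw <- features[test_ids, , drop = FALSE]
  sc <- minmax_scale(Xtr_raw, Xte_raw)
  ytr <- outcome[train_ids]
  y_min <- min(ytr); y_rng <- max(ytr) - y_min
  if (y_rng == 0) stop("constant training outcome")
  ys <- (ytr - y_min) / y_rng

  tuned <- tune_lambda_loo(sc$train, ys, lambda_grid, epsilon)
  final_lambda <- tuned$lambda
  if (selection_mode == "select") {
    sel <- select_significant_features(tuned$fold_weights, alpha)
    # the final fit re-tunes the penalty on the selected feature set: the
    # selection-stage penalty was calibrated against the full set and
    # over-shrinks the survivors
    if (length(sel) && length(sel) < ncol(sc$train)) {
      final_lambda <- tune_lambda_loo(sc$train[, sel, drop = FALSE], ys,
                                      lambda_grid, epsilon)$lambda
    }
  } else {
    sel <- seq_len(ncol(sc$train))
  }

  if (!length(sel)) {
    final <- list(weights = numeric(0), intercept = stats::median(ys))
    pred_tr_s <- rep(final$intercept, length(train_ids))
    pred_te_s <- rep(final$intercept, length(test_ids))
  } else {
    final <- fit_svr_lasso(sc$train[, sel, drop = FALSE], ys, final_lambda,
                           epsilon)
    pred_tr_s <- drop(sc$train[, sel, drop = FALSE] %*% final$weights) +
      final$intercept
    pred_te_s <- drop(sc$apply_to[, sel, drop = FALSE] %*% final$weights) +
      final$intercept
  }
  pred_tr <- pred_tr_s * y_rng + y_min
  pred_te <- pred_te_s * y_rng + y_min

  report <- list(
    train = c(evaluate_predictions(pred_tr, outcome[train_ids]),
              list(predicted = stats::setNames(pred_tr, train_ids),
                   observed = outcome[train_ids])),
    test = c(evaluate_predictions(pred_te, outcome[test_ids]),
             list(predicted = stats::setNames(pred_te, test_ids),
                  observed = outcome[test_ids])))

  sel_names <- colnames(sc$train)[sel]
  structure(list(
    weights = stats::setNames(if (length(sel)) final$weights else numeric(0),
                              sel_names),
    intercept = if (length(sel)) final$intercept else final$intercept,
    lambda = final_lambda, lambda_selection = tuned$lambda,
    epsilon = epsilon,
    selected_features = sel_names,
    cv_mse = tuned$cv_mse,
    scale_min = sc$min, scale_max = sc$max,
    outcome_min = y_min, outcome_range = y_rng,
    selection_mode = selection_mode,
    report = report,
    audit = list(scaling = train_ids, tuning = train_ids,
                 selection = if (selection_mode == "select") train_ids else character(0),
                 test = test_ids)),
    class = "svr_model")
}
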