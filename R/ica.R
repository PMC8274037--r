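#' Map pathway gene regions to CpG probes
#'
#' A probe is selected when its position falls in `[start - flank,
#' end + flank)` of a region on the same chromosome (regions are 0-based
#' half-open). Probes are deduplicated across genes, annotation order
#' preserved.
#'
#' @param regions Data frame `gene`, `chrom`, `start`, `end`.
#' @param annotation Probe annotation with `probe_id`, `chrom`, `pos`.
#' @param flank Flanking width in bp (default 20000).
#' @return Character vector of probe ids (possibly empty, with a warning).
#' @export
map_pathway_probes <- function(regions, annotation, flank = 20000) {
  hit <- rep(FALSE, nrow(annotation))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (annotation$chrom == regions$chrom[i] &
                    annotation$pos >= regions$start[i] - flank &
                    annotation$pos < regions$end[i] + flank)
  }
  ids <- annotation$probe_id[hit]
  if (!length(ids)) warning("no probes map to the supplied regions")
  ids
}

# One FastICA pass (deflation, tanh nonlinearity) on pre-whitened rows Z
# (k x p, unit-variance uncorrelated rows). Returns the orthogonal unmixing
# matrix W (k x k) with attribute "n_unconverged".
fastica_core <- function(Z, max_iter = 200, tol = 1e-4) {
  k <- nrow(Z); p <- ncol(Z)
  W <- matrix(0, k, k)
  n_unconverged <- 0L
  for (comp in seq_len(k)) {
    w <- stats::rnorm(k)
    w <- w / sqrt(sum(w^2))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wx <- drop(crossprod(w, Z))
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- drop(Z %*% g) / p - mean(gp) * w
      if (comp > 1) {
        Wp <- W[seq_len(comp - 1), , drop = FALSE]
        w_new <- w_new - drop(crossprod(Wp, Wp %*% w_new))
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) { w <- stats::rnorm(k); w <- w / sqrt(sum(w^2)); next }
      w_new <- w_new / nrm
      converged <- abs(abs(sum(w_new * w)) - 1) < tol
      w <- w_new
      if (converged) break
    }
    if (!converged) n_unconverged <- n_unconverged + 1L
    W[comp, ] <- w
  }
  structure(W, n_unconverged = n_unconverged)
}

#' Fit an ICA decomposition X = A x S
#'
#' Centers each probe, whitens through the SVD, runs fixed-point ICA with
#' deflation (tanh contrast) on the top-`k` subspace, then normalizes each
#' component row of `S` to unit length, fixes its sign so the
#' largest-magnitude entry is positive, recomputes `A` as the centered data
#' times the pseudoinverse of `S`, and orders components by descending
#' explained variance.
#'
#' @param X Samples x probes matrix (e.g. pathway-probe betas of patients).
#' @param k Number of components, `k <= min(dim(X))`.
#' @param seed Integer seed. `max_restarts` seeded deflation passes are run
#'   (restarting non-converged passes with incremented seeds) and the
#'   solution with the largest log-cosh negentropy proxy is kept, since the
#'   contrast has local optima on near-saturated beta data.
#' @param max_restarts Restart budget (default 8).
#' @return Object of class `ica_model`: `S` (k x probes), `A` (samples x k),
#'   `n_components`, `probe_ids`, `sample_ids`, `center`, `seed`, `r2`
#'   (reconstruction R-squared).
#' @export
fit_ica <- function(X, k, seed = 1, max_restarts = 8) {
  X <- as.matrix(X)
  if (k > min(dim(X))) stop("k exceeds min(samples, probes)")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%d", seq_len(nrow(X)))
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0, nv = k)
  if (sv$d[k] < 1e-12 * sv$d[1]) stop("rank of X is below k")
  p <- ncol(Xc)
  Z <- sqrt(p) * t(sv$v[, seq_len(k), drop = FALSE]) # k x p, whitened rows

  # the tanh contrast has local optima on saturated beta-scale data, so run
  # several seeded deflation passes and keep the one with the largest
  # negentropy proxy sum_j (E[log cosh s_j] - E[log cosh nu])^2
  EG_gauss <- 0.3745672
  best <- NULL; best_val <- -Inf
  for (r in seq_len(max_restarts)) {
    set.seed(seed + r - 1)
    W <- fastica_core(Z)
    val <- sum((rowMeans(log(cosh(W %*% Z))) - EG_gauss)^2)
    if (val > best_val) { best <- W; best_val <- val }
  }
  W <- best
  if (attr(W, "n_unconverged") > 0L)
    warning(attr(W, "n_unconverged"),
            " component(s) hit the iteration cap; using the final state")

  S <- W %*% Z
  S <- S / sqrt(rowSums(S^2))
  flip <- apply(S, 1, function(s) sign(s[which.max(abs(s))]))
  S <- S * flip
  A <- Xc %*% t(S) %*% solve(tcrossprod(S))
  ord <- order(colSums(A^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  dimnames(S) <- list(sprintf("IC%d", seq_len(k)), colnames(X))
  dimnames(A) <- list(rownames(X), sprintf("IC%d", seq_len(k)))
  names(center) <- colnames(X)

  recon <- A %*% S
  r2 <- 1 - sum((Xc - recon)^2) / sum(Xc^2)
  structure(list(S = S, A = A, n_components = as.integer(k),
                 probe_ids = colnames(X), sample_ids = rownames(X),
                 center = center, seed = seed, r2 = r2),
            class = "ica_model")
}

#' Project new samples onto fitted components
#'
#' `A_new = (X_new - center) x pinv(S)`; projecting the training matrix
#' reproduces the model's loadings.
#'
#' @param model An `ica_model`.
#' @param X_new Samples x probes matrix containing the model's probes.
#' @return Samples x components loading matrix.
#' @export
project_loadings <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new)) && ncol(X_new) == length(model$probe_ids)) {
    colnames(X_new) <- model$probe_ids
  }
  miss <- setdiff(model$probe_ids, colnames(X_new))
  if (length(miss)) stop("X_new is missing model probes: ",
                         paste(utils::head(miss), collapse = ", "))
  Xc <- sweep(X_new[, model$probe_ids, drop = FALSE], 2, model$center)
  A <- Xc %*% t(model$S) %*% solve(tcrossprod(model$S))
  colnames(A) <- rownames(model$S)
  A
}

#' Fraction of data variance retained by the decomposition
#'
#' `1 - ||X_c - A S||_F^2 / ||X_c||_F^2`, with loadings obtained by
#' projection, so the full-rank decomposition returns 1.
#'
#' @param model An `ica_model`.
#' @param X Samples x probes matrix on the model's probes.
#' @return Scalar fraction.
#' @export
variance_retained <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) == length(model$probe_ids))
    colnames(X) <- model$probe_ids
  Xc <- sweep(X[, model$probe_ids, drop = FALSE], 2, model$center)
  tot <- sum(Xc^2)
  if (tot == 0) stop("X has zero variance about the model center")
  A <- project_loadings(model, X)
  1 - sum((Xc - A %*% model$S)^2) / tot
}

#' Estimate the component number by half-sample consistency
#'
#' For each candidate `k`, ICA is fit `n_runs` times on random half-sample
#' resamples; for every pair of runs the component rows are matched by the
#' Hungarian algorithm on absolute correlation, a pair is scored by its
#' worst-matched component, and the consistency score is the mean of those
#' worst-component |correlations| across pairs (so every component must be
#' reproducible, which is what makes the score drop sharply past the true
#' count). Returns the largest candidate whose consistency exceeds `floor`;
#' if none passes, the argmax with a warning.
#'
#' @param X Samples x probes matrix.
#' @param candidates Candidate component counts.
#' @param n_runs Resampling runs per candidate (default 8).
#' @param seed Integer seed.
#' @param floor Consistency floor (default 0.8).
#' @return Integer count with attribute `"consistency"` (named vector).
#' @export
estimate_component_number <- function(X, candidates, n_runs = 8, seed = 1,
                                      floor = 0.8) {
  X <- as.matrix(X)
  n <- nrow(X)
  half <- floor(n / 2)
  candidates <- candidates[candidates <= min(half, ncol(X))]
  if (!length(candidates)) stop("no feasible candidate component counts")
  consistency <- stats::setNames(numeric(length(candidates)),
                                 as.character(candidates))
  for (ci in seq_along(candidates)) {
    k <- candidates[ci]
    Ss <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      set.seed(seed * 10000 + k * 100 + r)
      rows <- sample(n, half)
      Ss[[r]] <- fit_ica(X[rows, , drop = FALSE], k,
                         seed = seed * 10000 + k * 100 + r)$S
    }
    vals <- c()
    for (a in seq_len(n_runs - 1)) for (b in seq(a + 1, n_runs)) {
      C <- abs(stats::cor(t(Ss[[a]]), t(Ss[[b]])))
      if (k == 1) { vals <- c(vals, C[1, 1]); next }
      m <- clue::solve_LSAP(C, maximum = TRUE)
      vals <- c(vals, min(C[cbind(seq_len(k), as.integer(m))]))
    }
    consistency[ci] <- mean(vals)
  }
  pass <- which(consistency > floor)
  if (length(pass)) {
    k_hat <- candidates[max(pass)]
  } else {
    warning("no candidate reached the consistency floor; returning argmax")
    k_hat <- candidates[which.max(consistency)]
  }
  structure(as.integer(k_hat), consistency = consistency)
}

#' Match estimated components to reference components
#'
#' Hungarian assignment maximizing absolute row correlations; used to compare
#' fitted components with planted sources or across runs.
#'
#' @param S_est,S_ref Components x probes matrices (same probe columns).
#' @return Data frame `est`, `ref`, `abs_cor`, one row per estimated row.
#' @export
match_components <- function(S_est, S_ref) {
  C <- abs(stats::cor(t(S_est), t(S_ref)))
  k <- min(nrow(S_est), nrow(S_ref))
  if (nrow(S_est) <= nrow(S_ref)) {
    m <- clue::solve_LSAP(C, maximum = TRUE)
    data.frame(est = seq_len(nrow(S_est)), ref = as.integer(m),
               abs_cor = C[cbind(seq_len(nrow(S_est)), as.integer(m))])
  } else {
    m <- clue::solve_LSAP(t(C), maximum = TRUE)
    data.frame(est = as.integer(m), ref = seq_len(nrow(S_ref)),
               abs_cor = t(C)[cbind(seq_len(nrow(S_ref)), as.integer(m))])
  }
}

#' Serialize / restore an ICA model
#'
#' Full-precision JSON; the round trip restores `S`, `A`, `center` and `seed`
#' exactly to the printed precision.
#'
#' @param model An `ica_model`.
#' @param path JSON file path.
#' @return `save_ica_model` returns the path invisibly; `read_ica_model`
#'   returns the restored `ica_model`.
#' @export
save_ica_model <- function(model, path) {
  obj <- unclass(model)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_ica_model
#' @export
read_ica_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nrow, byrow = TRUE) {
    if (is.matrix(x)) return(x)
    matrix(unlist(x), nrow = nrow, byrow = byrow)
  }
  k <- as.integer(obj$n_components)
  S <- as_mat(obj$S, k)
  A <- as_mat(obj$A, length(obj$sample_ids))
  dimnames(S) <- list(sprintf("IC%d", seq_len(k)), obj$probe_ids)
  dimnames(A) <- list(obj$sample_ids, sprintf("IC%d", seq_len(k)))
  model <- list(
    S = S,
    A = A,
    n_components = k,
    probe_ids = obj$probe_ids, sample_ids = obj$sample_ids,
    center = stats::setNames(as.numeric(obj$center), obj$probe_ids),
    seed = obj$seed, r2 = obj$r2)
  class(model) <- "ica_model"
  model
}
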