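# Partial least squares regression (single response, NIPALS) with
# z-scoring, k-fold cross-validation and jackknife coefficient variances.
# Standardization uses the population-sd convention (divide by n) and, in
# cross-validation, is always computed on the training part only.

#' Standardize predictors and response
#'
#' Centers and scales every column (and `y`) to mean 0, sd 1 using the
#' population-sd convention. The returned parameters invert the transform
#' exactly.
#'
#' @param X Numeric matrix or data.frame.
#' @param y Optional numeric response.
#' @return List with `Xz`, `yz` and `params` (`x_center`, `x_scale`,
#'   `y_center`, `y_scale`).
#' @export
standardize <- function(X, y = NULL) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, pop_sd)
  zero <- scl <= 0
  if (any(zero)) {
    stop("zero-variance column: ", colnames(X)[zero][1], call. = FALSE)
  }
  Xz <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  params <- list(x_center = ctr, x_scale = scl)
  yz <- NULL
  if (!is.null(y)) {
    params$y_center <- mean(y)
    params$y_scale <- pop_sd(y)
    if (params$y_scale <= 0) stop("zero-variance response", call. = FALSE)
    yz <- (y - params$y_center) / params$y_scale
  }
  list(Xz = Xz, yz = yz, params = params)
}

#' Fit a PLS1 model by NIPALS
#'
#' Sequentially extracts components maximizing covariance with the
#' response, with deflation of X. Inputs are assumed standardized; the
#' intercept in standardized space is 0. Coefficients for every nested
#' component count 1..`n_components` are kept (`beta_path`), which makes
#' cross-validating over the component number cheap.
#'
#' @param Xz Standardized predictor matrix.
#' @param yz Standardized response.
#' @param n_components Number of latent components (<= rank of `Xz`).
#' @return Object of class `pls_model`: `n_components`, `x_weights`,
#'   `x_loadings`, `y_loadings`, `scores`, `beta` (coefficients in
#'   standardized space), `beta0` (0), `beta_path`.
#' @export
fit_pls <- function(Xz, yz, n_components) {
  Xz <- as.matrix(Xz)
  n <- nrow(Xz); p <- ncol(Xz)
  A <- min(n_components, p, n - 1L)
  if (n_components > min(p, n - 1L)) {
    stop("n_components exceeds the rank bound of X", call. = FALSE)
  }
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  q <- numeric(A); TT <- matrix(0, n, A)
  E <- Xz; f <- yz
  a_done <- 0L
  for (a in seq_len(A)) {
    wv <- crossprod(E, f)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break               # response orthogonal to residual X
    wv <- wv / nw
    tv <- E %*% wv
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- crossprod(E, tv) / tt
    qa <- sum(f * tv) / tt
    E <- E - tcrossprod(tv, pv)
    f <- f - qa * tv
    W[, a] <- wv; P[, a] <- pv; q[a] <- qa; TT[, a] <- tv
    a_done <- a
  }
  beta_path <- matrix(0, p, max(a_done, 1L),
                      dimnames = list(colnames(Xz), NULL))
  if (a_done > 0L) {
    for (a in seq_len(a_done)) {
      Wa <- W[, seq_len(a), drop = FALSE]
      Pa <- P[, seq_len(a), drop = FALSE]
      R <- Wa %*% solve(crossprod(Pa, Wa))
      beta_path[, a] <- R %*% q[seq_len(a)]
    }
  }
  structure(list(
    n_components = a_done,
    x_weights = W[, seq_len(max(a_done, 1L)), drop = FALSE],
    x_loadings = P[, seq_len(max(a_done, 1L)), drop = FALSE],
    y_loadings = q[seq_len(max(a_done, 1L))],
    scores = TT[, seq_len(max(a_done, 1L)), drop = FALSE],
    beta = beta_path[, max(a_done, 1L)],
    beta0 = 0,
    beta_path = beta_path
  ), class = "pls_model")
}

#' Predict from a PLS model in standardized space
#' @param model A `pls_model`.
#' @param Xz Standardized predictors (same columns as at fit time).
#' @param n_components Component count (default: the fitted one).
#' @return Predicted standardized response.
#' @export
predict_pls <- function(model, Xz, n_components = model$n_components) {
  a <- max(min(n_components, ncol(model$beta_path)), 1L)
  drop(as.matrix(Xz) %*% model$beta_path[, a])
}

# Fold-internal standardization: a column constant within the training
# part is centered and left unscaled (it then carries no weight), so CV
# does not abort on rare indicator features.
#' @noRd
standardize_safe <- function(X, y) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, pop_sd)
  scl[scl <= 0] <- 1
  Xz <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  yc <- mean(y); ys <- pop_sd(y)
  if (ys <= 0) stop("zero-variance response", call. = FALSE)
  list(Xz = Xz, yz = (y - yc) / ys,
       params = list(x_center = ctr, x_scale = scl, y_center = yc,
                     y_scale = ys))
}

#' @noRd
make_folds <- function(n, k, seed) {
  with_seed(seed, {
    idx <- sample.int(n)
    stats::setNames(rep(seq_len(k), length.out = n)[order(idx)], NULL)
  })
}

#' k-fold cross-validation of a PLS fit
#'
#' Rows are partitioned into `k` near-equal folds by a seeded random
#' assignment. For each fold the model is fitted on the complement
#' (standardizing on the training rows only) and held-out rows are
#' predicted; `cv_r2 = 1 - SSE/SST` over the pooled held-out predictions
#' (SST about the overall response mean). When `select_ncomp` is `TRUE`
#' the pooled CV R-squared is computed for every component count
#' 1..`n_components` and the reported fit uses the smallest count within
#' `ncomp_tol` of the maximum.
#'
#' @param X Predictor matrix (raw scale).
#' @param y Response (raw scale).
#' @param n_components Maximum component count.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param select_ncomp Re-choose the component count by CV (default
#'   `TRUE`).
#' @param ncomp_tol Tolerance for the parsimonious component choice
#'   (default 0.002).
#' @return Object of class `cv_result`: `k`, `fold_assignment`, `cv_r2`,
#'   `cv_r2_per_ncomp`, `n_components` (chosen), `per_fold_beta` (k x p,
#'   standardized space, at the chosen count), `seed`.
#' @export
cross_validate <- function(X, y, n_components, k = 10L, seed = 20140206L,
                           select_ncomp = TRUE, ncomp_tol = 0.002) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("more folds than rows", call. = FALSE)
  if (n < 2L * k) stop("need at least 2k rows", call. = FALSE)
  amax <- min(n_components, ncol(X), n - ceiling(n / k) - 1L)
  folds <- make_folds(n, k, seed)
  preds <- matrix(NA_real_, n, amax)
  per_fold_beta <- vector("list", k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    std <- standardize_safe(X[tr, , drop = FALSE], y[tr])
    fit <- fit_pls(std$Xz, std$yz, amax)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, std$params$x_center),
                 2L, std$params$x_scale, "/")
    for (a in seq_len(ncol(fit$beta_path))) {
      preds[!tr, a] <- drop(Xte %*% fit$beta_path[, a]) *
        std$params$y_scale + std$params$y_center
    }
    if (ncol(fit$beta_path) < amax) {  # rank-deficient fold: pad
      for (a in seq.int(ncol(fit$beta_path) + 1L, amax)) {
        preds[!tr, a] <- preds[!tr, ncol(fit$beta_path)]
      }
    }
    per_fold_beta[[fold]] <- fit$beta_path
  }
  sst <- sum((y - mean(y))^2)
  r2 <- apply(preds, 2L, function(pr) 1 - sum((y - pr)^2) / sst)
  a_star <- if (select_ncomp) {
    min(which(r2 >= max(r2) - ncomp_tol))
  } else amax
  beta_mat <- do.call(rbind, lapply(per_fold_beta, function(bp) {
    bp[, min(a_star, ncol(bp))]
  }))
  colnames(beta_mat) <- colnames(X)
  structure(list(k = k, fold_assignment = folds, cv_r2 = r2[a_star],
                 cv_r2_per_ncomp = r2, n_components = a_star,
                 per_fold_beta = beta_mat, seed = seed),
            class = "cv_result")
}

#' Jackknife standard errors from per-fold coefficients
#'
#' Delete-a-group jackknife over the CV folds:
#' `se_j = sqrt(((k - 1) / k) * sum_i (beta_ij - mean_j)^2)`.
#'
#' @param per_fold_beta k x p matrix of per-fold coefficient vectors.
#' @param beta Optional point-estimate coefficients for the t-like ratio
#'   (default: fold means).
#' @return List with `se` and `t_like` (`|beta| / se`; `Inf` where
#'   `se = 0` and `beta != 0`, 0 where both are 0).
#' @export
jackknife_se <- function(per_fold_beta, beta = NULL) {
  per_fold_beta <- as.matrix(per_fold_beta)
  k <- nrow(per_fold_beta)
  if (k < 2L) stop("jackknife needs k >= 2 folds", call. = FALSE)
  m <- colMeans(per_fold_beta)
  se <- sqrt(((k - 1) / k) *
               colSums(sweep(per_fold_beta, 2L, m)^2))
  if (is.null(beta)) beta <- m
  t_like <- ifelse(se > 0, abs(beta) / se,
                   ifelse(abs(beta) > 0, Inf, 0))
  list(se = se, t_like = t_like)
}

#' Serialize a fitted model to JSON
#' @param model A `pls_model`.
#' @param params Standardization parameters (from [standardize()]).
#' @param path Output path.
#' @param extra Named list of extra metadata (seed, manifest hash, ...).
#' @export
write_model_json <- function(model, params, path, extra = list()) {
  obj <- c(list(n_components = model$n_components,
                beta = as.list(model$beta), beta0 = model$beta0,
                standardization = params), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
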