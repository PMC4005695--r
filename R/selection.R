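# Backward feature elimination driven by jackknife t-like statistics with
# cross-validated-R2-preserving stopping.

#' Backward elimination over the predictor set
#'
#' Iteratively removes predictors: at each step the current set is fitted
#' by PLS with 10-fold CV (component count re-chosen each time), jackknife
#' t-like statistics `|beta|/se` are computed from the per-fold
#' coefficients, and removal of the predictor with the smallest t-like
#' value is proposed (ties broken by smaller `|beta|`, then by name).
#' A removal is accepted if the new CV R-squared is at least the current
#' one minus `tol`; otherwise the predictor is set aside for the rest of
#' the pass and the next-smallest is tried. The loop terminates when no
#' predictor can be removed. Deterministic given the seed (the same fold
#' seed is used for every evaluation, so fold assignments are identical
#' across steps).
#'
#' @param table A `feature_table`, or a numeric predictor matrix.
#' @param response Numeric response vector (raw scale).
#' @param k Folds (default 10).
#' @param seed Fold seed.
#' @param tol CV-R2 tolerance for accepting a removal (default 0.002).
#' @param protected Predictor names never proposed for removal.
#' @param max_components Upper bound on the PLS component count
#'   (default 15).
#' @return Object of class `selection_result`: `surviving`, `trajectory`
#'   (data.frame: step, removed, cv_r2_before, cv_r2_after),
#'   `final_model` (fit on all rows, surviving set), `final_cv`,
#'   `final_cv_r2`, `initial_cv_r2`.
#' @export
backward_eliminate <- function(table, response, k = 10L, seed = 20140206L,
                               tol = 0.002, protected = character(),
                               max_components = 15L) {
  X <- if (inherits(table, "feature_table")) table$X else as.matrix(table)
  if (ncol(X) == 0L) stop("empty predictor table", call. = FALSE)
  stopifnot(length(response) == nrow(X))

  # constant columns carry no information; they are removed first and
  # recorded in the trajectory
  const <- colnames(X)[apply(X, 2L, pop_sd) <= 0]
  const <- setdiff(const, protected)
  X0 <- X[, setdiff(colnames(X), const), drop = FALSE]

  evaluate <- function(cols) {
    cross_validate(X0[, cols, drop = FALSE], response,
                   n_components = max_components, k = k, seed = seed)
  }

  current <- colnames(X0)
  cv <- evaluate(current)
  initial_cv_r2 <- cv$cv_r2
  trajectory <- list()
  step <- 0L
  for (cand in const) {
    step <- step + 1L
    trajectory[[step]] <- data.frame(
      step = step, removed = cand, cv_r2_before = cv$cv_r2,
      cv_r2_after = cv$cv_r2, stringsAsFactors = FALSE)
  }
  repeat {
    if (length(current) <= 1L) break
    jk <- jackknife_se(cv$per_fold_beta,
                       beta = colMeans(cv$per_fold_beta))
    ord <- order(jk$t_like, abs(colMeans(cv$per_fold_beta)), current)
    candidates <- setdiff(current[ord], protected)
    accepted <- FALSE
    for (cand in candidates) {
      new_cols <- setdiff(current, cand)
      new_cv <- evaluate(new_cols)
      if (new_cv$cv_r2 >= cv$cv_r2 - tol) {
        step <- step + 1L
        trajectory[[step]] <- data.frame(
          step = step, removed = cand, cv_r2_before = cv$cv_r2,
          cv_r2_after = new_cv$cv_r2, stringsAsFactors = FALSE)
        current <- new_cols
        cv <- new_cv
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }

  std <- standardize(X[, current, drop = FALSE], response)
  final <- fit_pls(std$Xz, std$yz,
                   min(cv$n_components, length(current)))
  traj <- if (length(trajectory)) do.call(rbind, trajectory) else
    data.frame(step = integer(), removed = character(),
               cv_r2_before = numeric(), cv_r2_after = numeric())
  structure(list(surviving = current, trajectory = traj,
                 final_model = final, final_std = std$params,
                 final_cv = cv, final_cv_r2 = cv$cv_r2,
                 initial_cv_r2 = initial_cv_r2,
                 k = k, seed = seed, tol = tol),
            class = "selection_result")
}
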