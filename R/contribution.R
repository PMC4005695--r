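# Per-gene decomposition of predictions into mRNA/TIR/CDS group
# contributions, variance attribution by group, and the expression-profile
# machinery (abundance tertile split by quartiles, transcription vs
# translation-efficiency estimates).

#' Per-gene group contributions
#'
#' For each gene, the contribution of group g is the weighted sum
#' `sum_{i in g} beta_i * xz_i` (standardized-response units). The group
#' contributions plus the intercept reproduce the model prediction
#' exactly.
#'
#' @param model A `pls_model` (coefficients in standardized space).
#' @param Xz Standardized predictor matrix restricted to the model's
#'   predictors.
#' @param group_of Named character vector mapping predictor to group.
#' @return data.frame: `gene_id`, one column per group, `prediction`.
#' @export
group_contribution <- function(model, Xz, group_of) {
  Xz <- as.matrix(Xz)
  cols <- colnames(Xz)
  if (any(!cols %in% names(group_of))) {
    stop("unknown group label for predictor ",
         cols[!cols %in% names(group_of)][1], call. = FALSE)
  }
  beta <- model$beta[cols]
  groups <- unique(unname(group_of[cols]))
  contrib <- vapply(groups, function(g) {
    gc <- cols[group_of[cols] == g]
    drop(Xz[, gc, drop = FALSE] %*% beta[gc])
  }, numeric(nrow(Xz)))
  if (is.null(dim(contrib))) contrib <- matrix(contrib, nrow = 1L,
                                               dimnames = list(NULL, groups))
  pred <- drop(Xz %*% beta) + model$beta0
  data.frame(gene_id = rownames(Xz) %||% as.character(seq_len(nrow(Xz))),
             contrib, prediction = pred, check.names = FALSE,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance explained, attributed by predictor group
#'
#' Normalized covariance decomposition: `raw_g = sum_{i in g} beta_i *
#' r(xz_i, yz)` and `share_g = raw_g / sum_g raw_g * R2`, where `R2` is
#' the squared correlation of the prediction with the response. Shares
#' sum to the model R-squared exactly; under mutually orthogonal
#' predictors at full rank each predictor's raw term reduces to its
#' squared correlation with the response.
#'
#' @param model A `pls_model`.
#' @param Xz Standardized predictors (model columns).
#' @param yz Standardized response.
#' @param group_of Predictor-to-group mapping.
#' @return List of class `variance_shares`: `share` (named numeric),
#'   `raw` (unnormalized covariance terms), `model_r2`,
#'   `negative_raw` (groups with negative raw terms, flagged).
#' @export
variance_shares <- function(model, Xz, yz, group_of) {
  Xz <- as.matrix(Xz)
  cols <- colnames(Xz)
  beta <- model$beta[cols]
  r <- drop(stats::cor(Xz, yz))
  raw_i <- beta * r
  groups <- unique(unname(group_of[cols]))
  raw <- vapply(groups, function(g) sum(raw_i[group_of[cols] == g]),
                numeric(1))
  if (abs(sum(raw)) < 1e-12) stop("degenerate model: zero total covariance",
                                  call. = FALSE)
  pred <- drop(Xz %*% beta)
  r2 <- stats::cor(pred, yz)^2
  share <- raw / sum(raw) * r2
  structure(list(share = share, raw = raw, model_r2 = r2,
                 negative_raw = names(raw)[raw < 0]),
            class = "variance_shares")
}

#' @noRd
quartile_split <- function(x, labels) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  out <- rep(labels[2L], length(x))
  out[x < q[1L]] <- labels[1L]
  out[x > q[2L]] <- labels[3L]
  factor(out, levels = labels)
}

#' Split genes into low/medium/high abundance groups
#'
#' Lower and upper quartiles of the protein means define the cut: low is
#' strictly below Q1, high strictly above Q3, everything else (including
#' boundary ties) medium. Quantiles use linear interpolation (type 7).
#'
#' @param protein_means Numeric vector (n >= 4).
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
abundance_groups <- function(protein_means) {
  stopifnot(length(protein_means) >= 4L)
  quartile_split(protein_means, c("low", "medium", "high"))
}

#' Transcription and translation-efficiency estimates
#'
#' Transcription is the mRNA-group contribution; translation efficiency
#' is the aggregated TIR + CDS contribution. Their Pearson correlation
#' quantifies the concerted operation of the two channels.
#'
#' @param contributions data.frame from [group_contribution()] with
#'   columns `mRNA`, `TIR`, `CDS`.
#' @return List: `transcription`, `translation_efficiency`, `pearson_r`
#'   (`NA` when degenerate).
#' @export
efficiency_estimates <- function(contributions) {
  need <- c("mRNA", "TIR", "CDS")
  if (any(!need %in% names(contributions))) {
    stop("missing group column: ",
         setdiff(need, names(contributions))[1], call. = FALSE)
  }
  tx <- contributions$mRNA
  te <- contributions$TIR + contributions$CDS
  r <- if (stats::sd(tx) == 0 || stats::sd(te) == 0) NA_real_ else
    stats::cor(tx, te)
  list(transcription = tx, translation_efficiency = te, pearson_r = r)
}

#' 2-D count matrix of mRNA vs CDS contributions
#'
#' Heatmap-style binned counts of genes over (mRNA contribution, CDS
#' contribution), optionally restricted to one abundance group.
#' @param contributions data.frame from [group_contribution()].
#' @param nbin Bins per axis.
#' @return Integer matrix of counts (rows: mRNA bins, cols: CDS bins).
#' @export
contribution_histogram <- function(contributions, nbin = 10L) {
  bx <- cut(contributions$mRNA, nbin)
  by <- cut(contributions$CDS, nbin)
  table(mRNA = bx, CDS = by)
}
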