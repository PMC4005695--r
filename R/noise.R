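# Expression-noise statistics: coefficient of variation, running-median
# noise differential, quartile group comparisons, Mann-Whitney tests,
# partial correlations and FDR adjustment.

#' Coefficient of variation
#'
#' `CoV = sqrt(variance) / mean` of protein abundance across the cell
#' population.
#' @param mean Positive mean abundance (molecules/cell); vectorized.
#' @param variance Nonnegative variance.
#' @return CoV.
#' @export
coefficient_of_variation <- function(mean, variance) {
  if (any(mean <= 0)) stop("mean must be positive", call. = FALSE)
  if (any(variance < 0)) stop("variance must be nonnegative", call. = FALSE)
  sqrt(variance) / mean
}

#' Noise differential against a running median
#'
#' Genes are ranked by mean abundance; the expected CoV of a gene is the
#' median CoV within the centered rank window of size `window`
#' (truncated at the edges). The noise differential is the gene's CoV
#' minus this expectation — its abundance-corrected excess noise.
#'
#' @param records data.frame with `gene_id`, `mean` and either `cov` or
#'   `variance`.
#' @param window Odd window size (default 51).
#' @return The input data.frame (original order) with `cov`,
#'   `expected_cov` and `noise_differential` columns added.
#' @export
noise_differential <- function(records, window = 51L) {
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  n <- nrow(records)
  stopifnot(n >= window, window >= 3L)
  cov <- if ("cov" %in% names(records)) records$cov else
    coefficient_of_variation(records$mean, records$variance)
  ord <- order(records$mean)
  cov_s <- cov[ord]
  h <- (window - 1L) %/% 2L
  expected_s <- vapply(seq_len(n), function(i) {
    stats::median(cov_s[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  expected <- numeric(n)
  expected[ord] <- expected_s
  records$cov <- cov
  records$expected_cov <- expected
  records$noise_differential <- cov - expected
  records
}

#' Quartile split of the noise differential
#'
#' @param records data.frame with a `noise_differential` column (or a
#'   numeric vector).
#' @return Factor with levels `low_nd`, `mid`, `high_nd` (below Q1,
#'   between, above Q3; boundary ties are `mid`).
#' @export
quartile_noise_groups <- function(records) {
  nd <- if (is.data.frame(records)) records$noise_differential else records
  stopifnot(length(nd) >= 4L)
  quartile_split(nd, c("low_nd", "mid", "high_nd"))
}

#' Mann-Whitney U test
#'
#' U is the smaller of the two rank-sum statistics, with midranks for
#' ties. The two-sided p-value comes from the normal approximation with
#' tie correction and continuity correction; when the pooled sample size
#' is at most 12 the exact permutation distribution of U is enumerated
#' instead (p = P(U <= observed) over all assignments).
#'
#' @param a,b Numeric samples.
#' @param exact_max Pooled size at or below which exact enumeration is
#'   used (default 12).
#' @return List with `U`, `p_two_sided` and `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 12L) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample",
                                               call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  Ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  U <- min(Ua, Ub)
  if (N <= exact_max) {
    combos <- utils::combn(N, na)
    us <- apply(combos, 2L, function(ix) {
      ua <- sum(rk[ix]) - na * (na + 1) / 2
      min(ua, na * nb - ua)
    })
    p <- mean(us <= U + 1e-9)
    return(list(U = U, p_two_sided = p, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p_two_sided = 1, method = "normal"))
  z <- (U - mu + 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(z))
  list(U = U, p_two_sided = p, method = "normal")
}

#' Partial correlation
#'
#' First-order partial correlation of `x` and `y` given `z`:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' For `method = "spearman"` the same formula is applied to midranks.
#' When the denominator is below 1e-12 (the controlled variable is
#' collinear with `x` or `y`) the convention is `r = 0` — controlling a
#' variable for itself carries no residual association. The p-value uses
#' the t statistic with n - 3 degrees of freedom.
#'
#' @param x,y,z Equal-length numeric vectors (n >= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p` and `n`.
#' @export
partial_correlation <- function(x, y, z, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("length mismatch", call. = FALSE)
  stopifnot(n >= 4L)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den2 <- (1 - rxz^2) * (1 - ryz^2)
  if (!is.finite(den2) || den2 < 1e-12) {
    return(list(r = 0, p = 1, n = n))
  }
  r <- (rxy - rxz * ryz) / sqrt(den2)
  r <- max(min(r, 1), -1)
  tt <- r * sqrt((n - 3) / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 3)
  list(r = r, p = p, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values (step-up, monotone, in \[0, 1\]).
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' @noRd
stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""))
}

#' Per-feature correlation report
#'
#' For every predictor: Pearson correlation with the response, partial
#' correlation given the mRNA level, and FDR-adjusted significance stars
#' (thresholds 0.05 / 0.01 / 0.001).
#'
#' @param ft A `feature_table`.
#' @param response Numeric response (e.g. log10 protein abundance).
#' @param control Column name controlled for in the partial correlation
#'   (default `"mrna_level"`).
#' @return data.frame: feature, group, r, p, partial_r, partial_p,
#'   fdr_p, fdr_partial_p, stars columns.
#' @export
correlation_report <- function(ft, response, control = "mrna_level") {
  X <- ft$X
  z <- X[, control]
  rows <- lapply(colnames(X), function(cn) {
    x <- X[, cn]
    if (pop_sd(x) == 0) {
      return(data.frame(feature = cn, group = unname(ft$group_of[cn]),
                        r = NA_real_, p = NA_real_,
                        partial_r = NA_real_, partial_p = NA_real_))
    }
    ct <- stats::cor.test(x, response)
    pc <- partial_correlation(x, response, z)
    data.frame(feature = cn, group = unname(ft$group_of[cn]),
               r = unname(ct$estimate), p = ct$p.value,
               partial_r = pc$r, partial_p = pc$p)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- bh_fdr(out$p)
  out$fdr_partial_p <- bh_fdr(out$partial_p)
  out$stars <- stars(out$fdr_p)
  out$partial_stars <- stars(out$fdr_partial_p)
  out[order(-abs(out$partial_r)), ]
}
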