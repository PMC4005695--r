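# Noise statistics: CoV, running-median differential, Mann-Whitney,
# partial correlations, FDR.

test_that("coefficient of variation follows its definition", {
  expect_equal(coefficient_of_variation(4, 4), 0.5)
  expect_equal(coefficient_of_variation(10, 0), 0)
  expect_error(coefficient_of_variation(0, 1), "positive")
  expect_error(coefficient_of_variation(2, -1), "nonnegative")
})

test_that("noise differential subtracts the rank-window median", {
  rec <- data.frame(gene_id = paste0("g", 1:5), mean = 1:5,
                    cov = c(0.5, 0.5, 0.9, 0.5, 0.5))
  out <- noise_differential(rec, window = 5)
  expect_equal(out$noise_differential, c(0, 0, 0.4, 0, 0))
  # identical CoV everywhere: all differentials zero
  rec$cov <- 0.7
  expect_equal(noise_differential(rec, window = 5)$noise_differential,
               rep(0, 5))
  expect_error(noise_differential(rec, window = 4), "odd")
})

test_that("noise differential is computed in mean-rank order, not row order", {
  rec <- data.frame(gene_id = paste0("g", 1:5), mean = c(3, 1, 5, 2, 4),
                    cov = c(0.9, 0.5, 0.5, 0.5, 0.5))
  out <- noise_differential(rec, window = 5)
  expect_equal(out$noise_differential, c(0.4, 0, 0, 0, 0))
})

test_that("CoV can come from a variance column", {
  rec <- data.frame(gene_id = paste0("g", 1:5), mean = rep(4, 5),
                    variance = c(4, 4, 4, 4, 4))
  out <- noise_differential(rec, window = 5)
  expect_equal(out$cov, rep(0.5, 5))
})

test_that("noise-differential quartile groups follow the quartile rule", {
  rec <- data.frame(noise_differential = 1:8)
  g <- quartile_noise_groups(rec)
  expect_equal(as.character(g),
               c("low_nd", "low_nd", "mid", "mid", "mid", "mid",
                 "high_nd", "high_nd"))
  expect_true(all(quartile_noise_groups(rep(0, 8)) == "mid"))
})

test_that("Mann-Whitney exact p matches enumeration on the worked example", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)
  expect_equal(same$p_two_sided, 1)
  expect_error(mann_whitney(numeric(), 1), "empty")
})

test_that("Mann-Whitney agrees with wilcox.test on larger samples", {
  set.seed(51)
  for (i in 1:5) {
    a <- rnorm(30); b <- rnorm(25, 0.5)
    r <- mann_whitney(a, b)
    w <- suppressWarnings(wilcox.test(a, b, correct = TRUE))
    expect_equal(min(w$statistic, length(a) * length(b) - w$statistic),
                 r$U, ignore_attr = TRUE)
    expect_lt(abs(r$p_two_sided - w$p.value), 0.01)
  }
})

test_that("the test statistic is invariant under monotone transforms", {
  set.seed(52)
  a <- rexp(20); b <- rexp(18, 0.6)
  r1 <- mann_whitney(a, b)
  r2 <- mann_whitney(log(a), log(b))
  expect_equal(r1$U, r2$U)
  expect_equal(r1$p_two_sided, r2$p_two_sided)
})

test_that("partial correlation reduces, degenerates and matches residuals", {
  set.seed(53)
  n <- 50
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + 0.4 * x + rnorm(n)
  # residual-regression oracle
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  expect_equal(partial_correlation(x, y, z)$r, cor(rx, ry),
               tolerance = 1e-10)
  # symmetry
  expect_equal(partial_correlation(x, y, z)$r,
               partial_correlation(y, x, z)$r, tolerance = 1e-12)
  # z = x: degeneracy convention returns 0
  expect_equal(partial_correlation(x, y, x)$r, 0)
  # orthogonal control: partial equals plain correlation
  z0 <- resid(lm(rnorm(n) ~ x + y))
  pr <- partial_correlation(x, y, z0)$r
  expect_equal(pr, cor(x, y), tolerance = 1e-10)
  expect_error(partial_correlation(x, y[1:10], z), "length")
})

test_that("spearman partial correlation works on midranks", {
  set.seed(54)
  x <- rexp(40); y <- x + rexp(40); z <- rnorm(40)
  ps <- partial_correlation(x, y, z, method = "spearman")
  pp <- partial_correlation(rank(x), rank(y), rank(z))
  expect_equal(ps$r, pp$r, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand computation and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.1)), c(0.03, 0.03, 0.1))
  expect_equal(bh_fdr(0.7), 0.7)
  set.seed(55)
  p <- runif(20)
  expect_true(all(bh_fdr(p) >= p))
  expect_true(all(bh_fdr(p) <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the correlation report ranks the transcript level first", {
  b <- get_bundle(120, 3)
  y <- log10(b$expression$protein_mean)
  rep <- correlation_report(b$features, y)
  expect_true(all(c("feature", "r", "partial_r", "fdr_p") %in% names(rep)))
  # controlling mRNA for itself gives 0 by the degeneracy convention
  expect_equal(rep$partial_r[rep$feature == "mrna_level"], 0)
  expect_gt(rep$r[rep$feature == "mrna_level"], 0.3)
})
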