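# PWM scanning, codon indices, composition features and table assembly.

test_that("a background-equal PWM scores zero everywhere", {
  mat <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm(mat)
  r <- score_sd_motif(strrep("A", 55), p)
  expect_equal(r$best_score, 0)
  expect_equal(r$n_above, 0L)
})

test_that("a single-column PWM scores log2(1/background) at its base", {
  mat <- matrix(c(1, 0, 0, 0), 4, 1,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm(mat)
  # upstream 5 nt "TTATT": the A sits at TIR coordinate -3
  tir <- paste0("TTATT", strrep("G", 6))
  r <- score_sd_motif(tir, p, scan_window = c(-5L, -1L), tir_upstream = 5L)
  expect_equal(r$best_score, 2)        # log2(1 / 0.25)
  expect_equal(r$best_offset, -3L)
})

test_that("spacing counts nucleotides between motif end and start codon", {
  # motif of length 6 placed to end at TIR coordinate -5 -> spacing 4
  motif <- "AGGAGG"
  up <- paste0(strrep("C", 25 - 4 - 6), motif, strrep("C", 4))
  tir <- paste0(up, strrep("A", 30))
  r <- score_sd_motif(tir, default_sd_pwm())
  expect_equal(r$spacing, 4L)
  expect_equal(r$best_offset, -10L)
  expect_error(score_sd_motif(tir, default_sd_pwm(),
                              scan_window = c(-4L, -1L)), "shorter")
})

test_that("relative adaptiveness is count/max within families with a floor", {
  counts <- c(GAA = 300, GAG = 100, TGT = 0, TGC = 50)
  w <- relative_adaptiveness(counts)$w
  expect_equal(unname(w["GAA"]), 1)
  expect_equal(unname(w["GAG"]), 1 / 3)
  expect_equal(unname(w["TGT"]), 0.01)
  expect_equal(unname(w["TGC"]), 1)
  all_equal <- relative_adaptiveness(
    stats::setNames(rep(10, 61), seq2abundance:::sense_codons()))$w
  expect_true(all(all_equal == 1))
  expect_error(relative_adaptiveness(integer()), "empty")
})

test_that("CAI is the geometric mean over non-excluded codons", {
  w <- relative_adaptiveness(c(GAA = 100, GAG = 25))
  expect_equal(cai("GAAGAGGAA", w), 0.25^(1 / 3), tolerance = 1e-12)
  # maximal-w codons give 1; appending a stop changes nothing
  expect_equal(cai("GAAGAA", w), 1)
  expect_equal(cai("GAAGAGGAATAA", w), cai("GAAGAGGAA", w))
  # ATG/TGG single-codon families are excluded
  expect_equal(cai("ATGGAATGG", w), 1)
  expect_error(cai("ATGTGG", w), "excluded")
})

test_that("tAI is the geometric mean over all sense codons", {
  wt <- list(w = stats::setNames(rep(1, 61), seq2abundance:::sense_codons()),
             source = "tai")
  expect_equal(tai("ATGAAATAA", wt), 1)
  wt$w["AAA"] <- 0.5
  expect_equal(tai("AAATAA", wt), 0.5)
  wt$w[c("AAA", "GAA")] <- c(0.8, 0.2)
  expect_equal(tai("AAAGAA", wt), sqrt(0.16), tolerance = 1e-12)
})

test_that("tAI weights follow the wobble rules on a toy tRNA set", {
  # Phe: TTT/TTC read by anticodon GAA only
  copies <- c(GAA = 2)
  w <- tai_weights_from_copies(copies)$w
  # TTC is Watson-Crick for GAA; TTT is read through G:U wobble
  expect_equal(unname(w["TTC"]), 1)
  expect_equal(unname(w["TTT"]), (1 - 0.41) * 2 / 2)
  expect_equal(unname(w["GGG"]), 0.01)  # no decoder: floored
})

test_that("composition features count codons, amino acids and content", {
  reg <- list(gene_id = "g", cds_seq = "ATGAAATAA", start_codon = "ATG",
              stop_codon = "TAA")
  f <- composition_features(reg)
  expect_equal(unname(f["codon_ATG"]), 0.5)
  expect_equal(unname(f["codon_AAA"]), 0.5)
  expect_equal(unname(f["aa_Met"]), 0.5)
  expect_equal(unname(f["aa_Lys"]), 0.5)
  expect_equal(unname(f["protein_length"]), 2)
  expect_equal(unname(f["stop_TAA"]), 1)
  expect_equal(unname(f["stop_TGA"]), 0)
  # poly-A body
  f2 <- composition_features(list(cds_seq = "ATGAAAAAATAA"))
  expect_equal(unname(f2["A_content"]), 9 / 12)
  expect_equal(unname(f2["AT_content"]), 11 / 12)
})

test_that("codon and amino-acid frequency blocks each sum to 1 per gene", {
  b <- get_bundle(12, 7)
  X <- b$features$X
  codon_cols <- grep("^codon_", colnames(X))
  aa_cols <- grep("^aa_", colnames(X))
  expect_equal(unname(rowSums(X[, codon_cols])), rep(1, nrow(X)))
  expect_equal(unname(rowSums(X[, aa_cols])), rep(1, nrow(X)))
  expect_true(all(X[, codon_cols] >= 0 & X[, codon_cols] <= 1))
})

test_that("the manifest is fixed at 107 features and the table at 108 columns", {
  man <- feature_manifest()
  expect_length(man, 107L)
  expect_equal(sum(feature_groups() == "TIR"), 16L)
  expect_equal(sum(feature_groups() == "CDS"), 91L)
  b <- get_bundle(12, 7)
  expect_equal(ncol(b$features$X), 108L)
  expect_setequal(colnames(b$features$X), c(man, "mrna_level"))
  expect_false(any(is.na(b$features$X)))
})

test_that("feature computation is a pure function of its inputs", {
  g <- simulate_genes(4, seed = 33)
  expr <- data.frame(gene_id = g$regions$gene_id,
                     mrna_level = c(2, 20, 200, 2000))
  f1 <- assemble_feature_table(g$regions, expr)
  f2 <- assemble_feature_table(g$regions, expr)
  expect_identical(f1$X, f2$X)
})

test_that("sentinel hybridization features are imputed with the column median", {
  g <- simulate_genes(4, seed = 34)
  reg <- g$regions
  # a TIR with no complementarity to the anti-SD probe (A/C only pairs
  # nothing in GATCACCTCCTTA except via G/T absent here)
  reg$tir_seq[1] <- strrep("A", 55)
  expr <- data.frame(gene_id = reg$gene_id, mrna_level = 10)
  expect_warning(ft <- assemble_feature_table(reg, expr), NA)
  others <- ft$X[-1, "exterior_loop_dg"]
  expect_equal(unname(ft$X[1, "exterior_loop_dg"]), median(others))
  expect_equal(unname(ft$X[1, "duplex_length"]), 0)
  expect_true("exterior_loop_dg" %in% names(ft$imputed))
})

test_that("duplicate gene ids and missing expression rows are handled", {
  g <- simulate_genes(3, seed = 35)
  expr <- data.frame(gene_id = g$regions$gene_id, mrna_level = 5)
  dup <- rbind(g$regions, g$regions[1, ])
  expect_error(assemble_feature_table(dup, expr), "duplicate")
  expect_warning(
    ft <- assemble_feature_table(g$regions, expr[-2, , drop = FALSE]),
    "without expression")
  expect_equal(length(ft$gene_ids), 2L)
})

test_that("an external initiation score column passes through", {
  g <- simulate_genes(3, seed = 36)
  expr <- data.frame(gene_id = g$regions$gene_id, mrna_level = 5)
  sc <- stats::setNames(c(1.5, -0.5, 0.25), g$regions$gene_id)
  ft <- assemble_feature_table(g$regions, expr, external_init_score = sc)
  expect_equal(unname(ft$X[, "external_init_score_passthrough"]),
               unname(sc))
})
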