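# Folding, hybridization and structure statistics against enumeration
# oracles under the shipped energy model.

test_that("sequences without complementarity fold to the empty structure", {
  s <- fold_mfe("AAAAAAAA")
  expect_equal(nrow(s$pairs), 0L)
  expect_equal(s$dg, 0)
  expect_equal(s$dot_bracket, "........")
})

test_that("a stable hairpin matches the enumeration minimum", {
  s <- fold_mfe("GGGAAAACCC")
  expect_equal(s$dot_bracket, "(((....)))")
  expect_equal(s$dg, oracle_mfe("GGGAAAACCC"))
})

test_that("no pair violates the minimum hairpin separation", {
  set.seed(5)
  for (i in 1:20) {
    s <- fold_mfe(random_dna(30))
    if (nrow(s$pairs)) {
      expect_true(all(s$pairs[, 2] - s$pairs[, 1] >= 4))
    }
  }
})

test_that("MFE is never positive and invariant under T/U relabeling", {
  set.seed(6)
  for (i in 1:15) {
    sq <- random_dna(25)
    s <- fold_mfe(sq)
    expect_lte(s$dg, 0)
    expect_equal(fold_mfe(gsub("T", "U", sq))$dg, s$dg)
  }
  expect_error(fold_mfe("ACGX"), "alphabet")
})

test_that("dynamic program equals exhaustive enumeration on short sequences", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(5:12, 1)
    sq <- random_dna(n)
    s <- fold_mfe(sq)
    expect_equal(s$dg, oracle_mfe(sq), tolerance = 1e-9, label = sq)
    # the reported structure scores to its reported energy
    expect_equal(score_structure(sq, s$pairs), s$dg, tolerance = 1e-9)
  }
})

test_that("a perfect duplex has full length and no exterior energy", {
  tgt <- "AAGGAGGT"
  h <- cofold_duplex(tgt, seq2abundance:::revcomp(tgt))
  expect_equal(h$duplex_length, 8L)
  expect_equal(h$dg_exterior, 0)
  expect_lt(h$dg_total, 0)
})

test_that("non-complementary strands give the sentinel hybrid", {
  h <- cofold_duplex("CCCCCCCC", "CCCCCCCC")
  expect_equal(h$duplex_length, 0L)
  expect_true(is.na(h$dg_total))
  expect_true(is.na(exterior_loop_energy(h)))
})

test_that("duplex energy equals the register/extension enumeration oracle", {
  set.seed(8)
  for (i in 1:6) {
    tgt <- paste0(random_dna(2), "AGGAG", random_dna(3))
    prb <- substr(anti_sd_probe(), 5, 11)   # CCTCCTT core
    h <- cofold_duplex(tgt, prb, max_gap = 2L)
    o <- oracle_duplex(tgt, prb, max_gap = 2L)
    if (h$duplex_length == 0L) expect_true(is.na(o)) else
      expect_equal(h$dg_total, o, tolerance = 1e-9)
  }
})

test_that("the anti-SD probe finds the SD tract inside a TIR", {
  set.seed(88)
  tir <- paste0(random_dna(8), "AGGAGG", random_dna(10))
  h <- cofold_duplex(tir, anti_sd_probe())
  expect_gte(h$duplex_length, 6L)
  expect_true(any(h$duplex_pairs[, "target"] %in% 9:14))
  expect_lt(h$dg_total, 0)
})

test_that("hybrid energies decompose exactly", {
  set.seed(9)
  model <- default_energy_model()
  for (i in 1:10) {
    h <- cofold_duplex(paste0(random_dna(6), "AGGAGG", random_dna(6)),
                       anti_sd_probe())
    if (h$duplex_length == 0L) next
    expect_equal(h$dg_total,
                 h$dg_duplex + h$dg_exterior + model$duplex_init,
                 tolerance = 1e-12)
    expect_equal(exterior_loop_energy(h), h$dg_exterior, tolerance = 1e-12)
  }
})

test_that("exterior loop energy is the sum of its dangle-table entries", {
  model <- default_energy_model()
  # GC closing pair with a single 5' dangling A on the target:
  # target ACCCC pairs its C-run against GGGG, leaving one upstream A
  h <- cofold_duplex("ACCCC", "GGGG", model)
  expect_equal(h$duplex_length, 4L)
  d1 <- seq2abundance:::dangle_energy(model, paste0("C", "G"), "A", "5p")
  expect_equal(h$dg_exterior, d1, tolerance = 1e-12)
  # two independent dangles add up
  h2 <- cofold_duplex("ACCCCA", "GGGG", model)
  d2 <- seq2abundance:::dangle_energy(model, paste0("C", "G"), "A", "3p")
  expect_equal(h2$dg_exterior, d1 + d2, tolerance = 1e-12)
})

test_that("structure statistics count unpaired bases within subregions", {
  s <- fold_mfe("GGGAAAACCC")
  st <- structure_statistics(s, c(4, 7))
  expect_equal(st$accessibility, 1.0)
  expect_equal(st$unpaired_count, 4L)
  expect_equal(st$dg, s$dg)
  stem <- structure_statistics(s, c(1, 3))
  expect_equal(stem$accessibility, 0.0)
  un <- fold_mfe("AAAAAAAA")
  expect_equal(structure_statistics(un, c(1, 8))$accessibility, 1.0)
  expect_equal(structure_statistics(un, c(1, 8))$unpaired_count, 8L)
  expect_error(structure_statistics(s, c(7, 4)), "subregion")
})

test_that("energy model tables load completely from TSV", {
  m <- read_energy_model()
  expect_equal(length(m$stack_table), 36L)
  expect_gte(m$min_hairpin, 3L)
  expect_true(all(m$stack_table < 0))
  expect_true(all(m$hairpin_penalty > 0))
})
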