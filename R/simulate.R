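# Seeded synthetic-data generator: genomes whose codon bias and
# Shine-Dalgarno motif strength covary with a latent expression level,
# log-scale mRNA abundance, protein abundance realized as a stated linear
# combination of the *realized* standardized sequence features plus noise,
# and per-gene CoV following an inverse-mean scaling law with planted
# gene-specific offsets. All draws derive from one master seed; ground
# truth is returned for recovery tests.

#' Default ground-truth coefficients
#'
#' 16 active predictors: a dominant mRNA effect (0.55), CAI (0.25), one
#' initiation feature (exterior-loop energy of the 16S:SD hybrid, +0.10)
#' and 13 codon/amino-acid effects with |beta| in 0.12..0.15. The set is
#' chosen for identifiability: at most one active codon per synonymous
#' family, and active amino acids only from 4- and 6-codon families
#' without an active codon, so no active predictor has a near-collinear
#' twin among the null features (an aliased active could otherwise be
#' replaced by its proxy during feature selection with no loss of fit;
#' the amino-acid frequency of a 2-codon family is the exact sum of its
#' two codon frequencies, making such actives structurally ambiguous).
#' @return Named numeric vector (standardized-predictor scale).
#' @export
default_true_beta <- function() {
  c(mrna_level = 0.55, cai = 0.25, exterior_loop_dg = 0.12,
    codon_ATC = 0.15, codon_GAA = 0.14, codon_GGT = 0.14,
    codon_CGG = -0.14, codon_TCA = -0.13, codon_ACC = -0.15,
    codon_TGT = -0.13, codon_AAA = 0.14, codon_AAC = -0.12,
    aa_Leu = 0.15, aa_Ala = -0.14, aa_Pro = -0.12, aa_Val = 0.14)
}

#' Dominant-mRNA ground-truth coefficients
#'
#' The configuration used to study the expression-profile and noise
#' patterns: transcript level dominates (beta 0.7) and the translation
#' features act in concert at small effect sizes (|beta| <= 0.1), so the
#' mRNA group carries the largest part of the explained variance, as in
#' the transcript-dominated regime of real expression data.
#' @return Named numeric vector (standardized-predictor scale).
#' @export
dominant_mrna_beta <- function() {
  beta <- default_true_beta()
  beta["mrna_level"] <- 0.7
  beta[names(beta) != "mrna_level"] <-
    sign(beta[names(beta) != "mrna_level"]) * 0.1
  beta
}

#' Simulate gene sequences with expression-coupled composition
#'
#' Per gene: a latent expression level `e ~ N(0, 1)`; CDS codons drawn
#' from a mixture `(1 - m) * uniform-synonymous + m * preferred-codon`
#' with `m = logistic(e + codon_mix_noise * u)`, `u ~ N(0, 1)`
#' independent, so CAI covaries with `e` while codon usage retains
#' variation independent of amino-acid composition; a TIR whose upstream
#' part carries an SD hexamer sampled from the PWM at a spacing drawn
#' from 4..12 nt with random flanks. Genes are laid out on one contig
#' (both strands) with intergenic spacers, so the output round-trips
#' through region extraction, and every gene passes
#' [screen_aberrant_genes()] by construction.
#'
#' @param n Number of genes.
#' @param seed Master seed.
#' @param length_mean,length_sd,length_range Protein length distribution
#'   (codons, stop excluded); defaults 250 +/- 70, clamped to 60..500.
#' @param aa_tilt SD of the per-gene log-normal tilt of amino-acid
#'   propensities (default 0.35).
#' @param codon_mix_noise SD of the latent-independent component of the
#'   codon-bias mixture (default 0.8).
#' @param family_mix_noise SD of the per-synonymous-family component of
#'   the mixture (default 0.8); genes favor different synonyms, so codon
#'   usage is not a deterministic function of amino-acid composition.
#' @param pwm SD matrix used for motif sampling.
#' @param cai_weights Codon weight table defining the preferred codons.
#' @return List: `genome` (contigs/annotations/topology, as from
#'   [load_annotated_genome()]), `regions` (data.frame), `latent`
#'   (named numeric), `seed`.
#' @export
simulate_genes <- function(n, seed = 1L, length_mean = 250, length_sd = 70,
                           length_range = c(60L, 500L), aa_tilt = 0.35,
                           codon_mix_noise = 0.8, family_mix_noise = 1.0,
                           pwm = default_sd_pwm(),
                           cai_weights = default_cai_weights()) {
  stopifnot(n >= 1L)
  sc <- sense_codons()
  aa_of <- codon_to_aa(sc)
  fam <- split(sc, aa_of)
  preferred <- vapply(fam, function(f) f[which.max(cai_weights$w[f])],
                      character(1))
  aa_levels <- names(AA_THREE)

  with_seed(seed, {
    e <- stats::rnorm(n)
    ids <- sprintf("sg%04d", seq_len(n))
    names(e) <- ids
    cassettes <- character(n)
    strands <- character(n)
    genes <- vector("list", n)
    for (g in seq_len(n)) {
      len <- round(stats::rnorm(1, length_mean, length_sd))
      len <- max(length_range[1L], min(length_range[2L], len))
      # per-gene amino-acid propensities (log-normal tilt of a uniform base)
      wa <- exp(aa_tilt * stats::rnorm(20L))
      aas <- sample(aa_levels, len - 1L, replace = TRUE, prob = wa / sum(wa))
      # per-family mixture strength: shared latent component plus
      # family-specific variation (genes favor different synonyms)
      mfam <- stats::plogis(e[g] + codon_mix_noise * stats::rnorm(1) +
                              family_mix_noise * stats::rnorm(length(fam)))
      names(mfam) <- names(fam)
      codons <- vapply(aas, function(a) {
        f <- fam[[a]]
        if (stats::runif(1) < mfam[[a]]) preferred[[a]] else sample(f, 1L)
      }, character(1))
      start <- sample(c("ATG", "GTG", "TTG"), 1L, prob = c(0.85, 0.10, 0.05))
      stopc <- sample(STOP_CODONS, 1L, prob = c(0.6, 0.1, 0.3))
      cds <- paste0(start, paste(codons, collapse = ""), stopc)
      # upstream 25 nt: AT-rich flanks with an SD motif at spacing 4..12
      up <- sample(DNA_BASES, 25L, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3))
      motif <- vapply(seq_len(pwm$length), function(pos) {
        sample(DNA_BASES, 1L, prob = pwm$freq[, pos])
      }, character(1))
      spacing <- sample(4:12, 1L)
      mstart <- 25L - spacing - pwm$length + 1L
      up[seq.int(mstart, mstart + pwm$length - 1L)] <- motif
      cassettes[g] <- paste0(paste(up, collapse = ""), cds)
      strands[g] <- sample(c("+", "-"), 1L, prob = c(0.7, 0.3))
      genes[[g]] <- list(id = ids[g], cds_len = nchar(cds))
    }
    spacers <- vapply(seq_len(n + 1L), function(i) {
      paste(sample(DNA_BASES, 30L + sample.int(40L, 1L), replace = TRUE),
            collapse = "")
    }, character(1))

    contig <- spacers[1L]
    ann <- vector("list", n)
    for (g in seq_len(n)) {
      cass <- cassettes[g]
      cds_len <- genes[[g]]$cds_len
      if (strands[g] == "+") {
        start <- nchar(contig) + 25L + 1L
        contig <- paste0(contig, cass)
        ann[[g]] <- data.frame(gene_id = genes[[g]]$id, start = start,
                               end = start + cds_len - 1L, strand = "+",
                               contig_id = "synthetic_contig_1",
                               stringsAsFactors = FALSE)
      } else {
        rc <- revcomp(cass)
        start <- nchar(contig) + 1L
        contig <- paste0(contig, rc)
        ann[[g]] <- data.frame(gene_id = genes[[g]]$id, start = start,
                               end = start + cds_len - 1L, strand = "-",
                               contig_id = "synthetic_contig_1",
                               stringsAsFactors = FALSE)
      }
      contig <- paste0(contig, spacers[g + 1L])
    }
    genome <- list(contigs = c(synthetic_contig_1 = contig),
                   annotations = do.call(rbind, ann),
                   topology = "linear")
    regions <- extract_regions_table(genome)
    list(genome = genome, regions = regions, latent = e, seed = seed)
  })
}

#' Simulate expression from realized features
#'
#' Realizes the linear model: `z(log10 protein) = sum_i beta_i xz_i +
#' eps`, `eps ~ N(0, noise_sd)`, where `xz` are the z-scored *realized*
#' features of the generated sequences (so feature extraction is on the
#' tested path). Protein means are mapped back to molecules/cell on a
#' log10 scale chosen so abundances span roughly 1..10^4.
#'
#' @param features A `feature_table` (must already carry `mrna_level`).
#' @param true_beta Named coefficients over feature columns.
#' @param noise_sd Residual noise SD on the standardized response.
#' @param seed Seed for the noise draw.
#' @param protein_log_mean,protein_log_sd Location/scale mapping the
#'   standardized response to log10 molecules/cell (defaults 1.7 and
#'   0.8, spanning roughly 1..10^4 molecules/cell).
#' @return List: `expression` (data.frame gene_id, mrna_level,
#'   protein_mean), `yz` (standardized response), `ground_truth` (list:
#'   true_beta, active_set, noise_sd, population_r2, seed).
#' @export
simulate_expression <- function(features, true_beta = default_true_beta(),
                                noise_sd = 0.55, seed = 1L,
                                protein_log_mean = 1.7,
                                protein_log_sd = 0.8) {
  X <- features$X
  if (any(!names(true_beta) %in% colnames(X))) {
    stop("unknown predictor in true_beta: ",
         setdiff(names(true_beta), colnames(X))[1], call. = FALSE)
  }
  Xz <- standardize(X[, names(true_beta), drop = FALSE])$Xz
  signal <- drop(Xz %*% true_beta)
  eps <- with_seed(seed + 1L, stats::rnorm(nrow(X), 0, noise_sd))
  yz <- signal + eps
  protein_mean <- 10^(protein_log_mean + protein_log_sd * yz)
  expression <- data.frame(
    gene_id = features$gene_ids,
    mrna_level = 10^X[, "mrna_level"],
    protein_mean = protein_mean,
    stringsAsFactors = FALSE)
  var_sig <- stats::var(signal)
  list(expression = expression, yz = yz,
       ground_truth = list(
         true_beta = true_beta,
         active_set = names(true_beta)[true_beta != 0],
         noise_sd = noise_sd,
         population_r2 = var_sig / (var_sig + noise_sd^2),
         seed = seed))
}

#' Simulate per-gene single-cell noise
#'
#' CoV follows an inverse-mean scaling law plus gene-specific offsets:
#' `CoV = sqrt(a / mu + c0) + delta`, with `delta` nonzero only for the
#' planted genes; `variance = (CoV * mu)^2`.
#'
#' @param protein_means Named positive vector (molecules/cell).
#' @param cov_law List with `a`, `c0` (law parameters, >= 0) and
#'   `planted_offsets` (named numeric, defaults empty).
#' @param seed Unused draws are reserved; kept for interface symmetry.
#' @return data.frame: gene_id, mean, variance, cov, delta.
#' @export
simulate_noise_profile <- function(protein_means,
                                   cov_law = list(a = 1, c0 = 0.1,
                                                  planted_offsets = NULL),
                                   seed = 1L) {
  stopifnot(all(protein_means > 0))
  if (cov_law$a < 0 || cov_law$c0 < 0) {
    stop("negative noise-law parameters", call. = FALSE)
  }
  ids <- names(protein_means) %||% as.character(seq_along(protein_means))
  delta <- stats::setNames(numeric(length(ids)), ids)
  po <- cov_law$planted_offsets
  if (!is.null(po)) delta[names(po)] <- po
  cov <- sqrt(cov_law$a / protein_means + cov_law$c0) + delta
  data.frame(gene_id = ids, mean = unname(protein_means),
             variance = unname((cov * protein_means)^2),
             cov = unname(cov), delta = unname(delta),
             stringsAsFactors = FALSE)
}

#' Generate the default synthetic bundle
#'
#' One master seed drives genome simulation, feature assembly, the
#' expression model and the noise profile. The planted noisy subgroup
#' (fraction `planted_frac`, offset `planted_delta` on the CoV) is the
#' set of genes with the largest `translation-signal minus mRNA` score,
#' emulating the association of excess noise with low transcription and
#' high translation efficiency.
#'
#' @param n Number of genes (default 800).
#' @param seed Master seed.
#' @param true_beta,noise_sd Expression-model parameters.
#' @param planted_frac Fraction of genes given a CoV offset (default
#'   0.10).
#' @param planted_delta Offset on the CoV scale (default 0.3).
#' @param cov_scatter_sd SD of the symmetric gene-specific CoV offset
#'   carried by every gene (default 0.05), emulating the biological and
#'   measurement scatter of single-cell noise around the scaling law.
#' @param mrna_latent_slope,mrna_noise_sd log10 mRNA model: `1 + slope *
#'   e + sd * N(0,1)`.
#' @return List of class `synthetic_bundle`: `genome`, `regions`,
#'   `features` (feature_table), `expression`, `yz`, `noise`,
#'   `ground_truth`.
#' @export
simulate_bundle <- function(n = 800L, seed = 1L,
                            true_beta = default_true_beta(),
                            noise_sd = 0.55,
                            planted_frac = 0.10, planted_delta = 0.3,
                            cov_scatter_sd = 0.05,
                            mrna_latent_slope = 0.45, mrna_noise_sd = 0.35) {
  genes <- simulate_genes(n, seed = seed)
  e <- genes$latent[genes$regions$gene_id]
  mrna_log10 <- with_seed(seed + 2L,
                          1 + mrna_latent_slope * e +
                            mrna_noise_sd * stats::rnorm(length(e)))
  expr0 <- data.frame(gene_id = names(e), mrna_level = 10^mrna_log10,
                      stringsAsFactors = FALSE)
  ft <- assemble_feature_table(genes$regions, expr0)
  sim <- simulate_expression(ft, true_beta = true_beta, noise_sd = noise_sd,
                             seed = seed)

  # plant the noisy subgroup where translation signal is high and mRNA low
  Xz <- standardize(ft$X[, names(true_beta), drop = FALSE])$Xz
  tx_cols <- names(true_beta)[names(true_beta) == "mrna_level"]
  te_cols <- setdiff(names(true_beta), tx_cols)
  te_sig <- drop(Xz[, te_cols, drop = FALSE] %*% true_beta[te_cols])
  tx_sig <- drop(Xz[, tx_cols, drop = FALSE] %*% true_beta[tx_cols])
  score <- zscore(te_sig) - zscore(tx_sig)
  n_plant <- round(planted_frac * nrow(Xz))
  planted <- ft$gene_ids[order(score, decreasing = TRUE)[seq_len(n_plant)]]
  # every gene carries a small symmetric offset around the scaling law;
  # the planted subgroup gets the large excess-noise offset on top
  po <- with_seed(seed + 3L,
                  stats::setNames(stats::rnorm(length(ft$gene_ids), 0,
                                               cov_scatter_sd),
                                  ft$gene_ids))
  po[planted] <- po[planted] + planted_delta

  pm <- stats::setNames(sim$expression$protein_mean, sim$expression$gene_id)
  noise <- simulate_noise_profile(pm, cov_law = list(a = 1, c0 = 0.1,
                                                     planted_offsets = po),
                                  seed = seed)
  gt <- sim$ground_truth
  gt$latent_expression <- e
  gt$cov_law <- list(a = 1, c0 = 0.1, planted_offsets = po)
  gt$planted <- planted
  gt$master_seed <- seed
  structure(list(genome = genes$genome, regions = genes$regions,
                 features = ft, expression = sim$expression, yz = sim$yz,
                 noise = noise, ground_truth = gt),
            class = "synthetic_bundle")
}

#' Write a bundle's genome as FASTA + GFF3 and tables as TSV/JSON
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(bundle$genome$contigs)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fasta"))
  ann <- bundle$genome$annotations
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig_id,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand, type = "CDS", ID = ann$gene_id,
    locus_tag = ann$gene_id, phase = 0L)
  rtracklayer::export(gr, file.path(dir, "annotations.gff3"),
                      format = "gff3")
  utils::write.table(merge(bundle$expression, bundle$noise[, c("gene_id", "variance", "cov")],
                           by = "gene_id"),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
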