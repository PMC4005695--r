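# The 107-feature catalogue and design-table assembly.
#
# 16 TIR features (Shine-Dalgarno motif score/position/spacing, 16S:SD
# hybridization energetics, TIR folding/accessibility, start-codon
# identity, an external initiation-score pass-through) plus 91 CDS
# features (61 codon frequencies, 20 amino-acid frequencies, CAI, tAI,
# AT/A/GC/GC3 content, protein length, 3 stop-codon indicators). With the
# log10 mRNA level the design table has 108 predictor columns.

TIR_FEATURES <- c(
  "sd_best_score", "sd_best_position", "sd_start_spacing",
  "spacing_deviation_from_optimum", "hybrid_total_dg", "duplex_dg",
  "exterior_loop_dg", "duplex_length", "tir_fold_dg", "tir_accessibility",
  "tir_unpaired_count", "start_ATG", "start_GTG", "start_TTG",
  "sd_motif_count_above_threshold", "external_init_score_passthrough")

#' The fixed, versioned 107-feature manifest
#'
#' @return Character vector of the 107 sequence-feature names, TIR block
#'   first, then the CDS block.
#' @export
feature_manifest <- function() {
  cds <- c(paste0("codon_", sense_codons()),
           paste0("aa_", unname(AA_THREE)),
           "cai", "tai", "AT_content", "A_content", "GC_content",
           "GC3_content", "protein_length", "stop_TAA", "stop_TAG",
           "stop_TGA")
  c(TIR_FEATURES, cds)
}

#' Group labels (mRNA/TIR/CDS) for all 108 predictors
#' @return Named character vector over `feature_manifest()` plus
#'   `mrna_level`.
#' @export
feature_groups <- function() {
  man <- feature_manifest()
  g <- ifelse(man %in% TIR_FEATURES, "TIR", "CDS")
  c(stats::setNames(g, man), mrna_level = "mRNA")
}

#' Compute the TIR + CDS feature vector for one gene
#' @noRd
gene_features <- function(regions, pwm, cai_w, tai_w, model, anti_sd,
                          accessibility_window = c(-4L, 16L),
                          optimal_spacing = 7L, sd_threshold = 0) {
  tir <- regions$tir_seq
  sd <- score_sd_motif(tir, pwm)
  hyb <- cofold_duplex(tir, anti_sd, model)
  ext <- exterior_loop_energy(hyb, model)
  fold <- fold_mfe(tir, model)
  # accessibility window in TIR coordinates (-25..+30, no 0)
  aw <- accessibility_window
  idx <- vapply(aw, function(k) if (k < 0) 25L + 1L + k else 25L + k,
                integer(1))
  st <- structure_statistics(fold, idx)
  tirf <- c(
    sd_best_score = sd$best_score,
    sd_best_position = sd$best_offset,
    sd_start_spacing = sd$spacing,
    spacing_deviation_from_optimum = abs(sd$spacing - optimal_spacing),
    hybrid_total_dg = hyb$dg_total,
    duplex_dg = hyb$dg_duplex,
    exterior_loop_dg = ext,
    duplex_length = as.numeric(hyb$duplex_length),
    tir_fold_dg = fold$dg,
    tir_accessibility = st$accessibility,
    tir_unpaired_count = as.numeric(st$unpaired_count),
    start_ATG = as.numeric(regions$start_codon == "ATG"),
    start_GTG = as.numeric(regions$start_codon == "GTG"),
    start_TTG = as.numeric(regions$start_codon == "TTG"),
    sd_motif_count_above_threshold = as.numeric(sd$n_above),
    external_init_score_passthrough = 0)
  c(tirf, composition_features(regions),
    cai = cai(regions$cds_seq, cai_w),
    tai = tai(regions$cds_seq, tai_w))
}

#' Assemble the genes x (107 features + mRNA level) design table
#'
#' Computes all 107 sequence features per gene, appends `mrna_level`
#' (log10 transcript abundance) and imputes not-available hybridization
#' features (sentinel: no stable 16S:SD duplex) with the column median of
#' the remaining genes.
#'
#' @param genes data.frame of gene regions ([extract_regions_table()]).
#' @param expression data.frame with `gene_id`, `mrna_level` (linear
#'   scale, > 0) and optionally `protein_mean`, `protein_variance`.
#' @param pwm,cai_weights,tai_weights,energy_model,anti_sd Parameter
#'   tables; package defaults used when omitted.
#' @param external_init_score Optional named vector of pass-through
#'   initiation-rate scores per gene (defaults to 0).
#' @param ... Passed to the per-gene feature computation (accessibility
#'   window, optimal spacing, SD score threshold).
#' @return Object of class `feature_table`: `gene_ids`, `X` (numeric
#'   matrix, 108 columns), `group_of`, `manifest`, `imputed` (log of
#'   imputed cells).
#' @export
assemble_feature_table <- function(genes, expression,
                                   pwm = default_sd_pwm(),
                                   cai_weights = default_cai_weights(),
                                   tai_weights = default_tai_weights(),
                                   energy_model = default_energy_model(),
                                   anti_sd = anti_sd_probe(),
                                   external_init_score = NULL, ...) {
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_ids in regions table", call. = FALSE)
  }
  has_expr <- genes$gene_id %in% expression$gene_id
  if (any(!has_expr)) {
    warning("skipping ", sum(!has_expr), " gene(s) without expression rows",
            call. = FALSE)
    genes <- genes[has_expr, , drop = FALSE]
  }
  expr <- expression[match(genes$gene_id, expression$gene_id), , drop = FALSE]
  if (any(expr$mrna_level <= 0)) {
    stop("nonpositive mRNA level for gene ",
         expr$gene_id[expr$mrna_level <= 0][1], call. = FALSE)
  }

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gene_features(genes[i, ], pwm, cai_weights, tai_weights, energy_model,
                  anti_sd, ...)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- genes$gene_id

  man <- feature_manifest()
  X <- X[, man, drop = FALSE]
  if (!is.null(external_init_score)) {
    v <- external_init_score[genes$gene_id]
    v[is.na(v)] <- 0
    X[, "external_init_score_passthrough"] <- as.numeric(v)
  }

  imputed <- list()
  hyb_cols <- c("hybrid_total_dg", "duplex_dg", "exterior_loop_dg")
  for (cn in hyb_cols) {
    na <- is.na(X[, cn])
    if (any(na)) {
      med <- stats::median(X[!na, cn])
      if (is.na(med)) med <- 0
      X[na, cn] <- med
      imputed[[cn]] <- rownames(X)[na]
    }
  }

  X <- cbind(X, mrna_level = log10(expr$mrna_level))
  structure(list(gene_ids = genes$gene_id, X = X,
                 group_of = feature_groups(), manifest = man,
                 imputed = imputed),
            class = "feature_table")
}

#' Write a feature table as TSV plus a JSON sidecar
#'
#' The sidecar carries the manifest, group labels and imputation log.
#' @param ft A `feature_table`.
#' @param path TSV path; the sidecar is written as `<path>.json`.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(gene_id = ft$gene_ids, ft$X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(manifest = ft$manifest, group_of = as.list(ft$group_of),
         imputed = ft$imputed),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
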