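# Codon, amino-acid and nucleotide composition features of a CDS.

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' Composition features of one gene
#'
#' Emits 61 sense-codon relative frequencies (stop codon excluded; sum
#' 1), 20 amino-acid relative frequencies (sum 1), AT and A fractions of
#' the whole CDS, GC fraction, GC3 fraction (third codon positions of
#' sense codons), protein length (codons excluding stop) and three
#' stop-codon indicators.
#'
#' @param regions A `gene_regions` object or a list with `cds_seq` and
#'   `stop_codon`.
#' @return Named numeric vector of 61 + 20 + 4 + 1 + 3 = 89 features.
#' @export
composition_features <- function(regions) {
  cds <- normalize_seq(regions$cds_seq)
  codons <- split_codons(cds)
  stop_codon <- codons[length(codons)]
  sense <- codons[-length(codons)]
  sense <- sense[!sense %in% STOP_CODONS]
  sc <- sense_codons()

  codon_freq <- table(factor(sense, levels = sc)) / length(sense)
  aa <- codon_to_aa(sense)
  aa_freq <- table(factor(aa, levels = names(AA_THREE))) / length(aa)

  ch <- strsplit(cds, "", fixed = TRUE)[[1]]
  third <- substring(sense, 3L, 3L)

  out <- c(
    stats::setNames(as.numeric(codon_freq), paste0("codon_", sc)),
    stats::setNames(as.numeric(aa_freq),
                    paste0("aa_", AA_THREE[names(AA_THREE)])),
    AT_content = mean(ch %in% c("A", "T")),
    A_content = mean(ch == "A"),
    GC_content = mean(ch %in% c("G", "C")),
    GC3_content = mean(third %in% c("G", "C")),
    protein_length = length(sense),
    stop_TAA = as.numeric(stop_codon == "TAA"),
    stop_TAG = as.numeric(stop_codon == "TAG"),
    stop_TGA = as.numeric(stop_codon == "TGA"))
  out
}
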