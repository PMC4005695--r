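# Codon adaptation index (CAI) and tRNA adaptation index (tAI).

#' Relative adaptiveness from reference codon counts
#'
#' Within each synonymous family, w(c) = count(c) / max count in the
#' family; zero counts are floored at 0.01 so the geometric mean stays
#' defined.
#'
#' @param reference_codon_counts Named integer vector over the 61 sense
#'   codons (zeros allowed).
#' @return A codon weight table: list with `w` (named numeric in (0, 1])
#'   and `source = "cai"`.
#' @export
relative_adaptiveness <- function(reference_codon_counts) {
  if (length(reference_codon_counts) == 0L) stop("empty reference",
                                                 call. = FALSE)
  sc <- sense_codons()
  counts <- stats::setNames(numeric(length(sc)), sc)
  nm <- normalize_seq(names(reference_codon_counts))
  counts[nm] <- as.numeric(reference_codon_counts)
  aa <- codon_to_aa(sc)
  w <- unlist(lapply(split(counts, aa), function(fam) {
    mx <- max(fam)
    if (mx == 0) return(stats::setNames(rep(0.01, length(fam)), names(fam)))
    pmax(fam / mx, 0.01)
  }), use.names = TRUE)
  names(w) <- sub("^[^.]*\\.", "", names(w))
  list(w = w[sc], source = "cai")
}

#' Default CAI weights (E. coli)
#'
#' Relative-adaptiveness values for E. coli from `seqinr::caitab`
#' (the classical highly-expressed-gene reference set).
#' @return A codon weight table (`w`, `source = "cai"`).
#' @export
default_cai_weights <- function() {
  if (is.null(.s2a_cache$cai_w)) {
    caitab <- NULL
    utils::data("caitab", package = "seqinr", envir = environment())
    w <- stats::setNames(caitab$ec, toupper(rownames(caitab)))
    w <- pmax(w[sense_codons()], 0.01)
    .s2a_cache$cai_w <- list(w = w, source = "cai")
  }
  .s2a_cache$cai_w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness of a CDS's codons,
#' excluding the stop codon and the single-codon families (ATG, TGG).
#'
#' @param cds_seq CDS string (length divisible by 3).
#' @param weights Codon weight table (see [relative_adaptiveness()]).
#' @return CAI in (0, 1].
#' @export
cai <- function(cds_seq, weights = default_cai_weights()) {
  codons <- split_codons(normalize_seq(cds_seq))
  if (codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  codons <- codons[!codons %in% c("ATG", "TGG", STOP_CODONS)]
  if (length(codons) == 0L) {
    stop("CDS contains only excluded codons; CAI undefined", call. = FALSE)
  }
  exp(mean(log(weights$w[codons])))
}

#' tAI weights from tRNA gene copy numbers
#'
#' dos Reis-style weights: for each codon, W = (1 - s_wc) * n(WC
#' anticodon) + (1 - s_wobble) * n(wobble anticodon), with the standard
#' wobble-penalty constants (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68),
#' then normalized to max 1; codons with no decoding tRNA are floored at
#' 0.01.
#'
#' @param copies Named numeric vector, anticodon (DNA alphabet, 5'->3')
#'   to gene copy number. Defaults to the shipped E. coli K-12 consensus
#'   table.
#' @return A codon weight table (`w`, `source = "tai"`).
#' @export
tai_weights_from_copies <- function(copies = default_trna_copies()) {
  sc <- sense_codons()
  nm <- normalize_seq(names(copies))
  cn <- function(ac) if (ac %in% nm) sum(copies[nm == ac]) else 0
  s <- c(TG = 0.41, IC = 0.28, IA = 0.9999, UG = 0.68) # wobble penalties
  W <- vapply(sc, function(codon) {
    wc <- revcomp(codon)                       # Watson-Crick anticodon
    b3 <- substr(codon, 3L, 3L)
    rest <- substr(wc, 2L, 3L)
    wob <- switch(b3,
      "T" = list(ac = paste0("G", rest), s = s[["TG"]]),   # G34 reads U
      "C" = list(ac = paste0("A", rest), s = s[["IC"]]),   # I(A34) reads C
      "A" = list(ac = paste0("A", rest), s = s[["IA"]]),   # I(A34) reads A
      "G" = list(ac = paste0("T", rest), s = s[["UG"]]))   # U34 reads G
    cn(wc) + (1 - wob$s) * cn(wob$ac)
  }, numeric(1))
  w <- W / max(W)
  list(w = pmax(w, 0.01), source = "tai")
}

#' Default tRNA gene copy numbers
#' @return Named numeric vector (anticodon to copy number).
#' @export
default_trna_copies <- function() {
  tab <- utils::read.delim(system.file("extdata",
                                       "trna_copy_numbers_default.tsv",
                                       package = "seq2abundance"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$copies, tab$anticodon)
}

#' Default tAI weights (cached)
#' @return A codon weight table (`w`, `source = "tai"`).
#' @export
default_tai_weights <- function() {
  if (is.null(.s2a_cache$tai_w)) {
    .s2a_cache$tai_w <- tai_weights_from_copies()
  }
  .s2a_cache$tai_w
}

#' tRNA adaptation index
#'
#' Geometric mean of tAI weights over all sense codons of the CDS
#' (stop codon excluded).
#'
#' @param cds_seq CDS string.
#' @param tai_weights Codon weight table from
#'   [tai_weights_from_copies()].
#' @return tAI in (0, 1].
#' @export
tai <- function(cds_seq, tai_weights = default_tai_weights()) {
  codons <- split_codons(normalize_seq(cds_seq))
  codons <- codons[!codons %in% STOP_CODONS]
  if (length(codons) == 0L) stop("no sense codons; tAI undefined",
                                 call. = FALSE)
  exp(mean(log(tai_weights$w[codons])))
}
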