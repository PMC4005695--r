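# Internal helpers shared across modules.
#
# Coordinate convention (used everywhere): external formats (GenBank, GFF3)
# are 1-based inclusive; internal substring arithmetic is done with base R's
# 1-based substr on plain uppercase DNA strings (U is normalized to T on
# input).

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' @noRd
check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("invalid %s alphabet (only A/C/G/T/U allowed): %s",
                 what, substr(x[bad][1], 1, 40)), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, "", fixed = TRUE),
                                function(ch) paste(rev(ch), collapse = ""),
                                character(1)))
}

#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3", call. = FALSE)
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
sense_codons <- function() {
  all <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                           stringsAsFactors = FALSE)[, 3:1], 1L,
               paste, collapse = "")
  sort(setdiff(all, STOP_CODONS))
}

#' @noRd
codon_to_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# Run an expression under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Population z-score (divide by n, not n-1); the convention used for all
# standardization in this package.
#' @noRd
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @noRd
zscore <- function(x) {
  s <- pop_sd(x)
  if (s <= 0) stop("zero-variance vector in z-score", call. = FALSE)
  (x - mean(x)) / s
}
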