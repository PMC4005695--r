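# Position weight matrix scanning for the Shine-Dalgarno motif.

#' Construct a position weight matrix
#'
#' @param mat 4 x L numeric matrix, rows named A, C, G, T; counts or
#'   frequencies (columns of a frequency matrix sum to 1).
#' @param background Length-4 background probabilities (A, C, G, T).
#' @param pseudocount Added to each cell before normalization. Defaults
#'   to 0.5 for count input, 0 for frequency input.
#' @return Object of class `pwm` with a `freq` matrix, `background` and
#'   the log2-odds `score_mat`.
#' @export
pwm <- function(mat, background = rep(0.25, 4), pseudocount = NULL) {
  stopifnot(nrow(mat) == 4L, ncol(mat) >= 1L)
  mat <- mat[DNA_BASES, , drop = FALSE]
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1",
                                            call. = FALSE)
  is_freq <- all(abs(colSums(mat) - 1) < 1e-6)
  if (is.null(pseudocount)) pseudocount <- if (is_freq) 0 else 0.5
  freq <- sweep(mat + pseudocount, 2L, colSums(mat) + 4 * pseudocount, "/")
  score_mat <- log2(sweep(freq, 1L, background, "/"))
  structure(list(freq = freq, background = background,
                 pseudocount = pseudocount, score_mat = score_mat,
                 length = ncol(mat)),
            class = "pwm")
}

#' Read a PWM from a tab table
#'
#' Expects a column `base` (A/C/G/T) followed by one column per motif
#' position.
#' @param path TSV path; defaults to the shipped SD matrix.
#' @param ... Passed to [pwm()].
#' @return A `pwm`.
#' @export
read_pwm <- function(path = system.file("extdata", "sd_pwm_default.tsv",
                                        package = "seq2abundance"), ...) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  pwm(mat, ...)
}

#' Default Shine-Dalgarno PWM
#' @return A `pwm` (cached).
#' @export
default_sd_pwm <- function() {
  if (is.null(.s2a_cache$sd_pwm)) .s2a_cache$sd_pwm <- read_pwm()
  .s2a_cache$sd_pwm
}

#' Scan a TIR for the Shine-Dalgarno motif
#'
#' Slides the PWM over the upstream part of the TIR (positions -25..-1 by
#' default; position +1 is the first base of the start codon, there is no
#' position 0) and scores each offset as the sum of per-position log2
#' odds against the background.
#'
#' @param tir_seq 55-nt TIR string.
#' @param pwm A `pwm`.
#' @param scan_window TIR coordinates `c(from, to)` within -25..-1.
#' @param tir_upstream Number of upstream bases in the TIR (default 25).
#' @param score_threshold Threshold (bits) above which an offset counts
#'   towards `n_above`.
#' @return List: `best_score` (bits), `best_offset` (TIR coordinate of
#'   the best motif start, negative), `spacing` (nt between the motif's
#'   last base and the start codon's first base) and `n_above`.
#' @export
score_sd_motif <- function(tir_seq, pwm = default_sd_pwm(),
                           scan_window = c(-25L, -1L), tir_upstream = 25L,
                           score_threshold = 0) {
  tir_seq <- normalize_seq(tir_seq)
  check_alphabet(tir_seq, "TIR")
  L <- pwm$length
  # TIR coordinate -k maps to string index tir_upstream + 1 - k
  from_idx <- scan_window[1L] + tir_upstream + 1L
  to_idx <- scan_window[2L] + tir_upstream + 1L
  if (to_idx - from_idx + 1L < L) stop("scan window shorter than motif",
                                       call. = FALSE)
  starts <- seq.int(from_idx, to_idx - L + 1L)
  ch <- strsplit(tir_seq, "", fixed = TRUE)[[1]]
  rows <- match(ch, DNA_BASES)
  scores <- vapply(starts, function(st) {
    sum(pwm$score_mat[cbind(rows[st:(st + L - 1L)], seq_len(L))])
  }, numeric(1))
  best <- which.max(scores)
  start_idx <- starts[best]
  best_offset <- start_idx - tir_upstream - 1L           # TIR coordinate
  end_idx <- start_idx + L - 1L
  spacing <- tir_upstream - end_idx                      # nt to start codon
  list(best_score = scores[best], best_offset = best_offset,
       spacing = spacing, n_above = sum(scores > score_threshold))
}
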