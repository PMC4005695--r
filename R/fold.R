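# Minimum-free-energy folding of a single RNA under the simplified
# nearest-neighbor model. Structure energy is the sum of stacking terms
# over adjacent pairs plus a length-dependent penalty per hairpin loop;
# pairs that neither stack nor close a hairpin contribute 0 (no multiloop
# or interior-loop penalties). The empty structure (energy 0) is always
# admissible, so the MFE is never positive.

#' Score an explicit nested structure
#'
#' Computes the energy of a given set of pairs directly from the model
#' definition (independent of the dynamic program); used as scoring core
#' and by enumeration-based checks.
#'
#' @param seq Nucleotide string.
#' @param pairs Two-column matrix of pair indices (i < j), possibly empty.
#' @param model An `energy_model`.
#' @return Energy in kcal/mol.
#' @export
score_structure <- function(seq, pairs, model = default_energy_model()) {
  if (is.null(pairs) || NROW(pairs) == 0L) return(0)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  paired <- logical(length(s))
  paired[c(pairs)] <- TRUE
  key <- paste(pairs[, 1L], pairs[, 2L])
  has_pair <- function(i, j) paste(i, j) %in% key
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    inner <- if (j - i >= 2L) seq.int(i + 1L, j - 1L) else integer()
    if (!any(paired[inner])) {
      e <- e + hairpin_energy(model, j - i - 1L)
    }
    if (has_pair(i + 1L, j - 1L)) {
      e <- e + stack_energy(model, paste0(s[i], s[j]),
                            paste0(s[i + 1L], s[j - 1L]))
    }
  }
  e
}

#' Fold a sequence to its minimum-free-energy nested structure
#'
#' Dynamic program over all nested (pseudoknot-free) structures under the
#' model's stacking + hairpin-penalty energy. Watson-Crick and GU pairs
#' are allowed; a pair (i, j) requires j - i >= min_hairpin + 1. Lonely
#' pairs are allowed.
#'
#' @param seq Nucleotide string (A/C/G/T/U).
#' @param model An `energy_model`.
#' @return Object of class `secondary_structure`: `sequence`, `pairs`
#'   (2-column matrix), `dg` (kcal/mol, <= 0), `dot_bracket`.
#' @export
fold_mfe <- function(seq, model = default_energy_model()) {
  seq <- normalize_seq(seq)
  check_alphabet(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  mh <- model$min_hairpin
  empty <- function() {
    structure(list(sequence = seq,
                   pairs = matrix(integer(), ncol = 2L,
                                  dimnames = list(NULL, c("i", "j"))),
                   dg = 0, dot_bracket = strrep(".", n)),
              class = "secondary_structure")
  }
  if (n < mh + 2L) return(empty())

  INF <- Inf
  V <- matrix(INF, n, n)   # best energy with (i, j) paired
  Wp <- matrix(INF, n, n)  # best nonempty structure on [i, j]
  Wm <- matrix(0, n, n)    # min(0, Wp): best structure incl. empty
  # integer pair codes and numeric lookup tables for speed
  pcode <- matrix(match(outer(s, s, paste0), CANONICAL_PAIRS), n, n)
  Smat <- matrix(model$stack_table[
    as.vector(outer(CANONICAL_PAIRS, CANONICAL_PAIRS,
                    function(a, b) paste0(a, ":", b)))], 6L, 6L)
  hp <- hairpin_energy(model, seq_len(n))
  w0 <- function(i, j) if (j <= i) 0 else Wm[i, j]

  for (d in seq.int(mh + 1L, n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      pc <- pcode[i, j]
      if (!is.na(pc)) {
        best <- hp[j - i - 1L]
        pin <- pcode[i + 1L, j - 1L]
        if (!is.na(pin) && is.finite(V[i + 1L, j - 1L])) {
          cand <- Smat[pc, pin] + V[i + 1L, j - 1L]
          if (cand < best) best <- cand
        }
        if (j - 1L > i + 1L && Wp[i + 1L, j - 1L] < best) {
          best <- Wp[i + 1L, j - 1L]
        }
        V[i, j] <- best
      }
      # rightmost top-level pair (k, j); j unpaired handled by Wp[i, j-1]
      best <- if (j - 1L > i) Wp[i, j - 1L] else INF
      ks <- seq.int(i, j - mh - 1L)
      vk <- V[ks, j]
      left <- if (length(ks) > 1L) c(0, Wm[i, ks[-1L] - 1L]) else 0
      cand <- suppressWarnings(min(vk + left))
      if (cand < best) best <- cand
      Wp[i, j] <- best
      if (best < 0) Wm[i, j] <- best
    }
  }

  dg <- w0(1L, n)
  if (dg >= 0) return(empty())

  # traceback
  tol <- 1e-9
  acc <- new.env(parent = emptyenv()); acc$p <- list()
  tb_V <- function(i, j) {
    acc$p[[length(acc$p) + 1L]] <- c(i, j)
    v <- V[i, j]
    if (abs(v - hairpin_energy(model, j - i - 1L)) < tol) return(invisible())
    if (is.finite(V[i + 1L, j - 1L])) {
      st <- stack_energy(model, paste0(s[i], s[j]),
                         paste0(s[i + 1L], s[j - 1L]))
      if (abs(v - (st + V[i + 1L, j - 1L])) < tol) return(tb_V(i + 1L, j - 1L))
    }
    tb_Wp(i + 1L, j - 1L)
  }
  tb_Wp <- function(i, j) {
    v <- Wp[i, j]
    if (j - 1L > i && is.finite(Wp[i, j - 1L]) &&
        abs(v - Wp[i, j - 1L]) < tol) {
      return(tb_Wp(i, j - 1L))
    }
    for (k in seq.int(i, j - mh - 1L)) {
      if (is.finite(V[k, j]) && abs(v - (w0(i, k - 1L) + V[k, j])) < tol) {
        tb_V(k, j)
        if (k - 1L > i && min(0, Wp[i, k - 1L]) < 0) tb_Wp2(i, k - 1L)
        return(invisible())
      }
    }
    stop("traceback failure", call. = FALSE) # nocov
  }
  tb_Wp2 <- function(i, j) { # W-context: only descend if nonempty part chosen
    if (abs(w0(i, j) - Wp[i, j]) < tol) tb_Wp(i, j)
  }
  tb_Wp2(1L, n)

  pairs <- do.call(rbind, acc$p)
  colnames(pairs) <- c("i", "j")
  db <- rep(".", n)
  db[pairs[, 1L]] <- "("
  db[pairs[, 2L]] <- ")"
  structure(list(sequence = seq, pairs = pairs, dg = dg,
                 dot_bracket = paste(db, collapse = "")),
            class = "secondary_structure")
}

#' Structure statistics over a subregion
#'
#' @param s A `secondary_structure`.
#' @param subregion Integer vector `c(from, to)`, 1-based inclusive
#'   positions within the sequence.
#' @return List with `unpaired_count` (unpaired positions in the whole
#'   structure), `accessibility` (fraction of unpaired positions within
#'   `subregion`) and `dg`.
#' @export
structure_statistics <- function(s, subregion) {
  n <- nchar(s$sequence)
  from <- subregion[1L]; to <- subregion[2L]
  if (from > to || from < 1L || to > n) {
    stop("empty or out-of-bounds subregion", call. = FALSE)
  }
  paired <- logical(n)
  if (NROW(s$pairs)) paired[c(s$pairs)] <- TRUE
  idx <- seq.int(from, to)
  list(unpaired_count = sum(!paired),
       accessibility = mean(!paired[idx]),
       dg = s$dg)
}
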