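# Bimolecular duplex between a target (e.g. a TIR) and a probe (e.g. the
# anti-Shine-Dalgarno tail of 16S rRNA). The duplex is a single
# intermolecular helix, antiparallel, with bulges/internal loops allowed
# and no intramolecular pairs. Energies: stacking between consecutive
# pairs, a per-loop opening penalty plus per-unpaired-base cost, dangling
# ends flanking the helix (the exterior loop), and a duplex initiation
# constant.

#' Anti-Shine-Dalgarno probe: 3' tail of E. coli 16S rRNA
#'
#' The 13 3'-terminal nucleotides, 5'-GAUCACCUCCUUA-3' (DNA alphabet).
#' @return Character scalar.
#' @export
anti_sd_probe <- function() "GATCACCTCCTTA"

#' Minimum-energy intermolecular duplex
#'
#' Finds the minimum-total-energy duplex between `target` and `probe`.
#' Consecutive pairs step antiparallel (target index up, probe index
#' down). If no duplex achieves a negative total energy, a sentinel with
#' `duplex_length = 0` and `NA` energies is returned.
#'
#' @param target,probe Nucleotide strings.
#' @param model An `energy_model`.
#' @param max_gap Largest bulge/internal-loop size per strand between
#'   consecutive pairs (default 4 nt).
#' @return Object of class `hybrid_structure`: `target`, `probe`,
#'   `duplex_pairs` (matrix of target/probe index pairs), `dg_total`,
#'   `dg_duplex`, `dg_exterior`, `duplex_length`.
#' @export
cofold_duplex <- function(target, probe, model = default_energy_model(),
                          max_gap = 4L) {
  target <- normalize_seq(target); probe <- normalize_seq(probe)
  check_alphabet(target, "target"); check_alphabet(probe, "probe")
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  p <- strsplit(probe, "", fixed = TRUE)[[1]]
  n <- length(t); m <- length(p)
  sentinel <- structure(list(target = target, probe = probe,
                             duplex_pairs = matrix(integer(), ncol = 2L,
                                                   dimnames = list(NULL, c("target", "probe"))),
                             dg_total = NA_real_, dg_duplex = NA_real_,
                             dg_exterior = NA_real_, duplex_length = 0L),
                        class = "hybrid_structure")

  pc <- matrix(match(outer(t, p, paste0), CANONICAL_PAIRS), n, m)
  if (all(is.na(pc))) return(sentinel)
  Smat <- matrix(model$stack_table[
    as.vector(outer(CANONICAL_PAIRS, CANONICAL_PAIRS,
                    function(a, b) paste0(a, ":", b)))], 6L, 6L)
  # dangle lookup: D[pair code, base code, side (1 = 5p, 2 = 3p)]
  D <- array(0, c(6L, 4L, 2L))
  for (a in 1:6) for (b in 1:4) for (sd in 1:2) {
    D[a, b, sd] <- dangle_energy(model, CANONICAL_PAIRS[a], DNA_BASES[b],
                                 c("5p", "3p")[sd])
  }
  rcv <- match(paste0(substr(CANONICAL_PAIRS, 2, 2),
                      substr(CANONICAL_PAIRS, 1, 1)), CANONICAL_PAIRS)
  bt <- match(t, DNA_BASES); bp <- match(p, DNA_BASES)
  start_term <- function(i, j) {
    code <- pc[i, j]
    (if (i > 1L) D[code, bt[i - 1L], 1L] else 0) +
      (if (j < m) D[rcv[code], bp[j + 1L], 2L] else 0)
  }
  end_term <- function(i, j) {
    code <- pc[i, j]
    (if (i < n) D[code, bt[i + 1L], 2L] else 0) +
      (if (j > 1L) D[rcv[code], bp[j - 1L], 1L] else 0)
  }

  INF <- Inf
  lo <- model$duplex_loop_open; lb <- model$duplex_loop_base
  H <- matrix(INF, n, m)       # internal + start-side dangles, last pair (i,j)
  St <- matrix(NA_real_, n, m) # start-side dangle sum of the chosen path
  Pi <- matrix(0L, n, m); Pj <- matrix(0L, n, m) # parent pointers
  for (i in seq_len(n)) for (j in rev(seq_len(m))) {
    code <- pc[i, j]
    if (is.na(code)) next
    st0 <- start_term(i, j)
    best <- st0; bi <- 0L; bj <- 0L; bst <- st0
    for (ii in if (i > 1L) seq.int(max(1L, i - 1L - max_gap), i - 1L) else integer()) {
      for (jj in if (j < m) seq.int(j + 1L, min(m, j + 1L + max_gap)) else integer()) {
        h <- H[ii, jj]
        if (h == INF) next
        gap <- (i - ii - 1L) + (jj - j - 1L)
        step <- if (gap == 0L) Smat[pc[ii, jj], code] else lo + lb * gap
        cand <- h + step
        if (cand < best) { best <- cand; bi <- ii; bj <- jj; bst <- St[ii, jj] }
      }
    }
    H[i, j] <- best; St[i, j] <- bst; Pi[i, j] <- bi; Pj[i, j] <- bj
  }

  tot <- H + model$duplex_init
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (is.finite(H[i, j])) tot[i, j] <- tot[i, j] + end_term(i, j)
  }
  if (!any(is.finite(tot)) || min(tot[is.finite(tot)]) >= 0) return(sentinel)
  idx <- which(tot == min(tot[is.finite(tot)]), arr.ind = TRUE)[1L, ]
  ei <- idx[[1L]]; ej <- idx[[2L]]

  pairs <- list(); i <- ei; j <- ej
  repeat {
    pairs[[length(pairs) + 1L]] <- c(i, j)
    if (Pi[i, j] == 0L) break
    ii <- Pi[i, j]; jj <- Pj[i, j]; i <- ii; j <- jj
  }
  pairs <- do.call(rbind, rev(pairs))
  colnames(pairs) <- c("target", "probe")
  dg_exterior <- St[ei, ej] + end_term(ei, ej)
  dg_total <- tot[ei, ej]
  structure(list(target = target, probe = probe, duplex_pairs = pairs,
                 dg_total = dg_total,
                 dg_duplex = dg_total - dg_exterior - model$duplex_init,
                 dg_exterior = dg_exterior,
                 duplex_length = nrow(pairs)),
            class = "hybrid_structure")
}

#' Exterior-loop free energy of a hybrid
#'
#' Sum of the dangling-end contributions of the unpaired bases
#' immediately flanking the duplex on both molecules (up to four terms:
#' both ends, both strands); 0 when no flanking unpaired bases exist.
#' For a sentinel (no-duplex) hybrid, `NA` is returned and the feature is
#' imputed downstream.
#'
#' @param h A `hybrid_structure`.
#' @param model An `energy_model`.
#' @return Energy in kcal/mol, or `NA` for a sentinel hybrid.
#' @export
exterior_loop_energy <- function(h, model = default_energy_model()) {
  if (h$duplex_length == 0L) return(NA_real_)
  t <- strsplit(h$target, "", fixed = TRUE)[[1]]
  p <- strsplit(h$probe, "", fixed = TRUE)[[1]]
  n <- length(t); m <- length(p)
  first <- h$duplex_pairs[1L, ]
  last <- h$duplex_pairs[nrow(h$duplex_pairs), ]
  e <- 0
  i <- first[[1L]]; j <- first[[2L]]
  if (i > 1L) e <- e + dangle_energy(model, paste0(t[i], p[j]), t[i - 1L], "5p")
  if (j < m) e <- e + dangle_energy(model, paste0(p[j], t[i]), p[j + 1L], "3p")
  i <- last[[1L]]; j <- last[[2L]]
  if (i < n) e <- e + dangle_energy(model, paste0(t[i], p[j]), t[i + 1L], "3p")
  if (j > 1L) e <- e + dangle_energy(model, paste0(p[j], t[i]), p[j - 1L], "5p")
  e
}
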