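# Independent oracles and shared fixtures.

# ---- enumeration oracle for single-strand folding -------------------------
# All nested structures (sets of non-crossing pairs with j - i >= mh + 1
# over complementary bases), scored directly from the model definition via
# score_structure(); feasible for n <= 12.
enumerate_nested <- function(s, mh = 3L) {
  n <- length(s)
  pairable <- outer(s, s, function(a, b)
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG"))
  structures <- list()
  # recursive: structures over interval [i, j]
  rec <- function(i, j) {
    if (j - i < mh + 1L) return(list(list()))
    out <- rec(i + 1L, j)  # i unpaired
    out <- lapply(out, identity)
    for (k in seq.int(i + mh + 1L, j)) {
      if (!pairable[i, k]) next
      inner <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (a in inner) for (b in right) {
        out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
      }
    }
    out
  }
  rec(1L, n)
}

oracle_mfe <- function(seq, model = default_energy_model()) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  structs <- enumerate_nested(s, model$min_hairpin)
  energies <- vapply(structs, function(ps) {
    if (length(ps) == 0L) return(0)
    score_structure(seq, do.call(rbind, ps), model)
  }, numeric(1))
  min(energies)
}

# ---- enumeration oracle for duplex hybridization --------------------------
# All antiparallel duplexes (monotone pair chains, per-strand gaps up to
# max_gap), scored like the model: stacks + loop penalties + terminal
# dangles + initiation. Returns the minimum total energy, or NA if no
# duplex is negative.
oracle_duplex <- function(target, probe, model = default_energy_model(),
                          max_gap = 4L) {
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  p <- strsplit(probe, "", fixed = TRUE)[[1]]
  n <- length(t); m <- length(p)
  prs <- c("AT", "TA", "GC", "CG", "GT", "TG")
  ok <- function(i, j) paste0(t[i], p[j]) %in% prs
  dang <- function(pair, base, side) {
    v <- model$dangle_table[paste(pair, base, side, sep = "|")]
    if (is.na(v)) 0 else unname(v)
  }
  best <- Inf
  # depth-first over chains starting at each pairable (i, j)
  extend <- function(chain, acc) {
    i <- chain[[length(chain)]][1]; j <- chain[[length(chain)]][2]
    # close the duplex here
    first <- chain[[1]]
    e <- acc + model$duplex_init
    if (first[1] > 1L) e <- e + dang(paste0(t[first[1]], p[first[2]]),
                                     t[first[1] - 1L], "5p")
    if (first[2] < m) e <- e + dang(paste0(p[first[2]], t[first[1]]),
                                    p[first[2] + 1L], "3p")
    if (i < n) e <- e + dang(paste0(t[i], p[j]), t[i + 1L], "3p")
    if (j > 1L) e <- e + dang(paste0(p[j], t[i]), p[j - 1L], "5p")
    best <<- min(best, e)
    for (ii in seq.int(i + 1L, min(n, i + 1L + max_gap))) {
      if (ii > n) break
      for (jj in rev(seq.int(max(1L, j - 1L - max_gap), j - 1L))) {
        if (jj < 1L || !ok(ii, jj)) next
        gap <- (ii - i - 1L) + (j - jj - 1L)
        step <- if (gap == 0L) {
          unname(model$stack_table[paste0(t[i], p[j], ":", t[ii], p[jj])])
        } else model$duplex_loop_open + model$duplex_loop_base * gap
        extend(c(chain, list(c(ii, jj))), acc + step)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (ok(i, j)) extend(list(c(i, j)), 0)
  }
  if (!is.finite(best) || best >= 0) NA_real_ else best
}

# ---- cached synthetic bundles --------------------------------------------
.bundles <- new.env(parent = emptyenv())
get_bundle <- function(n, seed, dominant = FALSE) {
  key <- paste0("n", n, "_s", seed, if (dominant) "_dom" else "")
  if (is.null(.bundles[[key]])) {
    .bundles[[key]] <- if (dominant) {
      # qualitative-replication configuration: dominant mRNA effect,
      # concerted translation features, planted fraction aligned with
      # the quartile split
      simulate_bundle(n, seed, true_beta = dominant_mrna_beta(),
                      planted_frac = 0.25)
    } else simulate_bundle(n, seed)
  }
  .bundles[[key]]
}
get_selection <- function(n, seed, dominant = FALSE) {
  key <- paste0("sel_n", n, "_s", seed, if (dominant) "_dom" else "")
  if (is.null(.bundles[[key]])) {
    b <- get_bundle(n, seed, dominant)
    y <- log10(b$expression$protein_mean)
    .bundles[[key]] <- backward_eliminate(b$features, y)
  }
  .bundles[[key]]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
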