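# Genome parsing, TIR/CDS extraction and gene-level quality filters.

#' Load an annotated genome
#'
#' Reads a genome plus CDS annotations either from a GenBank flat file or
#' from a FASTA file with a GFF3 companion. Sequences are uppercased and
#' U is normalized to T.
#'
#' @param path Path to the GenBank file, or to the FASTA file when
#'   `format = "fasta+gff3"`.
#' @param format `"genbank"` or `"fasta+gff3"`.
#' @param gff_path Path to the GFF3 annotation (required for
#'   `"fasta+gff3"`).
#' @return A list with elements `contigs` (named character vector of
#'   contig sequences), `annotations` (data.frame with `gene_id`, `start`,
#'   `end`, `strand`, `contig_id`; coordinates 1-based inclusive) and
#'   `topology` (`"linear"` or `"circular"`, as declared by the file).
#' @export
load_annotated_genome <- function(path, format = c("genbank", "fasta+gff3"),
                                  gff_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  res <- if (format == "genbank") {
    parse_genbank(path)
  } else {
    if (is.null(gff_path)) {
      stop("format error: 'fasta+gff3' requires a GFF3 companion via gff_path",
           call. = FALSE)
    }
    if (!file.exists(gff_path)) stop("file not found: ", gff_path, call. = FALSE)
    seqs <- Biostrings::readDNAStringSet(path)
    contigs <- normalize_seq(as.character(seqs))
    names(contigs) <- sub("\\s.*$", "", names(seqs))
    gr <- rtracklayer::import(gff_path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    if (length(gr) == 0L) stop("format error: no CDS features in ", gff_path,
                               call. = FALSE)
    ids <- if (!is.null(gr$locus_tag) && !all(is.na(gr$locus_tag))) {
      as.character(gr$locus_tag)
    } else as.character(gr$ID)
    ann <- data.frame(
      gene_id = ids,
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      stringsAsFactors = FALSE
    )
    list(contigs = contigs, annotations = ann, topology = "linear")
  }
  validate_annotations(res$annotations, res$contigs, res$topology)
  res
}

# Minimal GenBank flat-file parser: LOCUS line (name, topology), CDS
# features with simple or complement(simple) locations, /locus_tag or
# /gene qualifiers, and the ORIGIN sequence block.
#' @noRd
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) {
    stop("format error: no LOCUS line in ", path, call. = FALSE)
  }
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  contig_id <- toks[2]
  topology <- if (any(grepl("circular", toks, ignore.case = TRUE)))
    "circular" else "linear"

  origin <- grep("^ORIGIN", lines)
  if (length(origin) == 0L) {
    stop("format error: no ORIGIN block in ", path, call. = FALSE)
  }
  seq_lines <- lines[(origin[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- normalize_seq(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq) == 0L) stop("format error: empty ORIGIN in ", path,
                             call. = FALSE)

  feat_idx <- grep("^ {5}CDS ", lines)
  ann <- lapply(feat_idx, function(i) {
    loc <- trimws(sub("^ {5}CDS\\s+", "", lines[i]))
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1]]
    if (length(m) != 3L) {
      stop("format error: unsupported CDS location '", loc, "' in ", path,
           call. = FALSE)
    }
    # pull the first /locus_tag or /gene qualifier following the feature
    gid <- NA_character_
    j <- i + 1L
    while (j <= length(lines) && grepl("^ {6,}", lines[j])) {
      q <- regmatches(lines[j],
                      regexec("/(locus_tag|gene)=\"([^\"]+)\"", lines[j]))[[1]]
      if (length(q) == 3L) { gid <- q[3]; break }
      if (grepl("^ {5}\\S", lines[j])) break
      j <- j + 1L
    }
    data.frame(gene_id = gid, start = as.integer(m[2]), end = as.integer(m[3]),
               strand = strand, contig_id = contig_id,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, ann)
  if (is.null(ann)) {
    ann <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      contig_id = character(), stringsAsFactors = FALSE)
  }
  miss <- is.na(ann$gene_id)
  if (any(miss)) ann$gene_id[miss] <- sprintf("cds_%04d", which(miss))
  contigs <- stats::setNames(seq, contig_id)
  list(contigs = contigs, annotations = ann, topology = topology)
}

#' @noRd
validate_annotations <- function(ann, contigs, topology) {
  if (nrow(ann) == 0L) return(invisible(ann))
  if (any(!ann$contig_id %in% names(contigs))) {
    stop("coordinate error: annotation references unknown contig ",
         setdiff(ann$contig_id, names(contigs))[1], call. = FALSE)
  }
  if (any(ann$start > ann$end)) {
    stop("coordinate error: start > end for gene ",
         ann$gene_id[ann$start > ann$end][1], call. = FALSE)
  }
  if (topology == "linear") {
    len <- nchar(contigs)[ann$contig_id]
    bad <- ann$start < 1L | ann$end > len
    if (any(bad)) {
      stop("coordinate error: gene ", ann$gene_id[bad][1],
           " lies outside its contig on linear topology", call. = FALSE)
    }
  }
  invisible(ann)
}

# 1-based inclusive substring with optional circular wrap-around.
#' @noRd
region_string <- function(contig, from, to, topology) {
  len <- nchar(contig)
  if (from >= 1L && to <= len) return(substr(contig, from, to))
  if (topology != "circular") {
    stop("coordinate window outside linear contig", call. = FALSE)
  }
  idx <- ((seq.int(from, to) - 1L) %% len) + 1L
  paste(substring(contig, idx, idx), collapse = "")
}

#' Extract TIR and CDS for one gene
#'
#' The translation initiation region (TIR) is the 55 nt window spanning
#' positions -25..-1 and +1..+30, where +1 is the first base of the start
#' codon (there is no position 0). The CDS is the annotated span, start
#' through stop codon inclusive. On the minus strand all coordinates are
#' interpreted on the reverse complement; on circular topology the
#' upstream window may wrap across the origin.
#'
#' @param contigs Named character vector of contig sequences.
#' @param annotation One-row data.frame (or list) with `gene_id`, `start`,
#'   `end`, `strand`, `contig_id`.
#' @param topology `"linear"` or `"circular"`.
#' @param tir_upstream,tir_downstream Bases upstream of the start codon
#'   and bases counted from the start codon's first base (defaults 25 and
#'   30, i.e. the -25..+30 window).
#' @return A list of class `gene_regions`: `gene_id`, `tir_seq`,
#'   `cds_seq`, `start_codon`, `stop_codon`.
#' @export
extract_gene_regions <- function(contigs, annotation,
                                 topology = c("linear", "circular"),
                                 tir_upstream = 25L, tir_downstream = 30L) {
  topology <- match.arg(topology)
  a <- as.list(annotation)
  contig <- contigs[[a$contig_id]]
  len <- nchar(contig)
  cds_len <- a$end - a$start + 1L
  if (cds_len < tir_downstream) {
    stop_extraction(a$gene_id, "cds_shorter_than_tir_window")
  }
  if (a$strand == "+") {
    up_from <- a$start - tir_upstream
    if (topology == "linear" && up_from < 1L) {
      stop_extraction(a$gene_id, "insufficient_upstream")
    }
    tir <- region_string(contig, up_from, a$start + tir_downstream - 1L,
                         topology)
    cds <- region_string(contig, a$start, a$end, topology)
  } else {
    up_to <- a$end + tir_upstream
    if (topology == "linear" && up_to > len) {
      stop_extraction(a$gene_id, "insufficient_upstream")
    }
    tir <- revcomp(region_string(contig, a$end - tir_downstream + 1L, up_to,
                                 topology))
    cds <- revcomp(region_string(contig, a$start, a$end, topology))
  }
  structure(list(gene_id = a$gene_id, tir_seq = tir, cds_seq = cds,
                 start_codon = substr(cds, 1L, 3L),
                 stop_codon = substr(cds, cds_len - 2L, cds_len)),
            class = "gene_regions")
}

#' @noRd
stop_extraction <- function(gene_id, reason) {
  cond <- structure(
    class = c("s2a_extraction_error", "error", "condition"),
    list(message = sprintf("extraction failed for gene %s: %s", gene_id,
                           reason),
         call = NULL, gene_id = gene_id, reason = reason))
  stop(cond)
}

#' Extract regions for all annotated genes
#'
#' Applies [extract_gene_regions()] to every annotation; genes whose TIR
#' cannot be extracted are skipped with a warning.
#'
#' @param genome A list as returned by [load_annotated_genome()].
#' @param ... Passed to [extract_gene_regions()].
#' @return data.frame with columns `gene_id`, `tir_seq`, `cds_seq`,
#'   `start_codon`, `stop_codon`.
#' @export
extract_regions_table <- function(genome, ...) {
  rows <- lapply(seq_len(nrow(genome$annotations)), function(i) {
    tryCatch(
      as.data.frame(unclass(extract_gene_regions(
        genome$contigs, genome$annotations[i, ], topology = genome$topology,
        ...)), stringsAsFactors = FALSE),
      s2a_extraction_error = function(e) {
        warning("skipping gene ", e$gene_id, ": ", e$reason, call. = FALSE)
        NULL
      })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), tir_seq = character(),
                      cds_seq = character(), start_codon = character(),
                      stop_codon = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Screen aberrant genes
#'
#' Partitions genes into valid and aberrant. A gene is aberrant iff its
#' CDS length is not a multiple of 3 (reason `frameshift`), its start
#' codon is not in `allowed_starts` (reason `nonsense_start_codon`), or an
#' in-frame stop codon occurs before the terminal codon (reason
#' `internal_stop`).
#'
#' @param regions data.frame of gene regions (see
#'   [extract_regions_table()]).
#' @param allowed_starts Allowed start codons.
#' @return List with `valid` (data.frame) and `aberrant` (data.frame with
#'   an extra `reason` column).
#' @export
screen_aberrant_genes <- function(regions,
                                  allowed_starts = c("ATG", "GTG", "TTG")) {
  if (nrow(regions) == 0L) {
    return(list(valid = regions,
                aberrant = cbind(regions, reason = character(0))))
  }
  reason <- vapply(seq_len(nrow(regions)), function(i) {
    cds <- regions$cds_seq[i]
    n <- nchar(cds)
    if (n %% 3L != 0L || n < 6L) return("frameshift")
    if (!regions$start_codon[i] %in% allowed_starts) {
      return("nonsense_start_codon")
    }
    codons <- split_codons(cds)
    if (any(codons[-length(codons)] %in% STOP_CODONS)) {
      return("internal_stop")
    }
    ""
  }, character(1))
  list(valid = regions[reason == "", , drop = FALSE],
       aberrant = cbind(regions[reason != "", , drop = FALSE],
                        reason = reason[reason != ""]))
}

#' Flag expression outliers
#'
#' Regresses z(log10 protein mean) on z(log10 mRNA level) by ordinary
#' least squares and removes genes whose absolute residual exceeds
#' `sd_threshold` residual standard deviations — genes whose protein
#' level deviates so strongly from the transcript-protein trend that
#' gene-specific posttranscriptional regulation is the likely cause.
#'
#' @param records data.frame with `gene_id`, `mrna_level`, `protein_mean`
#'   (and optionally further columns, carried through).
#' @param sd_threshold Residual SD multiple beyond which a gene is
#'   removed (default 3).
#' @return List with `kept` and `removed` data.frames; `removed` gains a
#'   `residual_sd` column.
#' @export
flag_expression_outliers <- function(records, sd_threshold = 3) {
  stopifnot(nrow(records) >= 10L)
  bad <- records$mrna_level <= 0 | records$protein_mean <= 0
  if (any(bad)) {
    stop("nonpositive abundance for gene ", records$gene_id[bad][1],
         call. = FALSE)
  }
  x <- zscore(log10(records$mrna_level))
  y <- zscore(log10(records$protein_mean))
  res <- stats::residuals(stats::lm(y ~ x))
  s <- stats::sd(res)
  # an (almost) exact linear relation has no meaningful residual scale
  out <- if (s < 1e-10) rep(FALSE, length(res)) else
    abs(res) > sd_threshold * s
  removed <- records[out, , drop = FALSE]
  if (nrow(removed)) removed$residual_sd <- res[out] / s
  list(kept = records[!out, , drop = FALSE], removed = removed)
}

#' Write gene regions to TSV
#' @param regions data.frame of gene regions.
#' @param path Output path.
#' @export
write_regions_tsv <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
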