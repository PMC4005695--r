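# Simplified nearest-neighbor energy model: stacking energies for adjacent
# base pairs, hairpin-loop length penalties, dangling-end terms and duplex
# constants. Parameters live in a versioned TSV (inst/extdata) so published
# values can be substituted; the shipped set is a documented simplified
# parameterization, not the Turner tables.

CANONICAL_PAIRS <- c("AT", "TA", "GC", "CG", "GT", "TG")

#' Read an energy model from its TSV representation
#'
#' The table has columns `kind`, `key`, `value` (kcal/mol). Kinds:
#' `stack` (key `"XY:ZW"`, outer pair then inner pair), `hairpin` (key =
#' loop length in nt), `dangle` (key `"XY|B|5p"` or `"...|3p"`: pair,
#' dangling base, side of the paired base on its own strand) and `const`
#' (`duplex_init`, `min_hairpin`, `duplex_loop_open`, `duplex_loop_base`).
#'
#' @param path TSV path; defaults to the shipped model.
#' @return An object of class `energy_model`.
#' @export
read_energy_model <- function(path = system.file("extdata",
                                                 "energy_model_default.tsv",
                                                 package = "seq2abundance")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "key", "value") %in% names(tab)))
  pick <- function(kind) {
    x <- tab[tab$kind == kind, ]
    stats::setNames(x$value, x$key)
  }
  stacks <- pick("stack")
  hp <- pick("hairpin")
  dangles <- pick("dangle")
  consts <- pick("const")
  need <- as.vector(outer(CANONICAL_PAIRS, CANONICAL_PAIRS, paste, sep = ":"))
  if (!all(need %in% names(stacks))) {
    stop("energy model incomplete: missing stack entries", call. = FALSE)
  }
  structure(list(
    stack_table = stacks,
    hairpin_penalty = hp,
    dangle_table = dangles,
    duplex_init = unname(consts[["duplex_init"]]),
    min_hairpin = as.integer(consts[["min_hairpin"]]),
    duplex_loop_open = unname(consts[["duplex_loop_open"]]),
    duplex_loop_base = unname(consts[["duplex_loop_base"]])
  ), class = "energy_model")
}

.s2a_cache <- new.env(parent = emptyenv())

#' Default simplified nearest-neighbor energy model
#' @return An `energy_model` (cached after first load).
#' @export
default_energy_model <- function() {
  if (is.null(.s2a_cache$energy_model)) {
    .s2a_cache$energy_model <- read_energy_model()
  }
  .s2a_cache$energy_model
}

#' @noRd
can_pair <- function(a, b) paste0(a, b) %in% CANONICAL_PAIRS

#' @noRd
hairpin_energy <- function(model, loop_len) {
  hp <- model$hairpin_penalty
  lens <- as.integer(names(hp))
  loop_len <- pmin(pmax(loop_len, min(lens)), max(lens))
  unname(hp[as.character(loop_len)])
}

#' @noRd
stack_energy <- function(model, outer_pair, inner_pair) {
  unname(model$stack_table[paste0(outer_pair, ":", inner_pair)])
}

#' @noRd
dangle_energy <- function(model, pair, base, side) {
  v <- model$dangle_table[paste(pair, base, side, sep = "|")]
  if (is.na(v)) 0 else unname(v)
}
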