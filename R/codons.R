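# Genetic-code helpers shared across modules. The standard code from
# Biostrings is the single source of truth; stop codons are excluded from all
# occupancy statistics because the analyzed codon window never reaches them.

#' The 61 sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense triplets over \{A,C,G,T\}, in
#'   alphabetical order.
#' @export
#' @examples
#' length(sense_codons())
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

#' Codon-to-amino-acid lookup table
#'
#' @param include_stop Include the three stop codons (amino acid `"*"`)?
#' @return A tibble with columns `codon` and `amino_acid` (one-letter code).
#' @export
codon_table <- function(include_stop = FALSE) {
  gc <- Biostrings::GENETIC_CODE
  out <- tibble(codon = names(gc), amino_acid = unname(gc)) |>
    arrange(.data$codon)
  if (!include_stop) out <- filter(out, .data$amino_acid != "*")
  out
}

#' Codons encoding a set of amino acids
#'
#' Convenience for building codon filters such as "all Pro and Ala codons".
#'
#' @param amino_acids One-letter amino-acid codes (e.g. `c("P", "A")`).
#' @return Character vector of codons.
#' @export
#' @examples
#' codons_for("P") # the four proline codons
codons_for <- function(amino_acids) {
  tab <- codon_table()
  bad <- setdiff(amino_acids, tab$amino_acid)
  if (length(bad) > 0) {
    abort(paste0("Unknown amino acid code(s): ", paste(bad, collapse = ", ")))
  }
  tab$codon[tab$amino_acid %in% amino_acids]
}

# Split a CDS string into its codons (no validation; internal).
split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds) - 2, by = 3), seq(3, nchar(cds), by = 3))
}

# Codon identities for indices `idx` (0-based) of a transcript row.
codon_at <- function(sequence, cds_start, idx) {
  start <- cds_start + 3L * idx + 1L
  substring(sequence, start, start + 2L)
}

# Analyzed codon window [5, L - 6] (0-based, inclusive); the first and last
# five codons are excluded to avoid atypical densities near start/stop.
analysis_window <- function(cds_codons) {
  if (cds_codons < 11L) return(integer(0))
  seq.int(5L, cds_codons - 6L)
}
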