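#' The 61 sense codons of the standard genetic code
#'
#' Codons are DNA-alphabet 3-mers in a fixed lexicographic order with the
#' three stop codons (TAA, TAG, TGA) removed.  All codon-indexed tables in
#' the package (decoding-rate tables, usage weights, demand matrices) use
#' this order.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T"), stringsAsFactors = FALSE)[, 3:1],
                1, paste0, collapse = "")
  sort(setdiff(all3, c("TAA", "TAG", "TGA")))
}

#' Map codons to one-letter amino acids
#'
#' @param codons Character vector of DNA codons; defaults to all 61 sense
#'   codons.
#' @return Named character vector of one-letter amino-acid codes.
#' @export
codon_to_aa <- function(codons = sense_codons()) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  names(aa) <- codons
  aa
}

#' Synonymous codon families
#'
#' @return Named list: one character vector of codons per amino acid.
#' @export
synonymous_families <- function() {
  aa <- codon_to_aa()
  split(names(aa), aa)
}

#' Translate a codon vector to an amino-acid string
#'
#' @param codons Character vector of in-frame sense codons.
#' @return Single amino-acid string.
#' @export
translate_codons <- function(codons) {
  paste(codon_to_aa()[codons], collapse = "")
}
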