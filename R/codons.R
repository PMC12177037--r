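# Codon-level helpers shared by the scaffold and library modules.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# One preferred codon per amino acid (common E. coli usage); used for
# reverse translation of designed protein sequences.
.preferred_codon <- c(
  A = "GCG", R = "CGT", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTT")

#' Translate a DNA coding sequence to protein
#'
#' Thin wrapper over the standard genetic code; the input length must be
#' a multiple of 3.
#'
#' @param dna character scalar (or vector) of DNA.
#' @return character vector of amino-acid sequences (stops as
#'   \code{"*"}).
#' @export
translate_dna <- function(dna) {
  if (any(nchar(dna) %% 3 != 0)) stop("DNA length must be a multiple of 3")
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     no.init.codon = TRUE))
}

#' Reverse-translate a protein to DNA using preferred codons
#'
#' @param protein amino-acid sequence (20-letter alphabet).
#' @return DNA string, 3x the protein length.
#' @export
reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, .AA20)
  if (length(bad)) stop("non-standard amino acid(s): ", paste(bad, collapse = ", "))
  paste(.preferred_codon[aa], collapse = "")
}

# All codons for one amino acid under the standard code.
.codons_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == aa])
}

# Replace the codon at protein position `pos` so it encodes `to`,
# changing as few nucleotides as possible (ties broken alphabetically).
.minimal_codon_change <- function(dna, pos, to) {
  start <- 3 * (pos - 1) + 1
  cur <- substr(dna, start, start + 2)
  cands <- .codons_for(to)
  if (!length(cands)) stop("no codon encodes '", to, "'")
  hd <- vapply(cands, function(cd) {
    sum(strsplit(cd, "")[[1]] != strsplit(cur, "")[[1]])
  }, integer(1))
  best <- cands[which.min(hd)]  # which.min takes the first = alphabetical
  paste0(substr(dna, 1, start - 1), best,
         substr(dna, start + 3, nchar(dna)))
}

.revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna)))
}
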