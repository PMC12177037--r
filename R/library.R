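# In silico construction of the three selection-library types: fully
# TRIM-randomised CDR libraries, single-codon affinity-maturation
# libraries, and CDR-shuffled oligopool libraries, plus expression
# cassette assembly.
#
# TRIM (trimer phosphoramidite) synthesis randomises whole codons, so
# stop codons never occur at randomised positions by construction.
# Golden-gate style assembly steps (BsaI/BbsI digests and ligations) are
# modelled as direct concatenation: only the final sequence identity has
# computational content.

#' Define a trimer-codon (TRIM) sampling alphabet
#'
#' The default alphabet covers 19 amino acids (cysteine excluded, the
#' usual choice for synthetic nanobody libraries to avoid stray
#' disulfides) with uniform weights, one preferred codon per amino acid.
#'
#' @param aas amino acids in the mix.
#' @param weights sampling weights (> 0; normalised to sum to 1).
#' @param codons named character vector mapping each amino acid to its
#'   trimer codon; defaults to preferred codons.
#' @return object of class \code{trim_codon_set}.
#' @export
trim_codon_set <- function(aas = setdiff(.AA20, "C"),
                           weights = NULL, codons = NULL) {
  aas <- unique(aas)
  if (!all(aas %in% .AA20)) stop("TRIM alphabet must contain standard amino acids only")
  if (is.null(weights)) weights <- rep(1, length(aas))
  if (length(weights) != length(aas) || any(weights <= 0)) {
    stop("weights must be positive, one per amino acid")
  }
  if (is.null(codons)) codons <- .preferred_codon[aas]
  codons <- toupper(codons[aas])
  if (any(translate_dna(unname(codons)) != aas)) {
    stop("supplied codons do not encode their amino acids")
  }
  structure(list(aas = aas, weights = weights / sum(weights),
                 codons = codons),
            class = "trim_codon_set")
}

#' Construct a variant gene
#'
#' A variant gene couples a coding DNA sequence with its translation and
#' (optionally) a protein-level CDR map and cassette element flags.  The
#' open reading frame must be intact: no internal stops.
#'
#' @param dna coding DNA (length a multiple of 3).
#' @param id identifier.
#' @param cdrs optional \code{cdr_map} in protein coordinates.
#' @param flags character vector of cassette element flags carried as
#'   metadata (e.g. "cys_tag", "avi_tag", "flag3x", "his10", "snap").
#' @return object of class \code{variant_gene}.
#' @export
variant_gene <- function(dna, id = "variant", cdrs = NULL, flags = character()) {
  protein <- translate_dna(dna)
  if (grepl("*", protein, fixed = TRUE)) {
    stop("open reading frame contains an internal stop codon")
  }
  if (!is.null(cdrs) && cdrs$seq_length != nchar(protein)) {
    stop("cdr map does not match protein length")
  }
  structure(list(id = id, dna = dna, protein = protein, cdrs = cdrs,
                 flags = flags),
            class = "variant_gene")
}

#' @export
print.variant_gene <- function(x, ...) {
  cat("variant_gene '", x$id, "': ", nchar(x$protein), " aa / ",
      nchar(x$dna), " nt\n", sep = "")
  invisible(x)
}

# framework = protein with CDR positions blanked
.framework_signature <- function(protein, cdrs) {
  aa <- strsplit(protein, "")[[1]]
  aa[cdr_indices(cdrs)] <- "."
  paste(aa, collapse = "")
}

#' Specify a randomised library design
#'
#' @param parent \code{variant_gene} (or \code{nanobody_record} with
#'   DNA) used as framework donor.
#' @param cdrs \code{cdr_map} for the parent protein.
#' @param mode \code{"full_trim"} (randomise the listed positions),
#'   \code{"single_codon_maturation"} (one random codon per CDR per
#'   variant) or \code{"cdr_shuffle"} (mix parent CDR cassettes; see
#'   \code{\link{shuffle_cdrs}}).
#' @param positions for full_trim: integer vector of protein positions
#'   to randomise; must lie inside the CDRs.  Default: all CDR positions.
#' @param trim \code{trim_codon_set}.
#' @param pools for cdr_shuffle: list of parent \code{variant_gene}s.
#' @return object of class \code{library_design}.
#' @export
library_design <- function(parent, cdrs,
                           mode = c("full_trim", "single_codon_maturation",
                                    "cdr_shuffle"),
                           positions = NULL, trim = trim_codon_set(),
                           pools = NULL) {
  mode <- match.arg(mode)
  if (inherits(parent, "nanobody_record")) {
    if (is.null(parent$dna)) stop("parent record needs DNA")
    parent <- variant_gene(parent$dna, parent$id, cdrs)
  }
  stopifnot(inherits(parent, "variant_gene"), inherits(cdrs, "cdr_map"),
            inherits(trim, "trim_codon_set"))
  cdr_idx <- cdr_indices(cdrs)
  if (mode == "full_trim") {
    if (is.null(positions)) positions <- cdr_idx
    if (!all(positions %in% cdr_idx)) {
      stop("randomised positions outside CDRs: ",
           paste(setdiff(positions, cdr_idx), collapse = ", "))
    }
  }
  if (mode == "cdr_shuffle" && (is.null(pools) || length(pools) < 1)) {
    stop("cdr_shuffle mode requires non-empty parent pools")
  }
  structure(list(parent = parent, cdrs = cdrs, mode = mode,
                 positions = sort(unique(as.integer(positions))),
                 trim = trim, pools = pools),
            class = "library_design")
}

.sample_codons <- function(trim, k) {
  unname(trim$codons[sample.int(length(trim$aas), k, replace = TRUE,
                                prob = trim$weights)])
}

.replace_codons <- function(dna, positions, codons) {
  chars <- strsplit(dna, "")[[1]]
  for (k in seq_along(positions)) {
    i <- 3 * (positions[k] - 1) + 1
    chars[i:(i + 2)] <- strsplit(codons[k], "")[[1]]
  }
  paste(chars, collapse = "")
}

#' Sample variants from a library design
#'
#' Variants are drawn i.i.d. according to the design mode and are
#' bit-reproducible under a fixed seed.  Every variant keeps the parent
#' framework intact and has a stop-free open reading frame.
#'
#' @param design \code{library_design}.
#' @param n number of variants (>= 1).
#' @param seed integer seed (optional; sampling uses the current RNG
#'   state if NULL).
#' @return list of \code{variant_gene}.
#' @export
sample_library <- function(design, n, seed = NULL) {
  stopifnot(inherits(design, "library_design"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (design$mode == "cdr_shuffle") {
    return(shuffle_cdrs(design$pools, n, seed = NULL))
  }
  parent <- design$parent
  lapply(seq_len(n), function(i) {
    if (design$mode == "full_trim") {
      pos <- design$positions
    } else {  # single_codon_maturation: one random codon per CDR
      pos <- vapply(c("cdr1", "cdr2", "cdr3"), function(nm) {
        iv <- design$cdrs[[nm]]
        sample(seq.int(iv[1], iv[2] - 1L), 1)
      }, integer(1))
    }
    dna <- .replace_codons(parent$dna, pos, .sample_codons(design$trim, length(pos)))
    variant_gene(dna, paste0(parent$id, "_v", i), design$cdrs, parent$flags)
  })
}

#' Shuffle CDR cassettes between parent variants
#'
#' Each child draws its CDR1, CDR2 and CDR3 DNA cassettes independently
#' and uniformly from the corresponding parent pools; the framework
#' comes from the first (reference) parent.  Parents must share an
#' identical framework protein.
#'
#' @param parents list of \code{variant_gene} with CDR maps.
#' @param n number of children.
#' @param seed integer seed (optional).
#' @return list of \code{variant_gene}.
#' @export
shuffle_cdrs <- function(parents, n, seed = NULL) {
  if (length(parents) < 1) stop("need >= 1 parent")
  if (!is.null(seed)) set.seed(seed)
  if (any(vapply(parents, function(p) is.null(p$cdrs), logical(1)))) {
    stop("all parents need CDR maps")
  }
  # compare concatenated framework segments (CDR lengths may differ)
  fw <- vapply(parents, function(p) {
    iv <- p$cdrs
    paste(substr(p$protein, 1, iv$cdr1[1] - 1),
          substr(p$protein, iv$cdr1[2], iv$cdr2[1] - 1),
          substr(p$protein, iv$cdr2[2], iv$cdr3[1] - 1),
          substr(p$protein, iv$cdr3[2], nchar(p$protein)), sep = "|")
  }, character(1))
  if (length(unique(fw)) != 1) {
    stop("parents have incompatible frameworks; CDR shuffling needs one shared framework")
  }
  ref <- parents[[1]]
  # DNA split into framework segments and CDR cassettes
  split_gene <- function(p) {
    iv <- lapply(c("cdr1", "cdr2", "cdr3"), function(nm) p$cdrs[[nm]])
    nt <- function(v) c(3 * (v[1] - 1) + 1, 3 * (v[2] - 1))  # inclusive nt range
    r1 <- nt(iv[[1]]); r2 <- nt(iv[[2]]); r3 <- nt(iv[[3]])
    list(fr = c(substr(p$dna, 1, r1[1] - 1),
                substr(p$dna, r1[2] + 1, r2[1] - 1),
                substr(p$dna, r2[2] + 1, r3[1] - 1),
                substr(p$dna, r3[2] + 1, nchar(p$dna))),
         cdr = c(substr(p$dna, r1[1], r1[2]),
                 substr(p$dna, r2[1], r2[2]),
                 substr(p$dna, r3[1], r3[2])))
  }
  ref_parts <- split_gene(ref)
  pools <- lapply(1:3, function(k) {
    vapply(parents, function(p) split_gene(p)$cdr[k], character(1))
  })
  lapply(seq_len(n), function(i) {
    picks <- vapply(1:3, function(k) pools[[k]][sample.int(length(parents), 1)],
                    character(1))
    dna <- paste0(ref_parts$fr[1], picks[1], ref_parts$fr[2], picks[2],
                  ref_parts$fr[3], picks[3], ref_parts$fr[4])
    # recompute the CDR map (shuffled CDRs may differ in length)
    l <- nchar(c(ref_parts$fr[1], picks[1], ref_parts$fr[2], picks[2],
                 ref_parts$fr[3], picks[3], ref_parts$fr[4])) / 3
    cm <- cdr_map(c(l[1] + 1, l[1] + l[2] + 1),
                  c(sum(l[1:3]) + 1, sum(l[1:4]) + 1),
                  c(sum(l[1:5]) + 1, sum(l[1:6]) + 1), sum(l))
    variant_gene(dna, paste0("shuffle_v", i), cm, ref$flags)
  })
}

#' Fixed cassette elements
#'
#' The PCR handle sequences are fixed assembly constants; the T7
#' promoter/terminator and ribosome-binding spacer are canonical
#' defaults (configurable -- the originals are not public).
#'
#' @param fwd_primer forward PCR handle (appears verbatim in the
#'   cassette).
#' @param rev_primer reverse PCR primer (the cassette ends with its
#'   reverse complement).
#' @param t7_promoter,t7_terminator transcription elements.
#' @param rbs ribosome-binding spacer placed immediately before the ORF;
#'   also the default 5' anchor for read filtering.
#' @return named list of elements.
#' @export
cassette_elements <- function(fwd_primer = "ACCCGGCATGACAGGAG",
                              rev_primer = "TGGCGGCCGCTCTA",
                              t7_promoter = "TAATACGACTCACTATAGGG",
                              t7_terminator = "CTAGCATAACCCCTTGGGGCCTCTAAACGGGTCTTGAGGGGTTTTTTG",
                              rbs = "GAAGGAGATATACC") {
  list(fwd_primer = toupper(fwd_primer), rev_primer = toupper(rev_primer),
       t7_promoter = toupper(t7_promoter),
       t7_terminator = toupper(t7_terminator), rbs = toupper(rbs))
}

#' Assemble the expression cassette for a variant
#'
#' Layout: forward-primer site, T7 promoter, RBS spacer, ORF
#' (ATG + variant DNA + stop), T7 terminator, reverse-primer site
#' (reverse complement of the reverse primer).
#'
#' @param v \code{variant_gene}.
#' @param elements \code{\link{cassette_elements}}.
#' @return cassette DNA string.
#' @export
assemble_cassette <- function(v, elements = cassette_elements()) {
  stopifnot(inherits(v, "variant_gene"))
  paste0(elements$fwd_primer, elements$t7_promoter, elements$rbs,
         "ATG", v$dna, "TAA", elements$t7_terminator,
         .revcomp(elements$rev_primer))
}

#' Extract and translate the ORF from a cassette
#'
#' Inverse of \code{\link{assemble_cassette}}: locates the RBS spacer
#' and terminator, pulls the enclosed ORF and translates it.
#'
#' @param cassette DNA string.
#' @param elements \code{\link{cassette_elements}}.
#' @return list with \code{dna} (ORF without start/stop codons) and
#'   \code{protein}.
#' @export
extract_orf <- function(cassette, elements = cassette_elements()) {
  a5 <- regexpr(elements$rbs, cassette, fixed = TRUE)
  a3 <- regexpr(elements$t7_terminator, cassette, fixed = TRUE)
  if (a5 < 0 || a3 < 0 || a3 <= a5) stop("cassette anchors not found in order")
  orf <- substr(cassette, a5 + attr(a5, "match.length"), a3 - 1)
  if (substr(orf, 1, 3) != "ATG") stop("ORF does not start with ATG")
  inner <- substr(orf, 4, nchar(orf) - 3)
  list(dna = inner, protein = translate_dna(inner))
}

#' Library diversity report
#'
#' @param variants list of \code{variant_gene}.
#' @param parent optional parent \code{variant_gene} for framework
#'   integrity (fraction of variants matching the parent exactly outside
#'   the CDRs).
#' @return list with \code{n}, \code{distinct_proteins}, \code{aa_freq}
#'   (positions x amino acids matrix, rows summing to 1; NULL when
#'   variant lengths differ) and \code{framework_integrity}.
#' @export
library_stats <- function(variants, parent = NULL) {
  if (!length(variants)) stop("need >= 1 variant")
  prot <- vapply(variants, `[[`, character(1), "protein")
  lens <- nchar(prot)
  aa_freq <- NULL
  if (length(unique(lens)) == 1) {
    m <- do.call(rbind, strsplit(prot, ""))
    aa_freq <- t(vapply(seq_len(ncol(m)), function(j) {
      tab <- table(factor(m[, j], levels = .AA20))
      as.numeric(tab) / length(prot)
    }, numeric(length(.AA20))))
    colnames(aa_freq) <- .AA20
  }
  integrity <- NA_real_
  if (!is.null(parent) && !is.null(parent$cdrs)) {
    fw_ref <- .framework_signature(parent$protein, parent$cdrs)
    ok <- vapply(variants, function(v) {
      cm <- if (!is.null(v$cdrs)) v$cdrs else parent$cdrs
      nchar(v$protein) == cm$seq_length &&
        .framework_signature(v$protein, cm) == fw_ref
    }, logical(1))
    integrity <- mean(ok)
  }
  list(n = length(variants), distinct_proteins = length(unique(prot)),
       aa_freq = aa_freq, framework_integrity = integrity)
}

#' Write variant genes to FASTA
#'
#' @param variants list of \code{variant_gene}.
#' @param path output FASTA.
#' @param what \code{"dna"} or \code{"protein"}.
#' @return invisibly, \code{path}.
#' @export
write_variant_fasta <- function(variants, path, what = c("dna", "protein")) {
  what <- match.arg(what)
  seqs <- vapply(variants, `[[`, character(1), what)
  ids <- vapply(variants, `[[`, character(1), "id")
  ss <- if (what == "dna") Biostrings::DNAStringSet(seqs) else {
    Biostrings::AAStringSet(seqs)
  }
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
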