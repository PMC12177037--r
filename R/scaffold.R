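# Nanobody CDR annotation and tryptophan engineering plans.
#
# Display numbering is 1-based contiguous over the mature nanobody
# sequence by default; IMGT/Kabat renumbering is deliberately not
# implemented -- supply a custom label map if needed.

#' Construct a nanobody record
#'
#' @param id record identifier.
#' @param protein amino-acid sequence (20-letter alphabet).
#' @param dna optional coding DNA; must translate to \code{protein}.
#' @param numbering optional integer vector mapping sequence index to
#'   display number (must be a bijection); default 1-based contiguous.
#' @return object of class \code{nanobody_record}.
#' @export
nanobody_record <- function(id, protein, dna = NULL, numbering = NULL) {
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, .AA20)
  if (length(bad)) stop("non-standard amino acid(s): ", paste(bad, collapse = ", "))
  n <- length(aa)
  if (is.null(numbering)) numbering <- seq_len(n)
  if (length(numbering) != n || anyDuplicated(numbering)) {
    stop("numbering must be a bijection on sequence indices")
  }
  if (!is.null(dna)) {
    if (nchar(dna) != 3 * n) stop("dna length must be 3x protein length")
    if (translate_dna(dna) != protein) stop("dna does not translate to protein")
  }
  structure(list(id = id, protein = protein, dna = dna,
                 numbering = as.integer(numbering)),
            class = "nanobody_record")
}

#' @export
print.nanobody_record <- function(x, ...) {
  cat("nanobody_record '", x$id, "': ", nchar(x$protein), " aa",
      if (!is.null(x$dna)) ", with DNA" else "", "\n", sep = "")
  invisible(x)
}

# display number -> sequence index
.index_of <- function(rec, display) {
  idx <- match(display, rec$numbering)
  if (anyNA(idx)) {
    stop("display position(s) not in record numbering: ",
         paste(display[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Construct a CDR map
#'
#' CDRs are half-open index intervals \code{[start, end)} in sequence
#' coordinates (1-based); the framework is the complement.
#'
#' @param cdr1,cdr2,cdr3 length-2 integer vectors \code{c(start, end)}.
#' @param seq_length sequence length the map applies to.
#' @return object of class \code{cdr_map}.
#' @export
cdr_map <- function(cdr1, cdr2, cdr3, seq_length) {
  iv <- list(cdr1 = as.integer(cdr1), cdr2 = as.integer(cdr2),
             cdr3 = as.integer(cdr3))
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2 || v[1] >= v[2]) stop(nm, " must be c(start, end) with start < end")
    if (v[1] < 1 || v[2] > seq_length + 1) stop(nm, " outside sequence [1, ", seq_length, "]")
  }
  if (!(iv$cdr1[2] <= iv$cdr2[1] && iv$cdr2[2] <= iv$cdr3[1])) {
    stop("CDR intervals must be disjoint and ordered CDR1 < CDR2 < CDR3")
  }
  structure(c(iv, list(seq_length = as.integer(seq_length))), class = "cdr_map")
}

#' Sequence indices covered by the CDRs
#'
#' @param cdrs a \code{cdr_map}.
#' @param which one of "all", "cdr1", "cdr2", "cdr3".
#' @return integer vector of sequence indices.
#' @export
cdr_indices <- function(cdrs, which = "all") {
  pick <- if (which == "all") c("cdr1", "cdr2", "cdr3") else which
  unlist(lapply(pick, function(nm) {
    v <- cdrs[[nm]]
    seq.int(v[1], v[2] - 1L)
  }), use.names = FALSE)
}

# Conserved VHH anchors used by the heuristic annotator.  FR2 is assumed
# to be the canonical 14 residues starting at the conserved framework
# tryptophan (W36 in contiguous numbering); FR3 starts with the RF[TS]IS
# motif and ends with the ...YYC cysteine; FR4 starts with the WG.G
# J-segment motif.
.anchor_regex <- list(fr2_w = "W[FIVY]RQ", fr3_start = "RF[TS]IS",
                      fr4_w = "WG.G")

#' Annotate nanobody CDRs
#'
#' Either validates user-supplied intervals or locates the CDRs from
#' conserved framework anchors (the FR1 cysteine, the W36-family
#' framework tryptophan, the FR3 start motif, the FR3-terminal cysteine
#' and the FR4 WG.G motif).  The heuristic assumes a canonical 14-residue
#' FR2 and flags its confidence; if anchors cannot be found it errors
#' and asks for user-supplied intervals.
#'
#' @param rec \code{nanobody_record} (length >= 90 aa).
#' @param mode \code{"user"} or \code{"anchor"}.
#' @param cdrs for user mode, a \code{cdr_map} or list of three
#'   \code{c(start, end)} half-open intervals.
#' @return \code{cdr_map} with attribute \code{confidence}
#'   (\code{"user"}, \code{"high"} or \code{"low"}).
#' @export
annotate_cdrs <- function(rec, mode = c("user", "anchor"), cdrs = NULL) {
  mode <- match.arg(mode)
  n <- nchar(rec$protein)
  if (n < 90) stop("sequence too short to be a nanobody domain (< 90 aa)")
  if (mode == "user") {
    if (is.null(cdrs)) stop("user mode requires cdrs")
    if (!inherits(cdrs, "cdr_map")) {
      cdrs <- cdr_map(cdrs[[1]], cdrs[[2]], cdrs[[3]], n)
    }
    if (cdrs$seq_length != n) stop("cdr map length does not match record")
    attr(cdrs, "confidence") <- "user"
    return(cdrs)
  }
  p <- rec$protein
  fail <- function(what) {
    stop("anchor-heuristic CDR annotation failed (", what,
         " not found); supply CDRs with mode = 'user'")
  }
  w2 <- regexpr(.anchor_regex$fr2_w, p)
  if (w2 < 0) fail("framework-2 tryptophan motif")
  # FR1 cysteine: last C before the framework tryptophan
  c1 <- max(gregexpr("C", substr(p, 1, w2 - 1))[[1]])
  if (c1 < 0) fail("framework-1 cysteine")
  fr3 <- regexpr(.anchor_regex$fr3_start, substr(p, w2, n)) + w2 - 1L
  if (fr3 < w2) fail("framework-3 start motif")
  rest <- substr(p, fr3, n)
  c2rel <- gregexpr("YYC", rest)[[1]]
  if (c2rel[1] < 0) fail("framework-3 terminal cysteine (YYC)")
  # FR3 is canonically ~30 aa: prefer the first YYC landing near its end,
  # so a chance YYC inside CDR3 is not picked up
  plausible <- c2rel[c2rel >= 20]
  c2 <- (if (length(plausible)) plausible[1] else max(c2rel)) + 2L + fr3 - 1L
  # FR4 is the terminal J segment: take the LAST WG.G match after the
  # cysteine (tryptophan-rich CDR3s can contain the motif internally)
  w4rel <- gregexpr(.anchor_regex$fr4_w, substr(p, c2 + 1L, n))[[1]]
  if (w4rel[1] < 0) fail("framework-4 WG.G motif")
  w4 <- max(w4rel) + c2
  out <- cdr_map(c(c1 + 4L, w2), c(w2 + 14L, fr3), c(c2 + 1L, w4), n)
  conf <- if (w2 >= 30 && w2 <= 45 && c1 >= 15 && (w4 - c2) <= 30) "high" else "low"
  attr(out, "confidence") <- conf
  out
}

#' Enumerate tryptophan-engineering candidate positions
#'
#' Knockout candidates are the CDR tryptophans (minus framework
#' exclusions, default the buried W36); reverse-substitution candidates
#' are the CDR tyrosines.  Framework residues are never proposed.
#'
#' @param rec \code{nanobody_record}.
#' @param cdrs \code{cdr_map} for the record.
#' @param exclude display positions never to propose (default 36).
#' @return list with integer display-position vectors \code{knockout}
#'   (W in CDRs) and \code{reverse} (Y in CDRs).
#' @export
enumerate_candidates <- function(rec, cdrs, exclude = 36) {
  aa <- strsplit(rec$protein, "")[[1]]
  idx <- cdr_indices(cdrs)
  disp <- rec$numbering[idx]
  keep <- !disp %in% exclude
  list(knockout = sort(disp[keep & aa[idx] == "W"]),
       reverse = sort(disp[keep & aa[idx] == "Y"]))
}

#' Build a substitution plan
#'
#' @param rec \code{nanobody_record} the plan applies to.
#' @param positions display positions to mutate.
#' @param to replacement amino acid(s), recycled.
#' @param kind one of \code{"knockout_W>Y"}, \code{"knockout_W>A"},
#'   \code{"reverse_Y>W"}, \code{"custom"}.
#' @return object of class \code{substitution_plan} (data.frame with
#'   columns position, from, to).
#' @export
substitution_plan <- function(rec, positions, to,
                              kind = c("custom", "knockout_W>Y",
                                       "knockout_W>A", "reverse_Y>W")) {
  kind <- match.arg(kind)
  if (anyDuplicated(positions)) stop("positions must be unique")
  if (!length(positions)) {
    plan <- data.frame(position = integer(), from = character(),
                       to = character(), stringsAsFactors = FALSE)
    attr(plan, "kind") <- kind
    class(plan) <- c("substitution_plan", "data.frame")
    return(plan)
  }
  idx <- .index_of(rec, positions)
  from <- substring(rec$protein, idx, idx)
  to <- rep_len(to, length(positions))
  expected_from <- switch(kind, `knockout_W>Y` = "W", `knockout_W>A` = "W",
                          `reverse_Y>W` = "Y", NA_character_)
  if (!is.na(expected_from) && any(from != expected_from)) {
    stop("plan kind ", kind, " expects ", expected_from, " at positions: ",
         paste(positions[from != expected_from], collapse = ", "))
  }
  plan <- data.frame(position = as.integer(positions), from = from, to = to,
                     stringsAsFactors = FALSE)
  attr(plan, "kind") <- kind
  class(plan) <- c("substitution_plan", "data.frame")
  plan
}

#' Apply a substitution plan to a record
#'
#' Produces a new record differing exactly at the planned positions.  If
#' the record carries DNA, each mutated codon is changed by the
#' minimal-nucleotide-change rule (ties broken alphabetically).
#'
#' @param rec \code{nanobody_record}.
#' @param plan \code{substitution_plan} (positions in display numbering).
#' @param id id for the mutant (default parent id plus mutation string).
#' @return new \code{nanobody_record}.
#' @export
apply_plan <- function(rec, plan, id = NULL) {
  stopifnot(inherits(rec, "nanobody_record"))
  if (nrow(plan) == 0) return(rec)
  idx <- .index_of(rec, plan$position)
  cur <- substring(rec$protein, idx, idx)
  if (any(cur != plan$from)) {
    bad <- plan$position[cur != plan$from]
    stop("plan 'from' mismatch at position(s): ", paste(bad, collapse = ", "))
  }
  aa <- strsplit(rec$protein, "")[[1]]
  aa[idx] <- plan$to
  dna <- rec$dna
  if (!is.null(dna)) {
    for (k in seq_along(idx)) dna <- .minimal_codon_change(dna, idx[k], plan$to[k])
  }
  if (is.null(id)) {
    id <- paste0(rec$id, "_", paste0(plan$from, plan$position, plan$to,
                                     collapse = "/"))
  }
  nanobody_record(id, paste(aa, collapse = ""), dna, rec$numbering)
}

#' Validate a multi-tryptophan scaffold
#'
#' @param rec \code{nanobody_record}.
#' @param required display positions that must carry tryptophan
#'   (default the optimised scaffold set 59, 101, 103, 110, 115).
#' @return list with \code{pass} (logical) and \code{missing} (display
#'   positions lacking W).
#' @export
check_scaffold <- function(rec, required = c(59, 101, 103, 110, 115)) {
  idx <- .index_of(rec, required)
  aa <- substring(rec$protein, idx, idx)
  missing <- required[aa != "W"]
  list(pass = length(missing) == 0, missing = as.integer(missing),
       required = as.integer(required))
}

# The optimised multi-tryptophan scaffold used as default parent for
# library construction: a synthetic consensus-framework VHH with
# tryptophans at display positions 59 (CDR2) and 101/103/110/115 (CDR3).
.scaffold_fr1 <- "QVQLVESGGGLVQPGGSLRLSCAAS"          # 1-25, C22
.scaffold_cdr1 <- "GRTFSSYAMG"                        # 26-35
.scaffold_fr2 <- "WFRQAPGKEREFVA"                     # 36-49, W36
.scaffold_cdr2 <- "AISGSGGSTWYADSVKG"                 # 50-66, W59
.scaffold_fr3 <- "RFTISRDNAKNTVYLQMNSLRAEDTAVYYC"     # 67-96, C96
.scaffold_cdr3 <- "AADSWGWGRDYEYWGSSYWDY"             # 97-117, W101/103/110/115
.scaffold_fr4 <- "WGQGTQVTVSS"                        # 118-128

#' The optimised tryptophan scaffold record
#'
#' A synthetic consensus-framework nanobody carrying the optimised
#' quenchbody tryptophan constellation: W59 in CDR2 and W101, W103,
#' W110, W115 in CDR3 (contiguous display numbering), with the buried
#' framework W36.  Used as the default parent for library construction
#' and as ground truth for the CDR-annotation heuristic.
#'
#' @param id record id.
#' @return list with \code{record} (\code{nanobody_record}, including
#'   preferred-codon DNA) and \code{cdrs} (\code{cdr_map}).
#' @export
trp_scaffold <- function(id = "trp_scaffold") {
  protein <- paste0(.scaffold_fr1, .scaffold_cdr1, .scaffold_fr2,
                    .scaffold_cdr2, .scaffold_fr3, .scaffold_cdr3,
                    .scaffold_fr4)
  rec <- nanobody_record(id, protein, dna = reverse_translate(protein))
  l1 <- nchar(.scaffold_fr1); l2 <- nchar(.scaffold_cdr1)
  l3 <- nchar(.scaffold_fr2); l4 <- nchar(.scaffold_cdr2)
  l5 <- nchar(.scaffold_fr3); l6 <- nchar(.scaffold_cdr3)
  cdrs <- cdr_map(c(l1 + 1, l1 + l2 + 1),
                  c(l1 + l2 + l3 + 1, l1 + l2 + l3 + l4 + 1),
                  c(l1 + l2 + l3 + l4 + l5 + 1, l1 + l2 + l3 + l4 + l5 + l6 + 1),
                  nchar(protein))
  list(record = rec, cdrs = cdrs)
}

#' Read nanobody records from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return list of \code{nanobody_record}.
#' @export
read_nanobody_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  lapply(seq_along(ss), function(i) {
    nanobody_record(names(ss)[i], as.character(ss[[i]]))
  })
}

#' Write nanobody records to FASTA
#'
#' @param recs list of \code{nanobody_record} (or a single record).
#' @param path output FASTA path.
#' @param what \code{"protein"} or \code{"dna"}.
#' @return invisibly, \code{path}.
#' @export
write_nanobody_fasta <- function(recs, path, what = c("protein", "dna")) {
  what <- match.arg(what)
  if (inherits(recs, "nanobody_record")) recs <- list(recs)
  seqs <- vapply(recs, function(r) {
    s <- r[[what]]
    if (is.null(s)) stop("record '", r$id, "' has no ", what)
    s
  }, character(1))
  ids <- vapply(recs, `[[`, character(1), "id")
  ss <- if (what == "protein") Biostrings::AAStringSet(seqs) else {
    Biostrings::DNAStringSet(seqs)
  }
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
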