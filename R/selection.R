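# Multi-round selection sequencing analysis: read quality filtering,
# per-variant abundances, blank-control enrichment scores, hit lists,
# and droplet-loading statistics.
#
# The quality filter is defined here as: both constant anchors found in
# order (on either strand), the enclosed region in frame and stop-free,
# framework segments matching the reference within tolerance, and CDR
# lengths in the allowed set.  Every criterion is individually
# toggleable and reported, and the filter is sequence-based only
# (quality strings are ignored).

#' Specify the assembled-gene quality filter
#'
#' @param anchor5,anchor3 constant flanking subsequences bracketing the
#'   ORF (defaults: the cassette RBS spacer and terminator prefix).
#' @param framework character vector of reference framework protein
#'   segments (FR1..FR4) that must appear in order in the translated
#'   call; NULL disables the framework criterion.
#' @param max_fw_mismatch maximum mismatches allowed per framework
#'   segment (default 0).
#' @param cdr_lengths list of three integer vectors of allowed CDR
#'   lengths (aa); NULL disables the length criterion.
#' @param check_frame require in-frame, stop-free translation.
#' @return object of class \code{filter_spec}.
#' @export
filter_spec <- function(anchor5 = cassette_elements()$rbs,
                        anchor3 = substr(cassette_elements()$t7_terminator, 1, 15),
                        framework = NULL, max_fw_mismatch = 0,
                        cdr_lengths = NULL, check_frame = TRUE) {
  if (!nzchar(anchor5) || !nzchar(anchor3)) stop("anchors must be non-empty")
  structure(list(anchor5 = toupper(anchor5), anchor3 = toupper(anchor3),
                 framework = framework,
                 max_fw_mismatch = as.integer(max_fw_mismatch),
                 cdr_lengths = cdr_lengths, check_frame = check_frame),
            class = "filter_spec")
}

#' Build a filter spec from a parent record and its CDR map
#'
#' @param parent \code{variant_gene} or \code{nanobody_record}.
#' @param cdrs \code{cdr_map} (taken from the parent if absent).
#' @param elements \code{\link{cassette_elements}} for the anchors.
#' @param cdr_length_slack allowed deviation (aa) from the parent CDR
#'   lengths; NULL disables the length criterion.
#' @param ... passed to \code{\link{filter_spec}}.
#' @return \code{filter_spec}.
#' @export
filter_spec_for <- function(parent, cdrs = parent$cdrs,
                            elements = cassette_elements(),
                            cdr_length_slack = NULL, ...) {
  if (is.null(cdrs)) stop("need a CDR map")
  p <- parent$protein
  fr <- c(substr(p, 1, cdrs$cdr1[1] - 1),
          substr(p, cdrs$cdr1[2], cdrs$cdr2[1] - 1),
          substr(p, cdrs$cdr2[2], cdrs$cdr3[1] - 1),
          substr(p, cdrs$cdr3[2], nchar(p)))
  lens <- NULL
  if (!is.null(cdr_length_slack)) {
    l0 <- vapply(c("cdr1", "cdr2", "cdr3"), function(nm) {
      diff(cdrs[[nm]])
    }, integer(1))
    lens <- lapply(l0, function(l) seq(max(1, l - cdr_length_slack),
                                       l + cdr_length_slack))
  }
  filter_spec(anchor5 = elements$rbs,
              anchor3 = substr(elements$t7_terminator, 1, 15),
              framework = fr, cdr_lengths = lens, ...)
}

#' Read a FASTQ file tolerantly
#'
#' Well-formed records are returned as sequences; malformed records
#' (bad header, missing separator, length mismatch between sequence and
#' quality) are skipped and counted, never silently dropped.
#'
#' @param path FASTQ path (gzip allowed).
#' @return list with \code{sequences} (character) and
#'   \code{n_malformed}.
#' @export
read_fastq_reads <- function(path) {
  lines <- readLines(path)
  n_mal <- 0L
  if (length(lines) %% 4 != 0) {
    # trailing partial record(s)
    n_mal <- n_mal + 1L
    lines <- lines[seq_len(4 * (length(lines) %/% 4))]
  }
  if (!length(lines)) return(list(sequences = character(), n_malformed = n_mal))
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  sep <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  ok <- startsWith(hdr, "@") & startsWith(sep, "+") &
    nchar(seqs) == nchar(qual) & grepl("^[ACGTN]*$", seqs)
  n_mal <- n_mal + sum(!ok)
  if (n_mal > 0) {
    message("read_fastq_reads: skipped ", n_mal, " malformed record(s) in ", path)
  }
  list(sequences = seqs[ok], n_malformed = n_mal)
}

# positions of `pattern` in each of `x` (fixed match), -1 when absent
.vfind <- function(pattern, x) {
  as.integer(regexpr(pattern, x, fixed = TRUE))
}

#' Quality-filter selection reads and call variants
#'
#' A read passes iff (i) both anchors are found in order on either
#' strand, (ii) the enclosed region is a whole number of codons starting
#' with ATG and translating without internal stops (when
#' \code{check_frame}), (iii) the framework segments match the reference
#' within tolerance, and (iv) CDR lengths are allowed.  The variant call
#' is the translated protein between the anchors (start/stop trimmed).
#'
#' @param reads FASTQ path, or a character vector of read sequences.
#' @param spec \code{\link{filter_spec}}.
#' @param round_id label for the report.
#' @return list with \code{report} (round id, total, passed, fraction,
#'   per-criterion failure counts) and \code{calls} (character vector of
#'   passing protein calls).
#' @export
quality_filter <- function(reads, spec = filter_spec(), round_id = "round1") {
  n_mal <- 0L
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fq <- read_fastq_reads(reads)
    reads <- fq$sequences
    n_mal <- fq$n_malformed
  }
  reads <- toupper(as.character(reads))
  total <- length(reads) + n_mal
  fails <- c(anchors = 0L, frame = 0L, framework = 0L, cdr_length = 0L,
             malformed = n_mal)

  # anchor search, forward then reverse strand
  a5 <- .vfind(spec$anchor5, reads)
  a3 <- .vfind(spec$anchor3, reads)
  fwd_ok <- a5 > 0 & a3 > 0 & (a3 > a5 + nchar(spec$anchor5) - 1)
  need_rc <- !fwd_ok
  if (any(need_rc)) {
    rc <- .revcomp(reads[need_rc])
    a5r <- .vfind(spec$anchor5, rc)
    a3r <- .vfind(spec$anchor3, rc)
    rc_ok <- a5r > 0 & a3r > 0 & (a3r > a5r + nchar(spec$anchor5) - 1)
    reads[need_rc][rc_ok] <- rc[rc_ok]
    a5[need_rc][rc_ok] <- a5r[rc_ok]
    a3[need_rc][rc_ok] <- a3r[rc_ok]
    fwd_ok[need_rc] <- rc_ok
  }
  fails["anchors"] <- sum(!fwd_ok)
  keep <- which(fwd_ok)
  inner <- substr(reads[keep], a5[keep] + nchar(spec$anchor5), a3[keep] - 1)

  if (spec$check_frame) {
    frame_ok <- nchar(inner) >= 9 & nchar(inner) %% 3 == 0 &
      startsWith(inner, "ATG")
    prot <- rep(NA_character_, length(inner))
    if (any(frame_ok)) prot[frame_ok] <- translate_dna(inner[frame_ok])
    stop_ok <- frame_ok & endsWith(prot, "*") &
      !grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE)
    stop_ok[is.na(stop_ok)] <- FALSE
    fails["frame"] <- sum(!stop_ok)
    keep <- keep[stop_ok]
    calls <- substr(prot[stop_ok], 2, nchar(prot[stop_ok]) - 1)
  } else {
    ok <- nchar(inner) %% 3 == 0 & nchar(inner) >= 9
    fails["frame"] <- sum(!ok)
    keep <- keep[ok]
    calls <- translate_dna(substring(inner[ok], 4, nchar(inner[ok]) - 3))
  }

  if (!is.null(spec$framework) && length(calls)) {
    seg <- .locate_frameworks(calls, spec$framework, spec$max_fw_mismatch)
    fails["framework"] <- sum(!seg$ok)
    calls <- calls[seg$ok]
    cdr_len <- seg$cdr_len[seg$ok, , drop = FALSE]
    if (!is.null(spec$cdr_lengths) && length(calls)) {
      len_ok <- rep(TRUE, length(calls))
      for (k in 1:3) len_ok <- len_ok & cdr_len[, k] %in% spec$cdr_lengths[[k]]
      fails["cdr_length"] <- sum(!len_ok)
      calls <- calls[len_ok]
    }
  }

  passed <- length(calls)
  report <- list(round = round_id, total = total, passed = passed,
                 pass_fraction = if (total > 0) passed / total else NA_real_,
                 failures = as.list(fails))
  class(report) <- "filter_report"
  list(report = report, calls = calls)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report %s: %d/%d reads passed (%.1f%%)\n",
              x$round, x$passed, x$total, 100 * x$pass_fraction))
  invisible(x)
}

# Locate the four framework segments, in order, in each call.
# Returns ok flags plus CDR lengths (gaps between segments).
.locate_frameworks <- function(calls, fr, max_mm = 0) {
  n <- length(calls)
  ok <- rep(TRUE, n)
  pos <- matrix(NA_integer_, n, 4)
  if (max_mm == 0) {
    at <- 1L
    offset <- rep(1L, n)
    for (k in 1:4) {
      hit <- as.integer(regexpr(fr[k], substring(calls, offset), fixed = TRUE))
      ok <- ok & hit > 0
      pos[, k] <- offset + hit - 1L
      offset <- pos[, k] + nchar(fr[k])
    }
    # FR1 must be a prefix and FR4 a suffix
    ok <- ok & pos[, 1] == 1 & (pos[, 4] + nchar(fr[4]) - 1L) == nchar(calls)
  } else {
    for (i in seq_len(n)) {
      subj <- Biostrings::AAString(calls[i])
      offset <- 1L
      for (k in 1:4) {
        m <- Biostrings::matchPattern(fr[k], subj, max.mismatch = max_mm)
        starts <- Biostrings::start(m)
        starts <- starts[starts >= offset]
        if (!length(starts)) { ok[i] <- FALSE; break }
        pos[i, k] <- starts[1]
        offset <- pos[i, k] + nchar(fr[k])
      }
      if (ok[i] && (pos[i, 1] != 1 ||
                    pos[i, 4] + nchar(fr[4]) - 1L != nchar(calls[i]))) {
        ok[i] <- FALSE
      }
    }
  }
  cdr_len <- cbind(pos[, 2] - (pos[, 1] + nchar(fr[1])),
                   pos[, 3] - (pos[, 2] + nchar(fr[2])),
                   pos[, 4] - (pos[, 3] + nchar(fr[3])))
  list(ok = ok & !is.na(rowSums(pos)), cdr_len = cdr_len)
}

#' Tabulate per-round variant abundances
#'
#' Counts are collapsed at the protein level (silent DNA variants
#' merge); per-round relative abundances are counts over the round's
#' passed-read total.
#'
#' @param calls named list: one character vector of variant calls per
#'   round, in round order.
#' @return object of class \code{abundance_table}: matrices
#'   \code{counts} and \code{freq} (variants x rounds).
#' @export
count_variants <- function(calls) {
  if (!length(calls)) stop("need >= 1 round")
  if (is.null(names(calls))) names(calls) <- paste0("round", seq_along(calls))
  empty <- names(calls)[lengths(calls) == 0]
  if (length(empty)) stop("round(s) with no calls: ", paste(empty, collapse = ", "))
  variants <- sort(unique(unlist(calls, use.names = FALSE)))
  counts <- vapply(calls, function(v) {
    as.integer(table(factor(v, levels = variants)))
  }, integer(length(variants)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(variants))
  rownames(counts) <- variants
  colnames(counts) <- names(calls)
  freq <- sweep(counts, 2, colSums(counts), "/")
  structure(list(counts = counts, freq = freq), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$counts), "variants x", ncol(x$counts),
      "rounds;", sum(x$counts), "reads total\n")
  invisible(x)
}

#' Blank-control enrichment scores
#'
#' The enrichment score of a variant is its relative abundance in the
#' final selection round divided by its abundance in the blank
#' (no-antigen) bead control.  Variants absent from the blank use the
#' pseudo-floor 1/(blank total + 1) -- a conservative upper bound on
#' their unobserved blank abundance.
#'
#' @param sel \code{abundance_table} for the selection.
#' @param blank \code{abundance_table} for the blank control (its last
#'   round is used).
#' @param final_round column name or index in \code{sel}; default the
#'   last round.
#' @param pseudo pseudo-floor abundance; default 1/(blank total + 1).
#' @param threshold enrichment score above which a variant is flagged a
#'   hit (default 200).
#' @return data.frame (class \code{enrichment_result}) with variant,
#'   selection/blank abundance, score and hit flag, sorted by
#'   descending score (ties lexicographic).
#' @export
enrichment_scores <- function(sel, blank, final_round = NULL, pseudo = NULL,
                              threshold = 200) {
  stopifnot(inherits(sel, "abundance_table"), inherits(blank, "abundance_table"))
  if (sum(blank$counts) == 0) stop("blank table is empty")
  if (is.null(final_round)) final_round <- ncol(sel$freq)
  if (is.character(final_round) && !final_round %in% colnames(sel$freq)) {
    stop("final_round '", final_round, "' not in selection table")
  }
  sel_ab <- sel$freq[, final_round]
  blank_col <- ncol(blank$freq)
  blank_total <- sum(blank$counts[, blank_col])
  if (is.null(pseudo)) pseudo <- 1 / (blank_total + 1)
  blank_ab <- blank$freq[match(rownames(sel$freq), rownames(blank$freq)), blank_col]
  blank_ab[is.na(blank_ab)] <- 0
  score <- sel_ab / pmax(blank_ab, pseudo)
  out <- data.frame(variant = rownames(sel$freq),
                    selection_abundance = unname(sel_ab),
                    blank_abundance = unname(blank_ab),
                    score = unname(score),
                    hit = unname(score > threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$variant), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "pseudo") <- pseudo
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Select hits from enrichment results or an abundance table
#'
#' Two selection rules: \code{"score_gt"} keeps variants with enrichment
#' score above a threshold (default 200); \code{"top_n"} keeps the top n
#' variants (default 12) by final-round abundance.  Ordering is stable
#' and ties are broken lexicographically by variant key.
#'
#' @param x \code{enrichment_result} (for score_gt) or
#'   \code{abundance_table} (for top_n).
#' @param rule \code{"score_gt"} or \code{"top_n"}.
#' @param threshold score threshold for score_gt.
#' @param n number of hits for top_n.
#' @param final_round round used for top_n ranking (default last).
#' @return data.frame of ranked hits.
#' @export
select_hits <- function(x, rule = c("score_gt", "top_n"), threshold = 200,
                        n = 12, final_round = NULL) {
  rule <- match.arg(rule)
  if (rule == "score_gt") {
    stopifnot(inherits(x, "enrichment_result"))
    hits <- x[x$score > threshold, , drop = FALSE]
    hits <- hits[order(-hits$score, hits$variant), ]
  } else {
    stopifnot(inherits(x, "abundance_table"))
    if (is.null(final_round)) final_round <- ncol(x$freq)
    ab <- x$freq[, final_round]
    ord <- order(-ab, rownames(x$freq))
    take <- head(ord, n)
    hits <- data.frame(variant = rownames(x$freq)[take],
                       final_abundance = unname(ab[take]),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  hits$rank <- seq_len(nrow(hits))
  hits
}

#' Poisson droplet-loading statistics
#'
#' For template concentration C (molar) encapsulated in droplets of
#' volume V (litre), the mean occupancy is lambda = C * N_A * V and the
#' per-droplet gene count is Poisson.  At ~125 pM in femtolitre-scale
#' droplets the loading is ~0.1 genes per droplet, keeping multi-gene
#' droplets (which would break the genotype-phenotype link) rare.
#'
#' @param concentration template concentration, mol/L.
#' @param volume droplet volume, L.
#' @param lambda mean occupancy, overrides concentration/volume.
#' @return list with \code{lambda}, \code{p_empty}, \code{p_single},
#'   \code{p_multi} and the fraction of occupied droplets that are
#'   single-gene (\code{single_given_occupied}).
#' @export
droplet_loading <- function(concentration = NULL, volume = NULL, lambda = NULL) {
  if (is.null(lambda)) {
    if (is.null(concentration) || is.null(volume)) {
      stop("supply lambda, or concentration and volume")
    }
    if (concentration <= 0 || volume <= 0) stop("concentration and volume must be > 0")
    lambda <- concentration * 6.02214076e23 * volume
  }
  if (lambda <= 0) stop("lambda must be > 0")
  p0 <- dpois(0, lambda)
  p1 <- dpois(1, lambda)
  list(lambda = lambda, p_empty = p0, p_single = p1,
       p_multi = 1 - p0 - p1,
       single_given_occupied = p1 / (1 - p0))
}

#' Write an abundance table to TSV
#'
#' @param tab \code{abundance_table}.
#' @param path output TSV.
#' @param what \code{"freq"} or \code{"counts"}.
#' @return invisibly, \code{path}.
#' @export
write_abundance_tsv <- function(tab, path, what = c("freq", "counts")) {
  what <- match.arg(what)
  m <- tab[[what]]
  out <- data.frame(variant = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write enrichment results to JSON
#'
#' @param res \code{enrichment_result}.
#' @param path output JSON.
#' @return invisibly, \code{path}.
#' @export
write_enrichment_json <- function(res, path) {
  jsonlite::write_json(list(threshold = attr(res, "threshold"),
                            pseudo_floor = attr(res, "pseudo"),
                            results = as.data.frame(res)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
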