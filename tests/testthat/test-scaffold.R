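# CDR annotation and tryptophan-engineering plans.

test_that("user-supplied CDR intervals are validated and passed through", {
  rec <- standin_record()
  cm <- annotate_cdrs(rec, mode = "user",
                      cdrs = list(c(26, 36), c(50, 67), c(97, 118)))
  expect_s3_class(cm, "cdr_map")
  expect_equal(c(cm$cdr3), c(97, 118))
  expect_identical(attr(cm, "confidence"), "user")

  expect_error(cdr_map(c(26, 55), c(50, 67), c(97, 118), 128), "disjoint")
  expect_error(cdr_map(c(36, 26), c(50, 67), c(97, 118), 128), "start < end")
  expect_error(annotate_cdrs(nanobody_record("short", strrep("A", 50)),
                             mode = "user", cdrs = standin_cdrs()),
               "too short")
})

test_that("anchor heuristic recovers the generating CDR intervals", {
  sc <- trp_scaffold()
  cm <- annotate_cdrs(sc$record, mode = "anchor")
  expect_equal(unclass(cm)[c("cdr1", "cdr2", "cdr3")],
               unclass(sc$cdrs)[c("cdr1", "cdr2", "cdr3")])
  expect_identical(attr(cm, "confidence"), "high")

  # still recovered after CDR mutations (frameworks untouched)
  mut <- apply_plan(sc$record,
                    substitution_plan(sc$record, c(101, 110), c("Y", "A")))
  cm2 <- annotate_cdrs(mut, mode = "anchor")
  expect_equal(unclass(cm2)[c("cdr1", "cdr2", "cdr3")],
               unclass(sc$cdrs)[c("cdr1", "cdr2", "cdr3")])

  # anchor-free sequence instructs user-supplied mode
  expect_error(annotate_cdrs(nanobody_record("x", strrep("A", 120)),
                             mode = "anchor"), "user")
})

test_that("enumerate_candidates proposes CDR W/Y positions and excludes W36", {
  # stand-in with W at 36/103/115 and Y at 27/104/110
  rec <- standin_record(c("36" = "W", "103" = "W", "115" = "W",
                          "27" = "Y", "104" = "Y", "110" = "Y"))
  cand <- enumerate_candidates(rec, standin_cdrs())
  expect_equal(cand$knockout, c(103, 115))
  expect_equal(cand$reverse, c(27, 104, 110))

  # CDR-free composition -> both sets empty
  plain <- standin_record()
  cand0 <- enumerate_candidates(plain, standin_cdrs())
  expect_length(cand0$knockout, 0)
  expect_length(cand0$reverse, 0)

  # random sequences: equals a brute-force scan over CDR intervals
  set.seed(53)
  cdrs <- standin_cdrs()
  for (k in 1:5) {
    aa <- sample(c("A", "G", "W", "Y", "S"), 128, replace = TRUE)
    rec <- nanobody_record("rand", paste(aa, collapse = ""))
    cand <- enumerate_candidates(rec, cdrs, exclude = 36)
    in_cdr <- cdr_indices(cdrs)
    expect_equal(cand$knockout,
                 sort(setdiff(in_cdr[aa[in_cdr] == "W"], 36)))
    expect_equal(cand$reverse,
                 sort(setdiff(in_cdr[aa[in_cdr] == "Y"], 36)))
    # never outside CDRs, never an exclusion
    expect_true(all(cand$knockout %in% in_cdr))
    expect_false(36 %in% c(cand$knockout, cand$reverse))
  }
})

test_that("apply_plan mutates exactly the planned positions and round-trips", {
  sc <- trp_scaffold()
  rec <- sc$record

  expect_identical(apply_plan(rec, substitution_plan(rec, integer(), character())),
                   rec)

  # involution: W103Y then Y103W restores the parent sequence
  koy <- apply_plan(rec, substitution_plan(rec, 103, "Y", kind = "knockout_W>Y"))
  back <- apply_plan(koy, substitution_plan(koy, 103, "W", kind = "reverse_Y>W"))
  expect_identical(back$protein, rec$protein)
  expect_identical(translate_dna(back$dna), rec$protein)

  # a triple plan produces exactly 3 mismatches vs parent
  rec3 <- standin_record(c("27" = "Y", "104" = "Y", "110" = "Y"))
  trip <- apply_plan(rec3, substitution_plan(rec3, c(27, 104, 110), "W",
                                             kind = "reverse_Y>W"))
  diffs <- which(strsplit(trip$protein, "")[[1]] != strsplit(rec3$protein, "")[[1]])
  expect_equal(diffs, c(27, 104, 110))

  # from-mismatch names the offending position
  expect_error(substitution_plan(rec, 50, "W", kind = "reverse_Y>W"), "50")
  bad <- substitution_plan(rec, 103, "Y")
  expect_error(apply_plan(apply_plan(rec, bad), bad), "103")

  # composition of disjoint plans is order-independent and length-preserving
  p1 <- substitution_plan(rec, 101, "A")
  p2 <- substitution_plan(rec, 115, "Y")
  ab <- apply_plan(apply_plan(rec, p1), p2)
  ba <- apply_plan(apply_plan(rec, p2), p1)
  expect_identical(ab$protein, ba$protein)
  expect_identical(ab$dna, ba$dna)
  expect_equal(nchar(ab$protein), nchar(rec$protein))
})

test_that("DNA mutations use the minimal-codon-change rule", {
  sc <- trp_scaffold()
  rec <- sc$record
  mut <- apply_plan(rec, substitution_plan(rec, 103, "Y"))
  i <- 3 * 102 + 1
  parent_codon <- substr(rec$dna, i, i + 2)   # TGG (W)
  mutant_codon <- substr(mut$dna, i, i + 2)
  expect_equal(parent_codon, "TGG")
  # TAC and TAT are both 2 changes from TGG; the tie breaks alphabetically
  expect_equal(mutant_codon, "TAC")
  hd <- sum(strsplit(parent_codon, "")[[1]] != strsplit(mutant_codon, "")[[1]])
  expect_equal(hd, 2)
  # all other codons untouched
  expect_equal(sum(strsplit(rec$dna, "")[[1]] != strsplit(mut$dna, "")[[1]]), hd)
})

test_that("check_scaffold verifies the optimised tryptophan constellation", {
  sc <- trp_scaffold()
  expect_true(check_scaffold(sc$record)$pass)

  w115y <- apply_plan(sc$record, substitution_plan(sc$record, 115, "Y"))
  res <- check_scaffold(w115y)
  expect_false(res$pass)
  expect_equal(res$missing, 115L)

  combo <- apply_plan(sc$record,
                      substitution_plan(sc$record,
                                        c(59, 101, 103, 110, 115), "Y",
                                        kind = "knockout_W>Y"))
  res5 <- check_scaffold(combo)
  expect_false(res5$pass)
  expect_equal(res5$missing, c(59L, 101L, 103L, 110L, 115L))
})

test_that("FASTA round trip preserves records", {
  sc <- trp_scaffold()
  f <- tempfile(fileext = ".fasta")
  write_nanobody_fasta(list(sc$record), f)
  back <- read_nanobody_fasta(f)
  expect_equal(back[[1]]$protein, sc$record$protein)
  expect_equal(back[[1]]$id, sc$record$id)
})
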