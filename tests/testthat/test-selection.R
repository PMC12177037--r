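# Read filtering, abundance tables, enrichment scores and droplet stats.

small_library <- function(n = 20, seed = 2) {
  sc <- trp_scaffold()
  des <- library_design(sc$record, sc$cdrs, mode = "full_trim")
  sample_library(des, n, seed = seed)
}

test_that("exact cassettes pass the filter and frameshifts fail", {
  lib <- small_library(5)
  spec <- filter_spec_for(lib[[1]])
  reads <- vapply(lib, assemble_cassette, character(1))
  res <- quality_filter(reads, spec)
  expect_equal(res$report$passed, 5)
  expect_identical(sort(res$calls),
                   sort(vapply(lib, `[[`, character(1), "protein")))

  # reverse-strand reads also pass
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  expect_equal(quality_filter(rc, spec)$report$passed, 5)

  # 1-nt deletion inside CDR2 causes a frameshift and fails
  cm <- lib[[1]]$cdrs
  orf_offset <- nchar(cassette_elements()$fwd_primer) +
    nchar(cassette_elements()$t7_promoter) + nchar(cassette_elements()$rbs) + 3
  nt <- orf_offset + 3 * (cm$cdr2[1] - 1) + 2
  shifted <- paste0(substr(reads[1], 1, nt - 1),
                    substr(reads[1], nt + 1, nchar(reads[1])))
  res2 <- quality_filter(shifted, spec)
  expect_equal(res2$report$passed, 0)
  expect_equal(res2$report$failures$frame, 1)
})

test_that("pass fraction recovers the simulated junk rate", {
  lib <- small_library(30)
  spec <- filter_spec_for(lib[[1]])
  sim <- simulate_selection(
    selection_sim_spec(lib, rounds = 1, reads_per_round = 1e4,
                       junk_rate = 0.30),
    seed = 19)
  res <- quality_filter(sim$reads[[1]], spec)
  se <- sqrt(0.7 * 0.3 / 1e4)
  expect_lt(abs(res$report$pass_fraction - 0.70), 3 * se)
})

test_that("pass fraction ignores read order and FASTQ quality strings", {
  lib <- small_library(10)
  spec <- filter_spec_for(lib[[1]])
  sim <- simulate_selection(
    selection_sim_spec(lib, rounds = 1, reads_per_round = 500,
                       junk_rate = 0.4), seed = 23)
  reads <- sim$reads[[1]]
  f0 <- quality_filter(reads, spec)$report$pass_fraction
  f1 <- quality_filter(rev(reads), spec)$report$pass_fraction
  expect_equal(f0, f1)

  # same reads via FASTQ with two different quality encodings
  write_fq <- function(rd, qual_char) {
    f <- tempfile(fileext = ".fastq")
    writeLines(as.vector(rbind(paste0("@r", seq_along(rd)), rd, "+",
                               strrep(qual_char, nchar(rd)))), f)
    f
  }
  fa <- quality_filter(write_fq(reads, "I"), spec)$report$pass_fraction
  fb <- quality_filter(write_fq(reads, "#"), spec)$report$pass_fraction
  expect_equal(fa, f0)
  expect_equal(fb, f0)
})

test_that("malformed FASTQ records are skipped and counted, not silent", {
  lib <- small_library(2)
  reads <- vapply(lib, assemble_cassette, character(1))
  f <- tempfile(fileext = ".fastq")
  writeLines(c(paste0("@r1"), reads[1], "+", strrep("I", nchar(reads[1])),
               "BADHEADER", reads[2], "+", strrep("I", nchar(reads[2]))), f)
  expect_message(out <- read_fastq_reads(f), "skipped 1 malformed")
  expect_equal(length(out$sequences), 1)
  expect_equal(out$n_malformed, 1)
  res <- quality_filter(f, filter_spec_for(lib[[1]]))
  expect_equal(res$report$total, 2)
  expect_equal(res$report$passed, 1)
})

test_that("count_variants collapses at protein level and tallies correctly", {
  tab <- count_variants(list(r1 = c(rep("A", 8), rep("B", 2))))
  expect_equal(unname(tab$freq[, 1]), c(0.8, 0.2))

  one <- count_variants(list(r1 = rep("X", 5), r2 = rep("X", 9)))
  expect_equal(unname(one$freq), matrix(1, 1, 2))

  expect_error(count_variants(list(r1 = c("A"), r2 = character())), "r2")

  # random multinomial draw equals a brute-force tally
  set.seed(61)
  vars <- paste0("v", 1:12)
  calls <- lapply(1:3, function(r) sample(vars, 400, replace = TRUE))
  names(calls) <- paste0("round", 1:3)
  tab <- count_variants(calls)
  for (r in 1:3) {
    brute <- table(calls[[r]])
    expect_equal(tab$counts[names(brute), r], as.integer(brute),
                 ignore_attr = TRUE)
  }
  expect_equal(unname(colSums(tab$freq)), rep(1, 3), tolerance = 1e-9)
})

test_that("enrichment scores divide selection by blank abundance with a floor", {
  # sel abundance 0.04, blank 0.0001 -> score 400, hit at threshold 200
  sel <- count_variants(list(r3 = c(rep("hit", 40), rep("bg", 960))))
  blank <- count_variants(list(b = c(rep("hit", 1), rep("bg", 9999))))
  es <- enrichment_scores(sel, blank, threshold = 200)
  expect_equal(es$score[es$variant == "hit"], 0.04 / 1e-4, tolerance = 1e-9)
  expect_true(es$hit[es$variant == "hit"])
  expect_false(es$hit[es$variant == "bg"])

  # selection identical to blank -> all scores 1, no hits
  calls <- c(rep("a", 30), rep("b", 70))
  es2 <- enrichment_scores(count_variants(list(r = calls)),
                           count_variants(list(r = calls)))
  expect_equal(es2$score, c(1, 1))
  expect_false(any(es2$hit))

  # a variant absent from the blank uses the documented pseudo-floor
  selx <- count_variants(list(r = c(rep("novel", 5), rep("bg", 95))))
  blankx <- count_variants(list(b = rep("bg", 1e5)))
  esx <- enrichment_scores(selx, blankx)
  expect_equal(attr(esx, "pseudo"), 1 / (1e5 + 1))
  expect_equal(esx$score[esx$variant == "novel"], 0.05 * (1e5 + 1),
               tolerance = 1e-9)

  empty_blank <- structure(list(counts = matrix(0L, 1, 1, dimnames = list("a", "b")),
                                freq = matrix(NaN, 1, 1)),
                           class = "abundance_table")
  expect_error(enrichment_scores(sel, empty_blank), "empty")
})

test_that("select_hits applies the hit rules with stable tie-breaks", {
  sel <- count_variants(list(r = c(rep("x", 15), rep("y", 25), rep("z", 60))))
  blank <- count_variants(list(b = c(rep("x", 100), rep("y", 100), rep("z", 60),
                                     rep("pad", 99740))))
  es <- enrichment_scores(sel, blank)
  es$score <- c(1000, 250, 150)[match(es$variant, c("z", "y", "x"))]
  es$hit <- es$score > 200
  hits <- select_hits(es, "score_gt", threshold = 200)
  expect_equal(hits$variant, c("z", "y"))
  expect_equal(hits$rank, 1:2)

  # top-12 by final-round abundance out of 20 variants
  set.seed(71)
  calls <- list(r5 = sample(paste0("v", sprintf("%02d", 1:20)), 5000,
                            replace = TRUE, prob = 20:1))
  hits12 <- select_hits(count_variants(calls), "top_n", n = 12)
  expect_equal(nrow(hits12), 12)
  ab <- count_variants(calls)$freq[, 1]
  expect_equal(hits12$final_abundance, sort(ab, decreasing = TRUE)[1:12],
               ignore_attr = TRUE)

  # all-tied abundances resolve lexicographically
  tied <- count_variants(list(r = rep(c("b", "a", "c"), each = 10)))
  ht <- select_hits(tied, "top_n", n = 2)
  expect_equal(ht$variant, c("a", "b"))
})

test_that("droplet loading follows the Poisson occupancy model", {
  # ~125 pM in ~1.33 fL droplets -> lambda ~ 0.1 genes/droplet
  dp <- droplet_loading(concentration = 125e-12, volume = 1.33e-15)
  expect_equal(dp$lambda, 125e-12 * 6.02214076e23 * 1.33e-15, tolerance = 1e-12)
  expect_equal(dp$lambda, 0.1, tolerance = 0.01)

  d01 <- droplet_loading(lambda = 0.1)
  expect_equal(d01$p_multi, 1 - exp(-0.1) * 1.1, tolerance = 1e-12)
  expect_equal(d01$p_multi, 0.00468, tolerance = 1e-3)

  # lambda -> 0: multi-occupancy vanishes
  expect_lt(droplet_loading(lambda = 1e-6)$p_multi, 1e-9)
  expect_error(droplet_loading(concentration = 0, volume = 1e-15), "> 0")
})

test_that("enrichment over rounds ranks variants by fitness", {
  lib <- small_library(25, seed = 41)
  fitness <- exp(seq(-0.7, 0.7, length.out = 25))
  spec <- filter_spec_for(lib[[1]])
  sim <- simulate_selection(
    selection_sim_spec(lib, fitness = fitness, rounds = 5,
                       reads_per_round = 2e4, junk_rate = 0.1),
    seed = 43)
  qf <- lapply(sim$reads, function(r) quality_filter(r, spec)$calls)
  tab <- count_variants(qf)
  prot <- vapply(lib, `[[`, character(1), "protein")
  f1 <- tab$freq[prot, 1]
  f5 <- tab$freq[prot, 5]
  growth <- (f5 + 1e-6) / (f1 + 1e-6)
  rc <- cor(rank(fitness), rank(growth), method = "spearman")
  expect_gte(rc, 0.9)
})
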