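test_that("motif canonicalization picks the minimum over rotations and reverse complements", {
  expect_identical(canonical_motif("TAA"), "AAT")
  expect_identical(canonical_motif("AC"), "AC")
  expect_identical(canonical_motif("GT"), "AC")
  # full (AAT) class: all rotations and reverse-complement rotations collapse
  class_aat <- c("AAT", "ATA", "TAA", "ATT", "TAT", "TTA")
  expect_identical(unique(canonical_motif(class_aat)), "AAT")
  # idempotence and class-function property on random motifs
  set.seed(41)
  for (k in 2:6) {
    m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
               collapse = "")
    can <- canonical_motif(m)
    expect_identical(canonical_motif(can), can)
    writings <- c(vapply(seq_len(k), function(i)
      paste0(substr(m, i, k), substr(m, 1, i - 1)), character(1)))
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(m, "")[[1]]), collapse = ""))
    writings <- c(writings, vapply(seq_len(k), function(i)
      paste0(substr(rc, i, k), substr(rc, 1, i - 1)), character(1)))
    expect_identical(unique(canonical_motif(writings)), can)
  }
  expect_error(canonical_motif("ANT"), "invalid motif")
})

test_that("period minimality rejects repeats of shorter units", {
  expect_false(is_period_minimal("ATAT"))
  expect_false(is_period_minimal("ATATAT"))
  expect_true(is_period_minimal("AAT"))
  expect_identical(is_period_minimal(c("AA", "AAAA", "AAGAAG", "ACGACG",
                                       "ACGTAC")),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("compound and interrupted repeats are reported as separate loci", {
  compound <- find_perfect_ssrs(
    paste0("GGG", strrep("TC", 8), strrep("TA", 6), "GGG"))
  expect_equal(nrow(compound), 2L)
  expect_identical(compound$canonical_motif, c("AG", "AT"))
  expect_equal(compound$length_bp, c(16L, 12L))
  expect_equal(compound$repeat_count, c(8L, 6L))

  imperfect <- find_perfect_ssrs(
    paste0(strrep("TA", 21), "G", strrep("AT", 6)))
  expect_equal(nrow(imperfect), 2L)
  expect_identical(unique(imperfect$canonical_motif), "AT")
  expect_equal(imperfect$length_bp, c(42L, 12L))
})

test_that("runs below their class threshold, and mononucleotide runs, are not reported", {
  expect_equal(nrow(find_perfect_ssrs(strrep("AT", 5))), 0L)   # 10 < 12 bp
  expect_equal(nrow(find_perfect_ssrs(strrep("A", 50))), 0L)
  expect_equal(nrow(find_perfect_ssrs(strrep("AT", 6))), 1L)   # 12 bp
  # custom criteria shift the boundary
  strict <- ssr_criteria(min_di = 14)
  expect_equal(nrow(find_perfect_ssrs(strrep("AT", 6), criteria = strict)),
               0L)
  expect_error(ssr_criteria(min_hexa = 6), "two repeat units")
})

test_that("N terminates runs and lowercase input is accepted", {
  hits <- find_perfect_ssrs(
    paste0(strrep("ag", 7), "n", strrep("AG", 7)))
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$length_bp, c(14L, 14L))
  expect_identical(unique(hits$canonical_motif), "AG")
})

test_that("reported loci are maximal and trailing partial units are trimmed", {
  # (AAC) x 6 plus a dangling 'AA'
  hits <- find_perfect_ssrs(paste0("T", strrep("AAC", 6), "AATTT"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$repeat_count, 6L)
  expect_equal(hits$end, 2L + 18L - 1L)
  # maximality against the sequence itself, over random repeat-rich strings
  set.seed(99)
  for (rep in 1:20) {
    s <- rand_repeatish(400)
    h <- find_perfect_ssrs(s)
    if (!nrow(h)) next
    unit <- h$motif
    left <- substring(s, pmax(h$start - h$unit_len, 1),
                      pmax(h$start - 1, 0))
    right <- substring(s, h$end + 1, pmin(h$end + h$unit_len, nchar(s)))
    expect_false(any(nchar(left) == h$unit_len & left == unit))
    expect_false(any(nchar(right) == h$unit_len & right == unit))
  }
})

test_that("scanner agrees with the brute-force oracle on repeat-rich sequences", {
  set.seed(1234)
  for (rep in 1:60) {
    s <- rand_repeatish(sample(200:1500, 1))
    got <- find_perfect_ssrs(s)
    want <- oracle_ssr_scan(s)
    expect_identical(ssr_key(got), ssr_key(want))
  }
})

test_that("summaries count SSR-positive sequences and canonical motifs", {
  seqs <- c(a = paste0(strrep("G", 30), strrep("AAC", 6), strrep("G", 30)),
            b = strrep("CGATT", 10),     # AATCG 5-mer run, 50 bp
            c = paste(rep("ACGTG", 8), collapse = ""))
  # the third sequence is (ACGTG)x8 = a pentanucleotide run; adjust:
  sm <- summarize_ssr_content(seqs)
  expect_equal(sm$n_sequences, 3L)
  expect_true(sm$n_with_ssr >= 2L)
  expect_equal(sm$fraction, sm$n_with_ssr / 3)
  expect_true("AAC" %in% names(sm$motif_counts))
  expect_error(summarize_ssr_content(character(0)), "no input")
  expect_equal(ssr_positive_fraction(0, 100), 0)
  expect_equal(round(100 * ssr_positive_fraction(1485, 52911), 1), 2.8)
})

test_that("FASTA round trip preserves sequences for scanning", {
  sim <- sim_ssr_sequences(n_sequences = 5, seq_len = 300, seed = 21)
  fa <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences), fa)
  seqs <- read_fasta(fa)
  hits <- scan_ssrs(seqs)
  expect_identical(paste(hits$seq_id, ssr_key(hits)),
                   paste(sim$truth$seq_id, ssr_key(sim$truth)))
  tsv <- tempfile(fileext = ".tsv")
  write_ssr_table(hits, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$start, hits$start)
  expect_equal(back$motif, hits$motif)
})
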