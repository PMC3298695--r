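test_that("motif construction enforces the k-mer set contract", {
  m <- motif(c("AACCTG", "CAGGTT"))
  expect_equal(m$length, 6L)
  expect_equal(m$span, 3L)
  expect_error(motif(c("AAA", "CCCC")), "mixed lengths")
  expect_error(motif(character(0)), "empty")
  expect_error(motif("AXA"), "non-ACGT")
  expect_equal(motif(c("AAA", "AAA"))$members, "AAA")  # dedup
})

test_that("span equals the enumerated maximum codon overlap", {
  # oracle: max over the three frame offsets of ceiling((offset + l) / 3)
  for (l in 1:20) {
    oracle <- max(vapply(0:2, function(o) ceiling((o + l) / 3), numeric(1)))
    expect_equal(motif_span(l), oracle)
  }
  expect_equal(motif_span(6), 3L)   # a 6-mer can overlap 3 codons
  expect_equal(motif_span(1), 1L)
  expect_equal(motif_span(7), 3L)
  expect_equal(motif_span(10), 4L)
  expect_error(motif_span(0), "positive")
})

test_that("occurrence counting is overlapping and member-aware", {
  expect_equal(count_occurrences("AAAAAA", motif("AAA")), 4L)
  expect_equal(count_occurrences("AAAAAG", motif("AAA")), 3L)
  expect_equal(count_occurrences("CCGGAAG", motif(c("CCGGAA", "CGGAAG"))), 2L)
  expect_equal(count_occurrences("AC", motif("AAA")), 0L)
})

test_that("theta counts occurrences ending in the last window codon", {
  expect_equal(theta("AAAAAAAAA", motif("AAAAAA")), 3L)
  expect_equal(theta("ATGATG", motif("ATG")), 1L)
  expect_equal(theta("GCAGCA", motif("ATG")), 0L)
  expect_error(theta("ATG", motif("ATGA")), "exactly")
})

test_that("summed theta over sliding windows reproduces plain counting", {
  set.seed(303)
  for (i in 1:30) {
    mo <- random_motif()
    span <- mo$span
    n_codons <- sample(span:12, 1)
    nt <- paste(sample(BASES, 3 * n_codons, replace = TRUE), collapse = "")
    # 5'-pad so that every codon is once the last codon of a full window
    padded <- paste0(strrep("N", 3 * (span - 1)), nt)
    tot <- 0L
    for (k in seq_len(n_codons)) {
      win <- substr(padded, 3 * (k - 1) + 1, 3 * (k - 1) + 3 * span)
      tot <- tot + theta(win, mo)
    }
    expect_equal(tot, count_occurrences(nt, mo))
  }
})

test_that("motif specs expand brackets, sets and reverse complements", {
  expect_setequal(parse_motif_spec("AGACT[AG]")$members, c("AGACTA", "AGACTG"))
  expect_setequal(parse_motif_spec("AGACT[A/G]")$members, c("AGACTA", "AGACTG"))
  expect_setequal(parse_motif_spec("AACCTG", include_revcomp = TRUE)$members,
                  c("AACCTG", "CAGGTT"))
  expect_setequal(parse_motif_spec("AACCTG/CAGGTT")$members,
                  c("AACCTG", "CAGGTT"))
  expect_setequal(parse_motif_spec("[AC]G[TG]")$members,
                  c("AGT", "AGG", "CGT", "CGG"))
  expect_error(parse_motif_spec("AAA/CCCC"), "mixed lengths")
  expect_error(parse_motif_spec("A[AG"), "unbalanced")
})

test_that("motif files parse members, labels and comments", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("# exhaustive list", "AGACT[AG]\tmyTF", "AACCTG/CAGGTT",
               "", "TTTTTT   # homopolymer"), tf)
  ms <- read_motif_file(tf)
  expect_length(ms, 3L)
  expect_equal(ms[[1]]$label, "myTF")
  expect_setequal(ms[[1]]$members, c("AGACTA", "AGACTG"))
  expect_equal(ms[[3]]$members, "TTTTTT")
  writeLines("# nothing", tf)
  expect_error(read_motif_file(tf), "no motifs")
})

test_that("window realizability agrees with exhaustive codon enumeration", {
  expect_true(motif_possible_in_window("M", motif("ATG")))
  expect_false(motif_possible_in_window("M", motif("AAA")))
  expect_false(motif_possible_in_window("KK", motif("TTT")))
  expect_error(motif_possible_in_window("K*", motif("AAA")), "stop symbol")
  set.seed(404)
  for (i in 1:40) {
    aa <- random_small_protein(max_codons = 4, max_states = 1500)
    mo <- random_motif(lmin = 2, lmax = 6)
    sets <- lapply(strsplit(aa, "")[[1]], codons_for)
    nts <- do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
    oracle <- any(vapply(nts, function(nt)
      count_occurrences(nt, mo) > 0, logical(1)))
    expect_equal(motif_possible_in_window(aa, mo), oracle)
  }
})

test_that("codon-window sparsity matches the genetic-code bound for 6-mers", {
  # over random amino-acid triples, the distinct 6-mers realizable across
  # all codon choices and the 4 in-window offsets stay <= 216 * 4 = 864,
  # i.e. at least 79% of the 4096 6-mers are forbidden in any 3-codon window
  set.seed(505)
  for (i in 1:40) {
    aa3 <- sample(AA20, 3, replace = TRUE)
    nts <- do.call(paste0, expand.grid(lapply(aa3, codons_for),
                                       stringsAsFactors = FALSE))
    kmers <- unique(unlist(lapply(1:4, function(s) substr(nts, s, s + 5))))
    expect_lte(length(kmers), 864L)
    expect_gte(1 - length(kmers) / 4096, 0.79)
  }
})
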