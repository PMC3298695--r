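test_that("segmentation isolates realizable stretches", {
  expect_length(segment_regions(cds_for_protein("KKK"), motif("AAA")), 1L)
  segs <- segment_regions(coding_sequence("x", "ATGTTTATG"), motif("ATG"))
  expect_length(segs, 2L)
  expect_equal(segs[[1]]$start, 1L); expect_equal(segs[[1]]$end, 1L)
  expect_equal(segs[[2]]$start, 3L); expect_equal(segs[[2]]$end, 3L)
  expect_length(segment_regions(coding_sequence("y", "ATGAAAATG"),
                                motif("TTT")), 0L)
})

test_that("regions merge when the 3' traceback reaches Ser/Arg/Leu inside the next region", {
  # M P W: ATG realizable in codon 1 and across codons 2-3; Pro has a fixed
  # first base, so the two stay independent
  segs <- segment_regions(coding_sequence("p", "ATGCCATGG"), motif("ATG"))
  expect_length(segs, 2L)
  expect_equal(segs[[1]]$boundary_3prime$terminus, "base")
  expect_equal(segs[[1]]$boundary_3prime$base, "C")
  # M S W: same structure but Ser (two first bases) opens the 3' region, so
  # the counts would be correlated through its first base -> one region
  segs2 <- segment_regions(coding_sequence("s", "ATGTCATGG", boundary_base = "T"),
                           motif("ATG"))
  expect_length(segs2, 1L)
  expect_equal(segs2[[1]]$start, 1L)
  expect_equal(segs2[[1]]$end, 3L)
  # both give exactly the brute-force distribution under a DCM
  dcm <- fitted_models()$dcm
  for (nt in c("ATGCCATGG", "ATGTCATGG")) {
    s <- coding_sequence("z", nt, boundary_base = "T")
    expect_lt(max_dist_err(
      sequence_distribution(s, motif("ATG"), dcm),
      brute_force_distribution(s$aa, motif("ATG"), dcm, boundary_base = "T")),
      1e-9)
  }
})

test_that("region induction reproduces enumerable cases exactly", {
  icm_u <- uniform_icm()
  s <- coding_sequence("kk", "AAAAAA")
  d <- sequence_distribution(s, motif("AAA"), icm_u)
  expect_equal(as.numeric(d), c(.25, .25, 0, .25, .25), tolerance = 1e-12)
  # forced codon contains the motif
  dm <- sequence_distribution(coding_sequence("m", "ATG"), motif("ATG"), icm_u)
  expect_equal(as.numeric(dm), c(0, 1), tolerance = 1e-12)
  # KKKK / AAAAAA vs enumeration over the 16 codon assignments
  s4 <- cds_for_protein("KKKK")
  expect_lt(max_dist_err(
    sequence_distribution(s4, motif("AAAAAA"), icm_u),
    brute_force_distribution("KKKK", motif("AAAAAA"), icm_u)), 1e-12)
})

test_that("split and no-split inductions agree across a separator", {
  icm_u <- uniform_icm()
  dcm <- fitted_models()$dcm
  s <- cds_for_protein("KKDKK", boundary_base = "T")
  mo <- motif("AAA")
  oracle <- brute_force_distribution("KKDKK", mo, icm_u)
  expect_lt(max_dist_err(sequence_distribution(s, mo, icm_u), oracle), 1e-9)
  expect_lt(max_dist_err(sequence_distribution(s, mo, icm_u, split = FALSE),
                         oracle), 1e-9)
  oracle_dcm <- brute_force_distribution("KKDKK", mo, dcm, boundary_base = "T")
  expect_lt(max_dist_err(sequence_distribution(s, mo, dcm), oracle_dcm), 1e-9)
  expect_lt(max_dist_err(sequence_distribution(s, mo, dcm, split = FALSE),
                         oracle_dcm), 1e-9)
})

test_that("sequences where the motif is impossible give the zero point mass", {
  icm_u <- uniform_icm()
  d <- sequence_distribution(coding_sequence("none", "ATGAAAATG"),
                             motif("TTT"), icm_u)
  expect_equal(as.numeric(d), 1)
})

test_that("dataset distribution convolves per-sequence distributions", {
  icm_u <- uniform_icm()
  s <- coding_sequence("kk", "AAAAAA")
  one <- dataset_distribution(list(s), motif("AAA"), icm_u)
  expect_equal(as.numeric(one), c(.25, .25, 0, .25, .25), tolerance = 1e-12)
  two <- dataset_distribution(list(s, s), motif("AAA"), icm_u)
  counts1 <- c(0, 1, 3, 4)
  pairs <- outer(counts1, counts1, `+`)
  oracle <- vapply(0:8, function(k) sum(pairs == k) / 16, numeric(1))
  expect_equal(as.numeric(two), oracle, tolerance = 1e-12)
  expect_error(dataset_distribution(list(), motif("AAA"), icm_u), "empty")
})

test_that("terminal-stop conditioning uses base T and excludes the stop codon", {
  # reference where p(AAA | K, T) = 1 but p(AAA | K, A) = 0.5: the last K of
  # a stop-terminated gene must be read under the T column
  cnt <- count_reference(c("AAAAAGAAATAA", "AAGAAGAAGTAA"))
  dcm <- build_dcm(cnt)
  expect_equal(unname(dcm$p["AAA", "T"]), 0.5)
  s_stop <- coding_sequence("g", "AAA", has_terminal_stop = TRUE)
  d_stop <- sequence_distribution(s_stop, motif("AAA"), dcm)
  expect_equal(as.numeric(d_stop)[2], unname(dcm$p["AAA", "T"]),
               tolerance = 1e-12)
  s_frag <- coding_sequence("f", "AAA", boundary_base = NA)
  d_frag <- sequence_distribution(s_frag, motif("AAA"), dcm)
  expect_equal(as.numeric(d_frag)[2], unname(dcm$icm$p["AAA"]),
               tolerance = 1e-12)
  # the motif is never sought across the detached stop: count on the stored
  # sense sequence only
  expect_equal(count_occurrences(s_stop$nt, motif("AAATAA")), 0L)
})

test_that("mean of the exact distribution equals the analytic expected count", {
  # independent-position expectation: sum over placements of P(window = member)
  m <- fitted_models()
  set.seed(606)
  for (i in 1:10) {
    aa <- random_small_protein(max_codons = 8)
    mo <- random_motif(lmin = 3, lmax = 5)
    s <- cds_for_protein(aa, boundary_base = "T")
    d <- sequence_distribution(s, mo, m$icm)
    aa_vec <- strsplit(aa, "")[[1]]
    exp_count <- 0
    nb <- 3 * length(aa_vec)
    if (nb >= mo$length) {
      for (st in 1:(nb - mo$length + 1)) {
        k1 <- (st - 1) %/% 3 + 1
        k2 <- (st + mo$length - 2) %/% 3 + 1
        sets <- lapply(aa_vec[k1:k2], codons_for)
        nts <- do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
        pr <- rep(1, length(nts))
        g <- expand.grid(sets, stringsAsFactors = FALSE)
        for (j in seq_along(sets)) pr <- pr * m$icm$p[g[[j]]]
        off <- st - 3 * (k1 - 1)
        hit <- substr(nts, off, off + mo$length - 1) %in% mo$members
        exp_count <- exp_count + sum(pr[hit])
      }
    }
    expect_equal(distribution_mean(d), exp_count, tolerance = 1e-9)
  }
})
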