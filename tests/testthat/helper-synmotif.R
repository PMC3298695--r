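# Shared builders for the test suite. All fixtures are generated in code.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")

# pad two distributions to a common support and return the max abs difference
max_dist_err <- function(d1, d2) {
  p1 <- as.numeric(d1); p2 <- as.numeric(d2)
  n <- max(length(p1), length(p2))
  max(abs(c(p1, numeric(n - length(p1))) - c(p2, numeric(n - length(p2)))))
}

# ICM with the uniform distribution over every synonymous set (each sense
# codon observed exactly once)
uniform_icm <- function() {
  build_icm(count_reference(paste(synmotif:::.CODE$sense_codons, collapse = "")))
}

# models fitted once on a biased synthetic reference corpus
fitted_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- synthetic_reference(60, 120, seed = 7)
      cnt <- count_reference(ref)
      cache <<- list(counts = cnt, icm = build_icm(cnt), dcm = build_dcm(cnt))
    }
    cache
  }
})

# random protein whose synonymous space stays enumerable
random_small_protein <- function(max_codons = 10, max_states = 2e4,
                                 alphabet = AA20) {
  repeat {
    n <- sample(2:max_codons, 1)
    aa <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
    deg <- prod(vapply(strsplit(aa, "")[[1]],
                       function(a) length(codons_for(a)), numeric(1)))
    if (deg <= max_states) return(aa)
  }
}

random_kmer <- function(l) paste(sample(BASES, l, replace = TRUE), collapse = "")

random_motif <- function(lmin = 3, lmax = 7, max_members = 2) {
  l <- sample(lmin:lmax, 1)
  motif(unique(replicate(sample(seq_len(max_members), 1), random_kmer(l))))
}

# a coding_sequence for an amino-acid string (codon choice is irrelevant to
# the null distribution; first synonymous codon is used)
cds_for_protein <- function(aa, boundary_base = NA, id = "test") {
  nt <- paste(vapply(strsplit(aa, "")[[1]],
                     function(a) codons_for(a)[1], character(1)),
              collapse = "")
  coding_sequence(id, nt, has_terminal_stop = identical(boundary_base, "T"),
                  boundary_base = boundary_base)
}
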