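## Brute-force enumeration oracle, null-model samplers, the synthetic
## motif-insertion benchmark, and composition diagnostics. Everything here is
## generated in code; no external data are required.

#' Brute-force count distribution by enumeration
#'
#' The definitional distribution: every synonymous nucleotide sequence of the
#' amino-acid string is enumerated, weighted by its model probability, and
#' its occurrence count tallied. Exponential in length — this is the
#' independent oracle the dynamic program is checked against, not a user
#' route.
#'
#' @param aa Amino-acid string (no stop symbol).
#' @param motif A [motif()].
#' @param model An `icm_model` or `dcm_model`.
#' @param boundary_base 3' conditioning base for the DCM (`NA` = none).
#' @param max_states Guard on the number of synonymous sequences (default 1e6).
#' @return A normalized [count_distribution()].
#' @export
brute_force_distribution <- function(aa, motif, model, boundary_base = NA,
                                     max_states = 1e6) {
  check_model(model)
  aa_vec <- strsplit(aa, "", fixed = TRUE)[[1L]]
  if ("*" %in% aa_vec) stop("stop symbol in amino-acid string")
  if (length(aa_vec) == 0L) return(count_distribution(1))
  sets <- lapply(aa_vec, codons_for)
  n_states <- prod(vapply(sets, length, numeric(1)))
  if (n_states > max_states)
    stop("size error: ", format(n_states), " synonymous sequences exceeds guard")
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  n <- length(aa_vec)
  if (is_dcm(model)) {
    pr <- if (is.na(boundary_base)) model$icm$p[grid[[n]]]
          else model$p[grid[[n]], boundary_base]
    if (n >= 2L) for (i in seq_len(n - 1L))
      pr <- pr * model$p[cbind(grid[[i]], substr(grid[[i + 1L]], 1L, 1L))]
  } else {
    pr <- rep(1, nrow(grid))
    for (i in seq_len(n)) pr <- pr * model$p[grid[[i]]]
  }
  nts <- do.call(paste0, grid)
  l <- motif$length
  cnt <- integer(nrow(grid))
  nb <- 3L * n
  if (nb >= l) {
    for (s in seq_len(nb - l + 1L))
      cnt <- cnt + (substring(nts, s, s + l - 1L) %in% motif$members)
  }
  probs <- numeric(max(cnt) + 1L)
  agg <- tapply(pr, cnt, sum)
  probs[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  count_distribution(probs / sum(probs))
}

#' Sample a synonymous coding sequence from a null model
#'
#' ICM: each codon drawn independently from `p(alpha | A)`. DCM: codons drawn
#' 3' to 5', each conditioned on the first base of the codon drawn before it
#' (its 3' neighbour); the 3'-most codon is conditioned on `boundary_base`,
#' or drawn from the ICM marginal when that is `NA`.
#'
#' Uses R's global RNG; call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @inheritParams brute_force_distribution
#' @param seed Optional integer seed applied before sampling.
#' @return A nucleotide string translating back to `aa`.
#' @export
sample_coding_sequence <- function(model, aa, boundary_base = NA, seed = NULL) {
  check_model(model)
  if (!is.null(seed)) set.seed(seed)
  aa_vec <- strsplit(aa, "", fixed = TRUE)[[1L]]
  if ("*" %in% aa_vec) stop("stop symbol in amino-acid string")
  n <- length(aa_vec)
  if (n == 0L) return("")
  out <- character(n)
  if (!is_dcm(model)) {
    for (i in seq_len(n)) {
      cs <- codons_for(aa_vec[i])
      out[i] <- if (length(cs) == 1L) cs else sample(cs, 1L, prob = model$p[cs])
    }
    return(paste(out, collapse = ""))
  }
  for (i in n:1) {
    cs <- codons_for(aa_vec[i])
    w <- if (i == n) {
      if (is.na(boundary_base)) model$icm$p[cs] else model$p[cs, boundary_base]
    } else model$p[cs, substr(out[i + 1L], 1L, 1L)]
    if (sum(w) <= 0) stop("estimation error: no admissible codon for ",
                          aa_vec[i], " in this context")
    out[i] <- if (length(cs) == 1L) cs else sample(cs, 1L, prob = w)
  }
  paste(out, collapse = "")
}

#' Sample a random protein
#'
#' Amino acids drawn i.i.d. from `composition` (uniform over the 20 by
#' default).
#'
#' @param n_codons Protein length.
#' @param composition Named probability vector over amino-acid symbols, or
#'   `NULL` for uniform.
#' @return Amino-acid string.
#' @export
sample_protein <- function(n_codons, composition = NULL) {
  if (is.null(composition)) {
    paste(sample(.CODE$amino_acids, n_codons, replace = TRUE), collapse = "")
  } else {
    paste(sample(names(composition), n_codons, replace = TRUE,
                 prob = composition), collapse = "")
  }
}

#' Synthetic reference corpus with codon and dinucleotide bias
#'
#' Builds a synthetic stand-in for a real coding-sequence reference: uniform
#' random proteins encoded codon by codon with per-amino-acid log-normal
#' codon weights, re-weighted by `cpg_factor` whenever the choice would
#' create a CG dinucleotide across the 3' codon boundary. Sequences are
#' encoded 3' to 5' so the bias acts on the *third* codon base — the base the
#' genetic code actually leaves free (first bases are fixed by the amino acid
#' for 17 of 20 amino acids, so depleting them could not create boundary
#' structure at all). The resulting CpG depletion is contextual: it is
#' visible in the conditional codon usage `F(alpha, b)` but largely invisible
#' to marginal codon usage, which is precisely the structure an
#' independent-codon null misses and the dinucleotide-corrected null absorbs.
#' Each sequence is returned with a terminal TAA stop codon.
#'
#' @param n_seqs,len_codons Number and length (sense codons) of sequences.
#' @param seed Optional integer seed.
#' @param cpg_factor Multiplier on the weight of C-ending codons when the
#'   3'-neighbouring codon starts with G (default 0.2, a strong CpG
#'   depletion).
#' @return Character vector of nucleotide sequences (each ending in TAA).
#' @export
synthetic_reference <- function(n_seqs, len_codons, seed = NULL,
                                cpg_factor = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  w <- exp(stats::rnorm(length(.CODE$sense_codons), sd = 0.8))
  names(w) <- .CODE$sense_codons
  ends_c <- structure(substr(.CODE$sense_codons, 3L, 3L) == "C",
                      names = .CODE$sense_codons)
  vapply(seq_len(n_seqs), function(i) {
    aa_vec <- strsplit(sample_protein(len_codons), "", fixed = TRUE)[[1L]]
    n <- length(aa_vec)
    cods <- character(n)
    next_first <- "T"                       # terminal stop starts with T
    for (j in n:1) {
      cs <- codons_for(aa_vec[j])
      wt <- w[cs]
      if (next_first == "G") wt[ends_c[cs]] <- wt[ends_c[cs]] * cpg_factor
      cods[j] <- if (length(cs) == 1L) cs else sample(cs, 1L, prob = wt)
      next_first <- substr(cods[j], 1L, 1L)
    }
    paste0(paste(cods, collapse = ""), "TAA")
  }, character(1))
}

#' Synthetic motif-insertion benchmark
#'
#' Generates `n_seqs` null sequences from the model (each a uniform random
#' protein of `len_codons` codons, 3'-most codon conditioned on a stop, i.e.
#' boundary base 'T'), then overwrites one copy of the motif at a uniformly
#' random position in each of `n_inserted` distinct sequences. If an
#' overwrite would create a premature stop codon the location is redrawn.
#'
#' @inheritParams sample_coding_sequence
#' @param n_seqs Number of sequences.
#' @param len_codons Codons per sequence.
#' @param motif A [motif()]; a random member is inserted per copy.
#' @param n_inserted Number of sequences receiving one motif copy
#'   (`0 <= n_inserted <= n_seqs`). The first `n_inserted` sequences are
#'   modified, so datasets at increasing insertion counts are nested.
#' @param proteins Optional character vector of amino-acid strings to encode
#'   (defaults to fresh uniform random proteins).
#' @return List of [coding_sequence()] objects with `boundary_base = "T"`.
#' @export
generate_insertion_dataset <- function(model, n_seqs, len_codons, motif,
                                       n_inserted, seed = NULL,
                                       proteins = NULL) {
  check_model(model)
  if (!is.null(seed)) set.seed(seed)
  if (n_inserted > n_seqs) stop("n_inserted exceeds n_seqs")
  if (motif$length > 3L * len_codons)
    stop("motif longer than the sequences")
  if (is.null(proteins))
    proteins <- vapply(seq_len(n_seqs), function(i) sample_protein(len_codons),
                       character(1))
  seqs <- lapply(seq_len(n_seqs), function(i) {
    nt <- sample_coding_sequence(model, proteins[i], boundary_base = "T")
    if (i <= n_inserted) nt <- insert_motif_copy(nt, motif)
    coding_sequence(sprintf("synthetic_%02d", i), nt,
                    has_terminal_stop = TRUE, boundary_base = "T")
  })
  seqs
}

#' Overwrite one motif copy at a random position
#'
#' Replaces `motif$length` bases of `nt` (a random member, at a uniformly
#' random start) in place; if the edit would create an in-frame stop codon
#' the location is redrawn. Building nested insertion datasets — the same
#' base sequences with 0, 1, 2, ... copies overwritten — is done by applying
#' this to successive sequences of one base dataset.
#'
#' @param nt In-frame nucleotide string without stop codons.
#' @param motif A [motif()].
#' @param max_tries Redraw limit before giving up.
#' @return The edited nucleotide string.
#' @export
insert_motif_copy <- function(nt, motif, max_tries = 1000L) {
  l <- motif$length
  n <- nchar(nt)
  member <- if (length(motif$members) == 1L) motif$members
            else sample(motif$members, 1L)
  for (try in seq_len(max_tries)) {
    s <- sample.int(n - l + 1L, 1L)
    cand <- paste0(substr(nt, 1L, s - 1L), member, substr(nt, s + l, n))
    if (!grepl("*", translate_cds(cand), fixed = TRUE)) return(cand)
  }
  stop("could not insert motif without creating a premature stop codon")
}

#' Dinucleotide composition of a sequence set
#'
#' Counts all overlapping dinucleotides within each sequence (including
#' across codon boundaries), never across sequence boundaries.
#'
#' @param seqs Character vector of nucleotide strings.
#' @return Object of class `"dinucleotide_table"`: `counts` and normalized
#'   `frequencies`, both named vectors over the 16 dinucleotides.
#' @export
dinucleotide_frequencies <- function(seqs) {
  seqs <- unlist(seqs, use.names = FALSE)
  if (length(seqs) == 0L) stop("empty sequence set")
  dinucs <- as.vector(outer(.BASES, .BASES, paste0))
  counts <- structure(numeric(16L), names = sort(dinucs))
  for (s in seqs) {
    n <- nchar(s)
    if (n < 2L) next
    dd <- substring(s, 1:(n - 1L), 2:n)
    tab <- table(dd)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  tot <- sum(counts)
  structure(list(counts = counts,
                 frequencies = if (tot > 0) counts / tot else counts),
            class = "dinucleotide_table")
}

#' @export
print.dinucleotide_table <- function(x, ...) {
  cat("<dinucleotide table> ", format(sum(x$counts), big.mark = ","),
      " dinucleotides\n", sep = "")
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Write a synthetic FASTA fixture with a JSON manifest
#'
#' @param seqs List of [coding_sequence()] objects (a terminal TAA is
#'   appended to records flagged `has_terminal_stop`).
#' @param fasta_path,manifest_path Output paths.
#' @param params Named list recorded in the manifest (seeds, generator
#'   parameters).
#' @return `fasta_path`, invisibly.
#' @export
write_fixture_fasta <- function(seqs, fasta_path, manifest_path = NULL,
                                params = list()) {
  nts <- vapply(seqs, function(s)
    if (s$has_terminal_stop) paste0(s$nt, "TAA") else s$nt, character(1))
  ids <- vapply(seqs, `[[`, character(1), "id")
  x <- Biostrings::DNAStringSet(nts)
  names(x) <- ids
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(manifest_path)) {
    manifest <- c(list(n_seqs = length(seqs),
                       ids = ids,
                       lengths_nt = unname(nchar(nts))),
                  params)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(fasta_path)
}
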