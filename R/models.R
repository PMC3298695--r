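## Null models estimated from a reference coding-sequence set:
##   ICM — independent codon model, p(alpha | A) from the codon-usage table;
##   DCM — dinucleotide-corrected codon Markov model, p(alpha | A, b) where b
##         is the first base of the 3'-neighbouring codon.
##
## Counting conventions: the 3'-terminal codon of each reference sequence has
## no 3' neighbour and contributes to F(alpha) only; a terminal stop codon is
## not a modelled codon but supplies conditioning base 'T' (first letter of
## all three stops) for its 5' neighbour. Counts never span sequences.

#' Count codon and codon-neighbour usage in a reference set
#'
#' @param coding_sequences Character vector (or list) of in-frame nucleotide
#'   strings. Sequences may or may not end in a stop codon; internal stops are
#'   rejected (admission policy lives in [read_coding_fasta()]).
#' @return Object of class `"reference_counts"`: `F_codon` (named count
#'   vector over the 61 sense codons), `F_codon_base` (61 x 4 matrix of
#'   codon-followed-by-first-base counts), `F_aa_base` (20 x 4 matrix
#'   aggregated by amino acid), and `n_codons`, the total sense-codon count.
#' @examples
#' counts <- count_reference("AAAAAGAAATAA")
#' counts$F_codon_base["AAA", ]
#' @export
count_reference <- function(coding_sequences) {
  coding_sequences <- unlist(coding_sequences, use.names = FALSE)
  if (length(coding_sequences) == 0L)
    stop("estimation error: empty reference sequence set")
  sense <- .CODE$sense_codons
  F_codon <- structure(numeric(length(sense)), names = sense)
  F_cb <- matrix(0, nrow = length(sense), ncol = 4L,
                 dimnames = list(sense, .BASES))
  for (i in seq_along(coding_sequences)) {
    nt <- coding_sequences[[i]]
    aa <- translate_cds(nt, id = paste0("reference[", i, "]"))
    cods <- codon_split(nt)
    aav <- strsplit(aa, "", fixed = TRUE)[[1L]]
    n <- length(cods)
    stops <- which(aav == "*")
    if (length(stops) > 0L && (length(stops) > 1L || stops != n))
      stop("estimation error: internal stop codon in reference[", i, "]")
    has_stop <- length(stops) == 1L
    if (has_stop) { cods <- cods[-n]; n <- n - 1L }
    if (n == 0L) next
    tab <- table(cods)
    F_codon[names(tab)] <- F_codon[names(tab)] + as.numeric(tab)
    nb <- if (has_stop) c(substr(cods[-1L], 1L, 1L), "T")
          else substr(cods[-1L], 1L, 1L)
    from <- if (has_stop) cods else cods[-n]
    for (j in seq_along(from))
      F_cb[from[j], nb[j]] <- F_cb[from[j], nb[j]] + 1
  }
  if (sum(F_codon) == 0)
    stop("estimation error: reference contains no sense codons")
  aa_of <- .CODE$codon_aa[sense]
  F_ab <- rowsum(F_cb, group = aa_of)
  structure(list(F_codon = F_codon, F_codon_base = F_cb, F_aa_base = F_ab,
                 n_codons = sum(F_codon)),
            class = "reference_counts")
}

#' @export
print.reference_counts <- function(x, ...) {
  cat("<reference counts> ", format(x$n_codons, big.mark = ","),
      " sense codons, ", sum(x$F_codon_base), " codon/base adjacencies\n",
      sep = "")
  invisible(x)
}

#' Fit the independent codon model
#'
#' `p(alpha | A) = F(alpha) / sum of F over the synonymous set`. Amino acids
#' entirely absent from the reference get the uniform distribution over their
#' codons, which keeps every synonymous re-encoding inside the support so
#' exact p-values stay well defined.
#'
#' @param counts A [count_reference()] result.
#' @return Object of class `"icm_model"` with field `p`, a named probability
#'   vector over the 61 sense codons.
#' @export
build_icm <- function(counts) {
  stopifnot(inherits(counts, "reference_counts"))
  sense <- .CODE$sense_codons
  aa_of <- .CODE$codon_aa[sense]
  p <- structure(numeric(length(sense)), names = sense)
  for (aa in .CODE$amino_acids) {
    cs <- .CODE$aa_codons[[aa]]
    tot <- sum(counts$F_codon[cs])
    p[cs] <- if (tot > 0) counts$F_codon[cs] / tot else 1 / length(cs)
  }
  structure(list(p = p, counts = counts), class = "icm_model")
}

#' @export
print.icm_model <- function(x, ...) {
  n <- if (is.null(x$counts)) "a TSV dump" else
    paste(format(x$counts$n_codons, big.mark = ","), "codons")
  cat("<independent codon model> fitted from ", n, "\n", sep = "")
  invisible(x)
}

#' Fit the dinucleotide-corrected codon model
#'
#' `p(alpha | A, b) = (F(alpha, b) + pseudocount) /
#' (F(A, b) + pseudocount * |codons(A)|)`, where `b` is the first base of the
#' 3'-neighbouring codon. With `pseudocount = 0`, any (A, b) cell unobserved
#' in the reference falls back to the embedded ICM conditional `p(alpha | A)`.
#'
#' @inheritParams build_icm
#' @param pseudocount Non-negative smoothing count added per (codon, base)
#'   cell; default 0 (pure observed conditional usage plus ICM fallback).
#' @return Object of class `"dcm_model"`: `p` (61 x 4 matrix of
#'   `p(alpha | A, b)`), `icm` (fallback [build_icm()] model from the same
#'   counts) and `pseudocount`.
#' @export
build_dcm <- function(counts, pseudocount = 0) {
  stopifnot(inherits(counts, "reference_counts"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  icm <- build_icm(counts)
  sense <- .CODE$sense_codons
  p <- matrix(NA_real_, nrow = length(sense), ncol = 4L,
              dimnames = list(sense, .BASES))
  for (aa in .CODE$amino_acids) {
    cs <- .CODE$aa_codons[[aa]]
    for (b in .BASES) {
      denom <- counts$F_aa_base[aa, b] + pseudocount * length(cs)
      p[cs, b] <- if (denom > 0)
        (counts$F_codon_base[cs, b] + pseudocount) / denom
      else icm$p[cs]            # unseen (A, b) cell: ICM fallback
    }
  }
  structure(list(p = p, icm = icm, pseudocount = pseudocount,
                 counts = counts),
            class = "dcm_model")
}

#' @export
print.dcm_model <- function(x, ...) {
  n <- if (is.null(x$counts)) "a TSV dump" else
    paste(format(x$counts$n_codons, big.mark = ","), "codons")
  cat("<dinucleotide-corrected codon model> fitted from ", n,
      ", pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

is_dcm <- function(model) inherits(model, "dcm_model")

check_model <- function(model) {
  if (!inherits(model, c("icm_model", "dcm_model")))
    stop("model must be an icm_model or dcm_model")
  model
}

#' Probability of a coding sequence under a null model
#'
#' ICM: the product of `p(alpha_i | A_i)` over codons. DCM: sequences are
#' generated 3' to 5', so the 3'-most codon is conditioned on
#' `boundary_base` — the first base of the codon immediately 3' of the
#' sequence ('T' for a whole gene, by the stop-codon convention) — and every
#' other codon on the first base of its 3' neighbour. When `boundary_base`
#' is `NA` (a fragment with no known 3' context), the 3'-most codon uses the
#' ICM marginal instead.
#'
#' @param model An `icm_model` or `dcm_model`.
#' @param nt_sequence In-frame nucleotide string without stop codons.
#' @param boundary_base `"A"`, `"C"`, `"G"`, `"T"` or `NA`.
#' @return Probability in `[0, 1]`.
#' @export
sequence_probability <- function(model, nt_sequence, boundary_base = NA) {
  check_model(model)
  aa <- translate_cds(nt_sequence)
  if (grepl("*", aa, fixed = TRUE))
    stop("sequence contains a stop codon; detach or reject it first")
  if (nchar(nt_sequence) == 0L) return(1)
  cods <- codon_split(nt_sequence)
  n <- length(cods)
  if (!is_dcm(model)) return(prod(model$p[cods]))
  p_last <- if (is.na(boundary_base)) model$icm$p[[cods[n]]]
            else model$p[cods[n], boundary_base]
  if (n == 1L) return(unname(p_last))
  nb <- substr(cods[-1L], 1L, 1L)
  unname(p_last * prod(model$p[cbind(cods[-n], nb)]))
}

## ---- plain-text model dump -------------------------------------------------

#' Dump a fitted model as TSV
#'
#' Four columns: amino acid, conditioning base (`"-"` for the ICM), codon,
#' probability. [read_model_tsv()] restores the model.
#'
#' @param model An `icm_model` or `dcm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  check_model(model)
  sense <- .CODE$sense_codons
  aa_of <- unname(.CODE$codon_aa[sense])
  if (is_dcm(model)) {
    df <- data.frame(
      amino_acid = rep(aa_of, times = 4L),
      base = rep(.BASES, each = length(sense)),
      codon = rep(sense, times = 4L),
      probability = as.numeric(model$p))
    df <- rbind(df, data.frame(amino_acid = aa_of, base = "-", codon = sense,
                               probability = unname(model$icm$p)))
  } else {
    df <- data.frame(amino_acid = aa_of, base = "-", codon = sense,
                     probability = unname(model$p))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restore a model written by [write_model_tsv()]
#'
#' @param path TSV path.
#' @return An `icm_model` or `dcm_model` (recognized by the presence of
#'   conditioning-base rows). Count fields are not restored.
#' @export
read_model_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "character", "numeric"))
  sense <- .CODE$sense_codons
  marg <- df[df$base == "-", ]
  p_icm <- structure(numeric(length(sense)), names = sense)
  p_icm[marg$codon] <- marg$probability
  icm <- structure(list(p = p_icm, counts = NULL), class = "icm_model")
  cond <- df[df$base != "-", ]
  if (nrow(cond) == 0L) return(icm)
  p <- matrix(NA_real_, nrow = length(sense), ncol = 4L,
              dimnames = list(sense, .BASES))
  p[cbind(cond$codon, cond$base)] <- cond$probability
  structure(list(p = p, icm = icm, pseudocount = NA_real_, counts = NULL),
            class = "dcm_model")
}
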