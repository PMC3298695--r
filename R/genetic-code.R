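## Standard genetic code tables, derived once at install time from Biostrings.
## All sequence handling in the package is DNA-alphabet ({A,C,G,T}), in frame.

.BASES <- c("A", "C", "G", "T")

.CODE <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  aa_codons <- split(sense, gc[sense])
  # 3 x n character matrix of codon bases per amino acid, for fast pattern tests
  aa_codon_mat <- lapply(aa_codons, function(cs) {
    matrix(unlist(strsplit(cs, "", fixed = TRUE)), nrow = 3L,
           dimnames = list(NULL, cs))
  })
  list(
    codons       = codons,
    codon_aa     = gc,
    stop_codons  = stops,
    sense_codons = sense,
    aa_codons    = aa_codons,
    aa_codon_mat = aa_codon_mat,
    aa_first     = lapply(aa_codons, function(cs) unique(substr(cs, 1L, 1L))),
    amino_acids  = names(aa_codons)
  )
})

#' The standard genetic code
#'
#' Returns the code tables used throughout the package: the 64 codon to
#' amino-acid assignments of the standard nuclear code, the synonymous codon
#' set of each amino acid, and the stop codon set \{TAA, TAG, TGA\}.
#' Alternative codes are not supported.
#'
#' @return A list with elements `codon_to_aa` (named character vector of
#'   length 64, stop = `"*"`), `aa_to_codons` (list of synonymous codon sets
#'   for the 20 amino acids) and `stop_codons`.
#' @examples
#' genetic_code()$aa_to_codons$K
#' @export
genetic_code <- function() {
  list(codon_to_aa = .CODE$codon_aa,
       aa_to_codons = .CODE$aa_codons,
       stop_codons = .CODE$stop_codons)
}

#' Translate an in-frame coding sequence
#'
#' @param nt_sequence An in-frame nucleotide string over \{A,C,G,T\}; length
#'   must be divisible by 3. Stop codons (terminal or internal) translate to
#'   `"*"`; rejecting internal stops is the caller's admission policy.
#' @param id Optional sequence name used in error messages.
#' @return One-letter amino-acid string, one symbol per codon.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK*"
#' @export
translate_cds <- function(nt_sequence, id = "<sequence>") {
  stopifnot(is.character(nt_sequence), length(nt_sequence) == 1L)
  n <- nchar(nt_sequence)
  if (n %% 3L != 0L)
    stop("frame error in '", id, "': length ", n, " is not divisible by 3")
  bad <- regexpr("[^ACGT]", nt_sequence)
  if (bad > 0L)
    stop("frame error in '", id, "': non-ACGT character at offset ", bad)
  if (n == 0L) return("")
  cods <- codon_split(nt_sequence)
  paste(.CODE$codon_aa[cods], collapse = "")
}

# split an in-frame string into its codons (no validation)
codon_split <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

check_aa <- function(aa) {
  if (!aa %in% .CODE$amino_acids)
    stop("unknown amino-acid symbol '", aa, "'")
  aa
}

#' Synonymous codons of an amino acid
#'
#' @param aa A one-letter amino-acid symbol (not `"*"`).
#' @return Character vector of synonymous codons (1 to 6 of them).
#' @examples
#' codons_for("L")  # the six leucine codons
#' @export
codons_for <- function(aa) .CODE$aa_codons[[check_aa(aa)]]

#' Possible first bases of an amino acid's codons
#'
#' For 17 of the 20 amino acids the first codon base is fixed by the amino
#' acid; only Ser, Arg and Leu admit two first bases. This structure is what
#' makes the dinucleotide-corrected model's 3' traceback shortcut cheap.
#'
#' @inheritParams codons_for
#' @return Character vector of distinct first bases (length 1 or 2).
#' @examples
#' first_bases("K")  # "A"
#' first_bases("S")  # "T" "A"
#' @export
first_bases <- function(aa) .CODE$aa_first[[check_aa(aa)]]
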