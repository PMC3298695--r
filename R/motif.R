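## Motifs: equal-length k-mer sets, occurrence counting, the per-window
## end-count theta, and codon-window realizability tests.

#' Construct a motif from a set of equal-length k-mers
#'
#' A motif is a non-empty set of equal-length nucleotide strings; an
#' occurrence of any member counts as an occurrence of the motif. The span
#' `ceiling((l + 2) / 3)` is the maximum number of codons a single occurrence
#' can overlap, which fixes the width of the dynamic-programming context.
#'
#' @param members Character vector of ACGT strings, all the same length.
#' @param label Display name; defaults to the members joined by "/".
#' @return An object of class `"motif"` with fields `members`, `length`,
#'   `span` and `label`.
#' @examples
#' motif(c("AACCTG", "CAGGTT"))
#' @export
motif <- function(members, label = NULL) {
  if (length(members) == 0L) stop("motif spec error: empty k-mer set")
  members <- unique(toupper(members))
  if (any(grepl("[^ACGT]", members)))
    stop("motif spec error: non-ACGT character in ", paste(members, collapse = "/"))
  l <- unique(nchar(members))
  if (length(l) != 1L)
    stop("motif spec error: members have mixed lengths (",
         paste(sort(unique(nchar(members))), collapse = ", "), ")")
  if (l < 1L) stop("motif spec error: zero-length member")
  structure(
    list(members = members, length = l, span = motif_span(l),
         label = if (is.null(label)) paste(members, collapse = "/") else label),
    class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif> ", x$label, ": ", length(x$members), " k-mer(s), length ",
      x$length, ", span ", x$span, " codons\n", sep = "")
  invisible(x)
}

#' Maximum number of codons an l-mer can overlap
#'
#' Over the three frame offsets, an l-mer starting at base offset o of a codon
#' covers `ceiling((o + l) / 3)` codons; the maximum over o = 0, 1, 2 is
#' `ceiling((l + 2) / 3)`. A 6-mer, for instance, can overlap 3 codons
#' (positions 2-7 or 3-8 of a 9-base window).
#'
#' @param l Motif length in bases (>= 1).
#' @return The span in codons.
#' @export
motif_span <- function(l) {
  if (!is.numeric(l) || length(l) != 1L || l < 1 || l != round(l))
    stop("motif length must be a positive integer")
  as.integer(ceiling((l + 2) / 3))
}

#' Count motif occurrences in a nucleotide sequence
#'
#' Counts start positions at which some member matches exactly; overlapping
#' occurrences are all counted. Members are equal-length, so at most one can
#' match a given start.
#'
#' @param nt_sequence Nucleotide string (any frame; plain text matching).
#' @param motif A [motif()].
#' @return Non-negative integer count.
#' @examples
#' count_occurrences("AAAAAA", motif("AAA"))  # 4
#' @export
count_occurrences <- function(nt_sequence, motif) {
  sum(occurrence_starts(nt_sequence, motif))
}

# logical vector over start positions 1..(n-l+1); length 0 when sequence too short
occurrence_starts <- function(nt, motif) {
  n <- nchar(nt)
  l <- motif$length
  if (n < l) return(logical(0))
  starts <- seq_len(n - l + 1L)
  substring(nt, starts, starts + l - 1L) %in% motif$members
}

#' Occurrences ending in the last codon of a window
#'
#' The induction increment of the count-distribution dynamic program: the
#' number of motif occurrences (any member) whose final base lies in the last
#' codon of a window of exactly `span` codons. Bounded by 3.
#'
#' @param window Nucleotide string of exactly `3 * motif$span` bases.
#' @param motif A [motif()].
#' @return Integer in 0..3.
#' @export
theta <- function(window, motif) {
  nb <- nchar(window)
  if (nb != 3L * motif$span)
    stop("theta window must be exactly ", motif$span, " codons (",
         3L * motif$span, " bases), got ", nb)
  l <- motif$length
  th <- 0L
  for (e in (nb - 2L):nb) {          # end positions inside the last codon
    s <- e - l + 1L
    if (s >= 1L && substr(window, s, e) %in% motif$members) th <- th + 1L
  }
  th
}

# Mirror of theta used by the 3'->5' DP: occurrences *starting* in the first
# codon of each window. Vectorized over windows (equal widths).
theta_start <- function(windows, motif) {
  if (length(windows) == 0L) return(integer(0))
  nb <- nchar(windows[[1L]])
  l <- motif$length
  th <- integer(length(windows))
  for (s in 1:3) {
    if (s + l - 1L <= nb)
      th <- th + (substring(windows, s, s + l - 1L) %in% motif$members)
  }
  th
}

## ---- realizability of a motif placement over amino-acid windows -----------

# Can `member` occur starting at base position s (1-based) of the coding
# window for amino-acid string `aa`? Constraints decompose per codon: each
# covered codon must have a synonymous codon matching the member's bases at
# the covered positions.
placement_ok <- function(aa_vec, s, member) {
  l <- nchar(member)
  e <- s + l - 1L
  if (e > 3L * length(aa_vec) || s < 1L) return(FALSE)
  k1 <- (s - 1L) %/% 3L + 1L
  k2 <- (e - 1L) %/% 3L + 1L
  mb <- strsplit(member, "", fixed = TRUE)[[1L]]
  for (k in k1:k2) {
    lo <- max(s, 3L * k - 2L)
    hi <- min(e, 3L * k)
    mat <- .CODE$aa_codon_mat[[aa_vec[k]]]
    ok <- rep(TRUE, ncol(mat))
    for (b in lo:hi)
      ok <- ok & (mat[b - 3L * (k - 1L), ] == mb[b - s + 1L])
    if (!any(ok)) return(FALSE)
  }
  TRUE
}

# logical over base starts 1..(3w - l + 1): is any member realizable there?
possible_starts <- function(aa_vec, motif) {
  w <- length(aa_vec)
  n <- 3L * w - motif$length + 1L
  if (n < 1L) return(logical(0))
  vapply(seq_len(n), function(s) {
    for (m in motif$members) if (placement_ok(aa_vec, s, m)) return(TRUE)
    FALSE
  }, logical(1))
}

#' Can a motif occur anywhere in an amino-acid window?
#'
#' Tests whether any assignment of synonymous codons to `aa_window` contains
#' at least one member occurrence at any offset. Because a single placement
#' constrains each covered codon independently, the test reduces to per-codon
#' pattern admissibility — no enumeration over codon combinations is needed.
#'
#' @param aa_window Amino-acid string (no stop symbol).
#' @param motif A [motif()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' motif_possible_in_window("M", motif("ATG"))   # TRUE
#' motif_possible_in_window("KK", motif("TTT"))  # FALSE
#' @export
motif_possible_in_window <- function(aa_window, motif) {
  aa_vec <- strsplit(aa_window, "", fixed = TRUE)[[1L]]
  if ("*" %in% aa_vec) stop("stop symbol inside amino-acid window")
  for (aa in aa_vec) check_aa(aa)
  any(possible_starts(aa_vec, motif))
}

## ---- motif spec / file parsing --------------------------------------------

#' Parse a motif specification token
#'
#' A spec is one or more '/'-separated ACGT tokens; within a token, a bracket
#' group such as `AGACT[AG]` (or `AGACT[A/G]`) expands positionally into one
#' member per listed base. With `include_revcomp`, the reverse complement of
#' every member is added, so motifs on either strand are counted.
#'
#' @param spec Character scalar, e.g. `"AGACT[AG]"` or `"AACCTG/CAGGTT"`.
#' @param include_revcomp Add reverse complements of all members?
#' @param label Optional display name.
#' @return A [motif()].
#' @examples
#' parse_motif_spec("AGACT[AG]")$members            # AGACTA AGACTG
#' parse_motif_spec("AACCTG", include_revcomp = TRUE)$members
#' @export
parse_motif_spec <- function(spec, include_revcomp = FALSE, label = NULL) {
  stopifnot(is.character(spec), length(spec) == 1L)
  tokens <- strsplit_toplevel(gsub("[[:space:]]", "", spec))
  members <- unlist(lapply(tokens, expand_brackets))
  if (include_revcomp) members <- c(members, vapply(members, revcomp, ""))
  motif(members, label = if (is.null(label)) spec else label)
}

# split on '/' outside brackets
strsplit_toplevel <- function(s) {
  out <- character(0); cur <- ""; depth <- 0L
  for (ch in strsplit(s, "", fixed = TRUE)[[1L]]) {
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") depth <- depth - 1L
    if (ch == "/" && depth == 0L) { out <- c(out, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  if (depth != 0L) stop("motif spec error: unbalanced brackets in '", s, "'")
  c(out, cur)
}

expand_brackets <- function(token) {
  m <- regexpr("\\[[^]]*\\]", token)
  if (m < 0L) {
    if (nchar(token) == 0L) stop("motif spec error: empty token")
    return(token)
  }
  inside <- substr(token, m + 1L, m + attr(m, "match.length") - 2L)
  alts <- strsplit(gsub("/", "", inside, fixed = TRUE), "", fixed = TRUE)[[1L]]
  if (length(alts) == 0L) stop("motif spec error: empty bracket group in '", token, "'")
  pre <- substr(token, 1L, m - 1L)
  post <- substr(token, m + attr(m, "match.length"), nchar(token))
  unlist(lapply(alts, function(a) expand_brackets(paste0(pre, a, post))))
}

revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

#' Read a motif file
#'
#' One motif per line: members separated by '/', optional bracket groups,
#' an optional label after a tab, and '#' comments.
#'
#' @param path File path.
#' @param include_revcomp Add reverse complements to every motif.
#' @return List of [motif()] objects, in file order.
#' @export
read_motif_file <- function(path, include_revcomp = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("motif spec error: no motifs in '", path, "'")
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    parse_motif_spec(parts[[1L]], include_revcomp = include_revcomp,
                     label = if (length(parts) > 1L) parts[[2L]] else NULL)
  })
}
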