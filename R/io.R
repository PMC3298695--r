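## FASTA ingestion with frame policing. Coordinates are 1-based inclusive in
## messages, 0-based half-open internally.

#' Read in-frame coding sequences from a multi-FASTA file
#'
#' Admission policy: records whose length is not a multiple of 3 are either
#' truncated at the 3' end to full codons (`frame_policy = "truncate"`, with
#' a warning) or dropped (`"reject"`). Records containing non-ACGT
#' characters, or an internal stop codon, are dropped with a warning — an
#' amino-acid-conditioned null is undefined for them. A terminal stop codon
#' is detached and recorded (`has_terminal_stop`, `boundary_base = "T"`);
#' sequences without one get `boundary_base = NA` (fragment, no 3' context).
#'
#' @param path Multi-FASTA file of coding sequences.
#' @param frame_policy `"truncate"` or `"reject"`.
#' @return List of [coding_sequence()] objects.
#' @export
read_coding_fasta <- function(path, frame_policy = c("truncate", "reject")) {
  frame_policy <- match.arg(frame_policy)
  if (!file.exists(path)) stop("cannot read FASTA file '", path, "'")
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  out <- list()
  for (i in seq_along(x)) {
    nt <- toupper(as.character(x[[i]]))
    id <- if (nzchar(ids[i])) ids[i] else paste0("record_", i)
    if (grepl("[^ACGT]", nt)) {
      warning("dropping '", id, "': non-ACGT characters", call. = FALSE)
      next
    }
    hang <- nchar(nt) %% 3L
    if (hang != 0L) {
      if (frame_policy == "reject") {
        warning("dropping '", id, "': length ", nchar(nt),
                " not a multiple of 3", call. = FALSE)
        next
      }
      warning("truncating ", hang, " hanging 3' base(s) of '", id, "'",
              call. = FALSE)
      nt <- substr(nt, 1L, nchar(nt) - hang)
    }
    if (nchar(nt) == 0L) {
      warning("dropping '", id, "': empty after frame repair", call. = FALSE)
      next
    }
    aa <- translate_cds(nt, id = id)
    aav <- strsplit(aa, "", fixed = TRUE)[[1L]]
    stops <- which(aav == "*")
    has_stop <- length(stops) == 1L && stops == length(aav)
    if (length(stops) > 0L && !has_stop) {
      warning("dropping '", id, "': internal stop codon at codon ",
              stops[1L], call. = FALSE)
      next
    }
    if (has_stop) nt <- substr(nt, 1L, nchar(nt) - 3L)
    if (nchar(nt) == 0L) {
      warning("dropping '", id, "': nothing left after stop detachment",
              call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- coding_sequence(
      id, nt, has_terminal_stop = has_stop,
      boundary_base = if (has_stop) "T" else NA)
  }
  if (length(out) == 0L)
    stop("admission error: no admissible coding sequences in '", path, "'")
  out
}

#' Write a motif evaluation report as TSV
#'
#' @param results Data frame from [evaluate_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
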