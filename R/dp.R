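## Core algorithm: per-sequence segmentation into independent regions where
## the motif is realizable, the conditional count-distribution induction over
## codons (3' -> 5', as the DCM conditions each codon on its 3' neighbour's
## first base), finalization, and convolution across regions and sequences.
##
## State at each induction step: a map from each compatible codon context
## (the span-1 most-5' codons placed so far; at least one codon under the
## DCM) to a sub-normalized count-distribution slice. Prepending a codon adds
## theta occurrences — those starting in the new codon — and multiplies by
## p(alpha | A) (ICM) or p(alpha | A, b(3' neighbour)) (DCM). Because every
## codon's probability is applied as it is prepended, finalization is the
## plain sum of the context slices.

#' Construct a coding sequence record
#'
#' @param id Sequence name.
#' @param nt In-frame nucleotide string with no stop codons (a terminal stop
#'   should be detached first; see [read_coding_fasta()]).
#' @param has_terminal_stop Did the original record end in a stop codon?
#' @param boundary_base First base of the codon 3'-adjacent to `nt`: `"T"`
#'   when a terminal stop was detached, `NA` for a fragment with unknown 3'
#'   context.
#' @return Object of class `"coding_sequence"` with fields `id`, `nt`, `aa`,
#'   `has_terminal_stop`, `boundary_base`.
#' @export
coding_sequence <- function(id, nt, has_terminal_stop = FALSE,
                            boundary_base = if (has_terminal_stop) "T" else NA) {
  aa <- translate_cds(nt, id = id)
  if (grepl("*", aa, fixed = TRUE))
    stop("coding sequence '", id, "' contains a stop codon; detach or reject it")
  if (!is.na(boundary_base) && !boundary_base %in% .BASES)
    stop("boundary_base must be one of A, C, G, T or NA")
  structure(list(id = id, nt = nt, aa = aa,
                 has_terminal_stop = isTRUE(has_terminal_stop),
                 boundary_base = boundary_base),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding sequence> ", x$id, ": ", nchar(x$aa), " codons",
      if (x$has_terminal_stop) " (+stop)", "\n", sep = "")
  invisible(x)
}

#' Split a coding sequence into independent motif regions
#'
#' A region is a maximal codon stretch such that (i) at least one synonymous
#' codon assignment places a motif occurrence inside it and (ii) no possible
#' occurrence extends across its boundary. Regions are found by computing all
#' realizable occurrence placements (see [motif_possible_in_window()]) and
#' merging placements that share a codon; codons touched by no placement are
#' excluded entirely.
#'
#' Additionally, two neighbouring regions are merged when the 3' conditioning
#' base of the 5' region cannot be resolved without reaching a Ser/Arg/Leu
#' codon *inside* the 3' region: in that case the regions' counts would be
#' correlated through the shared first base under the DCM, so they are
#' treated as one. (The merge does not change ICM results.) Each region
#' carries the traceback to its 3' conditioning base: the run of
#' two-first-base amino acids separating it from the nearest fixed first
#' base, stop boundary, or open sequence end.
#'
#' @param seq A [coding_sequence()].
#' @param motif A [motif()].
#' @return List of regions; each is a list with `parent_id`, `start`, `end`
#'   (1-based inclusive codon indices), `aa` (amino-acid string of the span)
#'   and `boundary_3prime` (list with `gap_aa`, character vector of
#'   amino acids between the region end and the traceback terminus, and
#'   `terminus`, one of `"base"` — with `base` — or `"open"`).
#' @export
segment_regions <- function(seq, motif) {
  stopifnot(inherits(seq, "coding_sequence"), inherits(motif, "motif"))
  aa_vec <- strsplit(seq$aa, "", fixed = TRUE)[[1L]]
  n <- length(aa_vec)
  if (n == 0L) return(list())
  ps <- possible_starts(aa_vec, motif)
  starts <- which(ps)
  if (length(starts) == 0L) return(list())
  l <- motif$length
  k1 <- (starts - 1L) %/% 3L + 1L          # first codon of each placement
  k2 <- (starts + l - 2L) %/% 3L + 1L      # last codon of each placement
  # merge placements sharing a codon into maximal codon intervals
  o <- order(k1)
  k1 <- k1[o]; k2 <- k2[o]
  rs <- k1[1L]; re <- k2[1L]
  ivs <- list()
  for (i in seq_along(k1)[-1L]) {
    if (k1[i] <= re) re <- max(re, k2[i])
    else { ivs[[length(ivs) + 1L]] <- c(rs, re); rs <- k1[i]; re <- k2[i] }
  }
  ivs[[length(ivs) + 1L]] <- c(rs, re)
  # resolve 3' traceback; merge regions when it reaches into the next region
  regions <- list()
  i <- length(ivs)
  while (i >= 1L) {
    rs <- ivs[[i]][1L]; re <- ivs[[i]][2L]
    nxt_start <- if (length(regions) > 0L) regions[[1L]]$start else n + 1L
    trace <- trace_boundary(aa_vec, re, nxt_start, seq$boundary_base)
    if (is.null(trace)) {                   # correlated with 3' region: merge
      merged <- regions[[1L]]
      regions <- regions[-1L]
      re <- merged$end
      trace <- merged$boundary_3prime
    }
    regions <- c(list(list(parent_id = seq$id, start = rs, end = re,
                           aa = paste(aa_vec[rs:re], collapse = ""),
                           boundary_3prime = trace)),
                 regions)
    i <- i - 1L
  }
  regions
}

# Scan 3' from codon `re` for the conditioning-base terminus. Returns the
# traceback (gap amino acids + terminus) or NULL when the scan reaches a
# two-first-base amino acid inside the next region (merge signal).
trace_boundary <- function(aa_vec, re, nxt_start, boundary_base) {
  n <- length(aa_vec)
  gap <- character(0)
  j <- re + 1L
  repeat {
    if (j > n) {
      term <- if (is.na(boundary_base)) list(terminus = "open")
              else list(terminus = "base", base = boundary_base)
      return(c(list(gap_aa = gap), term))
    }
    fb <- .CODE$aa_first[[aa_vec[j]]]
    if (length(fb) == 1L)
      return(list(gap_aa = gap, terminus = "base", base = fb))
    if (j >= nxt_start) return(NULL)
    gap <- c(gap, aa_vec[j])
    j <- j + 1L
  }
}

# Distribution over the first base of the codon immediately 3' of a region,
# obtained by propagating the Markov chain 3' -> 5' through the traceback.
# Returns a named probability vector over .BASES, or NULL meaning "no 3'
# context at all" (open end, empty gap): seed the region from the ICM
# marginal instead.
resolve_boundary_q <- function(trace, model) {
  q <- switch(trace$terminus,
    base = { v <- structure(numeric(4L), names = .BASES); v[trace$base] <- 1; v },
    open = NULL)
  gap <- trace$gap_aa
  for (j in rev(seq_along(gap))) {          # 3'-most gap codon first
    cs <- .CODE$aa_codons[[gap[j]]]
    pc <- if (is.null(q)) model$icm$p[cs] else as.numeric(model$p[cs, ] %*% q)
    v <- structure(numeric(4L), names = .BASES)
    fb <- substr(cs, 1L, 1L)
    for (b in unique(fb)) v[b] <- sum(pc[fb == b])
    q <- v
  }
  q
}

#' Exact count distribution of one region
#'
#' Runs the codon induction over the region, 3' to 5': each step prepends one
#' codon, adds the occurrences starting in it, and weights by the model's
#' codon probability; the context tracks the last span-1 codons placed
#' (enumerating only codon tuples compatible with the amino acids). Under
#' the DCM the 3'-most codon is conditioned on the region's resolved
#' boundary-base distribution.
#'
#' @param region One element of [segment_regions()] output.
#' @param motif A [motif()].
#' @param model An `icm_model` or `dcm_model`.
#' @return A normalized [count_distribution()].
#' @export
region_distribution <- function(region, motif, model) {
  check_model(model)
  aa_vec <- strsplit(region$aa, "", fixed = TRUE)[[1L]]
  dcm <- is_dcm(model)
  q <- if (dcm) resolve_boundary_q(region$boundary_3prime, model)
  dp_run(aa_vec, motif, model, q)
}

# The induction proper. aa_vec is the region's amino acids 5'->3'; q is the
# 3' boundary first-base distribution (DCM; NULL = seed from ICM marginal).
dp_run <- function(aa_vec, motif, model, q = NULL) {
  dcm <- is_dcm(model)
  n <- length(aa_vec)
  span <- motif$span
  K <- max(span - 1L, if (dcm) 1L else 0L)  # codons kept in the context
  # seed with the 3'-most codon
  cs <- .CODE$aa_codons[[aa_vec[n]]]
  w <- if (!dcm) model$p[cs]
       else if (is.null(q)) model$icm$p[cs]
       else as.numeric(model$p[cs, ] %*% q)
  th <- theta_start(cs, motif)
  ctx <- if (K == 0L) rep("", length(cs)) else cs
  dists <- lapply(seq_along(cs), function(i) {
    d <- numeric(th[i] + 1L); d[th[i] + 1L] <- w[i]; d
  })
  st <- collapse_state(ctx, dists)
  if (n >= 2L) {
    for (i in (n - 1L):1L) {
      st <- dp_step(st, aa_vec[i], motif, model, dcm, span, K)
    }
  }
  # finalize: all codon probabilities already applied; sum the slices
  maxlen <- max(vapply(st$dists, length, integer(1)))
  total <- numeric(maxlen)
  for (d in st$dists) total[seq_along(d)] <- total[seq_along(d)] + d
  s <- sum(total)
  if (abs(s - 1) > 1e-9)
    stop("internal error: region distribution mass ", format(s, digits = 12))
  count_distribution(trim_distribution(total / s))
}

# one induction step: prepend a codon of amino acid `aa`
dp_step <- function(st, aa, motif, model, dcm, span, K) {
  ctx <- st$ctx; dists <- st$dists
  cs <- .CODE$aa_codons[[aa]]
  b_ctx <- if (dcm) substr(ctx, 1L, 1L)     # first base of the 3' neighbour
  new_ctx <- character(0)
  new_dists <- list()
  for (c in cs) {
    full <- paste0(c, ctx)
    th <- theta_start(substr(full, 1L, 3L * span), motif)
    nc <- substr(full, 1L, 3L * K)
    w <- if (dcm) model$p[c, b_ctx] else rep(model$p[[c]], length(ctx))
    for (j in seq_along(ctx)) {
      if (w[j] == 0) next
      d <- dists[[j]] * w[j]
      if (th[j] > 0L) d <- c(numeric(th[j]), d)
      new_ctx <- c(new_ctx, nc[j])
      new_dists[[length(new_dists) + 1L]] <- d
    }
  }
  collapse_state(new_ctx, new_dists)
}

# merge slices sharing a context key
collapse_state <- function(ctx, dists) {
  if (anyDuplicated(ctx)) {
    keys <- unique(ctx)
    merged <- vector("list", length(keys))
    names(merged) <- keys
    for (j in seq_along(ctx)) {
      k <- ctx[j]; d0 <- merged[[k]]; d <- dists[[j]]
      if (is.null(d0)) merged[[k]] <- d
      else {
        if (length(d0) < length(d)) { tmp <- d0; d0 <- d; d <- tmp }
        d0[seq_along(d)] <- d0[seq_along(d)] + d
        merged[[k]] <- d0
      }
    }
    list(ctx = keys, dists = unname(merged))
  } else list(ctx = ctx, dists = dists)
}

#' Exact count distribution of one coding sequence
#'
#' Segments the sequence (unless `split = FALSE`, which runs the induction
#' over the whole sequence as a single region — same result, slower), runs
#' the induction per region, and convolves the region distributions. With no
#' region the motif cannot occur and the point mass at zero is returned.
#'
#' @inheritParams region_distribution
#' @param seq A [coding_sequence()].
#' @param split Use the sparse-region decomposition (default) or run a single
#'   induction over the full sequence.
#' @param method Convolution method, see [convolve_distributions()].
#' @return A normalized [count_distribution()].
#' @export
sequence_distribution <- function(seq, motif, model, split = TRUE,
                                  method = c("direct", "fft")) {
  method <- match.arg(method)
  check_model(model)
  if (!split) {
    aa_vec <- strsplit(seq$aa, "", fixed = TRUE)[[1L]]
    if (length(aa_vec) == 0L) return(count_distribution(1))
    q <- if (is_dcm(model)) {
      if (is.na(seq$boundary_base)) NULL
      else { v <- structure(numeric(4L), names = .BASES)
             v[seq$boundary_base] <- 1; v }
    }
    return(dp_run(aa_vec, motif, model, q))
  }
  regions <- segment_regions(seq, motif)
  if (length(regions) == 0L) return(count_distribution(1))
  ds <- lapply(regions, region_distribution, motif = motif, model = model)
  combine_distributions(ds, method = method)
}

#' Exact count distribution of a sequence set
#'
#' Convolution of the per-sequence distributions; occurrences never span
#' sequence boundaries.
#'
#' @inheritParams sequence_distribution
#' @param seqs Non-empty list of [coding_sequence()] objects.
#' @return A normalized [count_distribution()].
#' @export
dataset_distribution <- function(seqs, motif, model, split = TRUE,
                                 method = c("direct", "fft")) {
  method <- match.arg(method)
  if (length(seqs) == 0L) stop("empty sequence set")
  ds <- lapply(seqs, sequence_distribution, motif = motif, model = model,
               split = split, method = method)
  combine_distributions(ds, method = method)
}
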