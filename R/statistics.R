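## Reported statistics: exact tail p-values, moments, z-score, count ratio.

#' Exact overrepresentation p-value
#'
#' Probability, under the null, of at least as many motif copies as observed
#' (inclusive tail). The underrepresentation p-value is its complement, so
#' the two tails overlap at the observed value by construction.
#'
#' @param d A normalized [count_distribution()].
#' @param observed Non-negative integer count.
#' @return Probability in `[0, 1]`.
#' @examples
#' d <- count_distribution(c(.25, .25, 0, .25, .25))
#' p_value_over(d, 3)   # 0.5
#' @export
p_value_over <- function(d, observed) {
  stopifnot(is.numeric(observed), length(observed) == 1L, observed >= 0)
  p <- as.numeric(d)
  if (observed + 1 > length(p)) return(0)
  sum(p[(observed + 1):length(p)])
}

#' @rdname p_value_over
#' @export
p_value_under <- function(d, observed) 1 - p_value_over(d, observed)

#' Standardized score of an observed count
#'
#' `(observed - mean) / sd`, with mean and variance computed exactly from the
#' null distribution (the ideal of what infinite-sample shuffling would
#' estimate). A point-mass null has no scale, so the score is `NA`.
#'
#' @inheritParams p_value_over
#' @return Numeric z-score, or `NA` when the null variance is zero.
#' @export
z_score <- function(d, observed) {
  v <- distribution_var(d)
  if (v <= 0) return(NA_real_)
  (observed - distribution_mean(d)) / sqrt(v)
}

#' Evaluate one motif against a query sequence set
#'
#' Computes the observed copy number (summed over sequences; occurrences
#' never span sequence boundaries), the exact null count distribution via
#' [dataset_distribution()], and all reported statistics.
#'
#' @param seqs List of [coding_sequence()] objects.
#' @param motif A [motif()].
#' @param model An `icm_model` or `dcm_model`.
#' @param keep_distribution Keep the full distribution in the result?
#' @param min_mean_for_ratio Report the count ratio only when the null mean
#'   is at least this large (`NA` otherwise); 0 reports it whenever the mean
#'   is positive.
#' @return Object of class `"motif_result"`: `motif_label`, `observed`,
#'   `mean`, `z`, `count_ratio`, `p_over`, `p_under`, and optionally
#'   `distribution`.
#' @export
evaluate_motif <- function(seqs, motif, model, keep_distribution = FALSE,
                           min_mean_for_ratio = 0) {
  stopifnot(inherits(motif, "motif"))
  check_model(model)
  if (inherits(seqs, "coding_sequence")) seqs <- list(seqs)
  observed <- sum(vapply(seqs, function(s) count_occurrences(s$nt, motif),
                         numeric(1)))
  d <- dataset_distribution(seqs, motif, model)
  m <- distribution_mean(d)
  p_over <- p_value_over(d, observed)
  structure(list(
    motif_label = motif$label,
    observed = observed,
    mean = m,
    z = z_score(d, observed),
    count_ratio = if (m > 0 && m >= min_mean_for_ratio) observed / m else NA_real_,
    p_over = p_over,
    p_under = 1 - p_over,
    distribution = if (keep_distribution) d else NULL),
    class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat("<motif result> ", x$motif_label, "\n",
      "  observed ", x$observed, ", null mean ", format(x$mean, digits = 5),
      ", z ", format(x$z, digits = 4), "\n",
      "  p(over) ", format(x$p_over, digits = 5),
      ", p(under) ", format(x$p_under, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Evaluate several motifs in succession
#'
#' @inheritParams evaluate_motif
#' @param motifs List of [motif()] objects.
#' @return A data frame with one row per motif, in input order, with columns
#'   `motif`, `observed`, `mean`, `z`, `count_ratio`, `p_over`, `p_under`.
#' @export
evaluate_motifs <- function(seqs, motifs, model, min_mean_for_ratio = 0) {
  rows <- lapply(motifs, function(mo) {
    r <- evaluate_motif(seqs, mo, model,
                        min_mean_for_ratio = min_mean_for_ratio)
    data.frame(motif = r$motif_label, observed = r$observed, mean = r$mean,
               z = r$z, count_ratio = r$count_ratio, p_over = r$p_over,
               p_under = r$p_under)
  })
  do.call(rbind, rows)
}
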