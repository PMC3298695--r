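## CountDistribution: dense probability array over motif copy numbers,
## with convolution (direct polynomial multiplication by default, FFT as an
## opt-in variant) and smallest-first hierarchical combination.

#' Construct a count distribution
#'
#' @param probs Numeric vector; entry k+1 is P(X = k) for k = 0, 1, ....
#'   Entries must be non-negative. Sub-normalized vectors are allowed (they
#'   arise as conditional slices during the dynamic program).
#' @return Object of class `"count_distribution"`.
#' @export
count_distribution <- function(probs) {
  if (length(probs) == 0L) stop("empty count distribution")
  if (any(probs < 0)) stop("negative probability in count distribution")
  structure(as.numeric(probs), class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  cat("<count distribution> support 0..", length(x) - 1L,
      ", mean ", format(distribution_mean(x), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Mean and variance of a count distribution
#'
#' @param d A [count_distribution()].
#' @return `distribution_mean`: the expected count; `distribution_var`: the
#'   variance, both computed exactly from the array.
#' @export
distribution_mean <- function(d) {
  k <- seq_along(d) - 1
  sum(k * as.numeric(d))
}

#' @rdname distribution_mean
#' @export
distribution_var <- function(d) {
  k <- seq_along(d) - 1
  m <- sum(k * as.numeric(d))
  sum(k * k * as.numeric(d)) - m * m
}

#' Convolve two count distributions
#'
#' The distribution of the sum of two independent counts. `method = "direct"`
#' multiplies the generating-function coefficients term by term, which is the
#' default: at typical motif lengths the FFT route is not faster and can
#' produce slightly negative coefficients from round-off. `method = "fft"`
#' uses [stats::convolve()]; negative round-off coefficients are clamped to
#' zero and the result rescaled back to the product of the input masses.
#'
#' @param d1,d2 [count_distribution()] objects (or bare numeric vectors).
#' @param method `"direct"` or `"fft"`.
#' @return A [count_distribution()] of length `length(d1) + length(d2) - 1`.
#' @examples
#' convolve_distributions(count_distribution(c(.5, .5)),
#'                        count_distribution(c(.5, .5)))
#' @export
convolve_distributions <- function(d1, d2, method = c("direct", "fft")) {
  method <- match.arg(method)
  p1 <- as.numeric(d1); p2 <- as.numeric(d2)
  if (length(p1) == 0L || length(p2) == 0L) stop("empty count distribution")
  if (method == "direct") {
    out <- conv_direct(p1, p2)
  } else {
    out <- stats::convolve(p1, rev(p2), type = "open")
    mass <- sum(p1) * sum(p2)
    out[out < 0] <- 0
    s <- sum(out)
    if (s > 0 && mass > 0) out <- out * (mass / s)
  }
  count_distribution(out)
}

conv_direct <- function(p1, p2) {
  if (length(p2) < length(p1)) { tmp <- p1; p1 <- p2; p2 <- tmp }
  n1 <- length(p1); n2 <- length(p2)
  out <- numeric(n1 + n2 - 1L)
  for (i in seq_len(n1)) {
    idx <- i:(i + n2 - 1L)
    out[idx] <- out[idx] + p1[i] * p2
  }
  out
}

#' Combine many count distributions, smallest first
#'
#' Repeatedly convolves the two currently smallest distributions until one
#' remains. This hierarchical schedule keeps intermediate arrays small; the
#' result is independent of combination order up to floating-point tolerance.
#'
#' @param ds Non-empty list of [count_distribution()] objects.
#' @inheritParams convolve_distributions
#' @return A single [count_distribution()].
#' @export
combine_distributions <- function(ds, method = c("direct", "fft")) {
  method <- match.arg(method)
  if (length(ds) == 0L) stop("empty list of count distributions")
  ds <- lapply(ds, function(d) count_distribution(as.numeric(d)))
  while (length(ds) > 1L) {
    lens <- vapply(ds, length, integer(1))
    o <- order(lens)[1:2]
    merged <- convolve_distributions(ds[[o[1L]]], ds[[o[2L]]], method = method)
    ds <- c(ds[-o], list(merged))
  }
  ds[[1L]]
}

# trim trailing (near-)zero entries, keep at least P(X = 0)
trim_distribution <- function(p, tol = 0) {
  last <- max(c(1L, which(p > tol)))
  p[seq_len(last)]
}

#' Write a count distribution as two-column TSV
#'
#' @param d A [count_distribution()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_distribution_tsv <- function(d, path) {
  df <- data.frame(count = seq_along(d) - 1L, probability = as.numeric(d))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
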