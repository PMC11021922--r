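#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical at every globally unmasked site (see
#' [unmasked_sites()]) are pooled into one haplotype. Network construction is
#' out of scope; only the identity collapse is performed.
#'
#' @param alignment a [seq_alignment()].
#' @return a list of class `haplotype_table`: `haplotype_seqs` (character
#'   vector of representative full-length sequences), `counts` (integer),
#'   `k` (number of haplotypes), `n` (number of samples), `assignment`
#'   (haplotype index per sample).
#' @export
collapse_haplotypes <- function(alignment) {
  if (n_samples(alignment) < 1L) stop("empty alignment")
  keep <- unmasked_sites(alignment)
  key <- if (any(keep)) {
    apply(alignment$seqs[, keep, drop = FALSE], 1L, paste, collapse = "")
  } else rep("", n_samples(alignment))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  counts <- tabulate(idx, nbins = sum(first))
  structure(list(
    haplotype_seqs = apply(alignment$seqs[first, , drop = FALSE], 1L,
                           paste, collapse = ""),
    counts = counts,
    k = sum(first),
    n = n_samples(alignment),
    assignment = idx
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", x$k, "haplotypes in", x$n, "samples; counts:",
      paste(sort(x$counts, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Nei's unbiased haplotype diversity
#'
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i \hat p_i^2\right)} where
#' \eqn{\hat p_i} are sample haplotype frequencies.
#'
#' @param table a `haplotype_table` (or anything with `counts` and `n`), or a
#'   bare integer vector of haplotype counts.
#' @return haplotype diversity in \[0, 1\].
#' @export
haplotype_diversity <- function(table) {
  counts <- if (is.numeric(table)) table else table$counts
  n <- sum(counts)
  if (n < 2L) stop("need at least 2 samples")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# pairwise difference counts on globally unmasked sites; returns the
# upper-triangle vector (length choose(n,2)), via one-hot cross-products
.pairwise_diffs <- function(alignment) {
  keep <- unmasked_sites(alignment)
  n <- n_samples(alignment)
  if (n < 2L) stop("need at least 2 samples")
  Lk <- sum(keep)
  if (Lk == 0L) return(rep(0, n * (n - 1) / 2))
  m <- .aln_int(alignment)[, keep, drop = FALSE]
  same <- matrix(0, n, n)
  for (b in 1:4) {
    X <- (m == b) * 1
    same <- same + tcrossprod(X)
  }
  D <- Lk - same
  D[upper.tri(D)]
}

#' Nucleotide diversity (per site)
#'
#' Mean number of pairwise differences divided by the number of unmasked
#' sites.
#'
#' @param alignment a [seq_alignment()].
#' @return \eqn{\pi} per site.
#' @export
nucleotide_diversity <- function(alignment) {
  keep <- unmasked_sites(alignment)
  if (sum(keep) == 0L) return(0)
  mean(.pairwise_diffs(alignment)) / sum(keep)
}

#' Mean and variance of pairwise difference counts
#'
#' Over all \eqn{\binom{n}{2}} sequence pairs, on globally unmasked sites.
#' The variance is the sample variance (denominator \eqn{n_{pairs}-1}), 0 when
#' there is a single pair.
#'
#' @param alignment a [seq_alignment()].
#' @return named numeric vector `c(mean, variance)`.
#' @export
pairwise_diff_stats <- function(alignment) {
  d <- .pairwise_diffs(alignment)
  v <- if (length(d) > 1L) stats::var(d) else 0
  c(mean = mean(d), variance = v)
}

#' Segregating sites
#'
#' Number of globally unmasked sites with more than one base observed.
#'
#' @param alignment a [seq_alignment()].
#' @return integer count.
#' @export
segregating_sites <- function(alignment) {
  keep <- unmasked_sites(alignment)
  if (!any(keep)) return(0L)
  m <- alignment$seqs[, keep, drop = FALSE]
  sum(apply(m, 2L, function(col) length(unique(col))) > 1L)
}

#' Tajima's D
#'
#' The standard normalized difference between the mean-pairwise-difference and
#' segregating-sites estimators of theta. When `S = 0` the statistic is
#' undefined and `NaN` is returned (downstream summary vectors replace this
#' sentinel by 0 and carry an indicator).
#'
#' @param alignment a [seq_alignment()]; `n >= 4` recommended.
#' @return Tajima's D, or `NaN` when there are no segregating sites.
#' @export
tajimas_d <- function(alignment) {
  n <- n_samples(alignment)
  if (n < 2L) stop("need at least 2 samples")
  S <- segregating_sites(alignment)
  if (S == 0L) return(NaN)
  k_mean <- mean(.pairwise_diffs(alignment))
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_mean - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
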