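## The 39-value ABC summary-statistic vector: 8 single-sample statistics for
## each of the three regions plus 5 two-sample statistics for each region
## pair, computed on globally unmasked sites.

.SINGLE_STATS <- c("k", "S", "mean_pd", "var_pd", "tajD", "privS",
                   "rar_mean", "rar_var")
.PAIR_STATS <- c("k", "S", "within_pd", "between_pd", "hudson_fst")

#' Names and order of the summary-statistic vector
#' @return character vector of length 39.
#' @export
summary_stat_names <- function() {
  c(as.vector(t(outer(c("A", "C", "S"), .SINGLE_STATS, paste, sep = "_"))),
    as.vector(t(outer(c("AC", "AS", "CS"), .PAIR_STATS, paste, sep = "_"))))
}

.tajima_from_counts <- function(n, S, k_mean) {
  if (S == 0) return(NaN)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k_mean - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

#' DIYABC-style summary-statistic vector
#'
#' For each region: number of distinct haplotypes, number of segregating
#' sites, mean and variance of the pairwise difference counts, Tajima's D,
#' number of private segregating sites (polymorphic within the region,
#' monomorphic in the union of the other two), and the mean and variance over
#' the region's segregating sites of the count of the rarest observed
#' nucleotide. For each region pair: pooled haplotype count, pooled
#' segregating sites, mean within-sample pairwise difference (average of the
#' two within-region means), mean between-sample pairwise difference, and
#' Hudson's pairwise \eqn{F_{ST} = 1 - H_w/H_b}.
#'
#' Tajima's D is undefined when a region has no segregating sites; the value
#' is then replaced by 0 and flagged in the `d_flags` attribute (flags are
#' excluded from ABC distance computation).
#'
#' @param alignment a [seq_alignment()].
#' @param partition a [pop_partition()] whose `region` labels take exactly the
#'   values `A`, `C`, `S` (each with at least 2 samples), or a bare region
#'   label vector in sample order.
#' @return named numeric vector of length 39 (order of
#'   [summary_stat_names()]), with attribute `d_flags`.
#' @export
summary_vector <- function(alignment, partition) {
  regions <- if (inherits(partition, "pop_partition")) {
    .partition_groups(partition, alignment$ids, "region")
  } else as.character(partition)
  if (!setequal(unique(regions), c("A", "C", "S")))
    stop("partition must contain exactly regions A, C, S")
  keep <- unmasked_sites(alignment)
  m <- .aln_int(alignment)[, keep, drop = FALSE]
  Lk <- ncol(m)
  idx <- lapply(c(A = "A", C = "C", S = "S"), function(r) which(regions == r))
  ns <- lengths(idx)
  if (any(ns < 2L)) stop("every region needs at least 2 samples")

  # one shared difference matrix and per-region base counts
  same <- matrix(0, nrow(m), nrow(m))
  counts <- lapply(idx, function(i) matrix(0, Lk, 4L))
  for (b in 1:4) {
    X <- (m == b) * 1
    same <- same + tcrossprod(X)
    for (r in c("A", "C", "S"))
      counts[[r]][, b] <- colSums(X[idx[[r]], , drop = FALSE])
  }
  D <- Lk - same
  seg <- lapply(counts, function(cc) rowSums(cc > 0) > 1)

  # number of distinct rows within a sub-block of D (zero distance = same)
  n_distinct <- function(i) {
    Z <- D[i, i, drop = FALSE] == 0
    Z[lower.tri(Z, diag = TRUE)] <- FALSE
    sum(colSums(Z) == 0L)
  }

  out <- numeric(0)
  d_flags <- logical(3); names(d_flags) <- c("A", "C", "S")
  within_mean <- numeric(3); names(within_mean) <- c("A", "C", "S")

  for (r in c("A", "C", "S")) {
    i <- idx[[r]]; n <- length(i)
    k <- n_distinct(i)
    S <- sum(seg[[r]])
    Dr <- D[i, i, drop = FALSE]
    pd <- Dr[upper.tri(Dr)]
    mean_pd <- mean(pd)
    var_pd <- if (length(pd) > 1L) stats::var(pd) else 0
    within_mean[r] <- mean_pd
    tajD <- .tajima_from_counts(n, S, mean_pd)
    # undefined at S = 0 and degenerate for n < 4 (zero normalizing variance)
    if (!is.finite(tajD)) { tajD <- 0; d_flags[r] <- TRUE }
    others <- setdiff(c("A", "C", "S"), r)
    cc_other <- counts[[others[1]]] + counts[[others[2]]]
    mono_other <- rowSums(cc_other > 0) == 1
    privS <- sum(seg[[r]] & mono_other)
    if (S > 0) {
      cs <- counts[[r]][seg[[r]], , drop = FALSE]
      cs[cs == 0] <- Inf
      rar <- do.call(pmin, as.data.frame(cs))
      rar_mean <- mean(rar)
      rar_var <- if (length(rar) > 1L) stats::var(rar) else 0
    } else rar_mean <- rar_var <- 0
    out <- c(out, k, S, mean_pd, var_pd, tajD, privS, rar_mean, rar_var)
  }

  pairs <- list(AC = c("A", "C"), AS = c("A", "S"), CS = c("C", "S"))
  for (pn in names(pairs)) {
    pr <- pairs[[pn]]
    k_pool <- n_distinct(c(idx[[pr[1]]], idx[[pr[2]]]))
    cc <- counts[[pr[1]]] + counts[[pr[2]]]
    S_pool <- sum(rowSums(cc > 0) > 1)
    between <- mean(D[idx[[pr[1]]], idx[[pr[2]]], drop = FALSE])
    within <- mean(within_mean[pr])
    fst <- if (between > 0) 1 - within / between else 0
    out <- c(out, k_pool, S_pool, within, between, fst)
  }
  names(out) <- summary_stat_names()
  attr(out, "d_flags") <- d_flags
  out
}
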