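## AMOVA: partition of (squared) molecular distances among and within groups.
## Matrix entries are treated as squared distances in the sums of squares,
## the convention under which 0/1 identity distances reproduce frequency FST.

# within-group and total pair sums of a squared-distance matrix, by labels
.amova_components <- function(D2, groups) {
  groups <- as.character(groups)
  n <- length(groups)
  gs <- table(groups)
  G <- length(gs)
  if (G < 2L) stop("AMOVA needs at least 2 groups")
  M <- rowsum(D2, groups)                 # G x n
  W <- rowsum(t(M), groups)               # G x G, W[g,g] = 2 * sum of pairs in g
  ssd_within <- sum(diag(W)[names(gs)] / 2 / as.numeric(gs))
  ssd_total <- sum(D2) / 2 / n
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (n - G)
  nbar <- (n - sum(as.numeric(gs)^2) / n) / (G - 1)
  sigma_a <- (ssd_among / (G - 1) - sigma_w) / nbar
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       phi = if (sigma_a + sigma_w == 0) NaN else sigma_a / (sigma_a + sigma_w))
}

.perm_pvalue <- function(obs, D2, groups, n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1L) return(NA_real_)
  b <- 0L
  for (i in seq_len(n_perm)) {
    phi <- .amova_components(D2, sample(groups))$phi
    if (!is.nan(phi) && phi >= obs) b <- b + 1L
  }
  (b + 1) / (n_perm + 1)
}

#' Analysis of molecular variance (Phi_ST / F_ST)
#'
#' Partitions squared molecular distances among and within groups and reports
#' the fixation index \eqn{\Phi_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}.
#' With identity (0/1 haplotype) distances this equals the frequency-based
#' \eqn{F_{ST}}. Significance is assessed by permuting sample labels among
#' groups; \eqn{p = (b+1)/(B+1)} with `b` the number of permuted statistics at
#' least as large as the observed one. Negative estimates are reported
#' unclamped.
#'
#' @param x a [seq_alignment()] (distances computed per `spec`) or a
#'   symmetric zero-diagonal distance matrix with sample ids as dimnames.
#' @param partition a [pop_partition()], or a bare vector of group labels in
#'   sample order.
#' @param level grouping level when `partition` is a [pop_partition()].
#' @param spec a [distance_spec()] (ignored when `x` is already a matrix).
#' @param n_perm number of label permutations (study convention: 10000).
#' @param seed optional RNG seed for the permutation test.
#' @param pairwise also compute the pairwise group-by-group statistic and
#'   p-value matrices (pair-restricted permutations).
#' @return object of class `amova_result` with elements `statistic`,
#'   `sigma_among`, `sigma_within`, `p_value`, `n_perm`, and (optionally)
#'   `pairwise_statistic` / `pairwise_p` matrices.
#' @export
amova <- function(x, partition, level = "location", spec = distance_spec(),
                  n_perm = 10000L, seed = NULL, pairwise = FALSE) {
  ids <- if (inherits(x, "seq_alignment")) x$ids else rownames(as.matrix(x))
  groups <- if (inherits(partition, "pop_partition")) {
    .partition_groups(partition, ids, level)
  } else as.character(partition)
  if (length(unique(groups)) < 2L) stop("AMOVA needs at least 2 groups")
  if (inherits(x, "seq_alignment")) {
    if (length(groups) != n_samples(x)) stop("labels do not match samples")
    D2 <- distance_matrix(x, spec)
    stat_name <- if (spec$model == "identity") "F_ST" else "Phi_ST"
  } else {
    D2 <- as.matrix(x)
    if (!isSymmetric(unname(D2)) || any(diag(D2) != 0))
      stop("distance matrix must be symmetric with zero diagonal")
    if (length(groups) != nrow(D2)) stop("labels do not match samples")
    stat_name <- "Phi_ST"
  }
  if (!is.null(seed)) set.seed(seed)

  comp <- .amova_components(D2, groups)
  p <- .perm_pvalue(comp$phi, D2, groups, n_perm)

  res <- list(statistic_name = stat_name, statistic = comp$phi,
              sigma_among = comp$sigma_a, sigma_within = comp$sigma_w,
              p_value = p, n_perm = n_perm, groups = sort(unique(groups)))
  if (pairwise) {
    gl <- res$groups
    ns <- length(gl)
    pm <- pp <- matrix(NA_real_, ns, ns, dimnames = list(gl, gl))
    for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
      sel <- groups %in% c(gl[i], gl[j])
      sub <- .amova_components(D2[sel, sel, drop = FALSE], groups[sel])
      pm[i, j] <- pm[j, i] <- sub$phi
      pp[i, j] <- pp[j, i] <- .perm_pvalue(sub$phi, D2[sel, sel, drop = FALSE],
                                           groups[sel], n_perm)
    }
    diag(pm) <- 0
    res$pairwise_statistic <- pm
    res$pairwise_p <- pp
  }
  class(res) <- "amova_result"
  res
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (sigma_a = %.4g, sigma_w = %.4g), p = %.4g [%d perms]\n",
              x$statistic_name, x$statistic, x$sigma_among, x$sigma_within,
              x$p_value, x$n_perm))
  invisible(x)
}

## ---- diploid multilocus F_ST -------------------------------------------

# per-locus variance components from allele counts split by group
.locus_components <- function(a1, a2, groups) {
  ok <- !is.na(a1)
  if (!any(ok)) return(NULL)
  g <- rep(groups[ok], 2L)
  al <- c(a1[ok], a2[ok])
  tab <- table(g, al)
  if (ncol(tab) < 2L) return(NULL)            # monomorphic locus
  m_g <- rowSums(tab)
  m_g <- m_g[m_g > 0]
  tab <- tab[names(m_g), , drop = FALSE]
  G <- length(m_g)
  if (G < 2L) return(NULL)
  m <- sum(m_g)
  ssd_w <- sum((m_g - rowSums(tab^2) / m_g) / 2)
  ctot <- colSums(tab)
  ssd_t <- (m - sum(ctot^2) / m) / 2
  ssd_a <- ssd_t - ssd_w
  sigma_w <- ssd_w / (m - G)
  nbar <- (m - sum(m_g^2) / m) / (G - 1)
  sigma_a <- (ssd_a / (G - 1) - sigma_w) / nbar
  c(sigma_a = sigma_a, sigma_w = sigma_w)
}

.multilocus_fst <- function(wide, groups) {
  comps <- lapply(wide, function(l) .locus_components(l$a1, l$a2, groups))
  comps <- comps[!vapply(comps, is.null, TRUE)]
  if (length(comps) == 0L) return(NaN)
  s <- Reduce(`+`, comps)
  if (sum(s) == 0) NaN else s[["sigma_a"]] / (s[["sigma_a"]] + s[["sigma_w"]])
}

#' Multilocus diploid F_ST by AMOVA on allele frequencies
#'
#' Identity-distance AMOVA at the allele level, with among- and within-group
#' variance components summed across loci before forming the ratio (a weighted
#' multilocus average). Individuals (both alleles together) are permuted among
#' groups for the significance test.
#'
#' @param genotypes a `genotype_table` (see [read_genotypes()]).
#' @param partition a [pop_partition()] or vector of group labels, one per
#'   distinct sample in `genotypes`.
#' @param level grouping level for a [pop_partition()].
#' @param n_perm,seed,pairwise as in [amova()].
#' @return an `amova_result` with `statistic_name = "F_ST"`.
#' @export
diploid_fst <- function(genotypes, partition, level = "location",
                        n_perm = 10000L, seed = NULL, pairwise = FALSE) {
  samples <- unique(genotypes$sample_id)
  groups <- if (inherits(partition, "pop_partition")) {
    .partition_groups(partition, samples, level)
  } else as.character(partition)
  if (length(groups) != length(samples)) stop("labels do not match samples")
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)

  # per-locus allele vectors aligned to `samples`
  wide <- lapply(split(genotypes, genotypes$locus), function(d) {
    i <- match(samples, d$sample_id)
    list(a1 = d$allele1[i], a2 = d$allele2[i])
  })
  fst <- .multilocus_fst(wide, groups)
  if (is.nan(fst)) stop("all loci monomorphic")

  p <- {
    b <- 0L
    for (i in seq_len(n_perm)) {
      f <- .multilocus_fst(wide, sample(groups))
      if (!is.nan(f) && f >= fst) b <- b + 1L
    }
    if (n_perm >= 1L) (b + 1) / (n_perm + 1) else NA_real_
  }

  res <- list(statistic_name = "F_ST", statistic = fst,
              sigma_among = NA_real_, sigma_within = NA_real_,
              p_value = p, n_perm = n_perm, groups = sort(unique(groups)))
  if (pairwise) {
    gl <- res$groups
    ns <- length(gl)
    pm <- pp <- matrix(NA_real_, ns, ns, dimnames = list(gl, gl))
    for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
      sel <- groups %in% c(gl[i], gl[j])
      wsub <- lapply(wide, function(l) list(a1 = l$a1[sel], a2 = l$a2[sel]))
      gsub <- groups[sel]
      f0 <- .multilocus_fst(wsub, gsub)
      pm[i, j] <- pm[j, i] <- f0
      b <- 0L
      for (r in seq_len(n_perm)) {
        f <- .multilocus_fst(wsub, sample(gsub))
        if (!is.nan(f) && f >= f0) b <- b + 1L
      }
      pp[i, j] <- pp[j, i] <- if (n_perm >= 1L) (b + 1) / (n_perm + 1) else NA_real_
    }
    diag(pm) <- 0
    res$pairwise_statistic <- pm
    res$pairwise_p <- pp
  }
  class(res) <- "amova_result"
  res
}
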