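# Independent oracles used across the suite. These deliberately re-derive
# quantities from definitions (explicit loops, closed forms) rather than
# calling the package's fast paths.

# log unsigned Stirling numbers of the first kind: L[m+1, k+1] = log |s(m,k)|
oracle_lstirling <- function(n) {
  lse <- function(a, b) {
    m <- pmax(a, b)
    ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(a, b) - m)))
  }
  L <- matrix(-Inf, n + 1, n + 1)
  L[1, 1] <- 0
  for (m in 1:n) for (k in 1:m)
    L[m + 1, k + 1] <- lse(L[m, k], L[m, k + 1] + log(m - 1))
  L
}

# exact E[sum p_i^2 | n, k] under the Ewens sampling formula:
# E[C_j | K=k] = C(n,j) (j-1)! |s(n-j,k-1)| / |s(n,k)| alleles of size j
oracle_fexp_exact <- function(n, k) {
  L <- oracle_lstirling(n)
  j <- 1:(n - k + 1)
  lEC <- lchoose(n, j) + lgamma(j) + L[cbind(n - j + 1, k)] - L[n + 1, k + 1]
  sum(j^2 * exp(lEC)) / n^2
}

# frequency F_ST from allele-count sums of squares (haploid identity AMOVA,
# derived independently from counts rather than a distance matrix)
oracle_fst_counts <- function(counts) {
  # counts: groups x alleles matrix
  n_g <- rowSums(counts)
  n <- sum(n_g)
  G <- nrow(counts)
  ssd_w <- sum((n_g - rowSums(counts^2) / n_g) / 2)
  ctot <- colSums(counts)
  ssd_t <- (n - sum(ctot^2) / n) / 2
  ssd_a <- ssd_t - ssd_w
  sig_w <- ssd_w / (n - G)
  nbar <- (n - sum(n_g^2) / n) / (G - 1)
  sig_a <- (ssd_a / (G - 1) - sig_w) / nbar
  sig_a / (sig_a + sig_w)
}

# brute-force diversity statistics by definition (character loops)
oracle_h <- function(counts) {
  n <- sum(counts)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

oracle_pairwise_diffs <- function(seqs) {
  # seqs: character vector; only sites where every sequence is in ACGT count
  mat <- do.call(rbind, strsplit(seqs, ""))
  ok <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  mat <- mat[, ok, drop = FALSE]
  n <- length(seqs)
  d <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d <- c(d, sum(mat[i, ] != mat[j, ]))
  list(diffs = d, L = ncol(mat))
}

# random toy alignment with controlled polymorphism
random_toy_alignment <- function(n = 6, L = 12, n_var = 4) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- replicate(n, {
    s <- base
    var_sites <- sample(L, n_var)
    flip <- runif(n_var) < 0.5
    s[var_sites[flip]] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    paste(s, collapse = "")
  })
  seq_alignment(seqs, sample_ids = sprintf("s%02d", seq_len(n)))
}

# uncorrected K2P from transition/transversion proportions
oracle_k2p_uncorrected <- function(P, Q) {
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# brute-force 39-statistic summary vector from definitions (slow loops)
oracle_summary_vector <- function(alignment, regions) {
  mat <- alignment$seqs
  ok <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  mat <- mat[, ok, drop = FALSE]
  tajima <- function(n, S, kmean) {
    if (S == 0) return(NA)
    i <- 1:(n - 1); a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (kmean - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  }
  pd <- function(block) {
    n <- nrow(block)
    d <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d <- c(d, sum(block[i, ] != block[j, ]))
    d
  }
  out <- c()
  within_means <- c()
  for (r in c("A", "C", "S")) {
    b <- mat[regions == r, , drop = FALSE]
    other <- mat[regions != r, , drop = FALSE]
    n <- nrow(b)
    k <- nrow(unique(b))
    seg <- which(apply(b, 2, function(col) length(unique(col)) > 1))
    S <- length(seg)
    d <- pd(b)
    m_pd <- mean(d)
    v_pd <- if (length(d) > 1) var(d) else 0
    within_means[r] <- m_pd
    D <- tajima(n, S, m_pd)
    if (!is.finite(D)) D <- 0
    priv <- sum(vapply(seg, function(s) length(unique(other[, s])) == 1, TRUE))
    if (S > 0) {
      rar <- vapply(seg, function(s) min(table(b[, s])), 1)
      rm_ <- mean(rar); rv_ <- if (length(rar) > 1) var(rar) else 0
    } else { rm_ <- 0; rv_ <- 0 }
    out <- c(out, k, S, m_pd, v_pd, D, priv, rm_, rv_)
  }
  for (pr in list(c("A", "C"), c("A", "S"), c("C", "S"))) {
    b1 <- mat[regions == pr[1], , drop = FALSE]
    b2 <- mat[regions == pr[2], , drop = FALSE]
    pool <- rbind(b1, b2)
    k <- nrow(unique(pool))
    S <- sum(apply(pool, 2, function(col) length(unique(col)) > 1))
    between <- c()
    for (i in seq_len(nrow(b1))) for (j in seq_len(nrow(b2)))
      between <- c(between, sum(b1[i, ] != b2[j, ]))
    hb <- mean(between)
    hw <- mean(within_means[pr])
    fst <- if (hb > 0) 1 - hw / hb else 0
    out <- c(out, k, S, hw, hb, fst)
  }
  out
}
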