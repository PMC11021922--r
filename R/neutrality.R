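## Neutrality tests built on the Ewens sampling formula (ESF).
##
## The allele-configuration law of a neutral sample conditional on the number
## of distinct alleles k is free of theta (k is sufficient for theta), so
## conditional draws can be obtained by running the Chinese-restaurant
## construction at any convenient theta and rejecting on k. We run it at the
## theta solving E[K] = k to keep the acceptance rate high, and fall back to
## exact sequential sampling via Stirling numbers of the first kind if the
## acceptance rate collapses.

# E[K] for a sample of n at theta
.esf_ek <- function(theta, n) sum(theta / (theta + 0:(n - 1)))

# theta with E[K] = k (k strictly between 1 and n)
.esf_theta_for_k <- function(n, k) {
  stats::uniroot(function(lt) .esf_ek(exp(lt), n) - k,
                 lower = log(1e-8), upper = log(1e8), tol = 1e-10)$root |> exp()
}

# Vectorized Chinese-restaurant construction: `draws` independent samples of
# size n at fixed theta. Returns list(k, F) per draw, where F = sum p_i^2.
.crt_draws <- function(n, theta, draws) {
  tab <- matrix(1L, draws, n)    # table label of each customer; labels in 1..n
  maxlab <- rep(1L, draws)
  for (m in 2:n) {
    new <- stats::runif(draws) < theta / (theta + m - 1)
    # joining customers pick a uniformly random earlier customer's table
    j <- 1L + floor(stats::runif(draws) * (m - 1))
    tab[, m] <- tab[cbind(seq_len(draws), j)]
    maxlab <- maxlab + new
    tab[new, m] <- maxlab[new]
  }
  # per-draw table sizes via one big tabulate: cell (d, m) of `tab`
  # contributes to bin (d-1)*n + label
  idx <- (rep(seq_len(draws), times = n) - 1L) * n + as.integer(tab)
  cnt <- tabulate(idx, nbins = draws * n)
  cm <- matrix(cnt, nrow = n, ncol = draws)   # label x draw
  k <- colSums(cm > 0L)
  Fv <- colSums((cm / n)^2)
  list(k = k, F = Fv)
}

# log unsigned Stirling numbers of the first kind, L[m+1, k+1] = log |s(m,k)|
.lstirling <- function(n) {
  L <- matrix(-Inf, n + 1L, n + 1L)
  L[1L, 1L] <- 0
  for (m in seq_len(n)) for (k in seq_len(m)) {
    a <- L[m, k]
    b <- if (m > 1L) L[m, k + 1L] + log(m - 1) else -Inf
    mx <- max(a, b)
    L[m + 1L, k + 1L] <- if (is.infinite(mx)) -Inf else mx + log1p(exp(min(a, b) - mx))
  }
  L
}

# Exact sequential sampler of an ESF configuration conditional on (n, k):
# allocate the size of the allele containing a marked gene copy, recurse.
# P(size = j | n, k) = C(n-1, j-1) (j-1)! |s(n-j, k-1)| / |s(n, k)|.
.esf_conditional_seq <- function(n, k, draws, Lst = .lstirling(n)) {
  Fv <- numeric(draws)
  for (d in seq_len(draws)) {
    nn <- n; kk <- k
    sizes <- integer(0)
    while (kk > 0L) {
      if (kk == 1L) { sizes <- c(sizes, nn); break }
      j <- 1:(nn - kk + 1L)
      lp <- lchoose(nn - 1L, j - 1L) + lgamma(j) + Lst[cbind(nn - j + 1L, kk)] -
        Lst[nn + 1L, kk + 1L]
      sz <- sample(j, 1L, prob = exp(lp - max(lp)))
      sizes <- c(sizes, sz)
      nn <- nn - sz; kk <- kk - 1L
    }
    Fv[d] <- sum((sizes / n)^2)
  }
  Fv
}

# `draws` values of F = sum p_i^2 from the ESF conditional on (n, k)
.esf_conditional_F <- function(n, k, draws, batch = 200000L) {
  if (k == 1L) return(rep(1, draws))
  if (k == n) return(rep(1 / n, draws))
  theta <- .esf_theta_for_k(n, k)
  out <- numeric(0)
  attempts <- 0L
  while (length(out) < draws) {
    got <- .crt_draws(n, theta, batch)
    out <- c(out, got$F[got$k == k])
    attempts <- attempts + batch
    if (attempts >= batch && length(out) / attempts < 0.01) {
      # acceptance collapsed; use the exact sequential sampler instead
      return(.esf_conditional_seq(n, k, draws))
    }
  }
  out[seq_len(draws)]
}

#' Ewens-Watterson homozygosity test
#'
#' Compares the observed sample homozygosity \eqn{F_{obs} = \sum \hat p_i^2}
#' with its expectation under the neutral Ewens sampling formula conditional
#' on the sample size n and observed number of alleles k. The conditional
#' distribution is theta-free, and is sampled by Monte Carlo. Both one-sided
#' p-values are reported (the low tail, `p_le`, flags excess homozygosity;
#' the convention used by published tables varies).
#'
#' @param n sample size (ignored when `counts` is given).
#' @param k number of distinct alleles (ignored when `counts` is given).
#' @param counts optional observed allele counts; supplies n, k and F_obs.
#' @param n_draws number of conditional configurations (>= 1e4 recommended).
#' @param seed optional RNG seed.
#' @return list of class `neutrality_result`: `F_obs` (NA without counts),
#'   `F_exp`, `F_sd`, `p_le` = Pr(F <= F_obs), `p_ge` = Pr(F >= F_obs),
#'   `n`, `k`, `n_draws`.
#' @export
ewens_watterson <- function(n = NULL, k = NULL, counts = NULL,
                            n_draws = 100000L, seed = NULL) {
  if (!is.null(counts)) {
    counts <- as.integer(counts)
    if (any(counts <= 0L)) stop("counts must be positive")
    n <- sum(counts)
    k <- length(counts)
  }
  if (is.null(n) || is.null(k)) stop("supply counts, or both n and k")
  if (k < 1L || k > n) stop("need 1 <= k <= n")
  if (!is.null(seed)) set.seed(seed)
  Fs <- .esf_conditional_F(n, k, n_draws)
  F_obs <- if (!is.null(counts)) sum((counts / n)^2) else NA_real_
  p_le <- p_ge <- NA_real_
  if (!is.na(F_obs)) {
    p_le <- (sum(Fs <= F_obs) + 1) / (length(Fs) + 1)
    p_ge <- (sum(Fs >= F_obs) + 1) / (length(Fs) + 1)
  }
  structure(list(F_obs = F_obs, F_exp = mean(Fs), F_sd = stats::sd(Fs),
                 p_le = p_le, p_ge = p_ge, n = n, k = k,
                 n_draws = length(Fs), test = "Ewens-Watterson"),
            class = "neutrality_result")
}

#' Chakraborty test of allele-count neutrality
#'
#' Estimates theta from the observed homozygosity by the moment relation
#' \eqn{E[F] = 1/(1+\theta)}, i.e. \eqn{\hat\theta = 1/F_{obs} - 1}, computes
#' the expected number of alleles
#' \eqn{k_{exp} = \sum_{i=0}^{n-1} \hat\theta/(\hat\theta + i)}, and reports
#' \eqn{p = \Pr(k \ge k_{obs})} under unconditional ESF draws at
#' \eqn{\hat\theta} (an excess of observed alleles gives a small p).
#'
#' @param n sample size.
#' @param F_obs observed homozygosity, in \[1/n, 1\].
#' @param k_obs observed allele count (optional; needed for the p-value).
#' @param n_draws Monte Carlo draws.
#' @param seed optional RNG seed.
#' @return `neutrality_result` with `theta_hat`, `k_exp`, `p_ge`.
#' @export
chakraborty <- function(n, F_obs, k_obs = NULL, n_draws = 100000L, seed = NULL) {
  if (F_obs < 1 / n || F_obs > 1) stop("F_obs must lie in [1/n, 1]")
  theta <- 1 / F_obs - 1
  k_exp <- if (theta == 0) 1 else .esf_ek(theta, n)
  p_ge <- NA_real_
  if (!is.null(k_obs)) {
    if (!is.null(seed)) set.seed(seed)
    if (theta == 0) {
      p_ge <- if (k_obs <= 1L) 1 else 1 / (n_draws + 1)
    } else {
      ks <- .crt_draws(n, theta, n_draws)$k
      p_ge <- (sum(ks >= k_obs) + 1) / (n_draws + 1)
    }
  }
  structure(list(theta_hat = theta, k_exp = k_exp, k_obs = k_obs,
                 F_obs = F_obs, p_ge = p_ge, n = n, n_draws = n_draws,
                 test = "Chakraborty"),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(x$test, "test (n =", x$n, ")\n")
  if (x$test == "Ewens-Watterson") {
    cat(sprintf("  k = %d; F_obs = %s; F_exp = %.4f (sd %.4f); p(F<=obs) = %s; p(F>=obs) = %s\n",
                x$k, format(x$F_obs, digits = 4), x$F_exp, x$F_sd,
                format(x$p_le, digits = 3), format(x$p_ge, digits = 3)))
  } else {
    cat(sprintf("  theta_hat = %.4f; k_exp = %.2f; k_obs = %s; p(k>=obs) = %s\n",
                x$theta_hat, x$k_exp, format(x$k_obs), format(x$p_ge, digits = 3)))
  }
  invisible(x)
}
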