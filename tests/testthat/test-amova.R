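test_that("fixed private haplotypes give Phi_ST = 1", {
  aln <- seq_alignment(c(rep("AAAA", 4), rep("TTTT", 4)), paste0("s", 1:8))
  res <- amova(aln, rep(c("g1", "g2"), each = 4),
               spec = distance_spec("identity"), n_perm = 499, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$sigma_within, 0)
  # only the 2/choose(8,4) label permutations matching the haplotype split
  # reach the observed statistic
  expect_lt(res$p_value, 0.1)
})

test_that("identity-distance AMOVA equals frequency F_ST from allele counts", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    n_hap <- sample(2:5, 1)
    hap_seqs <- replicate(n_hap, paste(sample(c("A", "C", "G", "T"), 8, TRUE),
                                       collapse = ""))
    while (anyDuplicated(hap_seqs) > 0)
      hap_seqs <- replicate(n_hap, paste(sample(c("A", "C", "G", "T"), 8, TRUE),
                                         collapse = ""))
    assign <- sample(n_hap, n, replace = TRUE)
    groups <- sample(rep(c("g1", "g2", "g3"), length.out = n))
    # need every group non-empty and overall polymorphism
    if (length(unique(assign)) < 2 || length(unique(groups)) < 2) next
    aln <- seq_alignment(hap_seqs[assign], paste0("s", 1:n))
    res <- amova(aln, groups, spec = distance_spec("identity"), n_perm = 0)
    counts <- as.matrix(table(groups, assign))
    expect_equal(res$statistic, oracle_fst_counts(counts), tolerance = 1e-12)
  }
})

test_that("AMOVA validates inputs and reports pairwise matrices", {
  aln <- seq_alignment(c(rep("AAAA", 4), rep("TTTT", 4), rep("AATT", 4)),
                       paste0("s", 1:12))
  expect_error(amova(aln, rep("g1", 12), n_perm = 0), "2 groups")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(amova(bad, c("a", "b"), n_perm = 0), "symmetric")
  res <- amova(aln, rep(c("g1", "g2", "g3"), each = 4),
               spec = distance_spec("identity"), n_perm = 49, seed = 5,
               pairwise = TRUE)
  expect_true(isSymmetric(res$pairwise_statistic))
  expect_equal(diag(res$pairwise_statistic), setNames(rep(0, 3), res$groups))
  expect_equal(res$pairwise_statistic["g1", "g2"], 1)
  expect_true(all(res$pairwise_p > 0 & res$pairwise_p <= 1, na.rm = TRUE))
})

test_that("diploid multilocus F_ST behaves at the fixation and panmixia limits", {
  # two demes fixed for different alleles at one locus
  g <- data.frame(sample_id = paste0("i", 1:8),
                  locus = "L1",
                  allele1 = rep(c("a", "b"), each = 4),
                  allele2 = rep(c("a", "b"), each = 4))
  class(g) <- c("genotype_table", "data.frame")
  res <- diploid_fst(g, rep(c("d1", "d2"), each = 4), n_perm = 49, seed = 2)
  expect_equal(res$statistic, 1)

  # identical allele frequencies in both demes: estimate <= 0, unclamped
  g2 <- data.frame(sample_id = paste0("i", 1:8), locus = "L1",
                   allele1 = rep(c("a", "b"), 4),
                   allele2 = rep(c("b", "a"), 4))
  class(g2) <- c("genotype_table", "data.frame")
  res2 <- diploid_fst(g2, rep(c("d1", "d2"), each = 4), n_perm = 0)
  expect_lte(res2$statistic, 0)

  # monomorphic data is an error
  g3 <- g
  g3$allele1 <- "a"; g3$allele2 <- "a"
  expect_error(diploid_fst(g3, rep(c("d1", "d2"), each = 4), n_perm = 0),
               "monomorphic")
})

test_that("diploid F_ST equals haploid identity AMOVA on the allele vectors", {
  # dual route: each allele treated as a haploid sample with the group label
  set.seed(3)
  for (i in 1:5) {
    n <- 12
    alleles <- sample(c("AAAA", "CCCC", "GGGG"), 2 * n, replace = TRUE)
    groups <- rep(c("d1", "d2"), each = n / 2)
    g <- data.frame(sample_id = paste0("i", 1:n), locus = "L1",
                    allele1 = alleles[1:n], allele2 = alleles[(n + 1):(2 * n)])
    class(g) <- c("genotype_table", "data.frame")
    if (length(unique(alleles)) < 2) next
    res <- diploid_fst(g, groups, n_perm = 0)
    aln <- seq_alignment(alleles, paste0("h", 1:(2 * n)))
    res2 <- amova(aln, rep(groups, 2), spec = distance_spec("identity"),
                  n_perm = 0)
    expect_equal(res$statistic, res2$statistic, tolerance = 1e-12)
  }
})
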