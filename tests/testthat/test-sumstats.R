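test_that("summary vector has the documented fixed layout", {
  expect_length(summary_stat_names(), 39)
  set.seed(51)
  d <- simulate_dataset(1, design = c(A = 3L, C = 3L, S = 3L), seed = 51)
  sv <- summary_vector(d$alignment, d$partition)
  expect_length(sv, 39)
  expect_equal(names(sv), summary_stat_names())
})

test_that("monomorphic input zeroes diversity and flags Tajima's D", {
  aln <- seq_alignment(rep("ACGTACGT", 6), paste0("s", 1:6))
  sv <- summary_vector(aln, rep(c("A", "C", "S"), each = 2))
  expect_equal(unname(sv[c("A_k", "C_k", "S_k")]), c(1, 1, 1))
  expect_equal(unname(sv[c("A_S", "A_mean_pd", "A_tajD", "AC_hudson_fst")]),
               c(0, 0, 0, 0))
  expect_true(all(attr(sv, "d_flags")))
  expect_error(summary_vector(aln, c("A", "A", "A", "C", "C", "S")),
               "at least 2")
})

test_that("a hand-enumerable toy matches manual counting", {
  # 2 sequences per region, 8 sites; site index:  12345678
  aln <- seq_alignment(c(A1 = "AAAAAAAA",
                         A2 = "AAAAAAAT",   # site 8 segregates in A
                         C1 = "CCAAAAAA",   # sites 1-2 fixed C in region C
                         C2 = "CCAAGAAA",   # site 5 segregates in C
                         S1 = "CCAATTAA",   # sites 5-6: T fixed in S
                         S2 = "CCAATTAA"))
  sv <- summary_vector(aln, c("A", "A", "C", "C", "S", "S"))
  expect_equal(unname(sv[c("A_k", "A_S", "A_mean_pd", "A_privS")]),
               c(2, 1, 1, 1))       # site 8 is monomorphic A elsewhere
  expect_equal(unname(sv[c("C_k", "C_S", "C_mean_pd")]), c(2, 1, 1))
  # C's segregating site 5 shows A/G; the union of A and S carries A and T,
  # so it is polymorphic in the complement: not private
  expect_equal(unname(sv[["C_privS"]]), 0)
  expect_equal(unname(sv[c("S_k", "S_S", "S_mean_pd")]), c(1, 0, 0))
  # pooled A+C: sites 1, 2 (A/C), 5 (A/G), 8 (A/T) segregate; 4 haplotypes
  expect_equal(unname(sv[c("AC_k", "AC_S")]), c(4, 4))
  # between A and C: pairs (A1,C1)=2 (A1,C2)=3 (A2,C1)=3 (A2,C2)=4 -> mean 3
  expect_equal(unname(sv[["AC_between_pd"]]), 3)
  expect_equal(unname(sv[["AC_within_pd"]]), 1)     # mean of 1 and 1
  expect_equal(unname(sv[["AC_hudson_fst"]]), 1 - 1 / 3)
  # S is monomorphic: within-pair mean = mean(1, 0) = 0.5;
  # C vs S pairs each differ at sites 5 and 6 -> between mean 2
  expect_equal(unname(sv[["CS_between_pd"]]), 2)
  expect_equal(unname(sv[["CS_hudson_fst"]]), 1 - 0.5 / 2)
  # all regions have n = 2, where the Tajima normalization degenerates, so
  # every D is sentinel-replaced
  expect_equal(attr(sv, "d_flags"), c(A = TRUE, C = TRUE, S = TRUE))
})

test_that("fast path equals the brute-force definition on random alignments", {
  set.seed(52)
  for (rep in 1:10) {
    n_r <- sample(2:5, 3, replace = TRUE)
    regions <- rep(c("A", "C", "S"), n_r)
    aln <- random_toy_alignment(n = sum(n_r), L = 20, n_var = 6)
    sv <- summary_vector(aln, regions)
    expect_equal(as.numeric(sv), oracle_summary_vector(aln, regions),
                 tolerance = 1e-12)
  }
})
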