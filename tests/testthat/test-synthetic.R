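test_that("the sampling-design preset reproduces the published counts", {
  d <- table1_design()
  expect_equal(nrow(d), 22)                       # 22 breeding sites
  expect_equal(length(unique(d$location_code)), 11)
  expect_equal(sum(d$n_mtdna), 202)
  expect_equal(sum(d$n_nuclear), 194)
  reg <- tapply(d$n_mtdna, d$region, sum)
  expect_equal(unname(reg[c("A", "C", "S")]), c(18L, 87L, 97L),
               ignore_attr = TRUE)
  # every site has usable coordinates
  expect_true(all(abs(d$lat) <= 90 & abs(d$lon) <= 180))
  expect_false(anyDuplicated(d$site_code) > 0)
})

test_that("generated study bundles are complete, deterministic and readable", {
  dir1 <- file.path(tempdir(), "bundle1")
  dir2 <- file.path(tempdir(), "bundle2")
  b1 <- generate_study(scenario_id = 1, seed = 71, dir = dir1)
  b2 <- generate_study(scenario_id = 1, seed = 71, dir = dir2)

  expect_equal(n_samples(b1$alignment), 202)
  expect_equal(nrow(b1$partition), 202)
  expect_equal(length(unique(b1$genotypes$sample_id)), 194)
  expect_equal(sort(unique(b1$genotypes$locus)),
               sort(c(paste0("msat", 1:4), paste0("intron", 1:2))))

  # determinism: byte-identical bundles from the same seed
  for (f in c("study.fasta", "popmap.tsv", "genotypes.tsv", "coords.tsv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))

  # round trip through the observed-data readers
  aln <- read_alignment(file.path(dir1, "study.fasta"))
  expect_identical(aln$seqs, b1$alignment$seqs)
  pm <- read_popmap(file.path(dir1, "popmap.tsv"))
  expect_equal(pm$sample_id, b1$partition$sample_id)
  expect_equal(length(unique(pm$location)), 11)
  gt <- read_genotypes(file.path(dir1, "genotypes.tsv"))
  expect_equal(nrow(gt), nrow(b1$genotypes))
  cd <- read_coords(file.path(dir1, "coords.tsv"))
  expect_equal(nrow(cd), 22)

  # microsatellite alleles are integer repeat counts in a sane band
  ms <- gt[grepl("^msat", gt$locus), ]
  vals <- suppressWarnings(as.integer(c(ms$allele1, ms$allele2)))
  expect_false(anyNA(vals))
  expect_true(all(vals >= 8 & vals <= 40))   # bounded repeat range
})

test_that("stepping-stone and island fixtures have the expected gene-flow geometry", {
  # strong migration in the island model: F_ST collapses toward 0
  set.seed(72)
  pan <- stepping_stone_fixture(n_demes = 6, N_per_deme = 200, m = 0.5,
                                topology = "island", n_loci = 10,
                                n_generations = 100, sample_size = 15)
  fst <- diploid_fst(pan$genotypes, pan$partition, n_perm = 0)
  expect_lt(abs(fst$statistic), 0.05)

  # linear topology: pairwise F_ST grows with deme separation (rank corr > 0)
  lin <- stepping_stone_fixture(n_demes = 8, N_per_deme = 200, m = 0.05,
                                topology = "linear", n_loci = 20,
                                n_generations = 400, sample_size = 15,
                                seed = 73)
  pw <- diploid_fst(lin$genotypes, lin$partition, n_perm = 0, pairwise = TRUE)
  ut <- upper.tri(pw$pairwise_statistic)
  expect_gt(cor(pw$pairwise_statistic[ut], lin$dist_km[ut],
                method = "spearman"), 0)
  expect_error(stepping_stone_fixture(n_demes = 3), "4 demes")
  expect_error(stepping_stone_fixture(m = 0.7), "0 < m")
})
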