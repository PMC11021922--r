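# region labels carried by each internal node's descendant tips
tip_regions_below <- function(gen) {
  below <- vector("list", 2 * gen$n_tips - 1)
  for (i in seq_len(gen$n_tips)) below[[i]] <- gen$tip_region[i]
  ord <- order(gen$node_time[gen$edge[, 1]])   # shallow parents first
  for (e in ord) {
    p <- gen$edge[e, 1]; ch <- gen$edge[e, 2]
    below[[p]] <- union(below[[p]], below[[ch]])
  }
  below
}

test_that("simulated genealogies satisfy structural invariants", {
  set.seed(41)
  pr <- prior_set()
  for (rep in 1:12) {
    sid <- sample(1:3, 1)
    scen <- build_scenario(sid)
    params <- sample_parameters(scen, pr)
    des <- c(A = sample(2:5, 1), C = sample(2:5, 1), S = sample(2:5, 1))
    gen <- simulate_genealogy(scen, params, des)
    n <- sum(des)
    expect_equal(gen$n_tips, n)
    expect_equal(nrow(gen$edge), 2 * n - 2)        # 2n-1 nodes, root has no edge
    expect_true(all(gen$edge.length >= 0))
    expect_equal(gen$node_time[seq_len(n)], rep(0, n))   # tips at present
    # every non-root node has exactly one parent; root has none
    kids <- tabulate(gen$edge[, 2], nbins = 2 * n - 1)
    expect_equal(kids[seq_len(2 * n - 2)], rep(1L, 2 * n - 2))
    expect_equal(kids[2 * n - 1], 0L)
    # parent strictly older than child
    expect_true(all(gen$node_time[gen$edge[, 1]] >
                      gen$node_time[gen$edge[, 2]] - 1e-9))
    # ape conversion is a valid rooted binary tree
    tr <- as_phylo(gen)
    expect_s3_class(tr, "phylo")
    expect_true(ape::is.rooted(tr) && ape::is.binary(tr))
  }
})

test_that("pair coalescence time averages N generations in one population", {
  set.seed(42)
  scen <- build_scenario(1)
  params <- c(N_A = 1000, N_C = 1000, N_S = 1000, N_ANC = 1000,
              t1 = 0, t2 = 0)   # immediate merges: one panmictic pool
  tm <- replicate(4000, simulate_genealogy(scen, params, c(S = 2L))$tmrca)
  se <- sd(tm) / sqrt(length(tm))
  expect_equal(mean(tm), 1000, tolerance = 4 * se / 1000)
})

test_that("deep-split structure forbids early cross-region coalescence", {
  set.seed(43)
  scen <- build_scenario(1)
  params <- c(N_A = 1000, N_C = 1000, N_S = 1000, N_ANC = 1000,
              t1 = 100, t2 = 100000)
  for (rep in 1:10) {
    gen <- simulate_genealogy(scen, params, c(A = 4, C = 4, S = 4))
    below <- tip_regions_below(gen)
    internal <- (gen$n_tips + 1):(2 * gen$n_tips - 1)
    mixedA <- vapply(internal, function(i)
      "A" %in% below[[i]] && length(below[[i]]) > 1, TRUE)
    expect_true(all(gen$node_time[internal][mixedA] >= params[["t2"]]))
  }
})

test_that("admixture relocates central lineages with probability ra", {
  # all 40 sampled lineages sit in C; with ra near 1 they almost surely all
  # relocate to A at t1 and coalesce in tiny A long before the huge t2,
  # whereas with ra = 0.5 at least one lineage ends in S almost surely and
  # the TMRCA is pushed to t2
  scen <- build_scenario(3)
  base <- c(N_A = 50, N_C = 1000, N_S = 1e9, N_ANC = 100, t1 = 10, t2 = 1e7)
  set.seed(44)
  frac_hi <- mean(replicate(150, {
    simulate_genealogy(scen, c(base, ra = 0.999), c(C = 40L))$tmrca < 1e6
  }))
  frac_mid <- mean(replicate(50, {
    simulate_genealogy(scen, c(base, ra = 0.5), c(C = 40L))$tmrca < 1e6
  }))
  expect_gt(frac_hi, 0.9)    # 0.999^40 = 0.96
  expect_lt(frac_mid, 0.05)  # 0.5^40 ~ 0
})

test_that("stranded lineages are reported for malformed histories", {
  scen <- build_scenario(1)
  scen$events <- scen$events[1]   # drop the final merge: A never joins
  params <- c(N_A = 100, N_C = 100, N_S = 100, N_ANC = 100, t1 = 5, t2 = 50)
  set.seed(45)
  expect_error(simulate_genealogy(scen, params, c(A = 2, C = 2, S = 2)),
               "stranded")
})

test_that("sequence evolution obeys the mutation model", {
  pair <- function(T) {
    # hand-built two-tip genealogy with fixed TMRCA T
    structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                   edge.length = c(T, T), node_time = c(0, 0, T),
                   tip_label = c("x", "y"), tip_region = c("A", "A"),
                   n_tips = 2L, root = 3L, tmrca = T),
              class = "genealogy")
  }
  set.seed(46)
  # (near-)zero rate: identical sequences
  m0 <- mutation_model(mu = 1e-300)
  expect_equal(unname(refugiabc:::.pairwise_diffs(evolve_sequences(pair(1e5), m0))), 0)
  expect_error(mutation_model(mu = 0), "mu")

  # extreme kappa with equal frequencies: observed differences are transitions
  mk <- mutation_model(mu = 6.5e-7, kappa = 1e6, base_freq = rep(0.25, 4),
                       prop_invariant = 0, gamma_shape = 100)
  ts_only <- replicate(30, {
    a <- evolve_sequences(pair(20000), mk)
    s1 <- a$seqs[1, ]; s2 <- a$seqs[2, ]
    d <- which(s1 != s2)
    length(d) == 0 ||
      all((s1[d] %in% c("A", "G")) == (s2[d] %in% c("A", "G")))
  })
  expect_gt(mean(ts_only), 0.95)

  # Poisson expectation: mean pairwise differences = 2 T mu L at low density
  mh <- mutation_model(mu = 6.5e-7, prop_invariant = 0, gamma_shape = 100)
  T <- 5000
  d <- replicate(600, unname(refugiabc:::.pairwise_diffs(
    evolve_sequences(pair(T), mh))))
  expect_equal(mean(d), 2 * T * 6.5e-7 * 723, tolerance = 0.05)
})

test_that("the scenario-1 divergence signature orders Hudson F_ST pairs", {
  set.seed(47)
  scen <- build_scenario(1)
  params <- c(N_A = 5000, N_C = 5000, N_S = 5000, N_ANC = 5000,
              t1 = 600, t2 = 60000)
  mm <- mutation_model()
  fst <- replicate(25, {
    gen <- simulate_genealogy(scen, params, c(A = 8, C = 8, S = 8))
    sv <- summary_vector(evolve_sequences(gen, mm), gen$tip_region)
    c(sv[["AS_hudson_fst"]], sv[["CS_hudson_fst"]])
  })
  expect_gt(mean(fst[1, ]), mean(fst[2, ]))
})

test_that("dataset simulation is deterministic given the seed", {
  d1 <- simulate_dataset(1, design = c(A = 3L, C = 3L, S = 3L), seed = 99)
  d2 <- simulate_dataset(1, design = c(A = 3L, C = 3L, S = 3L), seed = 99)
  expect_identical(d1$alignment$seqs, d2$alignment$seqs)
  expect_identical(as.numeric(d1$params), as.numeric(d2$params))
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_alignment(d1$alignment, f1); write_alignment(d2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(table(d1$partition$region)[c("A", "C", "S")],
               table(factor(rep(c("A", "C", "S"), each = 3)))[c("A", "C", "S")],
               ignore_attr = TRUE)
})
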