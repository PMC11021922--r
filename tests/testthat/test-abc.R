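# a hand-crafted reference table with normal summary statistics, for testing
# the choice machinery without the simulation cost
fake_table <- function(n_per = 200, shift = c(0, 0, 0), sd = 1, seed = 1) {
  set.seed(seed)
  stat_names <- summary_stat_names()
  rows <- do.call(rbind, lapply(1:3, function(s) {
    m <- matrix(rnorm(n_per * 39, mean = shift[s], sd = sd), n_per, 39)
    colnames(m) <- stat_names
    data.frame(scenario = s, m, check.names = FALSE)
  }))
  for (p in refugiabc:::.PARAM_COLS) rows[[p]] <- NA_real_
  rows$dflag_A <- rows$dflag_C <- rows$dflag_S <- FALSE
  mads <- apply(as.matrix(rows[, stat_names]), 2, mad)
  mads[mads == 0] <- 1
  structure(rows, mad_scale = mads, scenarios = 1:3,
            class = c("reference_table", "data.frame"))
}

fake_target <- function(value = 0) {
  setNames(rep(value, 39), summary_stat_names())
}

test_that("reference tables are reproducible and carry the parameter layout", {
  des <- c(A = 3L, C = 3L, S = 3L)
  # tiny designs legitimately produce degenerate (constant) statistics
  t1 <- suppressWarnings(
    build_reference_table(n_per_scenario = 100L, design = des, seed = 61))
  t2 <- suppressWarnings(
    build_reference_table(n_per_scenario = 100L, design = des, seed = 61))
  expect_equal(nrow(t1), 300)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # scenario-specific parameter columns
  expect_true(all(is.na(t1$ra[t1$scenario == 1])))
  expect_true(all(!is.na(t1$ra[t1$scenario == 3])))
  expect_true(all(is.na(t1$ta[t1$scenario != 2])))
  expect_true(all(!is.na(t1$t2[t1$scenario == 1])))
  # serialization round trip
  f <- tempfile(fileext = ".csv")
  write_reference_table(t1, f)
  back <- read_reference_table(f)
  expect_equal(as.data.frame(back), as.data.frame(t1), tolerance = 1e-12)
  expect_equal(attr(back, "mad_scale"), attr(t1, "mad_scale"), tolerance = 1e-12)
  expect_equal(attr(back, "design"), attr(t1, "design"))
  expect_error(build_reference_table(n_per_scenario = 10L), ">= 100")
})

test_that("posteriors sum to one and respect separation and symmetry limits", {
  # scenario 2 coincides with the target; 1 and 3 are so far away that the
  # retained neighbourhood is pure scenario 2 and the rejection fallback fires
  tab <- fake_table(shift = c(8, 0, -8), sd = 0.3, seed = 62)
  expect_warning(mc <- model_choice(fake_target(0), tab, n_closest = 150),
                 "rejection")
  expect_equal(sum(mc$posterior), 1, tolerance = 1e-9)
  expect_gt(mc$posterior[["2"]], 0.95)

  # exchangeable scenarios: posteriors near 1/3
  tab2 <- fake_table(shift = c(0, 0, 0), sd = 1, seed = 63)
  mc2 <- model_choice(fake_target(0), tab2, n_closest = 300)
  expect_equal(mc2$method, "logistic")
  expect_equal(sum(mc2$posterior), 1, tolerance = 1e-9)
  expect_true(all(abs(mc2$posterior - 1 / 3) < 0.15))

  # a dominated-but-mixed neighbourhood: logistic and rejection agree
  tab3 <- fake_table(shift = c(0, 1.1, -1.1), sd = 1, seed = 65)
  mc3 <- model_choice(fake_target(0), tab3, n_closest = 150)
  expect_equal(mc3$method, "logistic")
  expect_gt(mc3$posterior[["1"]], 0.8)
  expect_true(all(abs(mc3$posterior - mc3$rejection) < 0.15))

  expect_error(model_choice(fake_target(0), tab, n_closest = 20),
               "at least 10 per scenario")
  expect_error(model_choice(fake_target(0), tab, n_closest = 1e6), "exceeds")
})

test_that("POD validation bookkeeping is consistent", {
  des <- c(A = 4L, C = 4L, S = 4L)
  tab <- suppressWarnings(
    build_reference_table(n_per_scenario = 150L, design = des, seed = 65))
  rep <- suppressWarnings(
    validate_model_choice(tab, n_pods_per_scenario = 10L,
                          n_closest = 45L, seed = 66))
  expect_equal(unname(rowSums(rep$confusion)), rep(10L, 3))
  expect_true(all(rep$type1 >= 0 & rep$type1 <= 1))
  expect_true(all(rep$type2 >= 0 & rep$type2 <= 1))
  expect_equal(unname(rep$type1),
               unname(1 - diag(rep$confusion) / 10))
  expect_error(validate_model_choice(tab, n_pods_per_scenario = 5L), "10 PODs")
})
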