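test_that("Mantel statistic hits its algebraic limits", {
  set.seed(21)
  A <- as.matrix(dist(matrix(runif(12), 6)))
  res <- mantel(A, A, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 0.05)
  B <- max(A) - A
  diag(B) <- 0
  expect_equal(mantel(A, B, n_perm = 99, seed = 1)$r, -1)
  expect_error(mantel(A, B[1:5, 1:5]), "dimensions")
  Z <- matrix(0, 6, 6)
  expect_error(mantel(A, Z, n_perm = 9), "zero variance")
})

test_that("Mantel r agrees with vegan and p is uniform under the null", {
  skip_if_not_installed("vegan")
  set.seed(22)
  A <- as.matrix(dist(matrix(runif(16), 8)))
  B <- as.matrix(dist(matrix(runif(16), 8)))
  r_pkg <- mantel(A, B, n_perm = 9)$r
  r_veg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 9)$statistic
  expect_equal(r_pkg, unname(r_veg), tolerance = 1e-10)

  # null uniformity: independent random matrices, many replicates
  set.seed(23)
  ps <- replicate(150, {
    A <- as.matrix(dist(matrix(runif(14), 7)))
    B <- as.matrix(dist(matrix(runif(14), 7)))
    mantel(A, B, n_perm = 99)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Slatkin linearization and B-Y threshold behave as documented", {
  expect_equal(slatkin_linearize(0), 0)
  expect_equal(slatkin_linearize(0.5), 1)
  expect_equal(slatkin_linearize(0.39), 0.39 / 0.61)
  expect_equal(round(slatkin_linearize(0.39), 4), 0.6393)
  expect_equal(slatkin_linearize(-0.2), 0)   # clamped before transform
  expect_error(slatkin_linearize(1), "f = 1")
  x <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(slatkin_linearize(x)) > 0))

  expect_equal(by_adjust(0.05, 1), 0.05)
  expect_equal(by_adjust(0.05, 3), 0.05 / (1 + 1/2 + 1/3))
  expect_equal(round(by_adjust(0.05, 3), 5), 0.02727)
  ms <- vapply(1:20, function(m) by_adjust(0.05, m), 0)
  expect_true(all(diff(ms) < 0))
  expect_error(by_adjust(0.05, 0), "m")
})

test_that("great-circle distances and midpoints are geometrically sound", {
  expect_equal(great_circle_km(45, -120, 45, -120), 0)
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  expect_equal(great_circle_km(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  expect_equal(round(great_circle_km(0, 0, 0, 1), 2), 111.19)

  mid <- refugiabc:::.geo_midpoint(c(10, -10), c(30, 30))
  expect_equal(unname(mid["lat"]), 0, tolerance = 1e-10)
  expect_equal(unname(mid["lon"]), 30, tolerance = 1e-10)

  part <- pop_partition(paste0("s", 1:4), c("A1", "A2", "B1", "B2"),
                        c("locA", "locA", "locB", "locB"), rep("R", 4))
  coords <- data.frame(site_code = c("A1", "A2", "B1", "B2"),
                       lat = c(50, 52, 40, 40), lon = c(-170, -170, -120, -122))
  D <- geo_distance_matrix(coords, part)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), setNames(c(0, 0), rownames(D)))
  expect_gt(D["locA", "locB"], 3000)
  coords2 <- coords[-1, ]
  expect_error(geo_distance_matrix(coords2, part), "missing coordinates")
})
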