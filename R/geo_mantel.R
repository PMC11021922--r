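#' Slatkin's linearized fixation index
#'
#' \eqn{f / (1 - f)}, approximately linear in divergence time or distance
#' under stepping-stone gene flow. Negative estimates are clamped to 0 before
#' the transform so that downstream Mantel inputs stay non-negative.
#'
#' @param f fixation index (scalar, vector or matrix), `f < 1`.
#' @return transformed values, same shape as `f`.
#' @export
slatkin_linearize <- function(f) {
  if (any(f >= 1, na.rm = TRUE)) stop("linearization undefined at f = 1")
  f <- pmax(f, 0)
  out <- f / (1 - f)
  if (is.matrix(f)) diag(out) <- 0
  out
}

#' Benjamini-Yekutieli adjusted significance threshold
#'
#' Threshold form of the B-Y correction for m dependent tests:
#' \eqn{\alpha / \sum_{i=1}^m 1/i}.
#'
#' @param alpha nominal level.
#' @param m family size (number of pairwise tests).
#' @return adjusted threshold.
#' @export
by_adjust <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / sum(1 / seq_len(m))
}

## ---- geography ----------------------------------------------------------

.EARTH_RADIUS_KM <- 6371

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (vectorized).
#' @param radius sphere radius in km.
#' @return distance in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2, radius = .EARTH_RADIUS_KM) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

# spherical midpoint of a set of points: 3-D centroid projected back
.geo_midpoint <- function(lat, lon) {
  r <- pi / 180
  x <- mean(cos(lat * r) * cos(lon * r))
  y <- mean(cos(lat * r) * sin(lon * r))
  z <- mean(sin(lat * r))
  c(lat = atan2(z, sqrt(x^2 + y^2)) / r, lon = atan2(y, x) / r)
}

#' Great-circle distances between location midpoints
#'
#' Sites are pooled by location; each location is represented by the
#' spherical midpoint of its sites, and pairwise great-circle distances are
#' returned in km.
#'
#' @param coords data.frame with `site_code`, `lat`, `lon` (see
#'   [read_coords()]).
#' @param partition a [pop_partition()] providing the site-to-location map, or
#'   a data.frame with columns `site` and `location`.
#' @return symmetric zero-diagonal matrix (km), locations as dimnames.
#' @export
geo_distance_matrix <- function(coords, partition) {
  map <- unique(data.frame(site = partition$site, location = partition$location))
  i <- match(map$site, coords$site_code)
  if (anyNA(i)) stop("missing coordinates for sites: ",
                     paste(map$site[is.na(i)], collapse = ", "))
  map$lat <- coords$lat[i]
  map$lon <- coords$lon[i]
  mids <- do.call(rbind, lapply(split(map, map$location),
                                function(d) .geo_midpoint(d$lat, d$lon)))
  locs <- rownames(mids)
  n <- length(locs)
  D <- matrix(0, n, n, dimnames = list(locs, locs))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    D[a, b] <- D[b, a] <- great_circle_km(mids[a, 1], mids[a, 2],
                                          mids[b, 1], mids[b, 2])
  }
  D
}

## ---- Mantel test --------------------------------------------------------

#' Mantel matrix-correlation permutation test
#'
#' Pearson correlation between the off-diagonal upper triangles of two
#' distance matrices, with significance from simultaneous row/column
#' permutation of the second matrix; \eqn{p = (b+1)/(B+1)}.
#'
#' @param A,B square symmetric matrices with zero diagonals, same dimension
#'   (n >= 4 recommended).
#' @param n_perm number of permutations (study convention: 10000).
#' @param seed optional RNG seed.
#' @param alternative `"greater"` (default; positive association, the
#'   isolation-by-distance direction), `"less"`, or `"two.sided"`.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `alternative`.
#' @export
mantel <- function(A, B, n_perm = 10000L, seed = NULL,
                   alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("matrix dimensions differ")
  if (any(diag(A) != 0) || any(diag(B) != 0)) stop("diagonals must be zero")
  if (!isSymmetric(unname(A)) || !isSymmetric(unname(B)))
    stop("matrices must be symmetric")
  ut <- upper.tri(A)
  a <- A[ut]
  if (stats::sd(a) == 0 || stats::sd(B[ut]) == 0)
    stop("zero variance in a distance matrix")
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(a, B[ut])
  n <- nrow(A)
  b <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- stats::cor(a, B[p, p][ut])
    hit <- switch(alternative,
                  greater = rp >= r_obs,
                  less = rp <= r_obs,
                  two.sided = abs(rp) >= abs(r_obs))
    if (hit) b <- b + 1L
  }
  structure(list(r = r_obs, p = (b + 1) / (n_perm + 1), n_perm = n_perm,
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$alternative, x$n_perm))
  invisible(x)
}
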