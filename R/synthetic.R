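## Synthetic study-shaped data: the published sampling design, full input
## bundles generated under a chosen demographic scenario, and Wright-Fisher
## stepping-stone / island fixtures for validating the isolation-by-distance
## machinery.

#' The study sampling design (22 sites, 11 locations, 3 regions)
#'
#' Reproduces the published per-site sample counts: 202 mtDNA and 194 nuclear
#' samples across 22 breeding sites in 11 locations, grouped into the three
#' scenario-testing regions (Aleutians, Central, South; mtDNA region totals
#' 18/87/97). Site coordinates are synthetic approximations of the colony
#' positions (the study publishes none); they are adequate for great-circle
#' distances at the ~100 km accuracy the isolation-by-distance tests need,
#' and for nothing finer.
#'
#' @return data.frame of class `sampling_design` with columns `subspecies`,
#'   `location`, `location_code`, `site`, `site_code`, `n_mtdna`,
#'   `n_nuclear`, `region`, `lat`, `lon`.
#' @export
table1_design <- function() {
  d <- data.frame(
    subspecies = c(rep("kaiurka", 3), rep("adianta", 15), rep("eureka", 4)),
    location = c(rep("Andreanof Is.", 3), rep("Fox Is.", 3),
                 rep("Shumigan Is.", 2), rep("Semidi Is.", 2),
                 rep("Cook Inlet", 2), rep("Prince William Sound", 2),
                 rep("Southeast Alaska", 2), "West Vancouver I.",
                 "Strait of Georgia", "Central Oregon",
                 rep("Central California", 3)),
    location_code = c(rep("Andr", 3), rep("Fox", 3), rep("Shum", 2),
                      rep("Semi", 2), rep("Cook", 2), rep("PWS", 2),
                      rep("SEAK", 2), "WVan", "SGeo", "cOre", rep("cCal", 3)),
    site = c("Tanaklak I.", "Great Sitkin I.", "Adak I.", "Anangula I.",
             "Unalaska I.", "Aiktak I.", "Belkofski Bay", "Yukon Hr.",
             "Semidi Is.", "Flat I.", "Shuyak I.", "Kachemak Bay",
             "Jackpot I.", "Naked I.", "Midway I.", "Couverden I.",
             "Cleland I.", "Mandarte I.", "Coos Bay",
             "Point Reyes National Park", "Southeast Farallon",
             "Ano Nuevo I."),
    site_code = c("Tn", "Gs", "Ad", "Aa", "Un", "Ai", "Be", "Yu", "Se", "Fl",
                  "Sh", "Ka", "Ja", "Nk", "Mi", "Cv", "Cl", "Ma", "Co", "PR",
                  "SF", "AN"),
    n_mtdna = c(4L, 2L, 4L, 1L, 2L, 5L, 3L, 4L, 4L, 3L, 2L, 32L, 12L, 18L,
                6L, 3L, 7L, 29L, 24L, 1L, 34L, 2L),
    n_nuclear = c(3L, 1L, 5L, 1L, 2L, 4L, 3L, 4L, 5L, 5L, 3L, 30L, 12L, 17L,
                  6L, 3L, 9L, 29L, 23L, 1L, 28L, 0L),
    # synthetic approximate colony coordinates (decimal degrees)
    lat = c(51.97, 52.06, 51.85, 52.99, 53.65, 54.18, 55.09, 55.20, 56.10,
            59.33, 58.55, 59.55, 60.33, 60.65, 56.80, 58.19, 49.17, 48.63,
            43.35, 38.00, 37.70, 37.11),
    lon = c(-176.20, -176.13, -176.65, -168.95, -166.75, -164.85, -162.05,
            -160.60, -156.70, -151.99, -152.50, -151.30, -148.17, -147.43,
            -134.30, -135.05, -126.09, -123.28, -124.33, -123.02, -123.00,
            -122.34),
    stringsAsFactors = FALSE)
  region_of <- c(Andr = "A", Fox = "A", Shum = "C", Semi = "C", Cook = "C",
                 PWS = "C", SEAK = "C", WVan = "S", SGeo = "S", cOre = "S",
                 cCal = "S")
  d$region <- unname(region_of[d$location_code])
  class(d) <- c("sampling_design", "data.frame")
  d
}

# per-region mtDNA totals for a design
.design_region_sizes <- function(design) {
  s <- tapply(design$n_mtdna, design$region, sum)
  s <- s[c("A", "C", "S")]
  stats::setNames(as.integer(s), c("A", "C", "S"))
}

## ---- nuclear locus simulation on coalescent genealogies -----------------

# genealogy of 2*n_ind gene copies under the scenario, population sizes
# multiplied by ploidy_ratio (nuclear autosomal Ne ~ 4x mtDNA gene copies)
.nuclear_genealogy <- function(scen, params, n_ind_per_region, ploidy_ratio = 4) {
  params2 <- params
  for (nm in c("N_A", "N_C", "N_S", "N_ANC"))
    params2[[nm]] <- params[[nm]] * ploidy_ratio
  simulate_genealogy(scen, params2, 2L * n_ind_per_region)
}

# place Poisson(rate * branch length) mutations on each branch; returns a
# list of per-tip mutation-event id vectors
.drop_mutations <- function(gen, rate) {
  n_mut_branch <- stats::rpois(nrow(gen$edge), rate * gen$edge.length)
  mut_id <- 0L
  node_muts <- vector("list", 2L * gen$n_tips - 1L)
  node_muts[[gen$root]] <- integer(0)
  ord <- order(gen$node_time[gen$edge[, 1L]], decreasing = TRUE)
  for (e in ord) {
    par <- gen$edge[e, 1L]; ch <- gen$edge[e, 2L]
    new <- if (n_mut_branch[e] > 0L) mut_id + seq_len(n_mut_branch[e]) else integer(0)
    mut_id <- mut_id + n_mut_branch[e]
    node_muts[[ch]] <- c(node_muts[[par]], new)
  }
  node_muts[seq_len(gen$n_tips)]
}

# microsatellite single-step mutation model with a bounded repeat range
# (steps that would leave [lo, hi] are suppressed, the truncated-SMM
# convention); alleles evolve root-to-tip along the genealogy
.simulate_microsat <- function(gen, rate, base_repeat = 20L,
                               bounds = c(8L, 40L)) {
  n_mut_branch <- stats::rpois(nrow(gen$edge), rate * gen$edge.length)
  allele <- integer(2L * gen$n_tips - 1L)
  allele[gen$root] <- base_repeat
  ord <- order(gen$node_time[gen$edge[, 1L]], decreasing = TRUE)
  for (e in ord) {
    a <- allele[gen$edge[e, 1L]]
    if (n_mut_branch[e] > 0L) {
      for (s in sample(c(-1L, 1L), n_mut_branch[e], replace = TRUE)) {
        nxt <- a + s
        if (nxt >= bounds[1L] && nxt <= bounds[2L]) a <- nxt
      }
    }
    allele[gen$edge[e, 2L]] <- a
  }
  allele[seq_len(gen$n_tips)]
}

# infinite-sites intron: allele identity = the set of mutations carried
.simulate_intron <- function(gen, rate) {
  muts <- .drop_mutations(gen, rate)
  keys <- vapply(muts, function(ids) paste(sort(ids), collapse = ","), "")
  match(keys, unique(keys))   # allele ids 1..K
}

#' Generate a complete synthetic study bundle
#'
#' Simulates a full set of study-shaped inputs under one demographic
#' scenario: a 723-bp mtDNA alignment following the design's per-site mtDNA
#' counts, a population map, site coordinates, and diploid nuclear genotypes
#' (four microsatellite loci under a symmetric single-step mutation model,
#' default rate 5e-4/generation, and two introns under infinite sites) for
#' the design's nuclear samples. Every nuclear locus is simulated on its own
#' independent genealogy under the same demographic history with population
#' sizes scaled by `ploidy_ratio`. Deterministic given `seed`.
#'
#' @param scenario_id 1, 2 or 3.
#' @param design a [table1_design()]-style data.frame.
#' @param model a [mutation_model()] for the mtDNA locus.
#' @param params optional fixed scenario parameters (drawn from `priors`
#'   otherwise).
#' @param priors a [prior_set()].
#' @param microsat_rate per-generation single-step mutation rate.
#' @param intron_rate per-generation per-locus mutation rate (rate x length
#'   for an ~500 bp intron at the mtDNA per-site rate).
#' @param ploidy_ratio nuclear-to-mtDNA effective-size ratio (default 4).
#' @param seed RNG seed.
#' @param dir optional output directory; when given, writes `study.fasta`,
#'   `popmap.tsv`, `coords.tsv`, `genotypes.tsv` and `metadata.json`.
#' @return list with `alignment`, `partition`, `coords`, `genotypes`,
#'   `params`, `scenario_id`, `seed` (and `dir` when written).
#' @export
generate_study <- function(scenario_id = 1L, design = table1_design(),
                           model = mutation_model(), params = NULL,
                           priors = prior_set(), microsat_rate = 5e-4,
                           intron_rate = 6.5e-7 * 500, ploidy_ratio = 4,
                           seed = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scen <- build_scenario(scenario_id)
  if (is.null(params)) params <- sample_parameters(scen, priors)

  region_sizes <- .design_region_sizes(design)
  gen <- simulate_genealogy(scen, params, region_sizes)
  aln <- evolve_sequences(gen, model)

  # assign simulated sequences to sites, walking the design within region
  ord <- order(match(design$region, c("A", "C", "S")))
  dd <- design[ord, ]
  site_of <- unlist(mapply(rep, dd$site_code, dd$n_mtdna, SIMPLIFY = FALSE))
  loc_of <- unlist(mapply(rep, dd$location_code, dd$n_mtdna, SIMPLIFY = FALSE))
  reg_of <- unlist(mapply(rep, dd$region, dd$n_mtdna, SIMPLIFY = FALSE))
  ssp_of <- unlist(mapply(rep, dd$subspecies, dd$n_mtdna, SIMPLIFY = FALSE))
  stopifnot(all(reg_of == gen$tip_region))
  ids <- paste0(site_of, sprintf("%03d", seq_along(site_of)))
  aln$ids <- ids
  rownames(aln$seqs) <- ids
  partition <- pop_partition(ids, site_of, loc_of, reg_of, ssp_of)

  # nuclear samples: truncate/refill sites to the nuclear counts
  nuc_sizes <- tapply(dd$n_nuclear, dd$region, sum)[c("A", "C", "S")]
  nuc_sizes <- stats::setNames(as.integer(nuc_sizes), c("A", "C", "S"))
  nn <- sum(nuc_sizes)
  nuc_site <- unlist(mapply(rep, dd$site_code, dd$n_nuclear, SIMPLIFY = FALSE))
  nuc_ids <- paste0("N", nuc_site, sprintf("%03d", seq_len(nn)))

  loci <- c(paste0("msat", 1:4), paste0("intron", 1:2))
  geno <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    g <- .nuclear_genealogy(scen, params, nuc_sizes, ploidy_ratio)
    alleles <- if (grepl("^msat", loci[li])) {
      as.character(.simulate_microsat(g, microsat_rate))
    } else {
      paste0("i", .simulate_intron(g, intron_rate))
    }
    # consecutive gene-copy pairs within each region form individuals
    a1 <- alleles[seq(1L, 2L * nn, 2L)]
    a2 <- alleles[seq(2L, 2L * nn, 2L)]
    geno[[li]] <- data.frame(sample_id = nuc_ids, locus = loci[li],
                             allele1 = a1, allele2 = a2,
                             stringsAsFactors = FALSE)
  }
  genotypes <- do.call(rbind, geno)
  class(genotypes) <- c("genotype_table", "data.frame")

  coords <- data.frame(site_code = dd$site_code, lat = dd$lat, lon = dd$lon)

  out <- list(alignment = aln, partition = partition, coords = coords,
              genotypes = genotypes, params = params,
              scenario_id = scenario_id, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_alignment(aln, file.path(dir, "study.fasta"))
    write_popmap(partition, file.path(dir, "popmap.tsv"))
    utils::write.table(coords, file.path(dir, "coords.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_genotypes(genotypes, file.path(dir, "genotypes.tsv"))
    jsonlite::write_json(list(seed = seed, scenario = scenario_id,
                              params = as.list(params)),
                         file.path(dir, "metadata.json"), auto_unbox = TRUE,
                         digits = NA)
    out$dir <- dir
  }
  out
}

#' Wright-Fisher stepping-stone / island gene-flow fixture
#'
#' Forward simulation of biallelic allele frequencies in `n_demes` demes of
#' `N_per_deme` diploids each, with per-generation migration rate `m` either
#' to nearest neighbours on a line (`"linear"`, producing isolation by
#' distance) or uniformly to all other demes (`"island"`, producing none).
#' Loci start at frequency 0.5 and drift independently. At the end,
#' `sample_size` diploid individuals are sampled per deme.
#'
#' @param n_demes number of demes (>= 4).
#' @param N_per_deme diploid deme size.
#' @param m total emigration rate per generation, in (0, 0.5\].
#' @param topology `"linear"` or `"island"`.
#' @param n_loci independent biallelic loci.
#' @param n_generations forward generations.
#' @param sample_size diploids sampled per deme.
#' @param deme_spacing_km spacing used for the distance matrix.
#' @param seed RNG seed.
#' @return list with `genotypes` (a `genotype_table`), `partition` (one
#'   location per deme), `coords` (deme positions on a line, km), `dist_km`
#'   (deme distance matrix), `freqs` (final allele frequencies, demes x loci).
#' @export
stepping_stone_fixture <- function(n_demes = 10L, N_per_deme = 200L, m = 0.05,
                                   topology = c("linear", "island"),
                                   n_loci = 20L, n_generations = 500L,
                                   sample_size = 20L, deme_spacing_km = 100,
                                   seed = NULL) {
  topology <- match.arg(topology)
  if (n_demes < 4L) stop("need at least 4 demes")
  if (m <= 0 || m > 0.5) stop("need 0 < m <= 0.5")
  if (!is.null(seed)) set.seed(seed)

  # migration matrix: row = destination deme, columns = sources
  M <- matrix(0, n_demes, n_demes)
  if (topology == "linear") {
    for (i in seq_len(n_demes)) {
      nb <- intersect(c(i - 1L, i + 1L), seq_len(n_demes))
      M[i, nb] <- m / length(nb)
    }
  } else {
    M[] <- m / (n_demes - 1L)
    diag(M) <- 0
  }
  diag(M) <- 1 - rowSums(M)

  p <- matrix(0.5, n_demes, n_loci)
  for (g in seq_len(n_generations)) {
    p <- M %*% p
    p <- matrix(stats::rbinom(n_demes * n_loci, 2L * N_per_deme, p) /
                  (2 * N_per_deme), n_demes, n_loci)
  }

  demes <- sprintf("D%02d", seq_len(n_demes))
  ids <- paste0(rep(demes, each = sample_size), "_",
                rep(seq_len(sample_size), n_demes))
  rows <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    pf <- rep(p[, l], each = sample_size)
    a1 <- ifelse(stats::runif(length(ids)) < pf, "1", "2")
    a2 <- ifelse(stats::runif(length(ids)) < pf, "1", "2")
    rows[[l]] <- data.frame(sample_id = ids, locus = sprintf("L%02d", l),
                            allele1 = a1, allele2 = a2,
                            stringsAsFactors = FALSE)
  }
  genotypes <- do.call(rbind, rows)
  class(genotypes) <- c("genotype_table", "data.frame")
  partition <- pop_partition(ids, rep(demes, each = sample_size),
                             rep(demes, each = sample_size),
                             rep("R", length(ids)))
  x <- (seq_len(n_demes) - 1L) * deme_spacing_km
  D <- abs(outer(x, x, "-"))
  dimnames(D) <- list(demes, demes)
  list(genotypes = genotypes, partition = partition,
       coords = data.frame(deme = demes, x_km = x), dist_km = D,
       freqs = p, topology = topology)
}
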