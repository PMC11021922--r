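## Config-driven orchestration: the observed-data statistics pipeline and the
## ABC scenario-choice pipeline, with seeded, reproducible, metadata-stamped
## TSV outputs.

# cheap stable config fingerprint (polynomial rolling hash mod 2^31 - 1;
# stays within exact double-integer range)
.fnv1a <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.meta_line <- function(seed, config) {
  ver <- as.character(utils::packageVersion("refugiabc"))
  cfg <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  paste0("# refugiabc ", ver, " seed=", seed, " config=", .fnv1a(as.character(cfg)))
}

.write_tsv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_matrix_tsv <- function(m, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(data.frame(location = rownames(m), m, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' JSON file of options; anything omitted takes the defaults documented in
#' [run_observed()] / [run_abc()].
#'
#' @param path JSON config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.cfg <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Observed-data analysis pipeline
#'
#' Reads an alignment, population map and (optionally) site coordinates and
#' nuclear genotypes, and writes: a per-location diversity/neutrality table;
#' global and pairwise Phi_ST (K2P-gamma sequence distances) and, when
#' genotypes are present, F_ST matrices with permutation p-values and
#' Benjamini-Yekutieli significance flags (family = number of location
#' pairs); and Mantel isolation-by-distance tests of Slatkin-linearized
#' indices against log great-circle distance, including a
#' haplotype-frequency-only (identity distance) variant and a variant
#' excluding the Aleutian-region locations.
#'
#' @param config list (or path handled by [read_run_config()]) with entries
#'   `fasta`, `popmap`, optional `coords`, `genotypes`, `outdir` (default
#'   `"results"`), `seed` (default 1), `n_perm` (default 10000),
#'   `alpha` (default 0.05), `alpha_dist` (default 0.42), `neutrality_draws`
#'   (default 1e5).
#' @return invisible character vector of files written.
#' @export
run_observed <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- .cfg(config, "outdir", "results")
  seed <- .cfg(config, "seed", 1L)
  n_perm <- .cfg(config, "n_perm", 10000L)
  alpha <- .cfg(config, "alpha", 0.05)
  spec <- distance_spec("K2P-gamma", .cfg(config, "alpha_dist", 0.42))
  ndraws <- .cfg(config, "neutrality_draws", 100000L)

  aln <- read_alignment(config$fasta)
  part <- read_popmap(config$popmap)
  if (!all(aln$ids %in% part$sample_id))
    stop("popmap is missing samples present in the FASTA")
  locs <- .partition_groups(part, aln$ids, "location")
  if (length(unique(locs)) < 2L) stop("need at least 2 locations")
  meta <- .meta_line(seed, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  written <- character(0)

  ## per-location diversity and neutrality (study Table 2 layout)
  rows <- lapply(sort(unique(locs)), function(lc) {
    sub <- subset_alignment(aln, which(locs == lc))
    hap <- collapse_haplotypes(sub)
    testable <- hap$k > 1L && hap$k < hap$n
    ew <- if (testable) ewens_watterson(counts = hap$counts, n_draws = ndraws)
    ch <- if (testable) {
      chakraborty(hap$n, sum((hap$counts / hap$n)^2), k_obs = hap$k,
                  n_draws = ndraws)
    }
    data.frame(location = lc, n = hap$n, k = hap$k,
               h = round(haplotype_diversity(hap), 4),
               pi_percent = round(100 * nucleotide_diversity(sub), 4),
               F_obs = if (testable) round(ew$F_obs, 4) else NA,
               F_exp = if (testable) round(ew$F_exp, 4) else NA,
               ew_p_le = if (testable) round(ew$p_le, 4) else NA,
               ew_p_ge = if (testable) round(ew$p_ge, 4) else NA,
               chak_k_exp = if (testable) round(ch$k_exp, 2) else NA,
               chak_p = if (testable) round(ch$p_ge, 4) else NA)
  })
  f <- file.path(outdir, "diversity_neutrality.tsv")
  .write_tsv(do.call(rbind, rows), f, meta)
  written <- c(written, f)

  ## global + pairwise Phi_ST on sequence distances
  am <- amova(aln, part, level = "location", spec = spec, n_perm = n_perm,
              pairwise = TRUE)
  n_pairs <- sum(upper.tri(am$pairwise_p))
  thr <- by_adjust(alpha, n_pairs)
  glob <- data.frame(marker = "mtDNA", statistic = am$statistic_name,
                     value = round(am$statistic, 4), p = am$p_value,
                     n_perm = n_perm, by_threshold = round(thr, 5))

  gt <- NULL
  if (!is.null(config$genotypes)) {
    gt <- read_genotypes(config$genotypes)
    fst <- diploid_fst(gt, part, level = "location", n_perm = n_perm,
                       pairwise = TRUE)
    glob <- rbind(glob, data.frame(marker = "nuclear", statistic = "F_ST",
                                   value = round(fst$statistic, 4),
                                   p = fst$p_value, n_perm = n_perm,
                                   by_threshold = round(thr, 5)))
  }
  f <- file.path(outdir, "global_structure.tsv")
  .write_tsv(glob, f, meta)
  written <- c(written, f)

  # Table 4 layout: Phi_ST below the diagonal, nuclear F_ST above
  comb <- am$pairwise_statistic
  if (!is.null(gt)) comb[upper.tri(comb)] <- fst$pairwise_statistic[upper.tri(comb)]
  f <- file.path(outdir, "pairwise_matrix.tsv")
  .write_matrix_tsv(round(comb, 4), f, meta)
  pv <- am$pairwise_p
  if (!is.null(gt)) pv[upper.tri(pv)] <- fst$pairwise_p[upper.tri(pv)]
  f2 <- file.path(outdir, "pairwise_p.tsv")
  .write_matrix_tsv(pv, f2, meta)
  sig <- ifelse(pv < thr, "*", "")
  f3 <- file.path(outdir, "pairwise_significance.tsv")
  .write_matrix_tsv(sig, f3, meta)
  written <- c(written, f, f2, f3)

  ## Mantel isolation-by-distance tests
  if (!is.null(config$coords)) {
    coords <- read_coords(config$coords)
    gd <- geo_distance_matrix(coords, part)
    logd <- gd
    logd[gd > 0] <- log(gd[gd > 0])
    ord <- rownames(am$pairwise_statistic)
    logd <- logd[ord, ord]
    variants <- list(
      mtDNA_phist = slatkin_linearize(am$pairwise_statistic),
      mtDNA_haplotype_freq_fst = slatkin_linearize(
        amova(aln, part, level = "location", spec = distance_spec("identity"),
              n_perm = 0L, pairwise = TRUE)$pairwise_statistic))
    if (!is.null(gt)) variants$nuclear_fst <- slatkin_linearize(fst$pairwise_statistic)
    mrows <- lapply(names(variants), function(v) {
      mt <- mantel(variants[[v]][ord, ord], logd, n_perm = n_perm)
      data.frame(variant = v, n_locations = length(ord),
                 r = round(mt$r, 4), p = mt$p)
    })
    # variant excluding the Aleutian-region locations
    non_a <- unique(part$location[part$region != "A"])
    keep <- intersect(ord, non_a)
    if (length(keep) >= 4L) {
      mt <- mantel(variants$mtDNA_phist[keep, keep], logd[keep, keep],
                   n_perm = n_perm)
      mrows <- c(mrows, list(data.frame(variant = "mtDNA_phist_no_aleutians",
                                        n_locations = length(keep),
                                        r = round(mt$r, 4), p = mt$p)))
    }
    f <- file.path(outdir, "mantel_results.tsv")
    .write_tsv(do.call(rbind, mrows), f, meta)
    written <- c(written, f)
  }
  invisible(written)
}

#' ABC scenario-choice pipeline
#'
#' Computes the observed 39-statistic summary vector from an mtDNA bundle
#' with a 3-region partition, builds (or reloads) a reference table, runs
#' logistic-regression model choice and POD validation, and writes the
#' posteriors, validation report and a JSON metadata sidecar.
#'
#' @param config list or JSON path: `fasta`, `popmap`, `outdir` (default
#'   `"results"`), `seed` (default 1), `n_per_scenario` (default 1000),
#'   `n_closest` (optional), `n_pods_per_scenario` (default 20, 0 to skip
#'   validation), `reference_table` (optional CSV path to reuse; written
#'   there when absent), `design` (optional named region sizes; defaults to
#'   the observed region counts).
#' @return invisible list with `posterior`, `validation`, `files`.
#' @export
run_abc <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- .cfg(config, "outdir", "results")
  seed <- .cfg(config, "seed", 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- .meta_line(seed, config)

  aln <- read_alignment(config$fasta)
  part <- read_popmap(config$popmap)
  regions <- .partition_groups(part, aln$ids, "region")
  target <- summary_vector(aln, regions)

  tab_path <- .cfg(config, "reference_table",
                   file.path(outdir, "reference_table.csv"))
  if (file.exists(tab_path)) {
    tab <- read_reference_table(tab_path)
  } else {
    design <- .cfg(config, "design", {
      s <- table(regions)[c("A", "C", "S")]
      stats::setNames(as.integer(s), c("A", "C", "S"))
    })
    design <- stats::setNames(as.integer(design), names(design))
    tab <- build_reference_table(n_per_scenario = .cfg(config, "n_per_scenario", 1000L),
                                 design = design, seed = seed)
    write_reference_table(tab, tab_path)
  }
  set.seed(seed + 1L)
  mc <- model_choice(target, tab, n_closest = config$n_closest)
  post_df <- data.frame(scenario = names(mc$posterior),
                        posterior = round(unname(mc$posterior), 4),
                        rejection = round(unname(mc$rejection), 4),
                        n_closest = mc$n_closest, method = mc$method)
  files <- file.path(outdir, "scenario_posteriors.tsv")
  .write_tsv(post_df, files, meta)

  val <- NULL
  n_pods <- .cfg(config, "n_pods_per_scenario", 20L)
  if (n_pods >= 10L) {
    val <- validate_model_choice(tab, n_pods_per_scenario = n_pods,
                                 n_closest = config$n_closest,
                                 seed = seed + 2L)
    vd <- data.frame(scenario = rownames(val$confusion), val$confusion,
                     type1 = round(val$type1, 3), type2 = round(val$type2, 3),
                     check.names = FALSE)
    f <- file.path(outdir, "abc_validation.tsv")
    .write_tsv(vd, f, meta)
    files <- c(files, f)
  }
  jsonlite::write_json(list(seed = seed, n_rows = nrow(tab),
                            reference_table = tab_path,
                            posterior = as.list(mc$posterior),
                            method = mc$method),
                       file.path(outdir, "abc_run.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(posterior = mc$posterior, validation = val, files = files))
}
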