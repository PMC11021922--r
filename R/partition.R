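#' Nested population partition
#'
#' Per-sample labels assigning each sample to a breeding site, a sampling
#' location (archipelago/inlet/bay), a region and a subspecies. The three
#' levels drive AMOVA grouping (by location, typically) and the pooling of
#' locations into the three regions used for scenario testing.
#'
#' @param sample_id,site,location,region,subspecies character vectors of equal
#'   length (subspecies optional).
#' @return a data.frame of class `pop_partition`.
#' @export
pop_partition <- function(sample_id, site, location, region,
                          subspecies = NA_character_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   site = as.character(site),
                   location = as.character(location),
                   region = as.character(region),
                   subspecies = as.character(subspecies),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in partition")
  # a site must sit inside exactly one location, a location in one region
  for (pair in list(c("site", "location"), c("location", "region"))) {
    tab <- unique(df[, pair])
    if (anyDuplicated(tab[[1L]]))
      stop("each ", pair[1L], " must belong to exactly one ", pair[2L])
  }
  class(df) <- c("pop_partition", "data.frame")
  df
}

#' @export
print.pop_partition <- function(x, ...) {
  cat("pop_partition:", nrow(x), "samples,",
      length(unique(x$site)), "sites,",
      length(unique(x$location)), "locations,",
      length(unique(x$region)), "regions\n")
  invisible(x)
}

# group labels for a set of sample ids at a given level, order-checked
.partition_groups <- function(partition, sample_ids, level = "location") {
  stopifnot(level %in% c("site", "location", "region", "subspecies"))
  i <- match(sample_ids, partition$sample_id)
  if (anyNA(i)) stop("samples missing from partition: ",
                     paste(utils::head(sample_ids[is.na(i)], 5), collapse = ", "))
  partition[[level]][i]
}

#' Read / write the sample population map
#'
#' TSV with columns `sample_id`, `site_code`, `location_code`, `region`,
#' `subspecies`.
#'
#' @param path TSV file.
#' @return [pop_partition()] for the reader; `path` invisibly for the writer.
#' @export
read_popmap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "site_code", "location_code", "region")
  if (!all(need %in% names(df)))
    stop("popmap must have columns ", paste(need, collapse = ", "))
  pop_partition(df$sample_id, df$site_code, df$location_code, df$region,
                if ("subspecies" %in% names(df)) df$subspecies else NA_character_)
}

#' @param partition a [pop_partition()].
#' @rdname read_popmap
#' @export
write_popmap <- function(partition, path) {
  out <- data.frame(sample_id = partition$sample_id,
                    site_code = partition$site,
                    location_code = partition$location,
                    region = partition$region,
                    subspecies = partition$subspecies)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read site coordinates
#'
#' TSV with columns `site_code`, `lat`, `lon` (decimal degrees).
#' @param path TSV file.
#' @return data.frame with validated coordinates.
#' @export
read_coords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("site_code", "lat", "lon") %in% names(df)))
    stop("coords must have columns site_code, lat, lon")
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180) || anyNA(df$lat) || anyNA(df$lon))
    stop("invalid coordinates")
  df
}

#' Read a diploid genotype table
#'
#' Long-format TSV with columns `sample_id`, `locus`, `allele1`, `allele2`;
#' missing alleles coded `.`. Microsatellite alleles are repeat lengths
#' (integers); intron alleles are arbitrary allele identifiers.
#'
#' @param path TSV file.
#' @return data.frame of class `genotype_table` with character alleles and
#'   `NA` for missing.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  need <- c("sample_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) stop("genotypes must have columns ",
                                      paste(need, collapse = ", "))
  df$allele1[df$allele1 == "."] <- NA
  df$allele2[df$allele2 == "."] <- NA
  # a sample-locus record is either fully typed or fully missing
  half <- xor(is.na(df$allele1), is.na(df$allele2))
  if (any(half)) stop("half-missing genotypes at ", sum(half), " records")
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' @param genotypes a `genotype_table` data.frame.
#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path) {
  out <- as.data.frame(genotypes)
  out$allele1[is.na(out$allele1)] <- "."
  out$allele2[is.na(out$allele2)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
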