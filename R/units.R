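#' Unit conversions between divergence rates, generations and years
#'
#' A per-lineage sequence divergence rate quoted in percent per million years
#' converts to a per-site per-generation mutation rate as
#' `percent/100 / 1e6 * generation_years` (e.g. 7.4%/my at a generation time
#' of 8.8 years gives 6.5e-7).
#'
#' @param percent_per_my per-lineage divergence rate, %/million years.
#' @param generation_years mean generation time in years.
#' @return mutation rate per site per generation.
#' @export
mutation_rate_per_generation <- function(percent_per_my, generation_years) {
  percent_per_my / 100 / 1e6 * generation_years
}

#' @param generations number of generations.
#' @return elapsed time in years.
#' @rdname mutation_rate_per_generation
#' @export
generations_to_years <- function(generations, generation_years) {
  generations * generation_years
}
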