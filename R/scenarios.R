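## Demographic scenarios for the three-refugium hypothesis test.
##
## Three sampled populations: A (Aleutians), C (Central), S (South).
## Backward in time:
##   scenario 1 - C merges into S at t1 (post-glacial split of C from S),
##                then S merges with A into ANC at t2 (pre-glacial split);
##   scenario 2 - single southern refugium with stepwise northward
##                colonization: A merges into C at ta, C into S at tb
##                (ta <= tb), and S takes the ancestral size at tc;
##   scenario 3 - two refugia with secondary contact: C is an admixture of A
##                and S formed at t1 (each C lineage relocates to A with
##                probability ra, else to S), then A and S merge into ANC
##                at t2.

#' Uniform prior bounds for scenario parameters
#'
#' Defaults follow the study setup: effective sizes uniform on 10 to 100,000
#' gene copies for every population including the ancestor; deep (pre-glacial)
#' times t2 and tc uniform on 1,250 to 100,000 generations ago; shallow
#' (post-glacial) times t1, ta, tb uniform on 0 to 1,250 generations; the
#' admixture rate ra uniform on 0.001 to 0.999. The mean generation time used
#' to convert generations to years is 8.8 years.
#'
#' @param ne_bounds,deep_bounds,shallow_bounds,ra_bounds length-2 numeric
#'   bounds (min, max).
#' @param generation_years generation time in years.
#' @return list of class `prior_set`.
#' @export
prior_set <- function(ne_bounds = c(10, 100000),
                      deep_bounds = c(1250, 100000),
                      shallow_bounds = c(0, 1250),
                      ra_bounds = c(0.001, 0.999),
                      generation_years = 8.8) {
  stopifnot(ne_bounds[1] > 0, deep_bounds[1] >= shallow_bounds[2],
            ra_bounds[1] > 0, ra_bounds[2] < 1)
  structure(list(ne = ne_bounds, deep = deep_bounds, shallow = shallow_bounds,
                 ra = ra_bounds, generation_years = generation_years),
            class = "prior_set")
}

#' Build one of the three refugial demographic scenarios
#'
#' Returns the backward-time event list over populations `A`, `C`, `S`,
#' `ANC`. Event times and sizes are symbolic (names of entries in a
#' parameter draw from [sample_parameters()]).
#'
#' @param id scenario id, 1, 2 or 3.
#' @return list of class `demographic_scenario` with elements `id`,
#'   `populations` (sampled at present), `events` (list of events with fields
#'   `time` (parameter name), `kind` (`"merge"`, `"admix"`, `"resize"`) and
#'   kind-specific fields), and `param_names`.
#' @export
build_scenario <- function(id) {
  if (!id %in% 1:3) stop("unknown scenario id: ", id)
  base_sizes <- c(A = "N_A", C = "N_C", S = "N_S")
  ev <- switch(as.character(id),
    "1" = list(
      list(time = "t1", kind = "merge", from = "C", to = "S"),
      list(time = "t2", kind = "merge", from = "A", to = "S",
           resize_to = "N_ANC")),
    "2" = list(
      list(time = "ta", kind = "merge", from = "A", to = "C"),
      list(time = "tb", kind = "merge", from = "C", to = "S"),
      list(time = "tc", kind = "resize", pop = "S", size = "N_ANC")),
    "3" = list(
      list(time = "t1", kind = "admix", from = "C", to1 = "A", to2 = "S",
           prob = "ra"),
      list(time = "t2", kind = "merge", from = "A", to = "S",
           resize_to = "N_ANC")))
  pn <- c("N_A", "N_C", "N_S", "N_ANC",
          switch(as.character(id),
                 "1" = c("t1", "t2"),
                 "2" = c("ta", "tb", "tc"),
                 "3" = c("t1", "t2", "ra")))
  structure(list(id = id, populations = c("A", "C", "S"),
                 sizes = base_sizes, events = ev, param_names = pn),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("demographic_scenario", x$id, "- events (backward time):\n")
  for (e in x$events) {
    desc <- switch(e$kind,
      merge = paste0("merge ", e$from, " -> ", e$to),
      admix = paste0("admix ", e$from, " -> ", e$to1, " (prob ", e$prob,
                     ") else ", e$to2),
      resize = paste0("resize ", e$pop, " -> ", e$size))
    cat("  at", e$time, ":", desc, "\n")
  }
  invisible(x)
}

#' Draw scenario parameters from the priors
#'
#' Independent uniform draws within the prior bounds. Scenario 2's stepwise
#' colonization constraint `ta <= tb` is enforced by resampling (bounded; an
#' error is raised after 1e6 failed attempts, which cannot occur with proper
#' uniform priors).
#'
#' @param scenario a [build_scenario()] result.
#' @param priors a [prior_set()].
#' @return named numeric vector of class `scenario_parameters`.
#' @export
sample_parameters <- function(scenario, priors = prior_set()) {
  u <- function(b) stats::runif(1, b[1], b[2])
  p <- c(N_A = u(priors$ne), N_C = u(priors$ne), N_S = u(priors$ne),
         N_ANC = u(priors$ne))
  if (scenario$id == 1) {
    p <- c(p, t1 = u(priors$shallow), t2 = u(priors$deep))
  } else if (scenario$id == 2) {
    for (i in seq_len(1e6)) {
      ta <- u(priors$shallow); tb <- u(priors$shallow)
      if (ta <= tb) break
      if (i == 1e6) stop("rejection loop exhausted")
    }
    p <- c(p, ta = ta, tb = tb, tc = u(priors$deep))
  } else {
    p <- c(p, t1 = u(priors$shallow), t2 = u(priors$deep), ra = u(priors$ra))
  }
  structure(p, class = "scenario_parameters")
}
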