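## Structured-coalescent simulator.
##
## Continuous-time approximation: within a population holding k lineages of
## (haploid gene-copy) size N, the waiting time to the next coalescence is
## exponential with rate choose(k,2)/N per generation. Demographic events
## relocate lineages between populations instantaneously.

#' Simulate a genealogy under a demographic scenario
#'
#' @param scenario a [build_scenario()] result.
#' @param params a named parameter vector (see [sample_parameters()]).
#' @param samples_per_region named integer vector of sample counts per
#'   sampled population, e.g. `c(A = 18, C = 87, S = 97)`.
#' @return list of class `genealogy`: `edge` (2-column matrix, parent/child
#'   node ids: tips `1..n`, internal nodes `n+1..2n-1`, root last),
#'   `edge.length` (generations), `node_time` (age of every node,
#'   generations), `tip_label`, `tip_region`, `n_tips`.
#' @export
simulate_genealogy <- function(scenario, params, samples_per_region) {
  pops <- scenario$populations
  if (!all(names(samples_per_region) %in% pops))
    stop("samples placed in unknown population")
  if (sum(samples_per_region) < 2L) stop("need at least 2 samples")

  N <- c(vapply(scenario$sizes, function(s) params[[s]], 0), ANC = NA_real_)
  names(N) <- c(names(scenario$sizes), "ANC")

  n <- sum(samples_per_region)
  lin_id <- seq_len(n)
  lin_pop <- rep(names(samples_per_region), samples_per_region)
  tip_region <- lin_pop
  tip_label <- paste0(lin_pop, "_", unlist(lapply(samples_per_region, seq_len)))

  events <- lapply(scenario$events, function(e) {
    e$at <- params[[e$time]]
    e
  })
  events <- events[order(vapply(events, function(e) e$at, 0))]

  max_nodes <- 2L * n - 1L
  edge <- matrix(0L, max_nodes - 1L, 2L)
  elen <- numeric(max_nodes - 1L)
  node_time <- numeric(max_nodes)
  next_node <- n + 1L
  n_edges <- 0L
  t_now <- 0
  ev_i <- 1L

  coalesce_pair <- function(pop, time) {
    idx <- which(lin_pop == pop)
    pick <- sample(idx, 2L)
    parent <- next_node
    node_time[parent] <<- time
    for (ch in lin_id[pick]) {
      n_edges <<- n_edges + 1L
      edge[n_edges, ] <<- c(parent, ch)
      elen[n_edges] <<- time - node_time[ch]
    }
    lin_id[pick[1L]] <<- parent
    lin_id <<- lin_id[-pick[2L]]
    lin_pop <<- lin_pop[-pick[2L]]
    next_node <<- next_node + 1L
  }

  pop_names <- names(N)
  while (length(lin_id) > 1L) {
    counts <- tabulate(match(lin_pop, pop_names), nbins = length(pop_names))
    active <- which(counts >= 2L)
    if (any(is.na(N[active]) | N[active] <= 0))
      stop("population ", paste(pop_names[active][is.na(N[active]) | N[active] <= 0],
                                collapse = ","), " has no size")
    rates <- counts[active] * (counts[active] - 1) / 2 / N[active]
    active <- pop_names[active]
    total <- sum(rates)
    t_next_ev <- if (ev_i <= length(events)) events[[ev_i]]$at else Inf
    dt <- if (total > 0) stats::rexp(1L, total) else Inf
    if (t_now + dt < t_next_ev) {
      t_now <- t_now + dt
      pop <- if (length(active) == 1L) active else
        sample(active, 1L, prob = rates / total)
      coalesce_pair(pop, t_now)
    } else {
      if (is.infinite(t_next_ev))
        stop("lineages stranded in populations with no outgoing event: ",
             paste(unique(lin_pop), collapse = ", "))
      e <- events[[ev_i]]
      t_now <- t_next_ev
      ev_i <- ev_i + 1L
      if (e$kind == "merge") {
        lin_pop[lin_pop == e$from] <- e$to
        if (!is.null(e$resize_to)) N[[e$to]] <- params[[e$resize_to]]
      } else if (e$kind == "admix") {
        src <- which(lin_pop == e$from)
        goes1 <- stats::runif(length(src)) < params[[e$prob]]
        lin_pop[src[goes1]] <- e$to1
        lin_pop[src[!goes1]] <- e$to2
      } else if (e$kind == "resize") {
        N[[e$pop]] <- params[[e$size]]
      } else stop("unknown event kind: ", e$kind)
    }
  }

  structure(list(edge = edge[seq_len(n_edges), , drop = FALSE],
                 edge.length = elen[seq_len(n_edges)],
                 node_time = node_time,
                 tip_label = tip_label, tip_region = tip_region,
                 n_tips = n, root = 2L * n - 1L,
                 tmrca = t_now),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy:", x$n_tips, "tips, TMRCA =", format(x$tmrca, digits = 5),
      "generations\n")
  invisible(x)
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' Branch lengths are in generations. Useful for plotting and newick export
#' via [ape::write.tree()].
#'
#' @param genealogy a [simulate_genealogy()] result.
#' @return an [ape] `phylo` object.
#' @export
as_phylo <- function(genealogy) {
  n <- genealogy$n_tips
  # ape wants the root numbered n+1; remap internal ids by reversing order
  remap <- c(seq_len(n), rev(seq.int(n + 1L, 2L * n - 1L)))
  tr <- list(edge = matrix(remap[genealogy$edge], ncol = 2L),
             edge.length = genealogy$edge.length,
             tip.label = genealogy$tip_label,
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}
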