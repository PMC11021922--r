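## DIYABC-style approximate Bayesian computation: reference table,
## rejection, and multinomial-logistic model choice with validation.

.PARAM_COLS <- c("N_A", "N_C", "N_S", "N_ANC", "t1", "t2", "ta", "tb", "tc", "ra")

#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets under each scenario with parameters
#' drawn from the priors, and records (scenario id, parameter draw, 39-value
#' summary vector, Tajima's-D sentinel flags). Column scales are robust
#' median absolute deviations used for standardization at choice time; a
#' degenerate column (MAD = 0) gets scale 1 with a warning.
#'
#' @param scenarios integer vector of scenario ids (default 1:3).
#' @param priors a [prior_set()].
#' @param n_per_scenario simulations per scenario (>= 100; the study ran 3e6,
#'   desk-scale work uses 1e3-1e4).
#' @param design named per-region sample sizes.
#' @param model a [mutation_model()].
#' @param seed RNG seed; the table is reproducible given the seed.
#' @return data.frame of class `reference_table` with columns `scenario`,
#'   parameter columns (NA where a parameter does not apply to a scenario),
#'   the 39 statistic columns, and `dflag_A/C/S`; attributes `mad_scale`,
#'   `design`, `model`, `priors`, `scenarios`, `seed`.
#' @export
build_reference_table <- function(scenarios = 1:3, priors = prior_set(),
                                  n_per_scenario = 1000L,
                                  design = c(A = 18L, C = 87L, S = 97L),
                                  model = mutation_model(), seed = NULL) {
  if (n_per_scenario < 100L) stop("n_per_scenario must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  stat_names <- summary_stat_names()
  total <- length(scenarios) * n_per_scenario
  pm <- matrix(NA_real_, total, length(.PARAM_COLS),
               dimnames = list(NULL, .PARAM_COLS))
  sm <- matrix(NA_real_, total, length(stat_names),
               dimnames = list(NULL, stat_names))
  fl <- matrix(FALSE, total, 3L, dimnames = list(NULL, c("dflag_A", "dflag_C", "dflag_S")))
  sc <- integer(total)
  row <- 0L
  for (sid in scenarios) {
    scen <- build_scenario(sid)
    for (i in seq_len(n_per_scenario)) {
      row <- row + 1L
      params <- sample_parameters(scen, priors)
      gen <- simulate_genealogy(scen, params, design)
      aln <- evolve_sequences(gen, model)
      sv <- summary_vector(aln, gen$tip_region)
      sc[row] <- sid
      pm[row, names(params)] <- as.numeric(params)
      sm[row, ] <- sv
      fl[row, ] <- attr(sv, "d_flags")
    }
  }
  tab <- data.frame(scenario = sc, pm, sm, fl, check.names = FALSE)
  mads <- apply(sm, 2L, stats::mad)
  degenerate <- !is.finite(mads) | mads == 0
  if (any(degenerate)) {
    warning("degenerate statistic columns (MAD = 0) set to scale 1: ",
            paste(stat_names[degenerate], collapse = ", "))
    mads[degenerate] <- 1
  }
  structure(tab, mad_scale = mads, design = design, model = model,
            priors = priors, scenarios = scenarios, seed = seed,
            class = c("reference_table", "data.frame"))
}

#' Write / read a reference table (CSV + JSON metadata sidecar)
#'
#' @param table a `reference_table`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return `path` (writer) or the `reference_table` (reader).
#' @export
write_reference_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(mad_scale = as.list(attr(table, "mad_scale")),
               design = as.list(attr(table, "design")),
               model = unclass(attr(table, "model"))[c("mu", "kappa", "base_freq",
                                                       "prop_invariant",
                                                       "gamma_shape", "L")],
               priors = unclass(attr(table, "priors")),
               scenarios = attr(table, "scenarios"),
               seed = attr(table, "seed"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  md <- meta$model
  model <- mutation_model(mu = md$mu, kappa = md$kappa,
                          base_freq = unlist(md$base_freq),
                          prop_invariant = md$prop_invariant,
                          gamma_shape = md$gamma_shape, L = md$L)
  priors <- prior_set(ne_bounds = meta$priors$ne, deep_bounds = meta$priors$deep,
                      shallow_bounds = meta$priors$shallow,
                      ra_bounds = meta$priors$ra,
                      generation_years = meta$priors$generation_years)
  mads <- unlist(meta$mad_scale)
  mads <- stats::setNames(as.numeric(mads), names(mads))
  structure(tab, mad_scale = mads,
            design = unlist(meta$design), model = model, priors = priors,
            scenarios = meta$scenarios, seed = meta$seed,
            class = c("reference_table", "data.frame"))
}

# ridge-penalized weighted multinomial logistic fit; returns K-vector of
# probabilities at x = 0, or NULL on numerical failure
.multinom_posterior_at_zero <- function(X, y, w, ridge = 1e-6) {
  classes <- levels(y)
  K <- length(classes)
  p <- ncol(X)
  Xi <- cbind(1, X)
  Y <- outer(as.integer(y), 2:K, function(a, b) (a == b) * 1)  # n x (K-1)
  npar <- (K - 1L) * (p + 1L)
  nll <- function(beta) {
    B <- matrix(beta, p + 1L, K - 1L)
    eta <- cbind(0, Xi %*% B)
    mx <- apply(eta, 1L, max)
    lse <- mx + log(rowSums(exp(eta - mx)))
    -sum(w * (rowSums(Y * eta[, -1L, drop = FALSE]) - lse)) +
      0.5 * ridge * sum(beta^2)
  }
  grad <- function(beta) {
    B <- matrix(beta, p + 1L, K - 1L)
    eta <- cbind(0, Xi %*% B)
    mx <- apply(eta, 1L, max)
    pr <- exp(eta - mx) / rowSums(exp(eta - mx))
    G <- t(Xi) %*% (w * (pr[, -1L, drop = FALSE] - Y))
    as.vector(G) + ridge * beta
  }
  fit <- tryCatch(
    stats::optim(rep(0, npar), nll, grad, method = "BFGS",
                 control = list(maxit = 500L)),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$par))) return(NULL)
  B <- matrix(fit$par, p + 1L, K - 1L)
  eta0 <- c(0, B[1L, ])
  pr <- exp(eta0 - max(eta0))
  stats::setNames(pr / sum(pr), classes)
}

#' ABC model choice by local logistic regression
#'
#' Statistics are standardized by the table's MAD scales; the `n_closest`
#' rows by Euclidean distance to the target are retained; a multinomial
#' logistic regression of the scenario indicator on the (statistic - target)
#' deviations, weighted by the Epanechnikov kernel
#' \eqn{w = 1 - (d/d_{max})^2}, is fit with a small ridge penalty, and the
#' posterior probabilities are the fitted class probabilities at deviation 0.
#' On numerical failure (e.g. perfect separation driving the fit unstable)
#' the rejection proportions among the retained rows are returned with a
#' warning.
#'
#' @param target a [summary_vector()] (length 39).
#' @param table a `reference_table`.
#' @param n_closest rows retained (default 1% of the table, at least
#'   10 x number of scenarios).
#' @return list of class `model_choice_result`: `posterior` (named, sums
#'   to 1), `rejection` (plain rejection proportions), `n_closest`,
#'   `d_max`, `method`.
#' @export
model_choice <- function(target, table, n_closest = NULL) {
  stat_names <- summary_stat_names()
  S <- as.matrix(table[, stat_names])
  scen_all <- sort(unique(table$scenario))
  if (length(scen_all) < 2L) stop("model choice needs >= 2 scenarios in table")
  if (is.null(n_closest))
    n_closest <- max(10L * length(scen_all), round(0.01 * nrow(S)))
  if (n_closest > nrow(S)) stop("n_closest exceeds table rows")
  if (n_closest < 10L * length(scen_all))
    stop("n_closest must be at least 10 per scenario")
  sc <- attr(table, "mad_scale")[stat_names]
  Z <- sweep(S, 2L, sc, "/")
  z0 <- as.numeric(target[stat_names]) / sc
  d <- sqrt(rowSums(sweep(Z, 2L, z0)^2))
  sel <- order(d)[seq_len(n_closest)]
  d_max <- max(d[sel])
  w <- if (d_max > 0) 1 - (d[sel] / d_max)^2 else rep(1, n_closest)
  w[w <= 0] <- min(w[w > 0], 1e-6)   # keep the boundary row in the fit
  y <- factor(table$scenario[sel], levels = scen_all)
  rej <- as.numeric(table(y)) / n_closest
  names(rej) <- scen_all
  X <- sweep(Z[sel, , drop = FALSE], 2L, z0)
  post <- if (length(unique(y)) < 2L) NULL else
    .multinom_posterior_at_zero(X, y, w)
  method <- "logistic"
  if (is.null(post)) {
    warning("logistic fit failed or degenerate; using rejection proportions")
    post <- rej
    method <- "rejection"
  }
  structure(list(posterior = post, rejection = rej, n_closest = n_closest,
                 d_max = d_max, method = method),
            class = "model_choice_result")
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat("ABC model choice (", x$method, ", n_closest = ", x$n_closest, "):\n",
      sep = "")
  for (s in names(x$posterior))
    cat(sprintf("  scenario %s: posterior %.3f (rejection %.3f)\n",
                s, x$posterior[[s]], x$rejection[[s]]))
  invisible(x)
}

#' Type I / Type II validation with pseudo-observed datasets
#'
#' Simulates `n_pods_per_scenario` fresh pseudo-observed datasets (PODs) under
#' each scenario, parameters drawn from the priors, assigns each POD to the
#' scenario with the highest posterior, and tabulates the confusion matrix.
#' Per scenario, Type I error is the fraction of its own PODs not assigned to
#' it; Type II error is the fraction of other scenarios' PODs assigned to it.
#'
#' @param table a `reference_table` (its priors/design/model attributes drive
#'   POD simulation).
#' @param n_pods_per_scenario PODs per scenario (>= 10).
#' @param n_closest passed to [model_choice()].
#' @param seed RNG seed.
#' @return list of class `validation_report`: `confusion` (rows = true
#'   scenario, columns = assigned), `type1`, `type2`, `n_pods_per_scenario`.
#' @export
validate_model_choice <- function(table, n_pods_per_scenario = 20L,
                                  n_closest = NULL, seed = NULL) {
  if (n_pods_per_scenario < 10L) stop("need at least 10 PODs per scenario")
  if (!is.null(seed)) set.seed(seed)
  scens <- attr(table, "scenarios")
  priors <- attr(table, "priors")
  design <- attr(table, "design")
  model <- attr(table, "model")
  K <- length(scens)
  conf <- matrix(0L, K, K, dimnames = list(true = scens, assigned = scens))
  for (sid in scens) {
    scen <- build_scenario(sid)
    for (i in seq_len(n_pods_per_scenario)) {
      params <- sample_parameters(scen, priors)
      gen <- simulate_genealogy(scen, params, design)
      sv <- summary_vector(evolve_sequences(gen, model), gen$tip_region)
      mc <- suppressWarnings(model_choice(sv, table, n_closest))
      pick <- names(mc$posterior)[which.max(mc$posterior)]
      conf[as.character(sid), pick] <- conf[as.character(sid), pick] + 1L
    }
  }
  type1 <- 1 - diag(conf) / rowSums(conf)
  type2 <- vapply(seq_len(K), function(j)
    sum(conf[-j, j]) / sum(conf[-j, ]), 0)
  names(type1) <- names(type2) <- scens
  structure(list(confusion = conf, type1 = type1, type2 = type2,
                 n_pods_per_scenario = n_pods_per_scenario),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("ABC model-choice validation (", x$n_pods_per_scenario,
      "PODs/scenario)\n")
  print(x$confusion)
  cat("Type I: ", paste(sprintf("%s=%.2f", names(x$type1), x$type1),
                        collapse = "  "), "\n")
  cat("Type II:", paste(sprintf("%s=%.2f", names(x$type2), x$type2),
                        collapse = "  "), "\n")
  invisible(x)
}
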