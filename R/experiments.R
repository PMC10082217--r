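#' Named fixture networks
#'
#' Small deterministic graphs with documented distance structure, used in
#' examples and tests:
#' \describe{
#'   \item{path7}{a path on 7 nodes.}
#'   \item{fig1-like}{7 nodes around one hub (`v01` of degree 4) with a
#'     3-node tail, mimicking a small message-spreading sketch.}
#'   \item{locatable10}{an asymmetric 10-node caterpillar tree whose
#'     full-observer distance signatures are pairwise non-affinely-related,
#'     so all 45 node pairs are distinguishable.}
#' }
#'
#' @param name fixture name.
#' @return an igraph network.
#' @export
make_fixture_network <- function(name) {
  path <- function(nodes) cbind(nodes[-length(nodes)], nodes[-1])
  nm <- sprintf("v%02d", 1:10)
  edges <- switch(name,
    "path7" = path(nm[1:7]),
    "fig1-like" = rbind(cbind(nm[1], nm[2:5]), path(nm[5:7])),
    "locatable10" = rbind(path(nm[1:6]),
                          c(nm[2], nm[7]), c(nm[3], nm[8]),
                          c(nm[5], nm[9]), c(nm[9], nm[10])),
    stop("unknown fixture: ", name))
  make_network(edges)
}

#' Experiment configuration
#'
#' Bundles a network specification, a dynamics specification, and the
#' randomized-design parameters of one repeated-simulation experiment.
#'
#' Seed splitting: repetition i runs under its own derived seed
#' `(seed + 48271 * i) mod (2^31 - 1)`; all randomness of that repetition
#' (network draw, source and observer draws, dynamics) flows from it, so
#' repetitions are independent and any one can be reproduced in isolation.
#'
#' Initial times: source j (1-based) starts at
#' `delta * u * (j - 1)` for diffusion and `delta * (j - 1)` for SI, so
#' `delta = 0` gives all sources a common start at time 0 and `delta > 0`
#' staggers them by the configured offset.
#'
#' @param network either an igraph network (reused across repetitions), or a
#'   list: `list(generator = "er", n, avg_degree)`,
#'   `list(generator = "ba", n, links_per_node)`,
#'   `list(generator = "fixture", name)`, or
#'   `list(generator = "edge_list", path)`.
#' @param dynamics `list(model = "diffusion", u, sigma)` or
#'   `list(model = "si", lam)`.
#' @param n_sources number of sources drawn uniformly each repetition.
#' @param delta initial-time offset multiplier between consecutive sources.
#' @param observers `list(strategy = "random", fraction = )`,
#'   `list(strategy = "random", r = )`, `list(strategy = "greedy", r = )`
#'   (first r nodes of the greedy locatability sequence), or
#'   `list(strategy = "fixed", nodes = )`.
#' @param repetitions number of repetitions (>= 1).
#' @param seed master integer seed.
#' @param regenerate_network draw a fresh generator network every repetition
#'   (default `TRUE`); ignored for fixed networks.
#' @param rewire_swaps degree-preserving swaps applied to each network draw
#'   (0 = none).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(network, dynamics, n_sources = 2, delta = 0,
                              observers = list(strategy = "random", fraction = 0.2),
                              repetitions = 50, seed = 1,
                              regenerate_network = TRUE, rewire_swaps = 0) {
  stopifnot(repetitions >= 1, n_sources >= 1, delta >= 0, rewire_swaps >= 0)
  if (!igraph::is_igraph(network)) {
    stopifnot(is.list(network), !is.null(network$generator))
    if (!network$generator %in% c("er", "ba", "fixture", "edge_list"))
      stop("unknown network generator: ", network$generator)
  }
  stopifnot(is.list(dynamics), dynamics$model %in% c("diffusion", "si"))
  if (dynamics$model == "diffusion") stopifnot(dynamics$u > 0, dynamics$sigma >= 0)
  if (dynamics$model == "si") stopifnot(dynamics$lam > 0, dynamics$lam <= 1)
  stopifnot(is.list(observers),
            observers$strategy %in% c("random", "greedy", "fixed"))
  structure(list(network = network, dynamics = dynamics,
                 n_sources = n_sources, delta = delta, observers = observers,
                 repetitions = repetitions, seed = seed,
                 regenerate_network = regenerate_network,
                 rewire_swaps = rewire_swaps),
            class = "experiment_config")
}

.build_network <- function(spec, seed) {
  if (igraph::is_igraph(spec)) return(spec)
  switch(spec$generator,
         er = generate_er(spec$n, spec$avg_degree, seed),
         ba = generate_ba(spec$n, spec$links_per_node, seed),
         fixture = make_fixture_network(spec$name),
         edge_list = read_edge_list(spec$path))
}

.n_observers <- function(obs_spec, n) {
  r <- if (!is.null(obs_spec$r)) obs_spec$r
       else if (!is.null(obs_spec$fraction)) round(obs_spec$fraction * n)
       else length(obs_spec$nodes)
  if (is.null(r) || r < 3)
    stop("observer specification yields fewer than 3 observers")
  r
}

#' Run a configured experiment
#'
#' Per repetition: build (or reuse) the network, optionally rewire it, draw
#' sources and observers, simulate the dynamics, score all nodes by f, and
#' record the AUC against the true sources. Deterministic given the config's
#' master seed.
#'
#' @param config an [experiment_config()].
#' @return a data frame with one row per repetition (`rep`, `seed`, `n`,
#'   `m`, `n_sources`, `r`, `auc`), with the config attached as attribute
#'   `config`.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  fixed_net <- NULL
  if (igraph::is_igraph(config$network) || !config$regenerate_network)
    fixed_net <- .build_network(config$network, config$seed)
  fixed_greedy <- NULL
  if (!is.null(fixed_net) && config$observers$strategy == "greedy")
    fixed_greedy <- greedy_observer_sequence(
      fixed_net,
      min(igraph::vcount(fixed_net), max(config$observers$r, 2)))$steps$observer
  rows <- vector("list", config$repetitions)
  for (i in seq_len(config$repetitions)) {
    rep_seed <- (config$seed + 48271 * i) %% 2147483647
    res <- withr::with_seed(rep_seed, {
      net <- if (!is.null(fixed_net)) fixed_net
             else .build_network(config$network, sample.int(2^31 - 2, 1))
      if (config$rewire_swaps > 0)
        net <- degree_preserving_rewire(net, config$rewire_swaps,
                                        sample.int(2^31 - 2, 1))
      nodes <- igraph::V(net)$name
      n <- length(nodes)
      sources <- sample(nodes, config$n_sources)
      u <- if (config$dynamics$model == "diffusion") config$dynamics$u else 1
      t0 <- config$delta * u * (seq_len(config$n_sources) - 1)
      obs_nodes <- switch(config$observers$strategy,
        random = sample(nodes, .n_observers(config$observers, n)),
        fixed = as.character(config$observers$nodes),
        greedy = {
          seq <- if (!is.null(fixed_greedy)) fixed_greedy
                 else greedy_observer_sequence(
                   net, min(n, max(config$observers$r, 2)))$steps$observer
          utils::head(seq, .n_observers(config$observers, n))
        })
      if (length(obs_nodes) < 3) stop("fewer than 3 observers")
      dyn_seed <- sample.int(2^31 - 2, 1)
      prop <- if (config$dynamics$model == "diffusion") {
        simulate_diffusion(net, sources, t0,
                           delay_model(config$dynamics$u, config$dynamics$sigma),
                           dyn_seed)
      } else {
        simulate_si(net, sources, t0, si_params(config$dynamics$lam), dyn_seed)
      }
      scores <- score_all_nodes(net, observe(prop, obs_nodes))
      list(n = n, m = igraph::ecount(net), r = length(obs_nodes),
           auc = roc_auc(scores, sources)$auc)
    })
    rows[[i]] <- data.frame(rep = i, seed = rep_seed, n = res$n, m = res$m,
                            n_sources = config$n_sources, r = res$r,
                            auc = res$auc)
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  out
}

# flatten a config into "# key: value" header lines
.config_header <- function(config) {
  flat <- c(
    network = if (igraph::is_igraph(config$network)) {
      paste0("igraph(n=", igraph::vcount(config$network),
             ",m=", igraph::ecount(config$network), ")")
    } else paste(names(config$network), unlist(config$network),
                 sep = "=", collapse = ","),
    dynamics = paste(names(config$dynamics), unlist(config$dynamics),
                     sep = "=", collapse = ","),
    n_sources = config$n_sources, delta = config$delta,
    observers = paste(names(config$observers),
                      vapply(config$observers, function(x)
                        paste(x, collapse = "+"), ""),
                      sep = "=", collapse = ","),
    repetitions = config$repetitions, seed = config$seed,
    regenerate_network = config$regenerate_network,
    rewire_swaps = config$rewire_swaps)
  paste0("# ", names(flat), ": ", flat)
}

#' Write experiment results to CSV
#'
#' The full configuration is echoed as `#`-prefixed header lines above the
#' per-repetition table, followed by an aggregate row (`rep = NA`) holding
#' the mean AUC.
#'
#' @param table a result table from [run_config()].
#' @param path file path.
#' @export
write_results <- function(table, path) {
  config <- attr(table, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(.config_header(config), con)
  agg <- table[1, ]
  agg[] <- NA
  agg$auc <- mean(table$auc)
  out <- rbind(table, agg)
  write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read experiment results written by [write_results()]
#'
#' @param path file path.
#' @return the per-repetition data frame (aggregate row dropped), with the
#'   header lines attached as attribute `header`.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  tab <- read.table(text = body, header = TRUE, sep = ",")
  required <- c("rep", "seed", "n", "m", "n_sources", "r", "auc")
  if (!all(required %in% names(tab)))
    stop("results file missing columns: ",
         paste(setdiff(required, names(tab)), collapse = ", "))
  tab <- tab[!is.na(tab$rep), ]
  attr(tab, "header") <- hdr
  tab
}
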