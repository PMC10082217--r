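#' Delay model for diffusion dynamics
#'
#' Each edge carries an independent propagation delay drawn from a Gaussian
#' `N(u, sigma^2)`, resampled until strictly positive (arrival times must
#' advance along a path).
#'
#' @param u mean delay, in time units; must be positive.
#' @param sigma standard deviation, non-negative.
#' @return an object of class `delay_model`.
#' @export
delay_model <- function(u, sigma) {
  stopifnot(is.numeric(u), length(u) == 1, u > 0,
            is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  structure(list(u = u, sigma = sigma), class = "delay_model")
}

#' SI dynamics parameters
#'
#' @param lam informed rate per infected contact per time step, in \[0, 1\].
#' @return an object of class `si_params`.
#' @export
si_params <- function(lam) {
  stopifnot(is.numeric(lam), length(lam) == 1, lam >= 0, lam <= 1)
  structure(list(lam = lam), class = "si_params")
}

.propagation_result <- function(informed_time, sources, initial_times) {
  structure(list(informed_time = informed_time,
                 sources = sources,
                 initial_times = initial_times),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat("Propagation result:", length(x$informed_time), "nodes,",
      length(x$sources), "source(s)\n")
  cat("  sources:", paste0(x$sources, " (t=", x$initial_times, ")",
                           collapse = ", "), "\n")
  cat("  informed times in [", min(x$informed_time), ", ",
      max(x$informed_time), "]\n", sep = "")
  invisible(x)
}

.check_sources <- function(net, sources, initial_times) {
  nodes <- igraph::V(net)$name
  sources <- as.character(sources)
  if (length(sources) == 0) stop("at least one source is required")
  if (anyDuplicated(sources)) stop("sources must be distinct")
  if (!all(sources %in% nodes)) stop("unknown source node(s)")
  if (length(initial_times) == 1) initial_times <- rep(initial_times, length(sources))
  if (length(initial_times) != length(sources))
    stop("`initial_times` must match the number of sources")
  names(initial_times) <- sources
  list(sources = sources, initial_times = initial_times)
}

#' Sample one Gaussian delay per undirected edge
#'
#' Draws are independent `N(u, sigma^2)` variates, resampled until strictly
#' positive; one delay per undirected edge, shared by both directions.
#'
#' @param net a network.
#' @param model a [delay_model()].
#' @param seed integer seed.
#' @return a numeric vector of positive delays, one per edge of `net`, in
#'   igraph edge order.
#' @export
sample_edge_delays <- function(net, model, seed) {
  stopifnot(inherits(model, "delay_model"))
  m <- igraph::ecount(net)
  withr::with_seed(seed, {
    delays <- rnorm(m, model$u, model$sigma)
    while (any(bad <- delays <= 0))
      delays[bad] <- rnorm(sum(bad), model$u, model$sigma)
  })
  delays
}

#' Simulate diffusion dynamics (earliest arrival over random edge delays)
#'
#' A source begins spreading at its initial time; a newly informed node
#' forwards the message to all neighbors, each arriving after that edge's
#' sampled delay. The informed time of node v is therefore the minimum over
#' sources s of `initial_time(s)` plus the delay-weighted shortest-path
#' length from s to v (Dijkstra semantics; all delays are positive).
#'
#' @param net a connected network.
#' @param sources character vector of source nodes.
#' @param initial_times numeric, one per source (or a single value recycled).
#' @param model a [delay_model()].
#' @param seed integer seed controlling the delay draws.
#' @return a `propagation_result`: named informed-time vector over all nodes,
#'   plus the source set and initial times.
#' @export
simulate_diffusion <- function(net, sources, initial_times, model, seed) {
  validate_network(net)
  s <- .check_sources(net, sources, initial_times)
  delays <- sample_edge_delays(net, model, seed)
  d <- igraph::distances(net, v = s$sources, weights = delays)
  arrivals <- d + s$initial_times[rownames(d)]
  informed <- apply(arrivals, 2, min)
  # a source's informed time is its own initial time by definition, even if
  # another source's wavefront reaches it earlier
  informed[s$sources] <- s$initial_times
  .propagation_result(informed, s$sources, s$initial_times)
}

#' One-step SI infection probability
#'
#' Probability that an uninformed node with `informed_neighbor_count`
#' informed neighbors becomes informed during one synchronous step:
#' `1 - (1 - lam)^count`.
#'
#' @param params an [si_params()].
#' @param informed_neighbor_count non-negative integer (vectorized).
#' @return probability in \[0, 1\].
#' @export
infection_probability <- function(params, informed_neighbor_count) {
  stopifnot(inherits(params, "si_params"),
            all(informed_neighbor_count >= 0))
  1 - (1 - params$lam)^informed_neighbor_count
}

#' Simulate discrete-time SI dynamics
#'
#' Synchronous unit time steps. At step t each uninformed node with c
#' neighbors informed at the start of the step becomes informed with
#' probability `1 - (1 - lam)^c`; once informed, a node stays informed. A
#' source activates at its own initial time (integer), so sources with later
#' initial times stay inert until then. The simulation runs until every node
#' is informed.
#'
#' @param net a connected network.
#' @param sources character vector of source nodes.
#' @param initial_times integer initial times, one per source (or one value).
#' @param params an [si_params()] with `lam > 0`.
#' @param seed integer seed.
#' @param max_steps step cap; exceeding it is an error naming the
#'   still-uninformed nodes.
#' @return a `propagation_result` with integer informed times.
#' @export
simulate_si <- function(net, sources, initial_times, params, seed,
                        max_steps = 10000L) {
  validate_network(net)
  stopifnot(inherits(params, "si_params"))
  if (params$lam <= 0) stop("`lam` must be positive for SI simulation")
  s <- .check_sources(net, sources, initial_times)
  if (any(s$initial_times != round(s$initial_times)))
    stop("SI initial times must be integers")
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  informed_time <- rep(NA_real_, n)
  names(informed_time) <- nodes
  withr::with_seed(seed, {
    t <- min(s$initial_times)
    informed_time[names(s$initial_times)[s$initial_times == t]] <- t
    while (anyNA(informed_time)) {
      if (t - min(s$initial_times) > max_steps)
        stop("max_steps exceeded; uninformed nodes: ",
             paste(nodes[is.na(informed_time)], collapse = ", "))
      informed <- !is.na(informed_time) & informed_time <= t
      t <- t + 1L
      # sources that have not yet activated stay inert: their informed time
      # is their initial time by definition
      pending <- nodes %in% names(s$initial_times)[s$initial_times >= t]
      counts <- as.numeric(adj %*% informed)
      susceptible <- is.na(informed_time) & !pending
      p <- infection_probability(params, counts[susceptible])
      newly <- susceptible
      newly[susceptible] <- runif(sum(susceptible)) < p
      informed_time[newly] <- t
      activating <- names(s$initial_times)[s$initial_times == t]
      informed_time[activating] <- t
    }
  })
  .propagation_result(informed_time, s$sources, s$initial_times)
}

#' Write a propagation result to CSV
#'
#' Two columns (node, informed_time) preceded by `#`-prefixed header lines
#' recording the sources and initial times.
#'
#' @param result a `propagation_result`.
#' @param path file path.
#' @export
write_propagation <- function(result, path) {
  stopifnot(inherits(result, "propagation_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# sources:", paste(result$sources, collapse = ",")),
               paste("# initial_times:", paste(result$initial_times, collapse = ",")),
               "node,informed_time"), con)
  writeLines(paste(names(result$informed_time), result$informed_time, sep = ","), con)
  invisible(path)
}
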