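#' @importFrom stats cor rnorm runif sd
#' @importFrom utils read.table write.table
NULL

# Internal: canonical vertex names "v001", "v002", ... for generated graphs.
.node_names <- function(n) sprintf("v%03d", seq_len(n))

#' Validate a network object
#'
#' Networks are undirected, simple (no self-loops, no multi-edges), connected
#' [igraph][igraph::igraph] graphs with named vertices. All higher-level
#' operations in this package assume this contract.
#'
#' @param net an igraph object.
#' @param require_connected reject disconnected graphs (default `TRUE`).
#' @return `net`, invisibly, after validation.
#' @export
validate_network <- function(net, require_connected = TRUE) {
  if (!igraph::is_igraph(net)) stop("`net` must be an igraph object")
  if (igraph::is_directed(net)) stop("network must be undirected")
  if (any(igraph::which_loop(net))) stop("network must not contain self-loops")
  if (any(igraph::which_multiple(net))) stop("network must not contain multi-edges")
  if (is.null(igraph::V(net)$name)) stop("network vertices must be named")
  if (anyDuplicated(igraph::V(net)$name)) stop("vertex names must be distinct")
  if (require_connected && igraph::vcount(net) > 0 && !igraph::is_connected(net))
    stop("network must be connected")
  invisible(net)
}

#' Build a network from an edge data frame or matrix
#'
#' @param edges two-column character matrix or data frame of endpoints.
#' @param nodes optional character vector of node identifiers (to keep
#'   isolated nodes or fix ordering); defaults to the sorted endpoint set.
#' @param require_connected reject disconnected graphs (default `TRUE`).
#' @return an igraph network with named vertices.
#' @export
make_network <- function(edges, nodes = NULL, require_connected = TRUE) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("`edges` must have two columns")
  mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2]))
    stop("self-loops are not allowed: ", paste(unique(edges[edges[, 1] == edges[, 2], 1]), collapse = ", "))
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) {
    warning("duplicate or reversed edges collapsed")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  if (is.null(nodes)) nodes <- sort(unique(as.character(edges)))
  if (!all(as.character(edges) %in% nodes))
    stop("every edge endpoint must be a listed node")
  net <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                       vertices = data.frame(name = nodes))
  validate_network(net, require_connected = require_connected)
  net
}

#' Generate a connected Erdos-Renyi random network
#'
#' Each node pair is linked independently with probability
#' `avg_degree / (n - 1)`. Because sparse G(n, p) draws are frequently
#' disconnected, draws are repeated (up to `max_attempts`) until a connected
#' graph appears; all simulations assume every node is eventually informed,
#' which requires connectivity.
#'
#' @param n number of nodes.
#' @param avg_degree target mean degree; must be below `n - 1`.
#' @param seed integer seed; the result is reproducible given the seed.
#' @param max_attempts connectivity retry cap (default 100).
#' @return a connected igraph network with nodes `v001..`.
#' @export
generate_er <- function(n, avg_degree, seed, max_attempts = 100) {
  stopifnot(n >= 2, avg_degree > 0)
  if (avg_degree > n - 1) stop("`avg_degree` must not exceed n - 1")
  p <- avg_degree / (n - 1)
  withr::with_seed(seed, {
    for (i in seq_len(max_attempts)) {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g)) {
        igraph::V(g)$name <- .node_names(n)
        return(g)
      }
    }
  })
  stop("no connected ER draw in ", max_attempts,
       " attempts (n = ", n, ", <k> = ", avg_degree, "); increase avg_degree")
}

#' Generate a Barabasi-Albert scale-free network
#'
#' Preferential-attachment growth starting from a complete graph on
#' `links_per_node + 1` nodes; each subsequent node attaches `links_per_node`
#' edges to distinct existing nodes with probability proportional to their
#' current degree. The edge count is therefore deterministic:
#' `choose(links_per_node + 1, 2) + (n - links_per_node - 1) * links_per_node`,
#' giving mean degree slightly below `2 * links_per_node`. With
#' `links_per_node = 1` and `n = 3` the seed clique is a single edge and the
#' result is a 3-node tree.
#'
#' @param n number of nodes.
#' @param links_per_node edges attached by each incoming node (>= 1, < n).
#' @param seed integer seed.
#' @return a connected igraph network with nodes `v001..`.
#' @export
generate_ba <- function(n, links_per_node, seed) {
  m <- as.integer(links_per_node)
  stopifnot(n >= 2)
  if (m < 1 || m >= n) stop("`links_per_node` must be in [1, n)")
  n0 <- m + 1
  deg <- integer(n)
  el_from <- integer(0); el_to <- integer(0)
  if (n0 >= 2) {
    cl <- utils::combn(n0, 2)
    el_from <- cl[1, ]; el_to <- cl[2, ]
    deg[seq_len(n0)] <- n0 - 1L
  }
  withr::with_seed(seed, {
    for (v in seq.int(n0 + 1L, length.out = n - n0)) {
      existing <- seq_len(v - 1L)
      targets <- sample(existing, m, prob = deg[existing])
      el_from <- c(el_from, rep.int(v, m)); el_to <- c(el_to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
  })
  nm <- .node_names(n)
  make_network(cbind(nm[el_from], nm[el_to]), nodes = nm)
}

#' All-pairs hop distances
#'
#' Breadth-first shortest-path lengths in edge counts between every node
#' pair, ignoring any edge delays: the localization statistic is purely
#' topological.
#'
#' @param net a network.
#' @return a symmetric integer-valued matrix with zero diagonal, dimnames set
#'   to the node names; `Inf` marks unreachable pairs in disconnected inputs.
#' @export
all_pairs_hop_distance <- function(net) {
  validate_network(net, require_connected = FALSE)
  igraph::distances(net, algorithm = "unweighted")
}

#' Average degree 2m/n of a network
#'
#' @param net a network.
#' @return `2 * ecount / vcount`.
#' @export
average_degree <- function(net) {
  validate_network(net, require_connected = FALSE)
  if (igraph::vcount(net) == 0) stop("empty network")
  2 * igraph::ecount(net) / igraph::vcount(net)
}

#' Degree-preserving rewiring by double-edge swaps
#'
#' Repeatedly picks two edges (a, b), (c, d) uniformly at random and replaces
#' them with (a, d), (c, b). A proposed swap is rejected if it would create a
#' self-loop or a multi-edge, and rolled back if it disconnects the graph, so
#' the output has exactly the input's degree sequence and stays connected.
#'
#' @param net a connected network.
#' @param n_swaps number of accepted swaps to attempt (proposals that are
#'   rejected still count toward an internal proposal cap of `20 * n_swaps`).
#' @param seed integer seed.
#' @return the rewired network.
#' @export
degree_preserving_rewire <- function(net, n_swaps, seed) {
  validate_network(net)
  stopifnot(n_swaps >= 0)
  if (n_swaps == 0) return(net)
  g <- net
  withr::with_seed(seed, {
    accepted <- 0L
    proposals <- 0L
    max_prop <- 20L * n_swaps
    while (accepted < n_swaps && proposals < max_prop) {
      proposals <- proposals + 1L
      m <- igraph::ecount(g)
      if (m < 2) break
      eids <- sample.int(m, 2)
      ends <- igraph::ends(g, eids, names = FALSE)
      a <- ends[1, 1]; b <- ends[1, 2]; c <- ends[2, 1]; d <- ends[2, 2]
      # randomize orientation of the second edge
      if (runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      if (length(unique(c(a, b, c, d))) < 4) next
      if (igraph::are_adjacent(g, a, d) || igraph::are_adjacent(g, c, b)) next
      g2 <- igraph::delete_edges(g, eids)
      g2 <- igraph::add_edges(g2, c(a, d, c, b))
      if (!igraph::is_connected(g2)) next
      g <- g2
      accepted <- accepted + 1L
    }
  })
  g
}

#' Read a network from a plain-text edge list
#'
#' One edge per line, two whitespace- or comma-separated node identifiers;
#' lines starting with `#` are ignored. Duplicate and reversed edges are
#' collapsed with a warning; self-loops are an error.
#'
#' @param path file path.
#' @param require_connected reject disconnected graphs (default `TRUE`).
#' @return an igraph network.
#' @export
read_edge_list <- function(path, require_connected = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no edges in ", path)
  parts <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("malformed edge at line ", idx[bad[1]], ": '", lines[idx[bad[1]]], "'")
  edges <- do.call(rbind, parts)
  make_network(edges, require_connected = require_connected)
}

#' Write a network as a plain-text edge list
#'
#' @param net a network.
#' @param path file path.
#' @export
write_edge_list <- function(net, path) {
  validate_network(net, require_connected = FALSE)
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}
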