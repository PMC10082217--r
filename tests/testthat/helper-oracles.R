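# Independent oracles and small random-instance generators used across the
# test files. These deliberately avoid the code paths they check.

# Random connected graph: spanning tree plus extra random edges.
random_connected_graph <- function(n, extra = n %/% 2) {
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- cbind(nodes[sapply(2:n, function(i) sample.int(i - 1, 1))],
                 nodes[2:n])
  all_pairs <- t(combn(nodes, 2))
  key <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
               pmax(all_pairs[, 1], all_pairs[, 2]))
  used <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  avail <- which(!key %in% used)
  if (extra > 0 && length(avail) > 0) {
    pick <- sample(avail, min(extra, length(avail)))
    edges <- rbind(edges, all_pairs[pick, , drop = FALSE])
  }
  make_network(edges, nodes = nodes)
}

# All-pairs shortest hop counts by Floyd-Warshall relaxation on the
# adjacency matrix (independent of the BFS-based implementation).
floyd_warshall_hops <- function(net) {
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  el <- igraph::as_edgelist(net)
  for (r in seq_len(nrow(el))) d[el[r, 1], el[r, 2]] <- d[el[r, 2], el[r, 1]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) {
    relax <- d[i, k] + d[k, ]
    d[i, ] <- pmin(d[i, ], relax)
  }
  d
}

# Earliest arrival time at every node by brute-force enumeration of all
# simple paths from every source (feasible only for tiny graphs).
brute_force_arrivals <- function(net, sources, initial_times, delays) {
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net)
  ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  delay_of <- function(a, b) delays[match(paste(pmin(a, b), pmax(a, b)), ekey)]
  best <- rep(Inf, length(nodes)); names(best) <- nodes
  for (si in seq_along(sources)) {
    s <- sources[si]
    best[s] <- min(best[s], initial_times[si])
    for (v in setdiff(nodes, s)) {
      paths <- igraph::all_simple_paths(net, from = s, to = v)
      for (p in paths) {
        pn <- igraph::V(net)$name[p]
        tt <- initial_times[si] +
          sum(delay_of(pn[-length(pn)], pn[-1]))
        best[v] <- min(best[v], tt)
      }
    }
  }
  best
}

# Brute-force affine-relatedness: grid-free exact check by trying every
# coordinate pair as the anchor (independent of the anchored implementation).
brute_affine <- function(dv, du) {
  n <- length(du)
  if (max(du) == min(du) && max(dv) == min(dv)) return(TRUE)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (du[i] == du[j]) next
    k <- (dv[i] - dv[j]) / (du[i] - du[j])
    c0 <- dv[i] - k * du[i]
    if (k > 0 && all(abs(dv - (k * du + c0)) < 1e-9)) return(TRUE)
  }
  FALSE
}

# Mann-Whitney AUC from the rank-sum formula (oracle for roc_auc).
rank_sum_auc <- function(f, sources) {
  is_src <- names(f) %in% sources
  r <- rank(f)
  ns <- sum(is_src)
  (sum(r[is_src]) - ns * (ns + 1) / 2) / (ns * (length(f) - ns))
}

# Pairwise-comparison AUC (second independent oracle).
pairwise_auc <- function(f, sources) {
  src <- f[names(f) %in% sources]
  non <- f[!names(f) %in% sources]
  tot <- 0
  for (a in src) for (b in non)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(src) * length(non))
}
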