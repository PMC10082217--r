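#' Positive-slope affine relation between two distance vectors
#'
#' Two nodes u, v are indistinguishable by Pearson centrality exactly when
#' their observer-distance vectors satisfy `dv = k * du + c` elementwise for
#' some real k > 0 and real c: the correlation of observed times with the
#' two vectors is then identical for every time vector. Both-constant pairs
#' are affinely related (k arbitrary); a constant paired with a non-constant
#' vector is not. The check is exact up to tolerance 1e-9, which is
#' effectively exact on integer hop distances.
#'
#' @param dv,du numeric vectors of equal length.
#' @return `TRUE` if an affine relation with positive slope exists.
#' @export
affinely_related <- function(dv, du) {
  if (length(dv) != length(du)) stop("vectors must have equal length")
  tol <- 1e-9
  cu <- max(du) - min(du) <= tol
  cv <- max(dv) - min(dv) <= tol
  if (cu && cv) return(TRUE)
  if (cu || cv) return(FALSE)
  # anchor on two coordinates with distinct du values
  i <- which.min(du); j <- which.max(du)
  k <- (dv[i] - dv[j]) / (du[i] - du[j])
  if (k <= 0) return(FALSE)
  c0 <- dv[i] - k * du[i]
  all(abs(dv - (k * du + c0)) <= tol * pmax(1, abs(dv)))
}

#' Observer-to-node shortest-path matrix
#'
#' One row per observer, one column per network node; entry = hop distance
#' from the observer to the node. Column j is the distance signature of node
#' j under the given observer set.
#'
#' @param net a network.
#' @param observers character vector of observer node identifiers.
#' @return an integer matrix (observers x nodes) with dimnames.
#' @export
observer_distance_matrix <- function(net, observers) {
  validate_network(net)
  observers <- as.character(observers)
  if (length(observers) == 0) stop("at least one observer is required")
  if (!all(observers %in% igraph::V(net)$name)) stop("unknown observer node(s)")
  igraph::distances(net, v = observers, to = igraph::V(net)$name,
                    algorithm = "unweighted")
}

#' Locatability index: number of distinguishable node pairs
#'
#' Counts unordered node pairs whose distance signatures (columns of `D`)
#' are NOT related by a positive-slope affine map; only such pairs can be
#' told apart by Pearson centrality. The maximum is `n (n - 1) / 2`, at
#' which point every node pair is distinguishable.
#'
#' @param D an [observer_distance_matrix()].
#' @return a non-negative integer.
#' @export
locatability_index <- function(D) {
  n <- ncol(D)
  if (n < 2) stop("at least two columns are required")
  x <- 0L
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n))
      if (!affinely_related(D[, j], D[, i])) x <- x + 1L
  x
}

#' Observer-set quality index q
#'
#' `q = 1 - (2 / (n (n - 1))) * sum_{i<j} Pearson(d_i, d_j)` over all node
#' pairs, where d_i is node i's distance signature. The more dissimilar the
#' signatures, the lower their mean correlation and the larger q (range
#' \[0, 2\]). Pairs where a signature has zero variance are scored by the
#' affine-relatedness fallback: correlation 1 when the pair is affinely
#' related (indistinguishable), 0 otherwise.
#'
#' @param D an [observer_distance_matrix()] with >= 2 rows.
#' @return a real number in \[0, 2\].
#' @export
q_index <- function(D) {
  if (nrow(D) < 2) stop("at least two observers are required")
  n <- ncol(D)
  if (n < 2) stop("at least two columns are required")
  C <- suppressWarnings(cor(D))
  if (anyNA(C)) {  # zero-variance signatures: affine-relatedness fallback
    zv <- which(apply(D, 2, function(x) max(x) == min(x)))
    for (i in zv) for (j in seq_len(n)) if (i != j)
      C[i, j] <- C[j, i] <- if (affinely_related(D[, j], D[, i])) 1 else 0
  }
  1 - 2 * sum(C[upper.tri(C)]) / (n * (n - 1))
}

#' Greedy observer selection maximizing locatability
#'
#' Builds an ordered observer sequence from the empty set: each step adds
#' the node whose inclusion distinguishes the most node pairs (maximizes the
#' locatability index x), breaking ties by the larger [q_index()] of the
#' resulting matrix (when at least two rows exist) and then by node
#' identifier. Once every pair is distinguishable the remaining budget is
#' spent maximizing q alone. Because adding a row can only break affine
#' relations, x is non-decreasing along the sequence, and any prefix of the
#' returned sequence is a usable observer set of that size.
#'
#' @param net a connected network.
#' @param budget number of observers to select, between 2 and n.
#' @return a `locatability_report`: list with `x` and `q` of the full
#'   selected set, and `steps`, a data frame (observer, x, q) recording the
#'   sequence with the indices after each addition (q is `NA` at size 1).
#' @export
greedy_observer_sequence <- function(net, budget) {
  validate_network(net)
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  if (budget < 2 || budget > n) stop("`budget` must be in [2, n]")
  dist <- all_pairs_hop_distance(net)
  total_pairs <- as.integer(n * (n - 1L) / 2)

  # state of each still-indistinguishable pair: column ids and, once
  # determined, the affine coefficients k, c mapping du -> dv
  pr <- t(utils::combn(n, 2))
  pair_u <- pr[, 1]; pair_v <- pr[, 2]
  k <- rep(NA_real_, nrow(pr)); c0 <- rep(NA_real_, nrow(pr))
  ref_u <- rep(NA_real_, nrow(pr)); ref_v <- rep(NA_real_, nrow(pr))
  alive <- rep(TRUE, nrow(pr))

  # pairs surviving (still indistinguishable) if observer row `row` is added
  surviving <- function(row) {
    s <- alive
    idx <- which(alive)
    du <- row[pair_u[idx]]; dv <- row[pair_v[idx]]
    det <- !is.na(k[idx])
    # determined pairs: new row must fit dv = k du + c
    bad <- det & abs(dv - (k[idx] * du + c0[idx])) > 1e-9
    # undetermined (both columns constant so far): slope from the new row
    und <- !det
    first <- und & is.na(ref_u[idx])
    est <- und & !first
    kk <- (dv - ref_v[idx]) / (du - ref_u[idx])
    bad <- bad | (est & ((du == ref_u[idx] & dv != ref_v[idx]) |
                           (du != ref_u[idx] & kk <= 0)))
    s[idx[bad]] <- FALSE
    s
  }

  chosen <- character(0)
  xs <- integer(0); qs <- numeric(0)
  D <- NULL
  for (step in seq_len(budget)) {
    cand <- setdiff(nodes, chosen)
    best <- NULL; best_x <- -1L; best_q <- -Inf
    for (v in cand) {
      row <- dist[v, ]
      x_new <- total_pairs - sum(surviving(row))
      if (x_new < best_x) next
      q_new <- if (!is.null(D)) q_index(rbind(D, row)) else NA_real_
      if (x_new > best_x ||
          (!is.na(q_new) && q_new > best_q + 1e-12)) {
        best <- v; best_x <- x_new
        best_q <- if (is.na(q_new)) -Inf else q_new
      }
    }
    row <- dist[best, ]
    alive <- surviving(row)
    # update affine state of surviving pairs with the new coordinate
    idx <- which(alive)
    du <- row[pair_u[idx]]; dv <- row[pair_v[idx]]
    und <- is.na(k[idx])
    newref <- und & is.na(ref_u[idx])
    ref_u[idx[newref]] <- du[newref]; ref_v[idx[newref]] <- dv[newref]
    fit <- und & !newref & du != ref_u[idx]
    k[idx[fit]] <- (dv[fit] - ref_v[idx[fit]]) / (du[fit] - ref_u[idx[fit]])
    c0[idx[fit]] <- dv[fit] - k[idx[fit]] * du[fit]
    D <- rbind(D, row)
    rownames(D)[nrow(D)] <- best
    chosen <- c(chosen, best)
    xs <- c(xs, total_pairs - sum(alive))
    qs <- c(qs, if (nrow(D) >= 2) q_index(D) else NA_real_)
  }
  structure(list(x = xs[length(xs)], q = qs[length(qs)],
                 steps = data.frame(observer = chosen, x = xs, q = qs,
                                    stringsAsFactors = FALSE)),
            class = "locatability_report")
}

#' @export
print.locatability_report <- function(x, ...) {
  cat("Locatability report:", nrow(x$steps), "observers, x =", x$x,
      ", q =", format(x$q, digits = 4), "\n")
  invisible(x)
}
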