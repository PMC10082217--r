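#' Observer record
#'
#' The information available to the locator: an ordered set of at least three
#' distinct observer nodes and their recorded informed times.
#'
#' @param observers character vector of observer node identifiers.
#' @param times numeric vector of informed times, parallel to `observers`.
#' @return an object of class `observer_record`.
#' @export
observer_record <- function(observers, times) {
  observers <- as.character(observers)
  if (length(observers) < 3) stop("at least 3 observers are required")
  if (anyDuplicated(observers)) stop("observers must be distinct")
  if (length(times) != length(observers))
    stop("`times` must be parallel to `observers`")
  if (!all(is.finite(times))) stop("observer times must be finite")
  structure(list(observers = observers, times = as.numeric(times)),
            class = "observer_record")
}

#' Record observers from a propagation result
#'
#' @param result a `propagation_result`.
#' @param observers character vector of observer nodes.
#' @return an [observer_record()].
#' @export
observe <- function(result, observers) {
  stopifnot(inherits(result, "propagation_result"))
  observers <- as.character(observers)
  if (!all(observers %in% names(result$informed_time)))
    stop("unknown observer node(s)")
  observer_record(observers, unname(result$informed_time[observers]))
}

#' Pearson product-moment correlation with an explicit undefined marker
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return the correlation in \[-1, 1\], or `NA` when either vector has zero
#'   variance (the correlation is undefined).
#' @export
pearson_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2) stop("at least two points are required")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Order observers by distance from a candidate source
#'
#' Observer indices sorted by ascending hop distance from the candidate;
#' ties keep the observers' original record order (stable sort), so the
#' result is deterministic and independent of the observed times.
#'
#' @param candidate a node identifier.
#' @param obs an [observer_record()].
#' @param dist a distance matrix from [all_pairs_hop_distance()].
#' @return an integer permutation of `seq_along(obs$observers)`.
#' @export
observer_order <- function(candidate, obs, dist) {
  stopifnot(inherits(obs, "observer_record"))
  d <- dist[candidate, obs$observers]
  order(d)  # radix sort: stable, ties by record position
}

# Prefix Pearson correlations of pre-ordered distance/time vectors via
# cumulative sums; entries with a zero-variance prefix are set to 0.
.prefix_pearson <- function(x, y) {
  r <- length(x)
  h <- seq_len(r)
  sx <- cumsum(x); sy <- cumsum(y)
  sxx <- cumsum(x * x); syy <- cumsum(y * y); sxy <- cumsum(x * y)
  vx <- pmax(h * sxx - sx^2, 0)
  vy <- pmax(h * syy - sy^2, 0)
  num <- h * sxy - sx * sy
  # relative guard against cancellation noise in the variance terms
  zx <- vx <= 1e-12 * pmax(h * sxx, 1)
  zy <- vy <= 1e-12 * pmax(h * syy, 1)
  rho <- ifelse(zx | zy, 0, num / sqrt(vx * vy))
  pmin(pmax(rho[-1], -1), 1)  # h = 2..r
}

#' Prefix Pearson profile of a candidate
#'
#' For each threshold h = 2..r, the Pearson correlation between the
#' candidate's h nearest observer distances (ascending) and the informed
#' times of those same observers. A source correlates strongly while h stays
#' inside its own infection region; once farther observers were informed by
#' other sources the correlation drops. Prefixes where either vector has
#' zero variance contribute 0 (a neutral, sign-free convention).
#'
#' @inheritParams observer_order
#' @return numeric vector of length r - 1 (thresholds h = 2..r).
#' @export
prefix_pearson_profile <- function(candidate, obs, dist) {
  ord <- observer_order(candidate, obs, dist)
  d <- as.numeric(dist[candidate, obs$observers][ord])
  t <- obs$times[ord]
  .prefix_pearson(d, t)
}

#' Candidate f-score
#'
#' The sum of the prefix Pearson profile over all thresholds h = 2..r.
#' Larger f marks a more source-like candidate; |f| <= r - 1.
#'
#' @inheritParams observer_order
#' @return a single numeric value.
#' @export
f_score <- function(candidate, obs, dist) {
  sum(prefix_pearson_profile(candidate, obs, dist))
}

#' Score every node of a network as a candidate source
#'
#' Hop distances are computed once and reused across candidates; observers
#' themselves are scored too (sources and observers are drawn independently,
#' so an observer may be a source).
#'
#' @param net a connected network.
#' @param obs an [observer_record()].
#' @param keep_profile retain the full per-candidate profile matrix
#'   (candidates x thresholds) as the `profile` element.
#' @return a `score_table`: list with `f` (named numeric over all nodes) and
#'   optionally `profile`.
#' @export
score_all_nodes <- function(net, obs, keep_profile = FALSE) {
  validate_network(net)
  stopifnot(inherits(obs, "observer_record"))
  if (!all(obs$observers %in% igraph::V(net)$name))
    stop("unknown observer node(s)")
  nodes <- igraph::V(net)$name
  dist <- igraph::distances(net, v = nodes, to = obs$observers,
                            algorithm = "unweighted")
  r <- length(obs$observers)
  prof <- matrix(NA_real_, length(nodes), r - 1,
                 dimnames = list(nodes, paste0("h", 2:r)))
  for (k in seq_along(nodes)) {
    d <- dist[k, ]
    ord <- order(d)
    prof[k, ] <- .prefix_pearson(as.numeric(d[ord]), obs$times[ord])
  }
  f <- rowSums(prof)
  out <- list(f = f, observers = obs$observers)
  if (keep_profile) out$profile <- prof
  structure(out, class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("Score table:", length(x$f), "candidates,",
      length(x$observers), "observers\n")
  top <- sort(x$f, decreasing = TRUE)[seq_len(min(5, length(x$f)))]
  cat("  top f:", paste0(names(top), "=", signif(top, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Rank candidates by descending f-score
#'
#' Nodes with larger f are more source-like and come first. Ties are broken
#' by node identifier order and flagged, so downstream AUC computation can
#' give tied groups half credit rather than trust the arbitrary tie-break.
#'
#' @param scores a `score_table` from [score_all_nodes()].
#' @return character vector of node identifiers, best candidate first, with
#'   attribute `tied` (logical, `TRUE` where a node shares its f value with
#'   an adjacent entry).
#' @export
rank_candidates <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  f <- scores$f
  if (length(f) == 0) stop("empty score table")
  ord <- order(-f, names(f), method = "radix")
  ranked <- names(f)[ord]
  fo <- f[ord]
  tied <- rep(FALSE, length(fo))
  if (length(fo) > 1) {
    same_prev <- c(FALSE, fo[-1] == fo[-length(fo)])
    tied <- same_prev | c(same_prev[-1], FALSE)
  }
  attr(ranked, "tied") <- tied
  ranked
}
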