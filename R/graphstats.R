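# Topological descriptors of nodes and node sets: degree, local clustering
# coefficient, betweenness, eigenvector centrality and shortest-path length,
# plus size-matched random-set baselines.

pe_check_nodes <- function(network, v) {
  missing <- setdiff(v, igraph::V(network)$name)
  if (length(missing) > 0L)
    stop("unknown node(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Node degree
#'
#' Number of distinct neighbours of `v` in a simple undirected network.
#'
#' @param network An igraph network.
#' @param v Node identifier(s).
#' @return Integer vector of degrees.
#' @export
node_degree <- function(network, v) {
  pe_check_nodes(network, v)
  as.integer(igraph::degree(network, v))
}

#' Local clustering coefficient
#'
#' Fraction of realised edges among the neighbours of `v`:
#' `2 * triangles(v) / (deg(v) * (deg(v) - 1))`, defined as 0 when
#' `deg(v) < 2`.
#'
#' @inheritParams node_degree
#' @return Numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(network, v) {
  pe_check_nodes(network, v)
  cc <- igraph::transitivity(network, type = "local", vids = v,
                             isolates = "zero")
  # igraph returns NaN for degree-1 nodes even with isolates="zero" in some
  # versions; pin the degenerate case to 0.
  cc[!is.finite(cc)] <- 0
  unname(cc)
}

#' Betweenness centrality
#'
#' Unnormalised betweenness on the unweighted graph: the sum over unordered
#' node pairs `(s, t)` with `s != t != v` of the fraction of shortest `s`-`t`
#' paths passing through `v`.  Endpoints are excluded.
#'
#' @inheritParams node_degree
#' @return Numeric vector of raw betweenness values.
#' @export
betweenness_centrality <- function(network, v) {
  pe_check_nodes(network, v)
  as.numeric(igraph::betweenness(network, v = v, directed = FALSE,
                                 normalized = FALSE))
}

#' Eigenvector centrality per connected component
#'
#' The principal eigenvector of the adjacency structure, computed separately
#' for each connected component.  Scores are non-negative and the score vector
#' of each component has unit Euclidean norm; an isolated node scores 1.
#'
#' @param network A non-empty igraph network.
#' @param tol Power-iteration convergence tolerance (default `1e-8`).
#' @param max_iter Maximum number of power iterations (default 1000).
#' @return Named numeric vector over all nodes.
#' @export
eigenvector_centrality <- function(network, tol = 1e-8, max_iter = 1000L) {
  if (igraph::vcount(network) == 0L)
    stop("eigenvector centrality undefined on an empty network")
  comp <- igraph::components(network)
  out <- setNames(numeric(igraph::vcount(network)), igraph::V(network)$name)
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    nm <- igraph::V(network)$name[vids]
    if (length(vids) == 1L) {
      out[nm] <- 1
      next
    }
    sub <- igraph::induced_subgraph(network, vids)
    A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    x <- rep(1 / sqrt(length(vids)), length(vids))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # shifted iteration (A + I) avoids oscillation on bipartite
      # components while preserving the principal eigenvector
      y <- as.numeric(A %*% x) + x
      ny <- sqrt(sum(y^2))
      if (ny == 0) { # component with no edges cannot occur for size > 1
        converged <- TRUE
        y <- x
        break
      }
      y <- y / ny
      if (max(abs(y - x)) < tol) {
        x <- y
        converged <- TRUE
        break
      }
      x <- y
    }
    if (!converged)
      stop("eigenvector centrality did not converge on the component ",
           "containing node '", nm[1L], "'")
    out[igraph::V(sub)$name] <- abs(x)
  }
  out
}

#' Breadth-first shortest-path lengths from a set of sources
#'
#' Unweighted shortest-path distances from each source to every network node.
#' Unreachable pairs are absent from the result.
#'
#' @param network An igraph network.
#' @param sources Character vector of source node identifiers.
#' @return A `data.frame` with columns `source`, `target`, `distance`
#'   (integer), one row per reachable ordered pair with `source != target`.
#' @export
shortest_path_lengths <- function(network, sources) {
  pe_check_nodes(network, sources)
  d <- igraph::distances(network, v = sources, mode = "all")
  rows <- which(is.finite(d), arr.ind = TRUE)
  out <- data.frame(source = rownames(d)[rows[, 1L]],
                    target = colnames(d)[rows[, 2L]],
                    distance = as.integer(d[rows]),
                    stringsAsFactors = FALSE)
  out[out$source != out$target, , drop = FALSE]
}

#' Topological summary of a node set
#'
#' Means of the five descriptors over the members of a node set: degree,
#' local clustering coefficient, raw betweenness, eigenvector centrality and
#' within-set shortest-path length.  The shortest-path mean is taken over
#' connected in-set pairs only, so it stays a descriptive statistic and is not
#' dominated by a penalty for unreachable pairs (contrast [compact_score()]).
#'
#' @param network An igraph network.
#' @param node_set Non-empty character vector of node identifiers, a subset of
#'   the network nodes.
#' @return A one-row `data.frame` with columns `n`, `mean_degree`,
#'   `mean_clustering`, `mean_betweenness`, `mean_eigenvector`,
#'   `mean_shortest_path` (`NA` if no connected in-set pair exists).
#' @export
topology_summary <- function(network, node_set) {
  node_set <- unique(as.character(node_set))
  if (length(node_set) == 0L) stop("node_set must be non-empty")
  pe_check_nodes(network, node_set)
  ev <- eigenvector_centrality(network)
  msp <- NA_real_
  if (length(node_set) >= 2L) {
    d <- igraph::distances(network, v = node_set, to = node_set, mode = "all")
    ut <- d[upper.tri(d)]
    ut <- ut[is.finite(ut)]
    if (length(ut) > 0L) msp <- mean(ut)
  }
  data.frame(
    n = length(node_set),
    mean_degree = mean(node_degree(network, node_set)),
    mean_clustering = mean(clustering_coefficient(network, node_set)),
    mean_betweenness = mean(betweenness_centrality(network, node_set)),
    mean_eigenvector = mean(ev[node_set]),
    mean_shortest_path = msp
  )
}

#' Size-matched random-set baseline for the topological summary
#'
#' Draws `n_sets` uniform samples of `size` nodes (without replacement, from
#' all network nodes), summarises each with [topology_summary()] and reports
#' the per-descriptor mean and standard deviation across samples.
#'
#' @param network An igraph network.
#' @param size Sample size; must not exceed the number of nodes.
#' @param n_sets Number of random sets (default 10).
#' @param seed Integer seed; the baseline is reproducible given the seed.
#' @return A list with `n_sets`, `seed`, `mean` and `sd` (named numeric
#'   vectors over the five descriptors), and `samples` (the per-sample
#'   summary `data.frame`).
#' @export
random_matched_baseline <- function(network, size, n_sets = 10L, seed = 1L) {
  n <- igraph::vcount(network)
  if (size > n) stop("size exceeds the number of network nodes")
  if (n_sets < 1L) stop("n_sets must be >= 1")
  nodes <- igraph::V(network)$name
  samples <- pe_with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_sets), function(i) {
      topology_summary(network, sample(nodes, size))
    }))
  })
  descr <- c("mean_degree", "mean_clustering", "mean_betweenness",
             "mean_eigenvector", "mean_shortest_path")
  list(n_sets = as.integer(n_sets), seed = as.integer(seed),
       mean = vapply(descr, function(d) mean(samples[[d]]), numeric(1)),
       sd = vapply(descr, function(d) stats::sd(samples[[d]]), numeric(1)),
       samples = samples)
}
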