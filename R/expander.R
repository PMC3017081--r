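# Core extension algorithm: candidate filtering by four graph-theoretic
# conditions, then greedy growth while the compactness score decreases.
#
# A candidate neighbour v of a mapped pathway p is admitted by the first
# filter when it satisfies condition (1) and at least one of (2)-(4):
#   (1) degree(v) > 1
#   (2) process_links(v, p) / outside_links(v, p)        > T1
#   (3) triangle_links(v, p) / possible_triangles(v, p)  > T2
#   (4) process_links(v, p) / process_nodes(p)           > T3
# With T1 = 1 condition (2) is the classical "strong community" criterion:
# more edges into the pathway than into the rest of the graph.  Admitted
# candidates are then added greedily, most-compactness-improving first, as
# long as the mean pairwise shortest-path length of the set strictly drops.

#' Extension configuration
#'
#' Thresholds and options of the extension procedure.
#'
#' @param t1 Threshold of the strong-community condition (2); a candidate
#'   passes when its in-pathway links strictly exceed `t1` times its
#'   out-of-pathway links.  Default 1.0.
#' @param t2 Threshold of the triangle-density condition (3), a fraction in
#'   (0, 1).  Default 0.1.
#' @param t3 Threshold of the pathway-coverage condition (4), a fraction in
#'   (0, 1); it must be below 1 because a candidate can be linked to at most
#'   all pathway nodes.  Default 0.3.
#' @param min_set_size Minimum original (pre-mapping) membership for a set to
#'   be examined by [extend_collection()].  Default 10.
#' @param penalty_mode How an unreachable node pair contributes to the
#'   compactness score: `"node_count"` (the number of network nodes, so that
#'   connecting two components always improves compactness) or `"fixed"` (a
#'   constant given by `penalty_value`).
#' @param penalty_value Penalty distance when `penalty_mode = "fixed"`.
#' @return A list of class `"extension_config"`.
#' @export
extension_config <- function(t1 = 1.0, t2 = 0.1, t3 = 0.3,
                             min_set_size = 10L,
                             penalty_mode = c("node_count", "fixed"),
                             penalty_value = NULL) {
  penalty_mode <- match.arg(penalty_mode)
  stopifnot(t1 > 0, t2 > 0, t2 < 1, t3 > 0, t3 < 1, min_set_size >= 2)
  if (penalty_mode == "fixed" &&
      (is.null(penalty_value) || penalty_value <= 0))
    stop("penalty_value must be a positive number when penalty_mode='fixed'")
  structure(list(t1 = t1, t2 = t2, t3 = t3,
                 min_set_size = as.integer(min_set_size),
                 penalty_mode = penalty_mode,
                 penalty_value = penalty_value),
            class = "extension_config")
}

pe_penalty <- function(network, config) {
  if (config$penalty_mode == "node_count") igraph::vcount(network)
  else config$penalty_value
}

#' Candidate set of a mapped gene set
#'
#' All network nodes adjacent to at least one member of the mapped set,
#' excluding the members themselves.
#'
#' @param network An igraph network.
#' @param mapped_set Character vector of member identifiers (network nodes).
#' @return Character vector of candidate node identifiers (sorted).
#' @export
candidate_set <- function(network, mapped_set) {
  mapped_set <- unique(as.character(mapped_set))
  if (length(mapped_set) == 0L) return(character())
  pe_check_nodes(network, mapped_set)
  nb <- igraph::adjacent_vertices(network, mapped_set)
  vnames <- igraph::V(network)$name
  cand <- unique(vnames[unlist(lapply(nb, as.integer), use.names = FALSE)])
  sort(setdiff(cand, mapped_set))
}

#' Evaluate the filter conditions for one candidate
#'
#' Computes the edge and triangle counts behind conditions (1)-(4) for a
#' single candidate `v` against a mapped set and a candidate pool, and which
#' conditions it passes under `config`.
#'
#' `triangle_links` counts pairs `(u, w)` with `u` an in-set neighbour of `v`,
#' `w` a candidate-pool neighbour of `v` (other than `v`), and the edge
#' `(u, w)` present — i.e. realised (candidate, member, candidate) triangles
#' through `v`.  `possible_triangles` counts the same pairs without requiring
#' the `(u, w)` edge, so the ratio is a well-defined fraction in `[0, 1]`.
#'
#' @param network An igraph network.
#' @param mapped_set Character vector of mapped members.
#' @param candidate_pool Character vector of candidates (see
#'   [candidate_set()]).
#' @param v A single candidate identifier, element of `candidate_pool`.
#' @param config An [extension_config()].
#' @return A one-row `data.frame` with columns `candidate`, `degree`,
#'   `process_links`, `outside_links`, `triangle_links`,
#'   `possible_triangles`, `process_node_count`, `cond1` .. `cond4`,
#'   `admitted`.
#' @export
evaluate_candidate <- function(network, mapped_set, candidate_pool, v,
                               config = extension_config()) {
  if (!v %in% candidate_pool) stop("'", v, "' is not in the candidate pool")
  adj <- pe_adj_list(network)
  pe_candidate_row(adj, mapped_set, candidate_pool, v, config)
}

# Named list: node -> character vector of neighbour names.
pe_adj_list <- function(network) {
  al <- igraph::as_adj_list(network, mode = "all")
  vnames <- igraph::V(network)$name
  out <- lapply(al, function(x) vnames[as.integer(x)])
  names(out) <- vnames
  out
}

pe_candidate_row <- function(adj, mapped_set, candidate_pool, v, config) {
  nbrs <- adj[[v]]
  deg <- length(nbrs)
  in_set <- intersect(nbrs, mapped_set)
  in_pool <- intersect(nbrs, setdiff(candidate_pool, v))
  p_links <- length(in_set)
  o_links <- deg - p_links
  possible <- p_links * length(in_pool)
  tri <- 0L
  if (p_links > 0L && length(in_pool) > 0L) {
    # realised (u, w) pairs: u in-set neighbour, w candidate neighbour,
    # edge (u, w) present
    tri <- sum(vapply(in_set, function(u) length(intersect(adj[[u]], in_pool)),
                      integer(1)))
  }
  n_proc <- length(mapped_set)
  cond1 <- deg > 1L
  cond2 <- p_links > config$t1 * o_links && p_links > 0L
  cond3 <- possible > 0L && tri / possible > config$t2
  cond4 <- n_proc > 0L && p_links / n_proc > config$t3
  data.frame(candidate = v, degree = deg, process_links = p_links,
             outside_links = o_links, triangle_links = as.integer(tri),
             possible_triangles = as.integer(possible),
             process_node_count = n_proc,
             cond1 = cond1, cond2 = cond2, cond3 = cond3, cond4 = cond4,
             admitted = cond1 && (cond2 || cond3 || cond4),
             stringsAsFactors = FALSE)
}

#' First filtering step: admit candidates by conditions (1)-(4)
#'
#' Evaluates every candidate of the mapped set and admits those satisfying
#' condition (1) and at least one of (2)-(4).  Diagnostics for all candidates
#' (admitted or not) are returned.
#'
#' @inheritParams evaluate_candidate
#' @return A `data.frame` with one row per candidate (columns as in
#'   [evaluate_candidate()]), ordered by candidate id; the `admitted` column
#'   marks the admitted subset.
#' @export
first_filter <- function(network, mapped_set, config = extension_config()) {
  mapped_set <- unique(as.character(mapped_set))
  pool <- candidate_set(network, mapped_set)
  if (length(pool) == 0L)
    return(data.frame(candidate = character(), degree = integer(),
                      process_links = integer(), outside_links = integer(),
                      triangle_links = integer(),
                      possible_triangles = integer(),
                      process_node_count = integer(),
                      cond1 = logical(), cond2 = logical(),
                      cond3 = logical(), cond4 = logical(),
                      admitted = logical(), stringsAsFactors = FALSE))
  adj <- pe_adj_list(network)
  rows <- lapply(pool, function(v) {
    pe_candidate_row(adj, mapped_set, pool, v, config)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compactness score of a node set
#'
#' The mean shortest-path length in the full network over all unordered pairs
#' of set members.  A pair with no connecting path contributes a penalty
#' distance: the number of network nodes (default) or a fixed constant, per
#' `config`.  Lower scores mean a more compact network representation.
#'
#' @param network An igraph network.
#' @param node_set Character vector of at least two network nodes.
#' @param config An [extension_config()] (controls the unreachable-pair
#'   penalty).
#' @return A single numeric score.
#' @export
compact_score <- function(network, node_set, config = extension_config()) {
  node_set <- unique(as.character(node_set))
  if (length(node_set) < 2L)
    stop("compact_score requires at least 2 nodes")
  pe_check_nodes(network, node_set)
  d <- igraph::distances(network, v = node_set, to = node_set, mode = "all")
  ut <- d[upper.tri(d)]
  ut[!is.finite(ut)] <- pe_penalty(network, config)
  mean(ut)
}

#' Extend a mapped gene set
#'
#' Runs the two-stage extension: candidates are admitted once by
#' [first_filter()] against the original mapped set, then added greedily.
#' At each step the admitted candidate whose addition yields the lowest
#' compactness score is added, provided that score is strictly below the
#' current one; ties are broken towards the lexicographically smallest node
#' id.  The loop stops when no remaining candidate strictly reduces the
#' score.  The algorithm is fully deterministic.
#'
#' @param network An igraph network.
#' @param mapped_set Character vector of at least two mapped members.
#' @param config An [extension_config()].
#' @return An object of class `"extension_result"`: a list with `set_id`
#'   (`NA` unless set by the caller), `original_mapped`, `added` (ordered),
#'   `trajectory` (compactness before any addition, then after each),
#'   `diagnostics` (the full [first_filter()] table) and `config`.
#' @export
extend_set <- function(network, mapped_set, config = extension_config()) {
  mapped_set <- sort(unique(as.character(mapped_set)))
  if (length(mapped_set) < 2L)
    stop("extend_set requires at least 2 mapped members")
  pe_check_nodes(network, mapped_set)
  diag <- first_filter(network, mapped_set, config)
  admitted <- sort(diag$candidate[diag$admitted])
  penalty <- pe_penalty(network, config)

  # Distances in the full network are fixed, so precompute the block we need:
  # members+admitted against members+admitted.
  universe <- c(mapped_set, admitted)
  D <- igraph::distances(network, v = universe, to = universe, mode = "all")
  D[!is.finite(D)] <- penalty

  current <- mapped_set
  pair_sum <- sum(D[current, current][upper.tri(diag(length(current)))])
  n <- length(current)
  score <- pair_sum / choose(n, 2)
  trajectory <- score
  added <- character()
  remaining <- admitted
  while (length(remaining) > 0L) {
    # score after adding v: (pair_sum + sum of d(v, current)) / C(n+1, 2)
    add_sums <- if (length(remaining) == 1L)
      sum(D[remaining, current]) else rowSums(D[remaining, current])
    new_scores <- (pair_sum + add_sums) / choose(n + 1L, 2L)
    best <- min(new_scores)
    if (!(best < score)) break
    # remaining is sorted, so which.min takes the lexicographically smallest
    pick <- remaining[which.min(new_scores)]
    pair_sum <- pair_sum + add_sums[[which.min(new_scores)]]
    current <- c(current, pick)
    n <- n + 1L
    score <- best
    trajectory <- c(trajectory, score)
    added <- c(added, pick)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(set_id = NA_character_, original_mapped = mapped_set,
                 added = added, trajectory = trajectory,
                 diagnostics = diag, config = config),
            class = "extension_result")
}

#' @export
print.extension_result <- function(x, ...) {
  cat("Extension result", if (!is.na(x$set_id)) paste0("for '", x$set_id, "'"),
      "\n  original mapped members:", length(x$original_mapped),
      "\n  added:", length(x$added),
      if (length(x$added) > 0L)
        paste0(" (", paste(x$added, collapse = ", "), ")"),
      "\n  compactness:", sprintf("%.4f", x$trajectory[1L]), "->",
      sprintf("%.4f", x$trajectory[length(x$trajectory)]), "\n")
  invisible(x)
}

#' Extend a collection of gene sets
#'
#' Maps each set onto the network and extends it.  Sets whose original
#' membership is below `config$min_set_size` are skipped (not examined);
#' sets with fewer than two mapped members are skipped as well (the
#' compactness score needs at least one pair).
#'
#' @param network An igraph network.
#' @param sets List of gene sets (see [read_gmt()]).
#' @param config An [extension_config()].
#' @return A list with `results` (named list of `extension_result`s, one per
#'   extended-or-examined set) and `summary`, a one-row `data.frame` with
#'   `n_sets`, `examined`, `extended`, `avg_size_before`, `avg_size_after`,
#'   `total_added`, `unique_added`.  Sizes are mapped sizes; `extended`
#'   counts sets that gained at least one protein.
#' @export
extend_collection <- function(network, sets, config = extension_config()) {
  results <- list()
  sizes_before <- integer()
  sizes_after <- integer()
  for (s in sets) {
    if (length(s$members) < config$min_set_size) next
    m <- map_gene_set(network, s)
    if (length(m$mapped_members) < 2L) next
    res <- extend_set(network, m$mapped_members, config)
    res$set_id <- s$set_id
    results[[s$set_id]] <- res
    sizes_before <- c(sizes_before, length(m$mapped_members))
    sizes_after <- c(sizes_after,
                     length(m$mapped_members) + length(res$added))
  }
  all_added <- unlist(lapply(results, `[[`, "added"), use.names = FALSE)
  summary <- data.frame(
    n_sets = length(sets),
    examined = length(results),
    extended = sum(vapply(results, function(r) length(r$added) > 0L,
                          logical(1))),
    avg_size_before = if (length(sizes_before)) mean(sizes_before) else NA_real_,
    avg_size_after = if (length(sizes_after)) mean(sizes_after) else NA_real_,
    total_added = length(all_added),
    unique_added = length(unique(all_added)))
  list(results = results, summary = summary)
}

#' Turn extension results into an extended gene-set collection
#'
#' @param sets The original gene-set list.
#' @param extension The value of [extend_collection()].
#' @return A gene-set list in GMT shape whose members are the original
#'   members plus the added proteins, for the sets that were examined.
#' @export
extended_gene_sets <- function(sets, extension) {
  out <- list()
  for (id in names(extension$results)) {
    s <- sets[[id]]
    s$members <- unique(c(s$members, extension$results[[id]]$added))
    out[[id]] <- s
  }
  out
}
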