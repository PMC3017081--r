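# Independent brute-force oracles used to validate the package's graph and
# statistics code.  These deliberately use naive dense-matrix algorithms and
# explicit enumeration, sharing no code with the implementation under test.

# Erdos-Renyi test graph with stable lexicographic node names.
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1L
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  list(graph = g, adj = A)
}

adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix.
oracle_fw <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Betweenness by closed-form shortest-path counting: the number of shortest
# s-t paths equals the (s,t) entry of A^d(s,t), and a path through v splits
# as shortest s-v times shortest v-t when d(s,v)+d(v,t)=d(s,t).
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_fw(A)
  maxd <- suppressWarnings(max(D[is.finite(D)]))
  if (!is.finite(maxd)) maxd <- 0
  pow <- vector("list", max(maxd, 1))
  pow[[1]] <- A
  if (maxd >= 2) for (k in 2:maxd) pow[[k]] <- pow[[k - 1]] %*% A
  sigma <- function(s, t) {
    d <- D[s, t]
    if (s == t) return(1)
    if (!is.finite(d)) return(0)
    pow[[d]][s, t]
  }
  bw <- numeric(n)
  if (n >= 3) {
    for (v in seq_len(n)) for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        bw[v] <- bw[v] + sigma(s, v) * sigma(v, t) / sigma(s, t)
    }
  }
  stats::setNames(bw, rownames(A))
}

# Local clustering by explicit neighbour-pair enumeration.
oracle_clustering <- function(A, v) {
  nb <- which(A[v, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  tri <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (A[nb[i], nb[j]] > 0) tri <- tri + 1
  2 * tri / (k * (k - 1))
}

# Per-component principal eigenvector via dense eigendecomposition,
# non-negative and Euclidean-normalised per component.
oracle_eigenvector <- function(A) {
  n <- nrow(A)
  out <- stats::setNames(numeric(n), rownames(A))
  D <- oracle_fw(A)
  seen <- rep(FALSE, n)
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- which(is.finite(D[s, ]))
    seen[comp] <- TRUE
    if (length(comp) == 1) {
      out[comp] <- 1
      next
    }
    e <- eigen(A[comp, comp, drop = FALSE], symmetric = TRUE)
    v <- e$vectors[, which.max(e$values)]
    v <- abs(v) / sqrt(sum(v^2))
    out[comp] <- v
  }
  out
}

# Brute-force candidate filter: explicit loops over Eqs. (1)-(4).
oracle_filter <- function(A, mapped, cfg) {
  nm <- rownames(A)
  cand <- setdiff(nm[colSums(A[mapped, , drop = FALSE]) > 0], mapped)
  admitted <- character()
  for (v in cand) {
    deg <- sum(A[v, ])
    pl <- sum(A[v, mapped])
    ol <- deg - pl
    tri <- 0; poss <- 0
    for (u in mapped) for (w in setdiff(cand, v)) {
      if (A[v, u] == 1 && A[v, w] == 1) {
        poss <- poss + 1
        if (A[u, w] == 1) tri <- tri + 1
      }
    }
    c1 <- deg > 1
    c2 <- pl > cfg$t1 * ol
    c3 <- poss > 0 && tri / poss > cfg$t2
    c4 <- pl / length(mapped) > cfg$t3
    if (c1 && (c2 || c3 || c4)) admitted <- c(admitted, v)
  }
  sort(admitted)
}

oracle_compact_score <- function(A, set, cfg) {
  D <- oracle_fw(A)
  pen <- if (cfg$penalty_mode == "node_count") nrow(A) else cfg$penalty_value
  d <- D[set, set][upper.tri(diag(length(set)))]
  d[!is.finite(d)] <- pen
  mean(d)
}

# Full greedy extension recomputing every candidate score from scratch.
oracle_extend <- function(A, mapped, cfg) {
  admitted <- oracle_filter(A, mapped, cfg)
  score <- function(set) oracle_compact_score(A, set, cfg)
  cur <- sort(mapped)
  traj <- score(cur)
  added <- character()
  rem <- admitted
  while (length(rem) > 0) {
    scores <- vapply(rem, function(v) score(c(cur, v)), numeric(1))
    best <- min(scores)
    if (!(best < traj[length(traj)])) break
    pick <- sort(rem[scores == best])[1]
    cur <- c(cur, pick)
    added <- c(added, pick)
    traj <- c(traj, best)
    rem <- setdiff(rem, pick)
  }
  list(added = added, trajectory = traj)
}

# Hypergeometric upper-tail by direct summation of the density.
oracle_fisher_tail <- function(universe, set_size, list_size, overlap) {
  ks <- overlap:min(set_size, list_size)
  sum(stats::dhyper(ks, set_size, universe - set_size, list_size))
}

# Benjamini-Hochberg step-up written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1)
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Ancestor enumeration by plain recursion (for the Jiang-Conrath oracle).
oracle_ancestors <- function(onto, t) {
  res <- t
  for (p in onto$parents[[t]]) res <- union(res, oracle_ancestors(onto, p))
  res
}

oracle_ic <- function(onto, ann, term) {
  ns <- onto$namespace[[term]]
  annotated <- names(ann)[vapply(names(ann), function(p) {
    any(vapply(ann[[p]], function(t) ns %in% onto$namespace[[t]], logical(1)))
  }, logical(1))]
  cnt <- sum(vapply(annotated, function(p) {
    any(vapply(ann[[p]], function(t) term %in% oracle_ancestors(onto, t),
               logical(1)))
  }, logical(1)))
  -log(cnt / length(annotated))
}

oracle_jc <- function(onto, ann, t1, t2) {
  common <- intersect(oracle_ancestors(onto, t1), oracle_ancestors(onto, t2))
  mica_ic <- max(vapply(common, function(a) oracle_ic(onto, ann, a),
                        numeric(1)))
  oracle_ic(onto, ann, t1) + oracle_ic(onto, ann, t2) - 2 * mica_ic
}

# Small deterministic fixture shared across tests: the default planted study.
default_fixture <- local({
  cache <- NULL
  function(seed = 42L) {
    if (is.null(cache)) {
      net <- generate_planted_network(planted_spec(seed = seed))
      gmt <- emit_incomplete_gmt(net$truth, 0.1, seed = seed)
      onto <- generate_toy_ontology(net$truth, seed = seed)
      cache <<- list(network = net$network, truth = net$truth,
                     sets = gmt$sets, hidden = gmt$hidden,
                     ontology = onto$ontology,
                     annotations = onto$annotations)
    }
    cache
  }
})
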