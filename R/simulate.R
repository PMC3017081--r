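# Synthetic data with known ground truth: planted-community (stochastic
# block model) networks, incomplete gene-set collections, toy ontologies and
# planted gene lists.  Everything the other modules consume can be generated
# here, so the full pipeline runs without any external download.

#' Specification of a planted-community network
#'
#' A stochastic block model: `n_communities` disjoint communities of
#' `community_size` nodes each, plus `background_nodes` nodes belonging to no
#' community.  Each within-community node pair is connected independently
#' with probability `p_in`; every other pair (cross-community, background)
#' with probability `p_out`.
#'
#' The defaults (5 communities of 20 nodes, 100 background nodes,
#' `p_in = 0.3`, `p_out = 0.01`) give communities that are dense relative to
#' their surroundings yet far from cliques, with enough background to supply
#' spurious candidates — a desk-scale stand-in for a pathway collection on a
#' real interactome.
#'
#' @param n_communities Number of planted communities.
#' @param community_size Nodes per community.
#' @param p_in Within-community edge probability.
#' @param p_out All other edge probabilities; must satisfy
#'   `0 <= p_out < p_in <= 1`.
#' @param background_nodes Number of community-free nodes.
#' @param seed Integer seed.
#' @return A list of class `"planted_spec"`.
#' @export
planted_spec <- function(n_communities = 5L, community_size = 20L,
                         p_in = 0.3, p_out = 0.01,
                         background_nodes = 100L, seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1,
            n_communities >= 1, community_size >= 2, background_nodes >= 0)
  structure(list(n_communities = as.integer(n_communities),
                 community_size = as.integer(community_size),
                 p_in = p_in, p_out = p_out,
                 background_nodes = as.integer(background_nodes),
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a planted-community network
#'
#' Draws a stochastic-block-model network according to a [planted_spec()].
#' Community nodes are named `C<k>_<i>`, background nodes `B_<i>`.
#' Reproducible given `spec$seed`.
#'
#' @param spec A [planted_spec()].
#' @return A list with `network` (igraph) and `truth`: `communities` (named
#'   list of node-id vectors) and `background` (character vector).
#' @export
generate_planted_network <- function(spec = planted_spec()) {
  stopifnot(inherits(spec, "planted_spec"))
  comm <- lapply(seq_len(spec$n_communities), function(k) {
    sprintf("C%d_%02d", k, seq_len(spec$community_size))
  })
  names(comm) <- sprintf("community_%d", seq_len(spec$n_communities))
  background <- if (spec$background_nodes > 0L)
    sprintf("B_%03d", seq_len(spec$background_nodes)) else character()
  nodes <- c(unlist(comm, use.names = FALSE), background)
  block <- rep(c(seq_len(spec$n_communities), 0L),
               c(rep(spec$community_size, spec$n_communities),
                 spec$background_nodes))
  n <- length(nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  within <- block[pairs[, 1L]] == block[pairs[, 2L]] & block[pairs[, 1L]] > 0L
  p <- ifelse(within, spec$p_in, spec$p_out)
  keep <- pe_with_seed(spec$seed, stats::rbinom(length(p), 1L, p) == 1L)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = nodes)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(nodes[pairs[keep, 1L]],
                                    nodes[pairs[keep, 2L]]))
  list(network = g,
       truth = list(communities = comm, background = background))
}

#' Emit an incomplete gene-set collection from planted communities
#'
#' Withholds `ceiling(hide_fraction * size)` members per community uniformly
#' at random; the remaining members form the emitted gene sets and the
#' withheld ones the hidden-member manifest.  Emitted and hidden members
#' partition each true community.
#'
#' @param truth The `truth` component of [generate_planted_network()].
#' @param hide_fraction Fraction of members to withhold, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list with `sets` (gene-set list in GMT shape) and `hidden`
#'   (named list of withheld members per set).
#' @export
emit_incomplete_gmt <- function(truth, hide_fraction = 0.1, seed = 1L) {
  stopifnot(hide_fraction >= 0, hide_fraction < 1)
  sets <- list(); hidden <- list()
  for (id in names(truth$communities)) {
    members <- truth$communities[[id]]
    n_hide <- ceiling(hide_fraction * length(members))
    hid <- if (n_hide > 0L)
      pe_with_seed(pe_derive_seed(seed, paste0("hide:", id)),
                   sample(members, n_hide)) else character()
    sets[[id]] <- list(set_id = id, name = paste0("planted ", id),
                       members = setdiff(members, hid))
    hidden[[id]] <- hid
  }
  list(sets = sets, hidden = hidden)
}

#' Generate a toy rooted ontology with community-specific annotations
#'
#' Builds a complete rooted tree (`branching` children per internal term,
#' `depth` levels below the root, single namespace) and annotates each
#' community's members to terms of one subtree under the root, assigned
#' round-robin.  Background nodes are annotated to uniformly random terms of
#' the whole tree, so that random candidate draws remain annotated but
#' functionally unspecific.
#'
#' @param truth The `truth` component of [generate_planted_network()].
#' @param depth Tree depth below the root (>= 1).
#' @param branching Children per internal node (>= 2).
#' @param terms_per_protein Annotations per protein (default 2).
#' @param seed Integer seed.
#' @return A list with `ontology` (a `"pe_ontology"`) and `annotations`
#'   (named list, protein -> terms).
#' @export
generate_toy_ontology <- function(truth, depth = 2L, branching = 3L,
                                  terms_per_protein = 2L, seed = 1L) {
  stopifnot(depth >= 1L, branching >= 2L)
  ns <- "biological_process"
  root <- "T:0"
  terms <- root; parents <- list(); parents[[root]] <- character()
  levels <- list(root)
  counter <- 0L
  for (d in seq_len(depth)) {
    lev <- character()
    for (p in levels[[d]]) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        t <- sprintf("T:%d", counter)
        terms <- c(terms, t)
        parents[[t]] <- p
        lev <- c(lev, t)
      }
    }
    levels[[d + 1L]] <- lev
  }
  ontology <- structure(
    list(terms = terms, parents = parents,
         namespace = setNames(rep(ns, length(terms)), terms),
         name = setNames(paste0("toy term ", terms), terms)),
    class = "pe_ontology")
  # subtree (descendant closure) of each depth-1 term
  top <- levels[[2L]]
  children <- split(rep(names(parents), lengths(parents)),
                    unlist(parents, use.names = FALSE))
  subtree <- function(t) {
    out <- t; frontier <- t
    while (length(frontier) > 0L) {
      nxt <- unlist(children[frontier], use.names = FALSE)
      out <- c(out, nxt); frontier <- nxt
    }
    out
  }
  subtrees <- lapply(top, subtree)
  annotations <- list()
  comm_ids <- names(truth$communities)
  for (k in seq_along(comm_ids)) {
    pool <- subtrees[[(k - 1L) %% length(subtrees) + 1L]]
    for (prot in truth$communities[[comm_ids[k]]]) {
      annotations[[prot]] <- pe_with_seed(
        pe_derive_seed(seed, paste0("ann:", prot)),
        unique(sample(pool, min(terms_per_protein, length(pool)))))
    }
  }
  for (prot in truth$background) {
    annotations[[prot]] <- pe_with_seed(
      pe_derive_seed(seed, paste0("ann:", prot)),
      unique(sample(terms, min(terms_per_protein, length(terms)))))
  }
  list(ontology = ontology, annotations = annotations)
}

#' Generate a planted gene list of interest
#'
#' Emulates a list of, e.g., tumour-mutated genes: a fraction of each
#' community's hidden members plus random background nodes.  Because hidden
#' members are prime extension candidates, extended sets should show stronger
#' enrichment for this list than the original (incomplete) sets.
#'
#' @param truth The `truth` component of [generate_planted_network()].
#' @param hidden Named list of hidden members (see [emit_incomplete_gmt()]).
#' @param n_background Number of background nodes to add (default 5).
#' @param seed Integer seed.
#' @return Character vector of gene identifiers.
#' @export
generate_gene_list <- function(truth, hidden, n_background = 5L, seed = 1L) {
  bg <- if (n_background > 0L && length(truth$background) > 0L)
    pe_with_seed(pe_derive_seed(seed, "genelist"),
                 sample(truth$background,
                        min(n_background, length(truth$background))))
  else character()
  unique(c(unlist(hidden, use.names = FALSE), bg))
}

#' Write a complete synthetic study to a directory
#'
#' Generates the default planted fixture and writes `edges.tsv`, `sets.gmt`,
#' `hidden.tsv`, `ontology.obo`, `annotations.tsv` and `mutated.txt`, all
#' plain text and re-readable through the package's readers.
#'
#' @param outdir Output directory (created if needed).
#' @param spec A [planted_spec()].
#' @param hide_fraction Fraction of community members withheld from the GMT.
#' @param seed Integer seed driving every stochastic step.
#' @return Invisibly, a list with `paths` (named list of the written files)
#'   and the in-memory objects (`network`, `truth`, `gene_sets`, `hidden`,
#'   `ontology`, `annotations`, `gene_list`).
#' @export
simulate_study <- function(outdir, spec = planted_spec(seed = seed),
                           hide_fraction = 0.1, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_planted_network(spec)
  gmt <- emit_incomplete_gmt(net$truth, hide_fraction,
                             seed = pe_derive_seed(seed, "emit"))
  onto <- generate_toy_ontology(net$truth,
                                seed = pe_derive_seed(seed, "onto"))
  genes <- generate_gene_list(net$truth, gmt$hidden,
                              seed = pe_derive_seed(seed, "genes"))
  paths <- list(
    edges = file.path(outdir, "edges.tsv"),
    sets = file.path(outdir, "sets.gmt"),
    hidden = file.path(outdir, "hidden.tsv"),
    ontology = file.path(outdir, "ontology.obo"),
    annotations = file.path(outdir, "annotations.tsv"),
    mutated = file.path(outdir, "mutated.txt"))
  write_edge_list(net$network, paths$edges)
  write_gmt(gmt$sets, paths$sets)
  writeLines(vapply(names(gmt$hidden), function(id)
    paste(c(id, gmt$hidden[[id]]), collapse = "\t"), character(1)),
    paths$hidden)
  write_obo(onto$ontology, paths$ontology)
  write_annotations(onto$annotations, paths$annotations)
  writeLines(genes, paths$mutated)
  invisible(list(paths = paths, network = net$network, truth = net$truth,
                 gene_sets = gmt$sets, hidden = gmt$hidden,
                 ontology = onto$ontology, annotations = onto$annotations,
                 gene_list = genes))
}
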