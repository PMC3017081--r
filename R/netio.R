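# Reading and writing interaction networks and mapping gene sets onto them.
#
# The network container is an undirected simple igraph object with character
# vertex names.  Identifiers are opaque, case-sensitive strings: no identifier
# translation is performed, users supply a pre-harmonised edge list.

# Build a simple undirected network from a two-column character matrix of
# endpoint identifiers.  Self-loops and duplicate pairs (in either order) are
# dropped, with counts logged.
pe_build_network <- function(a, b, verbose = TRUE) {
  a <- as.character(a)
  b <- as.character(b)
  all_nodes <- unique(c(a, b))
  n_loops <- sum(a == b)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste0(lo, "\r", hi)
  dup <- duplicated(key)
  n_dups <- sum(dup)
  if (verbose && (n_loops > 0L || n_dups > 0L))
    pe_log("dropped ", n_loops, " self-loop(s) and ", n_dups,
           " duplicate edge(s)")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (any(!dup))
    g <- igraph::add_edges(g, rbind(lo[!dup], hi[!dup]))
  g
}

#' Read an interaction network from a two-column edge-list file
#'
#' Each non-comment line must contain at least two delimited fields; the first
#' two are taken as the endpoints of an undirected interaction.  Lines starting
#' with `#` and blank lines are ignored.  Self-loops and duplicate edges
#' (regardless of endpoint order) are silently dropped and their counts logged.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter, default tab.  Any single character.
#' @return An undirected simple [igraph::graph] with character vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tC", "C\tA"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)  # 3
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  parts <- strsplit(lines[idx], delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    stop("malformed edge-list line ", bad, " in '", path,
         "': fewer than 2 fields")
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  pe_build_network(a, b)
}

#' Read an interaction network from a PSI-MI TAB 2.5-style file
#'
#' A minimal MITAB reader: interactor identifiers are taken from the first two
#' tab-separated columns (unique identifier A and B).  A namespace prefix such
#' as `"uniprotkb:"` is stripped when present.  A header line starting with
#' `#` is skipped.  The graph contract is the same as [read_edge_list()]:
#' undirected, simple, self-loops and duplicates dropped.
#'
#' @param path Path to the MITAB file.
#' @param strip_prefix Strip a `db:` namespace prefix from identifiers
#'   (default `TRUE`).
#' @return An undirected simple [igraph::graph].
#' @export
read_psimitab <- function(path, strip_prefix = TRUE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    stop("malformed MITAB line ", bad, " in '", path,
         "': missing interactor column")
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  if (strip_prefix) {
    a <- sub("^[A-Za-z0-9_.-]+:", "", a)
    b <- sub("^[A-Za-z0-9_.-]+:", "", b)
  }
  pe_build_network(a, b)
}

#' Write a network as a two-column tab-separated edge list
#'
#' An isolated node is encoded as a self-loop line (`X TAB X`); the reader
#' drops the loop but keeps the node, so the round-trip is lossless on both
#' nodes and edges.
#'
#' @param network An igraph network.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed provenance lines.
#' @export
write_edge_list <- function(network, path, header = character()) {
  el <- igraph::as_edgelist(network, names = TRUE)
  iso <- igraph::V(network)$name[igraph::degree(network) == 0L]
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  if (nrow(el) > 0L)
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  if (length(iso) > 0L)
    writeLines(paste(iso, iso, sep = "\t"), con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `set_id TAB description TAB member1 TAB
#' member2 ...`.  Duplicate members within one line are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A list of gene sets; each element is a list with components
#'   `set_id`, `name` (the description field) and `members` (character vector).
#'   The list is named by `set_id`.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*$", lines))
  sets <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(lines[idx[k]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", idx[k], " in '", path,
           "': fewer than 3 fields")
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    sets[[k]] <- list(set_id = fields[1L], name = fields[2L],
                      members = members)
  }
  names(sets) <- vapply(sets, `[[`, character(1), "set_id")
  if (anyDuplicated(names(sets)))
    stop("duplicate set_id in '", path, "'")
  sets
}

#' Write gene sets to a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(sets, f))` is the identity on
#' `(set_id, name, members)`.
#'
#' @param sets A list of gene sets as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$name, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map a gene set onto an interaction network
#'
#' Restricts a gene set to the members present as network nodes.  Interaction
#' data never covers the whole proteome, so typically only a fraction of the
#' annotated pathway members can be mapped.
#'
#' @param network An igraph network.
#' @param gene_set A gene set (list with `set_id`, `name`, `members`).
#' @return A mapped gene set: list with `origin` (the input set),
#'   `mapped_members` (character vector, the intersection with network nodes)
#'   and `coverage` (`|mapped| / |members|`).
#' @export
map_gene_set <- function(network, gene_set) {
  nodes <- igraph::V(network)$name
  mapped <- intersect(gene_set$members, nodes)
  list(origin = gene_set,
       mapped_members = mapped,
       coverage = if (length(gene_set$members) > 0L)
         length(mapped) / length(gene_set$members) else NA_real_)
}

#' Mapping-coverage report for a gene-set collection
#'
#' One row per set with its size, mapped size and coverage, plus the mean
#' coverage over sets as an attribute (`attr(x, "mean_coverage")`).
#'
#' @param network An igraph network.
#' @param sets List of gene sets.
#' @return A `data.frame` with columns `set_id`, `size`, `mapped_size`,
#'   `coverage`; attribute `mean_coverage` holds the mean over sets (`NA` for
#'   an empty collection).
#' @export
mapping_report <- function(network, sets) {
  if (length(sets) == 0L) {
    out <- data.frame(set_id = character(), size = integer(),
                      mapped_size = integer(), coverage = numeric())
    attr(out, "mean_coverage") <- NA_real_
    return(out)
  }
  rows <- lapply(sets, function(s) {
    m <- map_gene_set(network, s)
    data.frame(set_id = s$set_id, size = length(s$members),
               mapped_size = length(m$mapped_members),
               coverage = m$coverage, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "mean_coverage") <- mean(out$coverage)
  out
}
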