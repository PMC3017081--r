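# Gene Ontology-style semantic similarity: minimal OBO / annotation readers,
# information content, Jiang-Conrath distance and the comparison of original
# vs. added proteins against a matched random-candidate null.
#
# Only the `id`, `name`, `namespace`, `is_a` and `is_obsolete` tags of OBO
# [Term] stanzas are interpreted; that is all the similarity computation
# needs.

#' Read a minimal OBO ontology
#'
#' Parses `[Term]` stanzas of an OBO 1.2 flat file, keeping term ids,
#' names, namespaces and `is_a` parent relations.  Obsolete terms are
#' dropped.  The result must be acyclic (checked lazily when ancestors are
#' first computed).
#'
#' @param path Path to the OBO file.
#' @return An object of class `"pe_ontology"`: list with `terms` (character
#'   vector), `parents` (named list, term -> character vector of is_a
#'   parents), `namespace` (named character vector), `name` (named character
#'   vector).
#' @export
read_obo <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  terms <- character(); parents <- list(); nspace <- character()
  tname <- character()
  cur <- NULL; cur_parents <- character(); cur_ns <- NA_character_
  cur_name <- NA_character_; cur_obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !cur_obsolete) {
      terms <<- c(terms, cur)
      parents[[cur]] <<- cur_parents
      nspace[cur] <<- cur_ns
      tname[cur] <<- cur_name
    }
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; cur_parents <- character(); cur_ns <- NA_character_
      cur_name <- NA_character_; cur_obsolete <- FALSE; in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term) {
      if (grepl("^id:", ln)) cur <- sub("^id:\\s*", "", ln)
      else if (grepl("^name:", ln)) cur_name <- sub("^name:\\s*", "", ln)
      else if (grepl("^namespace:", ln)) cur_ns <- sub("^namespace:\\s*", "", ln)
      else if (grepl("^is_a:", ln)) {
        p <- sub("^is_a:\\s*", "", ln)
        p <- sub("\\s*!.*$", "", p)  # strip trailing "! name" comment
        cur_parents <- c(cur_parents, p)
      } else if (grepl("^is_obsolete:\\s*true", ln)) cur_obsolete <- TRUE
    }
  }
  flush()
  parents <- lapply(parents, function(p) intersect(p, terms))
  structure(list(terms = terms, parents = parents,
                 namespace = nspace, name = tname),
            class = "pe_ontology")
}

#' Write a minimal OBO ontology
#'
#' Inverse of [read_obo()] for the tags it understands.
#'
#' @param ontology A `"pe_ontology"`.
#' @param path Output path.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ontology$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    if (!is.na(ontology$name[t]))
      writeLines(paste0("name: ", ontology$name[t]), con)
    if (!is.na(ontology$namespace[t]))
      writeLines(paste0("namespace: ", ontology$namespace[t]), con)
    for (p in ontology$parents[[t]])
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read protein-to-term annotations
#'
#' Accepts either a two-column tab-separated file (`protein TAB term`) or a
#' GAF 2.x file (detected by a `!gaf-version` header or >= 15 columns;
#' protein from column 2, term from column 5, aspect from column 9).
#'
#' @param path Path to the annotation file.
#' @param aspect Optional GAF aspect filter (`"P"`, `"F"` or `"C"`).
#' @return A named list: protein -> character vector of term ids.
#' @export
read_annotations <- function(path, aspect = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  is_gaf <- any(grepl("^!gaf-version", lines))
  lines <- lines[!grepl("^\\s*(!|#|$)", lines)]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (!is_gaf) is_gaf <- length(parts[[1L]]) >= 15L
  if (is_gaf) {
    prot <- vapply(parts, `[[`, character(1), 2L)
    term <- vapply(parts, `[[`, character(1), 5L)
    asp <- vapply(parts, `[[`, character(1), 9L)
    if (!is.null(aspect)) {
      keep <- asp == aspect
      prot <- prot[keep]; term <- term[keep]
    }
  } else {
    if (any(lengths(parts) < 2L))
      stop("malformed annotation line in '", path, "'")
    prot <- vapply(parts, `[[`, character(1), 1L)
    term <- vapply(parts, `[[`, character(1), 2L)
  }
  lapply(split(term, prot), unique)
}

#' Write annotations as a two-column TSV
#'
#' @param annotations Named list, protein -> term ids.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  prot <- rep(names(annotations), lengths(annotations))
  term <- unlist(annotations, use.names = FALSE)
  writeLines(paste(prot, term, sep = "\t"), path)
  invisible(path)
}

# Ancestor sets (including the term itself) for every term, via memoised
# depth-first traversal; detects is_a cycles.
pe_ancestors <- function(ontology) {
  anc <- vector("list", length(ontology$terms))
  names(anc) <- ontology$terms
  state <- setNames(integer(length(ontology$terms)), ontology$terms)
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop("is_a cycle detected at term '", t, "'")
    state[[t]] <<- 1L
    res <- t
    for (p in ontology$parents[[t]]) res <- union(res, visit(p))
    state[[t]] <<- 2L
    anc[[t]] <<- res
    res
  }
  for (t in ontology$terms) visit(t)
  anc
}

# Precomputed index used by all similarity computations: ancestor closure,
# per-term annotation counts under the closure, information content, and the
# per-namespace annotated-protein totals.
#' Build a semantic-similarity index
#'
#' Precomputes ancestor closures and information content for an ontology and
#' an annotation corpus.  A protein annotated to a term counts towards that
#' term and all its ancestors.  `IC(t) = -ln p(t)` with `p(t)` the fraction
#' of annotated proteins in the term's namespace annotated to `t` or any of
#' its descendants; a namespace root therefore has IC 0.
#'
#' @param ontology A `"pe_ontology"`.
#' @param annotations Named list, protein -> term ids.
#' @return An object of class `"pe_semsim_index"` with `ancestors`, `ic`,
#'   `counts`, `n_annotated` (per namespace), and the inputs.
#' @export
semsim_index <- function(ontology, annotations) {
  annotations <- lapply(annotations, function(t) intersect(t, ontology$terms))
  annotations <- annotations[lengths(annotations) > 0L]
  anc <- pe_ancestors(ontology)
  # proteins counted once per term of their annotation closure
  counts <- setNames(integer(length(ontology$terms)), ontology$terms)
  prot_ns <- list()
  for (p in names(annotations)) {
    closure <- unique(unlist(anc[annotations[[p]]], use.names = FALSE))
    counts[closure] <- counts[closure] + 1L
    prot_ns[[p]] <- unique(ontology$namespace[closure])
  }
  ns_levels <- unique(ontology$namespace)
  n_annot <- setNames(integer(length(ns_levels)), ns_levels)
  for (ns in ns_levels)
    n_annot[ns] <- sum(vapply(prot_ns, function(x) ns %in% x, logical(1)))
  ic <- setNames(rep(NA_real_, length(ontology$terms)), ontology$terms)
  usable <- counts > 0L
  tot <- n_annot[ontology$namespace[ontology$terms]]
  ic[usable] <- -log(counts[usable] / tot[usable])
  structure(list(ontology = ontology, annotations = annotations,
                 ancestors = anc, counts = counts, ic = ic,
                 n_annotated = n_annot),
            class = "pe_semsim_index")
}

pe_as_index <- function(x, annotations = NULL) {
  if (inherits(x, "pe_semsim_index")) x
  else semsim_index(x, annotations)
}

#' Information content of a term
#'
#' @param ontology A `"pe_ontology"` or a prebuilt [semsim_index()].
#' @param annotations Named list, protein -> terms (ignored when `ontology`
#'   is already an index).
#' @param term Term id.
#' @return `IC(term) = -ln p(term)`, non-negative; 0 for a namespace root.
#' @export
information_content <- function(ontology, annotations, term) {
  idx <- pe_as_index(ontology, annotations)
  if (!term %in% names(idx$ic)) stop("unknown term '", term, "'")
  v <- idx$ic[[term]]
  if (is.na(v))
    stop("term '", term, "' annotates no protein (directly or via ",
         "descendants); its information content is undefined")
  v
}

#' Jiang-Conrath distance between two terms
#'
#' `d(t1, t2) = IC(t1) + IC(t2) - 2 * IC(MICA)` where MICA is the common
#' ancestor of maximal information content.  Symmetric, zero for identical
#' terms.
#'
#' @inheritParams information_content
#' @param t1,t2 Term ids in the same namespace.
#' @return Non-negative distance.
#' @export
jc_distance <- function(ontology, annotations, t1, t2) {
  idx <- pe_as_index(ontology, annotations)
  ic1 <- information_content(idx, NULL, t1)
  ic2 <- information_content(idx, NULL, t2)
  common <- intersect(idx$ancestors[[t1]], idx$ancestors[[t2]])
  common <- common[!is.na(idx$ic[common])]
  if (length(common) == 0L)
    stop("terms '", t1, "' and '", t2, "' have no common ancestor ",
         "(different namespaces?)")
  ic1 + ic2 - 2 * max(idx$ic[common])
}

#' Average semantic similarity between two protein sets
#'
#' Collects the distinct annotated terms (restricted to `namespace` unless
#' `"all"`) of each protein set, and averages `sim = 1 / (1 + d_JC)` over all
#' term pairs (one set's terms against the other's), each distinct term pair
#' counted once.  Proteins without usable annotations are dropped with a
#' logged count.
#'
#' @inheritParams information_content
#' @param proteins_a,proteins_b Character vectors of protein identifiers.
#' @param namespace Ontology namespace to restrict to, or `"all"`.
#' @return Mean pairwise similarity in `(0, 1]`.
#' @export
set_similarity <- function(ontology, annotations, proteins_a, proteins_b,
                           namespace = "all") {
  idx <- pe_as_index(ontology, annotations)
  terms_of <- function(prots) {
    tt <- unique(unlist(idx$annotations[intersect(prots,
                                                  names(idx$annotations))],
                        use.names = FALSE))
    if (!identical(namespace, "all"))
      tt <- tt[idx$ontology$namespace[tt] == namespace]
    tt[!is.na(idx$ic[tt])]
  }
  ta <- terms_of(proteins_a)
  tb <- terms_of(proteins_b)
  if (length(ta) == 0L || length(tb) == 0L)
    stop("no annotated protein on one side; set similarity undefined")
  sims <- outer(ta, tb, Vectorize(function(x, y)
    1 / (1 + jc_distance(idx, NULL, x, y))))
  mean(sims)
}

#' Semantic-similarity validation of extension results
#'
#' For every extended set, compares the similarity between original members
#' and added proteins with a null of `n_random` same-size draws from the
#' set's candidate pool, excluding the extended membership.  The empirical
#' p-value per set is the fraction of null draws at least as similar as the
#' real extension.
#'
#' @param network An igraph network.
#' @param extension_results List of `extension_result`s (see
#'   [extend_collection()], component `results`).
#' @param ontology A `"pe_ontology"`.
#' @param annotations Named list, protein -> terms.
#' @param n_random Number of null draws per set (default 100).
#' @param seed Integer base seed; per-set seeds are derived from it and the
#'   set id.
#' @param namespace Ontology namespace restriction (default `"all"`).
#' @return A list of class `"semsim_report"`: `per_set` (`data.frame` with
#'   `set_id`, `n_added`, `real_similarity`, `mean_random_similarity`,
#'   `empirical_p`), `random_similarities` (named list), `n_random`, `seed`.
#'   Sets with no additions are skipped with a log notice.
#' @export
semsim_validation <- function(network, extension_results, ontology,
                              annotations, n_random = 100L, seed = 1L,
                              namespace = "all") {
  stopifnot(n_random >= 1L)
  idx <- pe_as_index(ontology, annotations)
  rows <- list(); rand_sims <- list()
  for (res in extension_results) {
    id <- res$set_id
    if (length(res$added) == 0L) {
      pe_log("set '", id, "' has no added proteins; skipped")
      next
    }
    real <- tryCatch(
      set_similarity(idx, NULL, res$original_mapped, res$added, namespace),
      error = function(e) NA_real_)
    if (is.na(real)) {
      pe_log("set '", id, "' has no usable annotations; skipped")
      next
    }
    pool <- setdiff(candidate_set(network, res$original_mapped),
                    c(res$original_mapped, res$added))
    k <- min(length(res$added), length(pool))
    sims <- pe_with_seed(pe_derive_seed(seed, paste0("sem:", id)), {
      vapply(seq_len(n_random), function(i) {
        draw <- sample(pool, k)
        tryCatch(set_similarity(idx, NULL, res$original_mapped, draw,
                                namespace),
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    usable <- sims[!is.na(sims)]
    rows[[id]] <- data.frame(
      set_id = id, n_added = length(res$added), real_similarity = real,
      mean_random_similarity = if (length(usable)) mean(usable) else NA_real_,
      empirical_p = if (length(usable)) mean(usable >= real) else NA_real_,
      stringsAsFactors = FALSE)
    rand_sims[[id]] <- sims
  }
  if (length(rows) == 0L)
    stop("no extension result with added proteins and usable annotations")
  structure(list(per_set = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 random_similarities = rand_sims,
                 n_random = as.integer(n_random), seed = as.integer(seed)),
            class = "semsim_report")
}
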