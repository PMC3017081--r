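# Deletion/recovery cross-validation of the extension procedure against a
# random-extension null model.
#
# For each pathway: delete a fraction of members (among those connected to
# another member), extend the reduced set, and count how many deleted members
# the extension recovers.  The same count is computed for size-matched random
# draws from the candidate pool.  The pooled empirical p-value is the relative
# frequency of (pathway, random draw) cases in which the random extension
# recovers strictly more deleted members than the method.

#' Delete a fraction of a mapped set's members
#'
#' Members eligible for deletion are those connected to at least one other
#' member of the set.  The deletion quota is `ceiling(fraction * |set|)`.
#' Deletions are drawn one at a time, recomputing eligibility among the
#' remaining members after each removal, until the quota is met or no
#' eligible member remains.
#'
#' @param mapped_set Character vector of mapped members.
#' @param network An igraph network.
#' @param fraction Fraction to delete, in (0, 1).  Default 0.1.
#' @param seed Integer seed making the draw reproducible.
#' @return A list with `reduced` (the remaining members) and `deleted`
#'   (in deletion order).
#' @export
delete_fraction <- function(mapped_set, network, fraction = 0.1, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  mapped_set <- unique(as.character(mapped_set))
  pe_check_nodes(network, mapped_set)
  quota <- ceiling(fraction * length(mapped_set))
  adj <- pe_adj_list(network)
  pe_with_seed(seed, {
    remaining <- mapped_set
    deleted <- character()
    while (length(deleted) < quota) {
      eligible <- remaining[vapply(remaining, function(u) {
        length(intersect(adj[[u]], setdiff(remaining, u))) > 0L
      }, logical(1))]
      if (length(eligible) == 0L) break
      pick <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      deleted <- c(deleted, pick)
      remaining <- setdiff(remaining, pick)
    }
    list(reduced = remaining, deleted = deleted)
  })
}

#' Random extension of a reduced set
#'
#' Uniform sample without replacement of `min(k, |candidates|)` nodes from
#' the candidate pool of the reduced set (see [candidate_set()]).
#'
#' @param reduced_set Character vector of members after deletion.
#' @param network An igraph network.
#' @param k Target extension size (the size of the method's extension).
#' @param seed Integer seed.
#' @return Character vector of sampled nodes (possibly empty).
#' @export
random_extension <- function(reduced_set, network, k, seed = 1L) {
  stopifnot(k >= 0)
  cands <- candidate_set(network, reduced_set)
  m <- min(k, length(cands))
  if (m == 0L) return(character())
  pe_with_seed(seed, sample(cands, m))
}

#' Deletion/recovery cross-validation
#'
#' Runs the full cross-validation over a gene-set collection: per eligible
#' set, delete `fraction` of the mapped members, extend the reduced set with
#' [extend_set()], count recovered deleted members, and compare with
#' `n_random` random extensions of the same size.  The pooled empirical
#' p-value is the fraction of the `n_sets * n_random` comparisons in which a
#' random extension recovered strictly more deleted members (ties favour the
#' method).
#'
#' Per-set seeds are derived from `seed` and the set id, so the report does
#' not depend on the order of the sets in the collection.
#'
#' @param network An igraph network.
#' @param sets List of gene sets.
#' @param config An [extension_config()]; `min_set_size` controls
#'   eligibility.
#' @param fraction Deletion fraction (default 0.1).
#' @param n_random Number of random extensions per set (default 100).
#' @param seed Integer base seed.
#' @return A list of class `"crossval_report"`: `per_set` (`data.frame` with
#'   `set_id`, `n_mapped`, `n_deleted`, `n_added`, `n_recovered`,
#'   `mean_random_recovered`, `n_random_exceed`), `recoveries_random`
#'   (named list of integer vectors), `pooled_p`, `n_random`, `seed`.
#' @export
crossvalidate <- function(network, sets, config = extension_config(),
                          fraction = 0.1, n_random = 100L, seed = 1L) {
  stopifnot(n_random >= 1L)
  rows <- list()
  rec_rand <- list()
  for (s in sets) {
    if (length(s$members) < config$min_set_size) next
    m <- map_gene_set(network, s)
    if (length(m$mapped_members) < 2L) next
    del <- delete_fraction(m$mapped_members, network, fraction,
                           seed = pe_derive_seed(seed, paste0("del:", s$set_id)))
    if (length(del$reduced) < 2L) next
    res <- extend_set(network, del$reduced, config)
    recovered <- length(intersect(res$added, del$deleted))
    k <- length(res$added)
    rand_rec <- vapply(seq_len(n_random), function(i) {
      re <- random_extension(del$reduced, network, k,
                             seed = pe_derive_seed(seed,
                                                   paste0("rnd:", s$set_id, ":", i)))
      length(intersect(re, del$deleted))
    }, integer(1))
    rows[[s$set_id]] <- data.frame(
      set_id = s$set_id, n_mapped = length(m$mapped_members),
      n_deleted = length(del$deleted), n_added = k,
      n_recovered = recovered,
      mean_random_recovered = mean(rand_rec),
      n_random_exceed = sum(rand_rec > recovered),
      stringsAsFactors = FALSE)
    rec_rand[[s$set_id]] <- rand_rec
  }
  if (length(rows) == 0L)
    stop("no eligible gene set for cross-validation")
  per_set <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  total_cases <- nrow(per_set) * n_random
  pooled_p <- sum(per_set$n_random_exceed) / total_cases
  if (pooled_p == 0)
    pe_log("pooled_p is 0; resolution is 1/",
           total_cases, " = ", signif(1 / total_cases, 3))
  structure(list(per_set = per_set, recoveries_random = rec_rand,
                 pooled_p = pooled_p, n_random = as.integer(n_random),
                 seed = as.integer(seed), fraction = fraction),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("Deletion/recovery cross-validation\n",
      " sets: ", nrow(x$per_set),
      "; deletion fraction: ", x$fraction,
      "; random extensions per set: ", x$n_random, "\n",
      " pooled empirical p-value: ", signif(x$pooled_p, 4), "\n", sep = "")
  invisible(x)
}
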