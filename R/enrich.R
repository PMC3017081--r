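# One-tailed Fisher over-representation analysis with Benjamini-Hochberg
# adjustment, comparing a gene list's enrichment in original versus extended
# gene sets.

#' One-tailed Fisher over-representation p-value
#'
#' Upper-tail hypergeometric probability `P(X >= overlap)` of drawing at
#' least `overlap` set members in a sample of `list_size` from a universe of
#' `universe_size` containing `set_size` set members.  Equivalent to the
#' one-tailed Fisher exact test on the 2x2 overlap table.
#'
#' @param universe_size,set_size,list_size,overlap Non-negative counts with
#'   `overlap <= min(set_size, list_size)` and
#'   `set_size, list_size <= universe_size`.
#' @return The p-value.
#' @export
fisher_ora <- function(universe_size, set_size, list_size, overlap) {
  if (overlap > min(set_size, list_size) || set_size > universe_size ||
      list_size > universe_size || any(c(universe_size, set_size,
                                         list_size, overlap) < 0))
    stop("inconsistent contingency counts")
  stats::phyper(overlap - 1, set_size, universe_size - set_size, list_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i}(p_(j) * m / j)`, capped at 1, returned in the input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
benjamini_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Compare gene-list enrichment before and after extension
#'
#' Runs the one-tailed Fisher ORA of `gene_list` against every original set
#' and every extended set, adjusting each family separately with
#' Benjamini-Hochberg (paired before/after q-values per set).  Gene-list
#' members outside the universe are dropped with a logged count.
#'
#' @param original_sets,extended_sets Gene-set lists with matching
#'   `set_id`s; each extended set must contain its original memberwise.
#' @param gene_list Character vector of genes of interest (e.g. mutated
#'   genes).
#' @param universe Character vector defining the background population,
#'   typically all network proteins.
#' @return A `data.frame` with one row per set: `set_id`, `size_before`,
#'   `size_after`, `overlap_before`, `overlap_after`, `p_before`, `p_after`,
#'   `q_before`, `q_after`, `overlap_members` and `added_overlap_members`
#'   (comma-separated), sorted by `q_after`.
#' @export
enrich_compare <- function(original_sets, extended_sets, gene_list,
                           universe) {
  ids <- names(original_sets)
  if (!setequal(ids, names(extended_sets)))
    stop("set_id mismatch between original and extended collections")
  universe <- unique(as.character(universe))
  dropped <- setdiff(gene_list, universe)
  if (length(dropped) > 0L)
    pe_log("dropped ", length(dropped),
           " gene-list member(s) outside the universe")
  gl <- intersect(unique(gene_list), universe)
  one_family <- function(sets) {
    rows <- lapply(ids, function(id) {
      members <- intersect(sets[[id]]$members, universe)
      ov <- intersect(members, gl)
      data.frame(set_id = id, size = length(members), overlap = length(ov),
                 p = fisher_ora(length(universe), length(members),
                                length(gl), length(ov)),
                 members = I(list(ov)), stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    fam$q <- benjamini_adjust(fam$p)
    fam
  }
  before <- one_family(original_sets)
  after <- one_family(extended_sets)
  added_overlap <- vapply(ids, function(id) {
    added <- setdiff(extended_sets[[id]]$members,
                     original_sets[[id]]$members)
    paste(intersect(intersect(added, universe), gl), collapse = ",")
  }, character(1))
  out <- data.frame(
    set_id = ids,
    size_before = before$size, size_after = after$size,
    overlap_before = before$overlap, overlap_after = after$overlap,
    p_before = before$p, p_after = after$p,
    q_before = before$q, q_after = after$q,
    overlap_members = vapply(after$members, paste, character(1),
                             collapse = ","),
    added_overlap_members = added_overlap,
    stringsAsFactors = FALSE)
  out[order(out$q_after, out$set_id), , drop = FALSE]
}
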