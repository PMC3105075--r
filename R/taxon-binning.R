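# Top-hit taxonomic binning with lowest-common-ancestor tie resolution.

#' Assign queries to taxa from their best alignment hit
#'
#' For each query, hits with e-value above `max_evalue` are discarded; the
#' remaining hits are ranked by bit score (descending) then e-value
#' (ascending). A unique best hit assigns its subject taxon; exact ties on
#' (bit score, e-value) pointing at different taxa are resolved to the
#' lowest common ancestor of the tied subjects. Queries with no surviving
#' hit are `"unassigned"`. Hits with an empty subject taxon cannot support
#' an assignment and are dropped up front.
#'
#' @param hits Alignment hits (see [read_hit_table()]).
#' @param tax A `taxonomy` object; every non-empty subject taxon among the
#'   significant hits must be present in it.
#' @param max_evalue Significance threshold (inclusive).
#' @param query_ids Optional character vector defining the query universe;
#'   defaults to the queries appearing in `hits`.
#' @return Data frame `query_id`, `taxon_id` (or `"unassigned"`), `basis`
#'   (`top_hit`, `lca_of_ties`, or `none`).
#' @export
bin_top_hit <- function(hits, tax, max_evalue = 1e-5, query_ids = NULL) {
  if (is.null(query_ids)) query_ids <- unique(hits$query_id)
  keep <- hits$e_value <= max_evalue & hits$subject_taxon != ""
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) > 0) {
    unknown <- setdiff(unique(h$subject_taxon), names(tax$index))
    if (length(unknown) > 0) {
      stop("subject taxon absent from taxonomy: ", unknown[1],
           call. = FALSE)
    }
  }
  assign_one <- function(df) {
    best_bit <- max(df$bit_score)
    df <- df[df$bit_score == best_bit, , drop = FALSE]
    best_e <- min(df$e_value)
    df <- df[df$e_value == best_e, , drop = FALSE]
    taxa <- unique(df$subject_taxon)
    if (length(taxa) == 1) c(taxa, "top_hit")
    else c(tax_lca(tax, taxa), "lca_of_ties")
  }
  res <- matrix("", nrow = length(query_ids), ncol = 2)
  if (nrow(h) > 0) {
    split_hits <- split(h, h$query_id)
    assigned <- t(vapply(split_hits, assign_one, character(2)))
    m <- match(query_ids, rownames(assigned))
    has <- !is.na(m)
    res[has, ] <- assigned[m[has], , drop = FALSE]
  }
  out <- data.frame(
    query_id = query_ids,
    taxon_id = ifelse(res[, 1] == "", "unassigned", res[, 1]),
    basis = ifelse(res[, 2] == "", "none", res[, 2]),
    stringsAsFactors = FALSE
  )
  out
}

#' Aggregate taxon assignments at a taxonomic rank
#'
#' Each assignment is lifted to its ancestor at the requested rank. An
#' assigned taxon whose lineage has no node of that rank (e.g. a hit
#' resolved above the rank by an LCA tie-break) is binned as `"other"`;
#' unassigned queries are kept as `"unassigned"`. Percentages are reported
#' both over the full query universe (summing to 100 including
#' unassigned) and over the assigned subset.
#'
#' @param assignments Data frame from [bin_top_hit()].
#' @param tax A `taxonomy` object.
#' @param rank One of kingdom/phylum/class/order/family/genus/species.
#' @param n_universe Optional universe size override (defaults to
#'   `nrow(assignments)`).
#' @return Data frame `taxon_id`, `name`, `count`, `percent_universe`,
#'   `percent_assigned`, sorted by descending count.
#' @export
aggregate_rank <- function(assignments, tax, rank, n_universe = NULL) {
  rank <- match.arg(rank, setdiff(TAXONOMY_RANKS, "root"))
  n_total <- n_universe %||% nrow(assignments)
  lifted <- vapply(assignments$taxon_id, function(id) {
    if (id == "unassigned") return("unassigned")
    anc <- tax_ancestor_at_rank(tax, id, rank)
    if (is.na(anc)) "other" else anc
  }, character(1), USE.NAMES = FALSE)
  counts <- sort(table(lifted), decreasing = TRUE)
  n_assigned <- sum(assignments$taxon_id != "unassigned")
  ids <- names(counts)
  out <- data.frame(
    taxon_id = ids,
    name = ifelse(ids %in% names(tax$index),
                  tax$nodes$name[tax$index[ids]], ids),
    count = as.integer(counts),
    percent_universe = if (n_total > 0) 100 * as.integer(counts) / n_total
                       else 0,
    percent_assigned = ifelse(ids == "unassigned", NA_real_,
                              if (n_assigned > 0)
                                100 * as.integer(counts) / n_assigned
                              else NA_real_),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out
}

#' Format a percentage the way community survey reports print them
#'
#' Values of 10 or more are rounded to whole percent ("31"); smaller values
#' keep one decimal ("3.4").
#'
#' @param x Numeric percentage(s).
#' @return Character vector.
#' @export
format_percent <- function(x) {
  ifelse(x >= 10, formatC(round(x), format = "d"),
         formatC(round(x, 1), format = "f", digits = 1))
}
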