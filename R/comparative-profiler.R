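# Comparative GH-family profiling: percentage matrix, Pearson-correlation
# distances, and UPGMA clustering with deterministic tie-breaking.

#' Build a samples-by-families profile matrix
#'
#' Counts are filled to the family universe (missing families become 0);
#' each row is normalised to percentages of its own total. Rows whose
#' counts are all zero are flagged empty and excluded from clustering.
#'
#' @param per_sample_counts Named list: sample -> named numeric vector of
#'   family counts.
#' @param family_universe Optional character vector fixing the family
#'   (column) order; defaults to the sorted union of observed families.
#' @return A `profile_matrix`: list with `counts`, `percents` (matrices,
#'   samples in rows) and `empty` (logical per sample).
#' @export
build_profile_matrix <- function(per_sample_counts, family_universe = NULL) {
  if (length(per_sample_counts) == 0) {
    stop("no samples given", call. = FALSE)
  }
  if (is.null(family_universe)) {
    family_universe <- sort(unique(unlist(lapply(per_sample_counts, names))))
  }
  counts <- t(vapply(per_sample_counts, function(v) {
    if (any(v < 0)) stop("negative family count", call. = FALSE)
    out <- stats::setNames(numeric(length(family_universe)), family_universe)
    common <- intersect(names(v), family_universe)
    out[common] <- v[common]
    out
  }, numeric(length(family_universe))))
  rownames(counts) <- names(per_sample_counts)
  rs <- rowSums(counts)
  empty <- rs == 0
  if (any(empty)) {
    warning("sample(s) with all-zero counts excluded from clustering: ",
            paste(rownames(counts)[empty], collapse = ", "), call. = FALSE)
  }
  percents <- counts
  percents[!empty, ] <- 100 * counts[!empty, , drop = FALSE] / rs[!empty]
  percents[empty, ] <- NA_real_
  structure(list(counts = counts, percents = percents, empty = empty),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile matrix:", nrow(x$counts), "samples x", ncol(x$counts),
      "families\n")
  invisible(x)
}

#' Pearson-correlation distance between sample profiles
#'
#' Distance between two samples is `1 - r`, with `r` the Pearson
#' correlation of their percentage rows; values lie in `[0, 2]`.
#'
#' @param pm A `profile_matrix` with at least two non-empty rows.
#' @return A symmetric `dist` object (zero diagonal).
#' @export
pearson_distance <- function(pm) {
  p <- pm$percents[!pm$empty, , drop = FALSE]
  if (nrow(p) < 2) stop("need at least two non-empty samples",
                        call. = FALSE)
  sds <- apply(p, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile for sample: ",
         rownames(p)[sds == 0][1], call. = FALSE)
  }
  r <- stats::cor(t(p), method = "pearson")
  stats::as.dist(1 - r)
}

#' UPGMA clustering
#'
#' Unweighted pair group method with arithmetic mean: repeatedly merge the
#' pair of clusters at minimal distance; the new cluster's distance to any
#' other is the size-weighted arithmetic mean of its constituents'
#' distances (i.e. the average of all between-member distances). The merge
#' height is half the merge distance, so the cophenetic distance between
#' two leaves equals the average linkage distance at which they join. Ties
#' in the minimal distance are broken by the lexicographically smallest
#' pair of cluster representative labels (each cluster represented by its
#' smallest member label), making the output platform-independent.
#'
#' @param d A `dist` object (or symmetric matrix) over >= 2 items with
#'   finite entries.
#' @return An object of class `c("upgma", "hclust")` with heights equal to
#'   merge distance / 2; usable with [stats::cophenetic()], [plot()], and
#'   convertible with [ape::as.phylo()].
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need at least two items to cluster", call. = FALSE)
  if (any(!is.finite(dm))) stop("non-finite value in distance matrix",
                                call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  active <- seq_len(n)            # column indices of live clusters
  size <- rep(1L, n)
  id <- -seq_len(n)               # hclust ids: negative leaf, positive merge
  rep_label <- labels             # smallest member label per cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  D <- dm
  diag(D) <- Inf

  for (step in seq_len(n - 1)) {
    sub <- D[active, active, drop = FALSE]
    dmin <- min(sub)
    # candidate pairs at the minimum; pick lexicographically smallest
    idx <- which(sub <= dmin, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    cand_i <- active[idx[, 1]]
    cand_j <- active[idx[, 2]]
    key_a <- pmin(rep_label[cand_i], rep_label[cand_j])
    key_b <- pmax(rep_label[cand_i], rep_label[cand_j])
    ord <- order(key_a, key_b)[1]
    i <- cand_i[ord]; j <- cand_j[ord]

    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- dmin / 2
    # average-linkage update into slot i
    others <- setdiff(active, c(i, j))
    if (length(others) > 0) {
      newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    rep_label[i] <- min(rep_label[i], rep_label[j])
    active <- setdiff(active, j)
  }

  tree <- structure(list(
    merge = merge, height = height,
    order = .hclust_order(merge),
    labels = labels, method = "upgma",
    call = match.call(), dist.method = "user"
  ), class = c("upgma", "hclust"))
  tree
}

# leaf ordering for plotting, by recursive traversal of the merge matrix
.hclust_order <- function(merge) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  walk(nrow(merge))
}

#' Export a dendrogram as a newick string
#'
#' @param tree An `upgma`/`hclust` object.
#' @return A newick string (with branch lengths derived from merge
#'   heights).
#' @export
as_newick <- function(tree) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy)
}

#' Read per-sample family count profiles from TSV
#'
#' Expects samples in rows (first column `sample`), families in the header.
#'
#' @param path Path to a tab-separated counts table.
#' @return Named list sample -> named numeric count vector, suitable for
#'   [build_profile_matrix()].
#' @export
read_profile_counts <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "sample") {
    stop("first column of a profile counts table must be 'sample'",
         call. = FALSE)
  }
  samples <- df$sample
  mat <- as.matrix(df[, -1, drop = FALSE])
  stats::setNames(
    lapply(seq_along(samples), function(i)
      stats::setNames(as.numeric(mat[i, ]), colnames(mat))),
    samples)
}
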