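# Expression and coverage summarisation; run-level summary statistics.

#' Count mapped reads per contig
#'
#' @param origins Data frame `read_id`, `contig_id` (one row per mapped
#'   read), or a character vector of contig ids (one element per read).
#' @param contig_ids Character vector of known contigs; contigs with no
#'   reads are reported with count 0.
#' @return Named integer vector contig_id -> read count.
#' @export
count_reads_per_contig <- function(origins, contig_ids) {
  v <- if (is.data.frame(origins)) origins$contig_id else origins
  unknown <- setdiff(unique(v), contig_ids)
  if (length(unknown) > 0) {
    stop("read mapped to unknown contig: ", unknown[1], call. = FALSE)
  }
  tab <- table(factor(v, levels = contig_ids))
  stats::setNames(as.integer(tab), contig_ids)
}

#' Fold coverage of a contig
#'
#' `read_count * mean_read_len / contig_len`, dimensionless.
#'
#' @param read_count Number of reads mapped to the contig.
#' @param mean_read_len Mean read length in nt.
#' @param contig_len Contig length in bp (> 0).
#' @return Fold coverage (vectorised).
#' @export
coverage <- function(read_count, mean_read_len, contig_len) {
  if (any(contig_len <= 0)) stop("contig_len must be > 0", call. = FALSE)
  read_count * mean_read_len / contig_len
}

#' Rank annotated records by expression
#'
#' @param records Data frame with at least `contig_id` and `read_count`.
#' @param min_reads Minimum read count (inclusive).
#' @return The qualifying rows sorted by descending `read_count`, ties
#'   broken by `contig_id`.
#' @export
rank_by_expression <- function(records, min_reads = 10000) {
  keep <- records[records$read_count >= min_reads, , drop = FALSE]
  keep <- keep[order(-keep$read_count, keep$contig_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Gene discovery rate per gigabase
#'
#' @param n_genes Number of genes identified.
#' @param total_gigabases Sequencing yield in Gb (> 0).
#' @return Genes per gigabase, rounded to the nearest integer.
#' @export
discovery_rate <- function(n_genes, total_gigabases) {
  if (total_gigabases <= 0) stop("total_gigabases must be > 0",
                                 call. = FALSE)
  round(n_genes / total_gigabases)
}

#' Ratio of two discovery rates
#'
#' @param rate_a,rate_b Rates in the same units; `rate_b` > 0.
#' @return Fold difference, one decimal.
#' @export
rate_ratio <- function(rate_a, rate_b) {
  if (rate_b <= 0) stop("rate_b must be > 0", call. = FALSE)
  round(rate_a / rate_b, 1)
}

#' Total sequencing yield in gigabases
#'
#' Computed as read count times mean read length (the summary-arithmetic
#' path); pass per-read lengths to `read_lengths` for the exact-sum path.
#'
#' @param n_reads Number of reads.
#' @param mean_read_len Mean read length in nt.
#' @param read_lengths Optional integer vector of per-read lengths; when
#'   given, the exact sum is used instead.
#' @param digits Decimal places for reporting (Gb), default one.
#' @return Total gigabases, rounded.
#' @export
total_gigabases <- function(n_reads, mean_read_len, read_lengths = NULL,
                            digits = 1) {
  bases <- if (!is.null(read_lengths)) sum(as.numeric(read_lengths))
           else n_reads * mean_read_len
  round(bases / 1e9, digits)
}

#' GC content of sequences
#'
#' `(G + C) / (A + C + G + T) * 100`; `N` bases are excluded from the
#' denominator. A sequence of only `N`s yields `NA`.
#'
#' @param x A `DNAStringSet` or character vector of sequences.
#' @return Numeric vector of GC percentages.
#' @export
gc_content <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  freq <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- rowSums(freq[, c("C", "G"), drop = FALSE])
  ifelse(acgt == 0, NA_real_, 100 * gc / acgt)
}

#' Mean GC content per read category
#'
#' Read-weighted: each sequence contributes its own GC percentage with
#' equal weight; all-`N` sequences are dropped from their category mean.
#'
#' @param x A `DNAStringSet` or character vector of sequences.
#' @param categories Character vector of category labels, one per
#'   sequence.
#' @return Named numeric vector category -> mean GC percent.
#' @export
gc_by_category <- function(x, categories) {
  stopifnot(length(x) == length(categories))
  gc <- gc_content(x)
  out <- tapply(gc, categories, mean, na.rm = TRUE)
  stats::setNames(as.numeric(out), names(out))
}

#' Run-level summary statistics
#'
#' Mirrors the headline statistics of a metatranscriptome run: read and
#' contig counts and mean lengths, total gigabases (one decimal), ncRNA
#' count and percentage (one decimal), GC percentages per category (one
#' decimal), and taxon bin percentages at the requested rank.
#'
#' @param reads Named `DNAStringSet` of reads (may be empty).
#' @param contigs Named `DNAStringSet` of contigs (may be empty).
#' @param ncrna_calls Calls data frame from [classify_ncrna()], or `NULL`.
#' @param assignments Assignments from [bin_top_hit()], or `NULL`.
#' @param tax Taxonomy used for aggregation (required when `assignments`
#'   given).
#' @param rank Rank for taxon percentages.
#' @return A named list of summary statistics.
#' @export
summarize_run <- function(reads, contigs, ncrna_calls = NULL,
                          assignments = NULL, tax = NULL,
                          rank = "kingdom") {
  n_reads <- length(reads)
  mean_read_len <- if (n_reads > 0) mean(Biostrings::width(reads)) else 0
  n_contigs <- length(contigs)
  out <- list(
    n_reads = n_reads,
    mean_read_length = round(mean_read_len, 1),
    total_gb = if (n_reads > 0)
      total_gigabases(n_reads, mean_read_len,
                      read_lengths = Biostrings::width(reads)) else 0,
    n_contigs = n_contigs,
    mean_contig_length = if (n_contigs > 0)
      round(mean(Biostrings::width(contigs)), 1) else 0,
    gc_contigs = if (n_contigs > 0)
      round(mean(gc_content(contigs), na.rm = TRUE), 1) else NA
  )
  if (!is.null(ncrna_calls) && n_reads > 0) {
    is_nc <- ncrna_calls$is_ncrna[match(names(reads), ncrna_calls$read_id)]
    is_nc[is.na(is_nc)] <- FALSE
    out$n_ncrna <- sum(is_nc)
    out$ncrna_percent <- round(100 * sum(is_nc) / n_reads, 1)
    gc <- gc_by_category(reads, ifelse(is_nc, "ncRNA", "coding"))
    out$gc_ncrna_reads <- round(unname(gc["ncRNA"]), 1)
    out$gc_coding_reads <- round(unname(gc["coding"]), 1)
  }
  if (!is.null(assignments)) {
    stopifnot(!is.null(tax))
    agg <- aggregate_rank(assignments, tax, rank)
    out$taxon_bins <- stats::setNames(
      as.list(round(agg$percent_universe, 1)), agg$taxon_id)
  }
  out
}
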