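# Non-coding RNA read classification and rRNA-depletion efficiency.

#' Classify reads as non-coding RNA
#'
#' A read is called ncRNA when it has an alignment hit against the rRNA
#' database passing the threshold rule -- e-value at or below `max_evalue`
#' (or, when the e-value is missing, bit score at or above `min_bit`) with
#' query overlap of at least `min_overlap` bp -- or when it was flagged by
#' an external rRNA/tRNA model scan (`hmm_flags`). The two evidence routes
#' are combined by union. Overlap of a hit spanning `q_start..q_end` is
#' `q_end - q_start + 1` (1-based inclusive coordinates).
#'
#' @param read_ids Character vector: the full read universe.
#' @param hits Alignment hits of reads against the rRNA database
#'   (see [read_hit_table()]); may be empty.
#' @param hmm_flags Character vector of read ids flagged by the model-scan
#'   route (rRNA/tRNA), folded into one flag set.
#' @param max_evalue Maximum e-value (inclusive).
#' @param min_bit Minimum bit score (inclusive), used only when a hit's
#'   e-value is missing (`NA`).
#' @param min_overlap Minimum query overlap in bp (inclusive).
#' @return A list with `calls` (data frame `read_id`, `is_ncrna`,
#'   `evidence` in blast_rule/hmm_flag/both/none), `n_ncrna`, and
#'   `fraction` (= n_ncrna / length(read_ids)).
#' @export
classify_ncrna <- function(read_ids, hits, hmm_flags = character(),
                           max_evalue = 1e-5, min_bit = 52,
                           min_overlap = 50) {
  stopifnot(max_evalue > 0, min_bit > 0, min_overlap > 0)
  if (anyDuplicated(read_ids)) {
    stop("duplicate read ids in read universe", call. = FALSE)
  }
  if (nrow(hits) > 0) {
    unknown <- setdiff(unique(hits$query_id), read_ids)
    if (length(unknown) > 0) {
      stop("hit read id absent from read universe: ", unknown[1],
           call. = FALSE)
    }
    overlap <- hits$q_end - hits$q_start + 1
    sig_e <- !is.na(hits$e_value) & hits$e_value <= max_evalue
    sig_bit <- is.na(hits$e_value) & hits$bit_score >= min_bit
    pass <- (sig_e | sig_bit) & overlap >= min_overlap
    blast_set <- unique(hits$query_id[pass])
  } else {
    blast_set <- character()
  }
  unknown_flag <- setdiff(hmm_flags, read_ids)
  if (length(unknown_flag) > 0) {
    stop("hmm-flagged read id absent from read universe: ", unknown_flag[1],
         call. = FALSE)
  }
  by_blast <- read_ids %in% blast_set
  by_hmm <- read_ids %in% hmm_flags
  evidence <- ifelse(by_blast & by_hmm, "both",
              ifelse(by_blast, "blast_rule",
              ifelse(by_hmm, "hmm_flag", "none")))
  calls <- data.frame(read_id = read_ids,
                      is_ncrna = by_blast | by_hmm,
                      evidence = evidence,
                      stringsAsFactors = FALSE)
  n_nc <- sum(calls$is_ncrna)
  list(calls = calls, n_ncrna = n_nc,
       fraction = if (length(read_ids) > 0) n_nc / length(read_ids) else 0)
}

#' Estimate rRNA-depletion efficiency from the surviving ncRNA fraction
#'
#' Given an assumed pre-depletion ncRNA fraction `c0` and an observed
#' post-depletion ncRNA read fraction `f`, with mRNA assumed fully
#' retained, the removed fraction of the original ncRNA is
#' \deqn{r = 1 - \frac{(1 - c_0)\, f}{c_0 (1 - f)}}
#' clamped to `[0, 1]`. With `c0 = 0.95` and `f = 0.184` this gives
#' approximately 0.99, i.e. about 99\% of the original ribosomal RNA
#' removed.
#'
#' @param observed_fraction Observed ncRNA read fraction `f`, in `[0, 1)`.
#' @param original_fraction Assumed original ncRNA fraction `c0`, in
#'   `(0, 1)`.
#' @return Removed fraction `r` in `[0, 1]`.
#' @export
estimate_removal_efficiency <- function(observed_fraction,
                                        original_fraction = 0.95) {
  f <- observed_fraction
  c0 <- original_fraction
  if (!is.finite(f) || f < 0 || f >= 1) {
    stop("observed_fraction must be in [0, 1)", call. = FALSE)
  }
  if (!is.finite(c0) || c0 <= 0 || c0 >= 1) {
    stop("original_fraction must be in (0, 1)", call. = FALSE)
  }
  r <- 1 - ((1 - c0) * f) / (c0 * (1 - f))
  min(1, max(0, r))
}
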