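# Collector's-curve rarefaction of category richness versus sequencing
# effort.

#' Collector's curve of category richness
#'
#' For each effort fraction `f` and each replicate, `floor(f * N)` reads
#' are subsampled without replacement and the number of distinct
#' categories among them is counted; the curve reports the mean and sd
#' across replicates. Subsampling within one replicate uses prefixes of a
#' single random permutation, so each replicate's curve is non-decreasing
#' and the subset at each fraction is uniform over subsets of that size.
#'
#' @param categories Character vector of per-read categories (gene
#'   accession or functional group), or a data frame with columns
#'   `read_id`, `category`.
#' @param fractions Increasing effort fractions in `(0, 1]`.
#' @param n_reps Number of replicate subsamples (>= 1).
#' @param seed Integer seed.
#' @return A `rarefaction_curve`: data frame `fraction`, `mean_richness`,
#'   `sd_richness`, with attributes `n_reps`, `seed`, `n_reads`,
#'   `total_richness`.
#' @export
collectors_curve <- function(categories,
                             fractions = seq(0.05, 1, by = 0.05),
                             n_reps = 10L, seed = 1L) {
  if (is.data.frame(categories)) categories <- categories$category
  if (length(categories) == 0) stop("empty category table", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (is.unsorted(fractions, strictly = TRUE) ||
      any(fractions <= 0) || any(fractions > 1)) {
    stop("fractions must be strictly increasing and in (0, 1]",
         call. = FALSE)
  }
  n <- length(categories)
  m <- pmin(n, floor(fractions * n))
  set.seed(seed)
  rich <- matrix(0, nrow = n_reps, ncol = length(fractions))
  for (r in seq_len(n_reps)) {
    perm <- categories[sample.int(n)]
    cum_rich <- cumsum(!duplicated(perm))
    rich[r, ] <- ifelse(m >= 1, cum_rich[pmax(m, 1)], 0)
  }
  out <- data.frame(
    fraction = fractions,
    mean_richness = colMeans(rich),
    sd_richness = apply(rich, 2, stats::sd)
  )
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  attr(out, "n_reads") <- n
  attr(out, "total_richness") <- length(unique(categories))
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Effort needed to reach a target richness fraction
#'
#' Returns the smallest effort fraction at which the mean richness reaches
#' `target_fraction` of the total richness, by linear interpolation
#' between evaluated curve points (with an implicit origin at zero effort,
#' zero richness). The curve must extend to effort 1.0.
#'
#' @param curve A `rarefaction_curve` from [collectors_curve()].
#' @param target_fraction Target fraction of total richness, in `(0, 1]`.
#' @return Effort fraction in `(0, 1]`.
#' @export
effort_at_richness <- function(curve, target_fraction = 0.8) {
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must be in (0, 1]", call. = FALSE)
  }
  if (abs(curve$fraction[nrow(curve)] - 1) > 1e-12) {
    stop("curve must cover effort up to 1.0", call. = FALSE)
  }
  total <- attr(curve, "total_richness")
  if (is.null(total)) total <- curve$mean_richness[nrow(curve)]
  target <- target_fraction * total
  f <- c(0, curve$fraction)
  r <- c(0, curve$mean_richness)
  for (i in seq_along(f)[-1]) {
    if (r[i] >= target) {
      if (r[i] == r[i - 1]) return(f[i])
      return(f[i - 1] + (target - r[i - 1]) / (r[i] - r[i - 1]) *
               (f[i] - f[i - 1]))
    }
  }
  1
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("collector's curve:", attr(x, "n_reads"), "reads,",
      attr(x, "total_richness"), "categories,",
      attr(x, "n_reps"), "replicates\n")
  print.data.frame(x, ...)
  invisible(x)
}
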