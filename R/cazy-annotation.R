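# CAZy module annotation: the staged model-to-family association procedure
# and module calling on contigs/reads.
#
# Route of a domain model to a family label:
#   Step A: families with a directly associated profile model (given map).
#   Step B: models associated to families by searching all family members
#           against the profile database; a model is conservatively accepted
#           for a family only when every implicated family passes 80%
#           member coverage (single family -> its label; several closely
#           related families -> a combined "X/Y" class).
#   Step C: families without any profile model, called from alignment hits
#           against representative member sequences (score cutoff 52).
#   Step D: families with neither a model nor representatives, represented
#           by externally built profile models supplied through the same
#           direct map with step = "D".

#' Build the model-to-family association table
#'
#' For each candidate model, collect the set of families whose members hit
#' it. A single-family model is accepted when at least `min_coverage` of
#' that family's members conform to the model; a model hit by members of
#' several families is accepted as a combined class (labels sorted and
#' joined by `/`) only when every implicated family passes coverage.
#' Otherwise the model is rejected: `low_coverage` when one family fails
#' its coverage alone, `impure` when several families are implicated and
#' not all pass.
#'
#' @param family_defs Family universe (see [default_family_defs()]).
#' @param member_model_hits Data frame `member_id`, `model_id`,
#'   `significant` (logical). Every member id must belong to exactly one
#'   family.
#' @param min_coverage Member coverage threshold (inclusive), default 0.80.
#' @return Data frame with columns `model_id`, `label`, `step`,
#'   `accepted`, `rejection_reason` (one of `none`, `impure`,
#'   `low_coverage`), sorted by `model_id`. Order-independent in its input.
#' @export
build_association_table <- function(family_defs, member_model_hits,
                                    min_coverage = 0.80) {
  fam_of <- rep(family_defs$family_id,
                lengths(family_defs$member_ids))
  names(fam_of) <- unlist(family_defs$member_ids)
  fam_size <- stats::setNames(lengths(family_defs$member_ids),
                              family_defs$family_id)
  h <- member_model_hits[member_model_hits$significant, , drop = FALSE]
  unknown <- setdiff(unique(h$member_id), names(fam_of))
  if (length(unknown) > 0) {
    stop("member id not in any family definition: ", unknown[1],
         call. = FALSE)
  }
  models <- sort(unique(h$model_id))
  rows <- lapply(models, function(m) {
    members <- unique(h$member_id[h$model_id == m])
    fams <- fam_of[members]
    cov <- tapply(members, fams, length) / fam_size[sort(unique(fams))]
    passing <- cov >= min_coverage
    if (length(cov) == 1) {
      if (passing) {
        data.frame(model_id = m, label = names(cov), step = "B",
                   accepted = TRUE, rejection_reason = "none",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(model_id = m, label = names(cov), step = "B",
                   accepted = FALSE, rejection_reason = "low_coverage",
                   stringsAsFactors = FALSE)
      }
    } else if (all(passing)) {
      data.frame(model_id = m,
                 label = paste(sort(names(cov)), collapse = "/"),
                 step = "B", accepted = TRUE, rejection_reason = "none",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(model_id = m,
                 label = paste(sort(names(cov)), collapse = "/"),
                 step = "B", accepted = FALSE, rejection_reason = "impure",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call CAZy modules on contigs or reads
#'
#' Domain hits are labelled through their route (direct model map for
#' Steps A/D, then accepted association-table entries for Step B);
#' alignment hits against representative sequences (Step C) are labelled
#' through `rep_labels`. Hits scoring below `min_score` are discarded
#' (the cutoff is inclusive: a score of exactly `min_score` is retained).
#' Overlapping surviving calls with the same label on the same query are
#' merged into one call spanning their union with the maximum score;
#' overlapping calls with different labels are both retained. Models with
#' no route to a label raise a warning and are labelled `"unclassified"`.
#'
#' @param domain_hits Domain hits (see [read_hit_table()]).
#' @param assoc Association table from [build_association_table()]
#'   (only accepted entries are used), or `NULL`.
#' @param direct_models Named character vector model_id -> label for
#'   families with directly usable models (Step A) or externally built
#'   ones (Step D), or `NULL`.
#' @param blast_hits Alignment hits against representative sequences
#'   (Step C), or `NULL`.
#' @param rep_labels Named character vector subject_id -> label for
#'   `blast_hits`.
#' @param min_score Bit-score cutoff, inclusive.
#' @return Data frame of module calls: `contig_id`, `label`, `q_start`,
#'   `q_end`, `score`, `source`, sorted by (`contig_id`, `q_start`).
#' @export
call_modules <- function(domain_hits, assoc = NULL, direct_models = NULL,
                         blast_hits = NULL, rep_labels = NULL,
                         min_score = 52) {
  pieces <- list()
  if (!is.null(domain_hits) && nrow(domain_hits) > 0) {
    lab <- rep(NA_character_, nrow(domain_hits))
    if (!is.null(direct_models)) {
      m <- match(domain_hits$model_id, names(direct_models))
      lab[!is.na(m)] <- direct_models[m[!is.na(m)]]
    }
    if (!is.null(assoc)) {
      acc <- assoc[assoc$accepted, , drop = FALSE]
      m <- match(domain_hits$model_id, acc$model_id)
      use <- is.na(lab) & !is.na(m)
      lab[use] <- acc$label[m[use]]
    }
    if (anyNA(lab)) {
      orphans <- unique(domain_hits$model_id[is.na(lab)])
      warning("no family route for model(s): ",
              paste(orphans, collapse = ", "),
              "; labelled 'unclassified'", call. = FALSE)
      lab[is.na(lab)] <- "unclassified"
    }
    pieces[[length(pieces) + 1]] <- data.frame(
      contig_id = domain_hits$query_id, label = lab,
      q_start = domain_hits$q_start, q_end = domain_hits$q_end,
      score = domain_hits$bit_score, source = domain_hits$source,
      stringsAsFactors = FALSE)
  }
  if (!is.null(blast_hits) && nrow(blast_hits) > 0) {
    if (is.null(rep_labels)) {
      stop("blast_hits given without rep_labels", call. = FALSE)
    }
    m <- match(blast_hits$subject_id, names(rep_labels))
    if (anyNA(m)) {
      warning("no family route for representative subject(s): ",
              paste(unique(blast_hits$subject_id[is.na(m)]), collapse = ", "),
              "; labelled 'unclassified'", call. = FALSE)
    }
    lab <- ifelse(is.na(m), "unclassified", rep_labels[m])
    pieces[[length(pieces) + 1]] <- data.frame(
      contig_id = blast_hits$query_id, label = unname(lab),
      q_start = blast_hits$q_start, q_end = blast_hits$q_end,
      score = blast_hits$bit_score, source = "blast",
      stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) return(empty_module_calls())
  calls <- do.call(rbind, pieces)
  calls <- calls[calls$score >= min_score, , drop = FALSE]
  if (nrow(calls) == 0) return(empty_module_calls())
  merged <- do.call(rbind, lapply(
    split(calls, list(calls$contig_id, calls$label), drop = TRUE),
    merge_same_label))
  merged <- merged[order(merged$contig_id, merged$q_start, merged$label), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

empty_module_calls <- function() {
  data.frame(contig_id = character(), label = character(),
             q_start = numeric(), q_end = numeric(), score = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

# Union of overlapping same-label intervals; the merged call keeps the
# maximum score and the source of the highest-scoring constituent.
merge_same_label <- function(df) {
  df <- df[order(df$q_start, df$q_end), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    last <- nrow(out)
    if (df$q_start[i] <= out$q_end[last]) {
      out$q_end[last] <- max(out$q_end[last], df$q_end[i])
      if (df$score[i] > out$score[last]) {
        out$score[last] <- df$score[i]
        out$source[last] <- df$source[i]
      }
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  out
}

#' Assemble per-contig annotations
#'
#' Joins module calls with contig lengths, per-contig read counts and the
#' best database hit per contig (highest bit score, then lowest e-value).
#' Only contigs carrying at least one module call are annotated.
#'
#' @param contig_info Data frame `contig_id`, `length`.
#' @param module_calls Data frame from [call_modules()].
#' @param top_hits Optional alignment hits of contigs against a protein
#'   database; the best hit per contig supplies `top_identity`,
#'   `top_evalue`, `top_annotation`.
#' @param read_counts Optional named vector or data frame
#'   (`contig_id`, `count`) of mapped-read counts.
#' @return A `contig_annotation` object: list with `contigs` (per-contig
#'   table) and `modules` (the calls restricted to annotated contigs).
#' @export
annotate_contigs <- function(contig_info, module_calls, top_hits = NULL,
                             read_counts = NULL) {
  annotated <- intersect(contig_info$contig_id, unique(module_calls$contig_id))
  ci <- contig_info[match(annotated, contig_info$contig_id), , drop = FALSE]
  out <- data.frame(contig_id = ci$contig_id, length = ci$length,
                    read_count = 0L,
                    top_identity = NA_real_, top_evalue = NA_real_,
                    top_annotation = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(read_counts)) {
    if (is.data.frame(read_counts)) {
      read_counts <- stats::setNames(read_counts$count,
                                     read_counts$contig_id)
    }
    m <- match(out$contig_id, names(read_counts))
    out$read_count[!is.na(m)] <- as.integer(read_counts[m[!is.na(m)]])
  }
  if (!is.null(top_hits) && nrow(top_hits) > 0) {
    th <- top_hits[top_hits$query_id %in% annotated, , drop = FALSE]
    if (nrow(th) > 0) {
      th <- th[order(th$query_id, -th$bit_score, th$e_value), , drop = FALSE]
      best <- th[!duplicated(th$query_id), , drop = FALSE]
      m <- match(out$contig_id, best$query_id)
      has <- !is.na(m)
      out$top_identity[has] <- best$percent_identity[m[has]]
      out$top_evalue[has] <- best$e_value[m[has]]
      out$top_annotation[has] <- best$subject_annotation[m[has]]
    }
  }
  mods <- module_calls[module_calls$contig_id %in% annotated, , drop = FALSE]
  mods <- mods[order(mods$contig_id, mods$q_start), , drop = FALSE]
  rownames(mods) <- NULL
  structure(list(contigs = out, modules = mods),
            class = "contig_annotation")
}

#' @export
print.contig_annotation <- function(x, ...) {
  cat("contig annotation:", nrow(x$contigs), "contigs,",
      nrow(x$modules), "module calls,",
      length(unique(x$modules$label)), "distinct labels\n")
  invisible(x)
}

#' Resolve multi-domain architectures
#'
#' Restricted to contigs of at least `min_len` bp, a contig is
#' multi-domain when it carries calls with at least two distinct labels
#' (repeated hits of one family do not qualify). Label co-occurrence is
#' counted once per contig and unordered; each label's share is the
#' percentage of multi-domain contigs containing it.
#'
#' @param ann A `contig_annotation`.
#' @param min_len Minimum contig length in bp (inclusive).
#' @return List with `n_considered`, `multi_domain_contigs` (character),
#'   `n_multi`, `cooccurrence` (data frame `label_a`, `label_b`, `count`),
#'   and `label_share` (data frame `label`, `n_contigs`, `percent` to one
#'   decimal, over multi-domain contigs).
#' @export
resolve_architectures <- function(ann, min_len = 500) {
  keep <- ann$contigs$contig_id[ann$contigs$length >= min_len]
  mods <- ann$modules[ann$modules$contig_id %in% keep, , drop = FALSE]
  labsets <- lapply(split(mods$label, mods$contig_id), unique)
  multi <- names(labsets)[lengths(labsets) >= 2]
  pairs <- lapply(multi, function(cg) {
    ls <- sort(labsets[[cg]])
    t(utils::combn(ls, 2))
  })
  if (length(pairs) > 0) {
    pm <- do.call(rbind, pairs)
    key <- paste(pm[, 1], pm[, 2], sep = "\t")
    tab <- sort(table(key), decreasing = TRUE)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    cooc <- data.frame(
      label_a = vapply(parts, `[`, character(1), 1),
      label_b = vapply(parts, `[`, character(1), 2),
      count = as.integer(tab), stringsAsFactors = FALSE, row.names = NULL)
  } else {
    cooc <- data.frame(label_a = character(), label_b = character(),
                       count = integer(), stringsAsFactors = FALSE)
  }
  if (length(multi) > 0) {
    lab_tab <- sort(table(unlist(labsets[multi])), decreasing = TRUE)
    share <- data.frame(
      label = names(lab_tab),
      n_contigs = as.integer(lab_tab),
      percent = round(100 * as.integer(lab_tab) / length(multi), 1),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    share <- data.frame(label = character(), n_contigs = integer(),
                        percent = numeric(), stringsAsFactors = FALSE)
  }
  list(n_considered = length(keep),
       multi_domain_contigs = sort(multi),
       n_multi = length(multi),
       cooccurrence = cooc,
       label_share = share)
}

#' Bin annotated contigs by best-hit percent identity
#'
#' Bins: identity below 50; 50 to 70 inclusive on both edges; above 70.
#' Contigs without a database hit are counted separately as `no_hit`.
#' Percentages are over contigs with a hit.
#'
#' @param ann A `contig_annotation`.
#' @return List with `counts` (named integer vector `<50`, `50-70`, `>70`,
#'   `no_hit`) and `percent` (over contigs with a hit, one decimal).
#' @export
bin_identity <- function(ann) {
  id <- ann$contigs$top_identity
  known <- id[!is.na(id)]
  if (any(known < 0 | known > 100)) {
    stop("percent identity outside [0, 100]", call. = FALSE)
  }
  counts <- c(
    "<50" = sum(known < 50),
    "50-70" = sum(known >= 50 & known <= 70),
    ">70" = sum(known > 70),
    "no_hit" = sum(is.na(id))
  )
  n_hit <- length(known)
  percent <- if (n_hit > 0) {
    round(100 * counts[1:3] / n_hit, 1)
  } else {
    stats::setNames(rep(NA_real_, 3), names(counts)[1:3])
  }
  list(counts = counts, percent = percent)
}

#' Count contigs per module label
#'
#' One count per contig per label (a label repeated on a contig counts
#' once), the unit used for family-level contig tallies.
#'
#' @param ann A `contig_annotation`.
#' @param min_len Minimum contig length in bp (0 keeps all).
#' @param class_codes Optional character vector restricting labels by CAZy
#'   class prefix (e.g. `"GH"`).
#' @return Named integer vector label -> contig count.
#' @export
count_contigs_per_family <- function(ann, min_len = 0,
                                     class_codes = NULL) {
  keep <- ann$contigs$contig_id[ann$contigs$length >= min_len]
  mods <- ann$modules[ann$modules$contig_id %in% keep, , drop = FALSE]
  u <- unique(mods[, c("contig_id", "label")])
  tab <- table(u$label)
  out <- stats::setNames(as.integer(tab), names(tab))
  if (!is.null(class_codes)) {
    pat <- paste0("^(", paste(class_codes, collapse = "|"), ")[0-9]")
    out <- out[grepl(pat, names(out))]
  }
  sort(out, decreasing = TRUE)
}
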