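# Synthetic community generator with planted truth.
#
# The generator emulates the statistical structure of a deeply sequenced
# rumen eukaryotic metatranscriptome: short reads (108 nt) from contigs with
# log-normal lengths (median 310 bp) and heavy-tailed expression, a
# configurable non-coding RNA read fraction drawn from a dedicated rRNA
# pool with higher GC, planted CAZy module architectures on a subset of
# contigs, and simulated search-tool output (alignment and domain hit
# tables) consistent with that truth plus configurable noise.

#' Default CAZy family universe
#'
#' The family universe covers the glycoside hydrolase, carbohydrate
#' esterase, polysaccharide lyase and carbohydrate-binding module families
#' prominent in anaerobic-fungus-dominated fibre-degrading communities,
#' plus swollenin as a non-hydrolytic accessory class. Each family carries
#' synthetic reference member ids and one associated profile-model id.
#'
#' @param n_members Number of synthetic reference members per family.
#' @return A data frame with columns `family_id`, `class_code`, and list
#'   columns `member_ids`, `pfam_model_ids`.
#' @export
default_family_defs <- function(n_members = 10L) {
  fams <- c(
    GH1 = "GH", GH5 = "GH", GH6 = "GH", GH9 = "GH", GH10 = "GH",
    GH11 = "GH", GH16 = "GH", GH26 = "GH", GH43 = "GH", GH45 = "GH",
    GH48 = "GH", GH53 = "GH", GH94 = "GH",
    CE1 = "CE", CE4 = "CE", CE7 = "CE",
    PL1 = "PL", PL3 = "PL", PL6 = "PL", PL9 = "PL", PL11 = "PL",
    CBM1 = "CBM", CBM6 = "CBM", CBM10 = "CBM", CBM13 = "CBM",
    CBM18 = "CBM", CBM29 = "CBM",
    SWO1 = "OTHER"
  )
  df <- data.frame(
    family_id = names(fams),
    class_code = unname(fams),
    stringsAsFactors = FALSE
  )
  df$member_ids <- lapply(df$family_id, function(f)
    sprintf("%s_m%02d", f, seq_len(n_members)))
  df$pfam_model_ids <- lapply(df$family_id, function(f) paste0("PF_", f))
  class(df) <- c("cazy_family_defs", "data.frame")
  df
}

#' Default module architecture distribution
#'
#' Probability over planted module architectures per contig. Roughly half
#' the contigs carry no CAZy module; the rest are dominated by cellulase
#' (GH6/GH48/GH45 with CBM10 docking modules), hemicellulase (GH10/GH11),
#' oligosaccharide-degrading (GH1), esterase and lyase architectures.
#'
#' @return A named list mapping architecture (a `+`-joined label string,
#'   `"none"` for no module) to probability. Probabilities sum to 1.
#' @export
default_architectures <- function() {
  list(
    "none"        = 0.47,
    "GH48+CBM10"  = 0.06,
    "GH6+CBM10"   = 0.05,
    "GH45+CBM10"  = 0.03,
    "GH11"        = 0.05,
    "GH10"        = 0.03,
    "GH1"         = 0.06,
    "GH5"         = 0.03,
    "GH9"         = 0.02,
    "GH16"        = 0.02,
    "GH26"        = 0.01,
    "GH43"        = 0.03,
    "GH48"        = 0.02,
    "GH53"        = 0.01,
    "GH94"        = 0.01,
    "CE1"         = 0.01,
    "CE4"         = 0.02,
    "CE7"         = 0.01,
    "PL1"         = 0.005,
    "PL6"         = 0.005,
    "PL9"         = 0.005,
    "PL11"        = 0.005,
    "CBM18"       = 0.01,
    "CBM1+GH10"   = 0.01,
    "CBM13"       = 0.005,
    "CBM29"       = 0.005,
    "SWO1"        = 0.01
  )
}

#' Synthetic rumen-eukaryote-like taxonomy
#'
#' A small fixed taxonomy with the clades typical of rumen communities:
#' anaerobic fungi (Neocallimastigomycota), ciliate protozoa (Litostomatea),
#' parabasalids, amoebae, plus bacterial and archaeal outgroups.
#'
#' @return A `taxonomy` object.
#' @export
generate_taxonomy <- function() {
  n <- function(id, parent, rank, name = id)
    data.frame(taxon_id = id, parent_id = parent, rank = rank, name = name,
               stringsAsFactors = FALSE)
  nodes <- rbind(
    n("root", "", "root", "cellular organisms"),
    n("Eukaryota", "root", "kingdom"),
    n("Bacteria", "root", "kingdom"),
    n("Archaea", "root", "kingdom"),
    n("Neocallimastigomycota", "Eukaryota", "phylum"),
    n("Neocallimastigomycetes", "Neocallimastigomycota", "class"),
    n("Neocallimastigales", "Neocallimastigomycetes", "order"),
    n("Neocallimastigaceae", "Neocallimastigales", "family"),
    n("Piromyces", "Neocallimastigaceae", "genus"),
    n("Neocallimastix", "Neocallimastigaceae", "genus"),
    n("Orpinomyces", "Neocallimastigaceae", "genus"),
    n("Ciliophora", "Eukaryota", "phylum"),
    n("Litostomatea", "Ciliophora", "class"),
    n("Entodiniomorphida", "Litostomatea", "order"),
    n("Ophryoscolecidae", "Entodiniomorphida", "family"),
    n("Entodinium", "Ophryoscolecidae", "genus"),
    n("Epidinium", "Ophryoscolecidae", "genus"),
    n("Parabasalia", "Eukaryota", "phylum"),
    n("Trichomonadea", "Parabasalia", "class"),
    n("Trichomonadida", "Trichomonadea", "order"),
    n("Trichomonadidae", "Trichomonadida", "family"),
    n("Trichomonas", "Trichomonadidae", "genus"),
    n("Amoebozoa", "Eukaryota", "phylum"),
    n("Archamoebae", "Amoebozoa", "class"),
    n("Mastigamoebida", "Archamoebae", "order"),
    n("Entamoebidae", "Mastigamoebida", "family"),
    n("Entamoeba", "Entamoebidae", "genus"),
    n("Bacteroidota", "Bacteria", "phylum"),
    n("Bacteroidia", "Bacteroidota", "class"),
    n("Bacteroidales", "Bacteroidia", "order"),
    n("Prevotellaceae", "Bacteroidales", "family"),
    n("Prevotella", "Prevotellaceae", "genus"),
    n("Fibrobacterota", "Bacteria", "phylum"),
    n("Fibrobacteria", "Fibrobacterota", "class"),
    n("Fibrobacterales", "Fibrobacteria", "order"),
    n("Fibrobacteraceae", "Fibrobacterales", "family"),
    n("Fibrobacter", "Fibrobacteraceae", "genus"),
    n("Euryarchaeota", "Archaea", "phylum"),
    n("Methanobacteria", "Euryarchaeota", "class"),
    n("Methanobacteriales", "Methanobacteria", "order"),
    n("Methanobacteriaceae", "Methanobacteriales", "family"),
    n("Methanobrevibacter", "Methanobacteriaceae", "genus")
  )
  taxonomy(nodes)
}

# Default genus weights: eukaryote-dominated, anaerobic fungi and ciliates
# most abundant, small bacterial/archaeal fractions.
default_taxon_weights <- function() {
  c(Piromyces = 0.20, Neocallimastix = 0.15, Orpinomyces = 0.15,
    Entodinium = 0.15, Epidinium = 0.05, Trichomonas = 0.05,
    Entamoeba = 0.05, Prevotella = 0.10, Fibrobacter = 0.05,
    Methanobrevibacter = 0.05)
}

# Random DNA with a given per-base GC probability.
random_dna <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic contig community with planted truth
#'
#' Contig lengths are log-normal with median `median_length`; per-contig GC
#' is drawn around `gc_target`; expression weights follow a log-normal law
#' with a heavy tail; each contig is assigned a genus and an ordered module
#' architecture sampled from `arch_distribution`, with planted module
#' coordinates recorded in the returned truth object.
#'
#' @param n_contigs Number of contigs (>= 1).
#' @param family_defs Family universe, as from [default_family_defs()].
#' @param tax A `taxonomy` object; contig taxa are sampled from its genera.
#' @param arch_distribution Named list architecture -> probability
#'   (probabilities must sum to 1; `"none"` means no planted module).
#' @param expression_law List with `meanlog`, `sdlog` of the log-normal
#'   expression weight law.
#' @param gc_target Mean contig GC fraction.
#' @param median_length Median contig length in bp.
#' @param length_sdlog Log-scale sd of the contig length law.
#' @param taxon_weights Named genus sampling weights (defaults to a
#'   rumen-eukaryote-dominated mixture).
#' @param seed Integer seed; output is fully deterministic given the seed.
#' @return A list with `contigs` (named `DNAStringSet`) and `truth`
#'   (a `community_truth` object).
#' @export
generate_community <- function(n_contigs,
                               family_defs = default_family_defs(),
                               tax = generate_taxonomy(),
                               arch_distribution = default_architectures(),
                               expression_law = list(meanlog = 3, sdlog = 1.5),
                               gc_target = 0.379,
                               median_length = 310,
                               length_sdlog = 0.7,
                               taxon_weights = default_taxon_weights(),
                               seed = 1L) {
  if (n_contigs < 1) stop("n_contigs must be >= 1", call. = FALSE)
  probs <- unlist(arch_distribution)
  if (abs(sum(probs) - 1) > 1e-8) {
    stop("architecture probabilities must sum to 1", call. = FALSE)
  }
  archs <- names(arch_distribution)
  needed <- unique(unlist(strsplit(archs[archs != "none"], "+", fixed = TRUE)))
  missing_fam <- setdiff(needed, family_defs$family_id)
  if (length(missing_fam) > 0 && any(probs[archs != "none"] > 0)) {
    stop("architecture references family absent from family_defs: ",
         missing_fam[1], call. = FALSE)
  }
  genera <- tax$nodes$taxon_id[tax$nodes$rank == "genus"]
  w <- taxon_weights[intersect(names(taxon_weights), genera)]
  if (length(w) == 0) w <- stats::setNames(rep(1, length(genera)), genera)

  set.seed(seed)
  ids <- sprintf("contig%05d", seq_len(n_contigs))
  len <- pmax(150L, as.integer(round(stats::rlnorm(
    n_contigs, meanlog = log(median_length), sdlog = length_sdlog))))
  gc <- pmin(0.95, pmax(0.05, stats::rnorm(n_contigs, gc_target, 0.03)))
  weight <- stats::rlnorm(n_contigs, expression_law$meanlog,
                          expression_law$sdlog)
  taxa <- sample(names(w), n_contigs, replace = TRUE, prob = w)
  arch <- sample(archs, n_contigs, replace = TRUE, prob = probs)

  # plant module coordinates; extend short contigs to fit their architecture
  mod_rows <- vector("list", n_contigs)
  for (i in seq_len(n_contigs)) {
    if (arch[i] == "none") next
    labels <- strsplit(arch[i], "+", fixed = TRUE)[[1]]
    spans <- as.integer(round(stats::runif(length(labels), 90, 240)))
    gaps <- as.integer(round(stats::runif(length(labels), 10, 40)))
    need <- sum(spans) + sum(gaps) + 20L
    if (len[i] < need) len[i] <- need
    pos <- 10L
    starts <- integer(length(labels))
    ends <- integer(length(labels))
    for (j in seq_along(labels)) {
      starts[j] <- pos + gaps[j]
      ends[j] <- starts[j] + spans[j] - 1L
      pos <- ends[j]
    }
    mod_rows[[i]] <- data.frame(contig_id = ids[i], label = labels,
                                q_start = starts, q_end = ends,
                                stringsAsFactors = FALSE)
  }
  modules <- do.call(rbind, mod_rows[!vapply(mod_rows, is.null, logical(1))])
  if (is.null(modules)) {
    modules <- data.frame(contig_id = character(), label = character(),
                          q_start = integer(), q_end = integer(),
                          stringsAsFactors = FALSE)
  }

  seqs <- vapply(seq_len(n_contigs), function(i) random_dna(len[i], gc[i]),
                 character(1))
  contigs <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))

  truth <- structure(list(
    contigs = data.frame(contig_id = ids, length = len, taxon_id = taxa,
                         weight = weight, gc = gc, architecture = arch,
                         stringsAsFactors = FALSE),
    modules = modules,
    reads = NULL,
    params = list(seed = seed, gc_target = gc_target,
                  expression_law = expression_law,
                  median_length = median_length)
  ), class = "community_truth")
  list(contigs = contigs, truth = truth)
}

#' @export
print.community_truth <- function(x, ...) {
  cat("community truth:", nrow(x$contigs), "contigs,",
      nrow(x$modules), "planted modules")
  if (!is.null(x$reads)) cat(",", nrow(x$reads), "reads")
  cat("\n")
  invisible(x)
}

#' Generate reads from a synthetic community
#'
#' Coding reads are sampled from contigs with probability proportional to
#' expression weight times length; non-coding (rRNA-like) reads are drawn
#' from a dedicated high-GC rRNA pool so that the ncRNA truth is
#' unambiguous. The per-read origin (contig id or `"ncRNA"`) is recorded in
#' the truth object.
#'
#' @param contigs Named `DNAStringSet` of contigs.
#' @param truth A `community_truth` from [generate_community()].
#' @param n_reads Number of reads (>= 1).
#' @param read_len Read length in nt.
#' @param ncrna_fraction Expected fraction of reads drawn from the rRNA
#'   pool, in `[0, 1]`.
#' @param ncrna_gc GC fraction of the rRNA pool.
#' @param seed Integer seed.
#' @return A list with `reads` (named `DNAStringSet`) and `truth` (the input
#'   truth with a `reads` table `read_id`/`origin` added).
#' @export
generate_reads <- function(contigs, truth, n_reads, read_len = 108L,
                           ncrna_fraction = 0.184, ncrna_gc = 0.51,
                           seed = 1L) {
  if (n_reads < 1) stop("n_reads must be >= 1", call. = FALSE)
  if (ncrna_fraction < 0 || ncrna_fraction > 1) {
    stop("ncrna_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  is_nc <- stats::runif(n_reads) < ncrna_fraction
  read_ids <- sprintf("read%07d", seq_len(n_reads))
  origin <- character(n_reads)
  seqs <- character(n_reads)

  # dedicated rRNA pool (LSU/SSU-like records)
  pool <- vapply(1:4, function(i) random_dna(3000L, ncrna_gc), character(1))
  n_nc <- sum(is_nc)
  if (n_nc > 0) {
    pk <- sample(length(pool), n_nc, replace = TRUE)
    st <- floor(stats::runif(n_nc, 1, 3000 - read_len + 1))
    seqs[is_nc] <- substr(pool[pk], st, st + read_len - 1)
    origin[is_nc] <- "ncRNA"
  }
  n_cod <- n_reads - n_nc
  if (n_cod > 0) {
    cinfo <- truth$contigs
    p <- cinfo$weight * cinfo$length
    ci <- sample(nrow(cinfo), n_cod, replace = TRUE, prob = p)
    cseq <- as.character(contigs)[cinfo$contig_id[ci]]
    clen <- cinfo$length[ci]
    eff_len <- pmin(read_len, clen)
    st <- floor(stats::runif(n_cod, 1, pmax(1, clen - eff_len + 1) + 1))
    seqs[!is_nc] <- substr(cseq, st, st + eff_len - 1)
    origin[!is_nc] <- cinfo$contig_id[ci]
  }
  reads <- Biostrings::DNAStringSet(stats::setNames(seqs, read_ids))
  truth$reads <- data.frame(read_id = read_ids, origin = origin,
                            stringsAsFactors = FALSE)
  truth$params$ncrna_fraction <- ncrna_fraction
  truth$params$read_len <- read_len
  truth$params$ncrna_gc <- ncrna_gc
  list(reads = reads, truth = truth)
}

# small annotation vocabulary for simulated database subjects
.annotation_vocab <- c(
  "cellulase Cel48A precursor", "cellobiohydrolase II-like cellulase",
  "xylanase", "beta-glucosidase", "licheninase", "cellobiose phosphorylase",
  "feruloyl esterase", "pectate lyase", "swollenin",
  "hypothetical protein", "predicted protein", "unnamed protein product"
)

#' Simulate search-tool output consistent with the planted truth
#'
#' Emits (a) domain hits for every planted module with probability
#' `1 - fn_rate` and scores at or above the calling cutoff, plus decoy
#' domain hits at `fp_rate` per contig with scores below the cutoff in
#' expectation; (b) alignment hits of ncRNA reads against rRNA-pool
#' subjects satisfying the ncRNA threshold rule with probability
#' `1 - fn_rate`, plus failing decoy rRNA hits on coding reads at
#' `fp_rate`; (c) alignment hits of coding reads against protein subjects
#' carrying the true origin taxon; (d) one best protein hit per contig
#' whose percent identity is drawn from a three-bin mixture
#' (`identity_bin_probs` over <50 / 50--70 / >70).
#'
#' @param truth A `community_truth` with reads attached.
#' @param family_defs Family universe (for model ids).
#' @param fn_rate,fp_rate False-negative / false-positive rates in `[0, 1)`.
#' @param score_jitter Non-negative sd of extra score spread above cutoff.
#' @param min_score Domain/alignment score cutoff the true hits respect.
#' @param identity_bin_probs Probabilities of the <50, 50--70, >70 percent
#'   identity bins for contig best hits.
#' @param seed Integer seed.
#' @return A list with data frames `alignment` (rRNA, read-protein, and
#'   contig-protein hits; rRNA subjects are prefixed `SILVA_`, protein
#'   subjects `NRP_`) and `domain`.
#' @export
generate_hit_tables <- function(truth, family_defs = default_family_defs(),
                                fn_rate = 0, fp_rate = 0, score_jitter = 0,
                                min_score = 52,
                                identity_bin_probs = c(0.46, 0.37, 0.17),
                                seed = 1L) {
  if (fn_rate < 0 || fn_rate > 1 || fp_rate < 0 || fp_rate > 1) {
    stop("fn_rate and fp_rate must be in [0, 1]", call. = FALSE)
  }
  if (is.null(truth$reads)) {
    stop("truth has no reads; run generate_reads() first", call. = FALSE)
  }
  set.seed(seed)
  model_of <- stats::setNames(
    vapply(family_defs$pfam_model_ids, `[[`, character(1), 1),
    family_defs$family_id)
  read_len <- truth$params$read_len %||% 108L

  align_row <- function(query, subject, pident, alen, qs, qe, e, bit,
                        taxon, annot) {
    data.frame(query_id = query, subject_id = subject,
               percent_identity = pident, align_length = alen,
               mismatches = round(alen * (100 - pident) / 100),
               gap_open = 0, q_start = qs, q_end = qe,
               s_start = 1, s_end = alen, e_value = e, bit_score = bit,
               subject_taxon = taxon, subject_annotation = annot,
               stringsAsFactors = FALSE)
  }

  aln <- list()
  # true rRNA hits for ncRNA reads
  nc <- truth$reads$read_id[truth$reads$origin == "ncRNA"]
  if (length(nc) > 0) {
    keep <- stats::runif(length(nc)) >= fn_rate
    nc <- nc[keep]
    if (length(nc) > 0) {
      aln[[length(aln) + 1]] <- align_row(
        nc, sample(paste0("SILVA_", c("LSU", "SSU"), "_", 1:2),
                   length(nc), replace = TRUE),
        round(stats::runif(length(nc), 85, 100), 1), read_len,
        1, read_len,
        10^-stats::runif(length(nc), 10, 40),
        round(stats::runif(length(nc), 60, 400), 1),
        "", "LSU/SSU ribosomal RNA")
    }
  }
  # decoy rRNA hits on coding reads: fail the rule (weak e-value, short overlap)
  cod <- truth$reads[truth$reads$origin != "ncRNA", , drop = FALSE]
  if (nrow(cod) > 0 && fp_rate > 0) {
    pick <- stats::runif(nrow(cod)) < fp_rate
    if (any(pick)) {
      n <- sum(pick)
      aln[[length(aln) + 1]] <- align_row(
        cod$read_id[pick], "SILVA_LSU_1",
        round(stats::runif(n, 70, 90), 1), 30,
        1, 30, 10^-stats::runif(n, 0, 4),
        round(stats::runif(n, 30, 50), 1), "", "spurious rRNA match")
    }
  }
  # protein hits for coding reads carry the true taxon
  if (nrow(cod) > 0) {
    keep <- stats::runif(nrow(cod)) >= fn_rate
    codk <- cod[keep, , drop = FALSE]
    if (nrow(codk) > 0) {
      taxa <- truth$contigs$taxon_id[match(codk$origin,
                                           truth$contigs$contig_id)]
      aln[[length(aln) + 1]] <- align_row(
        codk$read_id, paste0("NRP_", codk$origin),
        round(pmin(99, pmax(25, stats::rnorm(nrow(codk), 75, 10))), 1),
        read_len, 1, read_len,
        10^-stats::runif(nrow(codk), 6, 60),
        round(stats::runif(nrow(codk), 55, 300), 1),
        taxa,
        sample(.annotation_vocab, nrow(codk), replace = TRUE))
    }
  }
  # one best protein hit per contig, identity from the three-bin mixture
  ci <- truth$contigs
  bins <- sample(3, nrow(ci), replace = TRUE, prob = identity_bin_probs)
  ident <- round(ifelse(bins == 1, stats::runif(nrow(ci), 25, 49.9),
                 ifelse(bins == 2, stats::runif(nrow(ci), 50, 70),
                        stats::runif(nrow(ci), 70.1, 95))), 1)
  aln[[length(aln) + 1]] <- align_row(
    ci$contig_id, paste0("NRP_ref_", seq_len(nrow(ci))),
    ident, pmin(ci$length, 600), 1, pmin(ci$length, 600),
    10^-stats::runif(nrow(ci), 10, 150),
    round(stats::runif(nrow(ci), 60, 500), 1),
    ci$taxon_id, sample(.annotation_vocab, nrow(ci), replace = TRUE))
  alignment <- validate_alignment_hits(do.call(rbind, aln))

  # domain hits: planted modules survive with prob 1 - fn_rate
  dom <- list()
  m <- truth$modules
  if (nrow(m) > 0) {
    keep <- stats::runif(nrow(m)) >= fn_rate
    mk <- m[keep, , drop = FALSE]
    if (nrow(mk) > 0) {
      score <- min_score + stats::rexp(nrow(mk), rate = 1 / 40) +
        score_jitter * abs(stats::rnorm(nrow(mk)))
      model <- model_of[mk$label]
      model[is.na(model)] <- paste0("PF_", mk$label[is.na(model)])
      dom[[length(dom) + 1]] <- data.frame(
        query_id = mk$contig_id, model_id = unname(model),
        bit_score = round(score, 1),
        e_value = 10^-(round(score, 1) / 3),
        q_start = mk$q_start, q_end = mk$q_end, source = "hmm",
        stringsAsFactors = FALSE)
    }
  }
  # decoy domain hits: scores centred well below the cutoff
  if (fp_rate > 0) {
    pick <- stats::runif(nrow(ci)) < fp_rate
    if (any(pick)) {
      n <- sum(pick)
      st <- floor(stats::runif(n, 1, pmax(1, ci$length[pick] - 60)))
      dom[[length(dom) + 1]] <- data.frame(
        query_id = ci$contig_id[pick],
        model_id = paste0("PF_", sample(family_defs$family_id, n,
                                        replace = TRUE)),
        bit_score = round(pmax(1, stats::rnorm(n, 40, 8)), 1),
        e_value = 10^-stats::runif(n, 0, 4),
        q_start = st, q_end = st + 59, source = "hmm",
        stringsAsFactors = FALSE)
    }
  }
  domain <- if (length(dom) > 0) {
    validate_domain_hits(do.call(rbind, dom))
  } else {
    empty_hits("domain")
  }
  list(alignment = alignment, domain = domain)
}

#' Simulate family-member versus profile-model hits
#'
#' Produces the member/model significance table that drives the
#' association-table construction: each family's model is hit by a fixed
#' fraction of that family's members.
#'
#' @param family_defs Family universe.
#' @param coverage Fraction of members hitting their family model.
#' @param seed Integer seed.
#' @return Data frame `member_id`, `model_id`, `significant`.
#' @export
generate_member_hits <- function(family_defs, coverage = 0.9, seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(family_defs)), function(i) {
    members <- family_defs$member_ids[[i]]
    model <- family_defs$pfam_model_ids[[i]][1]
    k <- max(1L, ceiling(coverage * length(members)))
    data.frame(member_id = sample(members, k),
               model_id = model, significant = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated dataset to disk
#'
#' Serialises contigs, reads, hit tables, taxonomy, family definitions and
#' the full planted truth as plain-text files under `outdir`.
#'
#' @param sim A list as returned by [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @param comments Optional `#` header comments for TSV outputs.
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir, comments = character()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(sim$contigs, p("contigs.fasta"))
  write_fasta(sim$reads, p("reads.fasta"))
  write_hit_table(sim$hits$alignment, p("hits_alignment.tsv"), comments)
  write_hit_table(sim$hits$domain, p("hits_domain.tsv"), comments)
  write_taxonomy(sim$taxonomy, p("taxonomy.tsv"), comments)
  write_tsv(sim$truth$contigs, p("truth_contigs.tsv"), comments)
  write_tsv(sim$truth$modules, p("truth_modules.tsv"), comments)
  write_tsv(sim$truth$reads, p("truth_reads.tsv"), comments)
  write_tsv(sim$member_hits, p("member_hits.tsv"), comments)
  fd <- sim$family_defs
  flat <- data.frame(
    family_id = fd$family_id, class_code = fd$class_code,
    member_ids = vapply(fd$member_ids, paste, character(1), collapse = ","),
    pfam_model_ids = vapply(fd$pfam_model_ids, paste, character(1),
                            collapse = ","),
    stringsAsFactors = FALSE)
  write_tsv(flat, p("families.tsv"), comments)
  invisible(outdir)
}

#' Read a family definition table written by [write_dataset()]
#' @param path Path to `families.tsv`.
#' @return A `cazy_family_defs` data frame.
#' @export
read_family_defs <- function(path) {
  df <- read_tsv(path)
  df$member_ids <- strsplit(df$member_ids, ",", fixed = TRUE)
  df$pfam_model_ids <- strsplit(df$pfam_model_ids, ",", fixed = TRUE)
  class(df) <- c("cazy_family_defs", "data.frame")
  df
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_community()], [generate_reads()],
#' [generate_hit_tables()] and [generate_member_hits()] under one seed.
#'
#' @param n_contigs,n_reads Community and read population sizes.
#' @param ncrna_fraction Expected ncRNA read fraction.
#' @param fn_rate,fp_rate,score_jitter Noise parameters for the hit tables.
#' @param gc_target Contig GC target fraction.
#' @param ncrna_gc rRNA-pool GC fraction.
#' @param read_len Read length in nt.
#' @param member_coverage Member/model hit coverage for the association step.
#' @param seed Integer seed driving all stages.
#' @param ... Passed to [generate_community()].
#' @return A list with `contigs`, `reads`, `truth`, `hits`, `member_hits`,
#'   `taxonomy`, `family_defs`.
#' @export
simulate_dataset <- function(n_contigs = 400L, n_reads = 50000L,
                             ncrna_fraction = 0.184,
                             fn_rate = 0, fp_rate = 0, score_jitter = 0,
                             gc_target = 0.379, ncrna_gc = 0.51,
                             read_len = 108L, member_coverage = 0.9,
                             seed = 1L, ...) {
  fd <- default_family_defs()
  tax <- generate_taxonomy()
  comm <- generate_community(n_contigs, family_defs = fd, tax = tax,
                             gc_target = gc_target, seed = seed, ...)
  rd <- generate_reads(comm$contigs, comm$truth, n_reads,
                       read_len = read_len,
                       ncrna_fraction = ncrna_fraction,
                       ncrna_gc = ncrna_gc, seed = seed + 1L)
  hits <- generate_hit_tables(rd$truth, family_defs = fd,
                              fn_rate = fn_rate, fp_rate = fp_rate,
                              score_jitter = score_jitter, seed = seed + 2L)
  mh <- generate_member_hits(fd, coverage = member_coverage, seed = seed + 3L)
  list(contigs = comm$contigs, reads = rd$reads, truth = rd$truth,
       hits = hits, member_hits = mh, taxonomy = tax, family_defs = fd)
}
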