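# End-to-end pipeline: simulate -> filter ncRNA -> bin taxa -> annotate
# CAZy modules -> expression profile -> comparative clustering -> rarefy
# -> JSON report. Stages communicate via plain-text files so each stage
# can be re-run or substituted with real search-tool output.

#' Default run configuration
#'
#' Collects every pipeline threshold (alignment significance `max_evalue`
#' 1e-5, bit-score fallback `min_bit` 52, ncRNA `min_overlap` 50 bp,
#' module-call `min_score` 52, architecture `min_len` 500 bp, ranked
#' report `min_reads` 10000) together with simulation parameters and the
#' seed.
#'
#' @param outdir Output directory for all stage files.
#' @param seed Integer seed for all randomness.
#' @param n_contigs,n_reads Simulated community size.
#' @param simulate Generate inputs (`TRUE`) or read them from `outdir`
#'   (`FALSE`; expects the file layout written by [write_dataset()]).
#' @param ncrna_fraction,fn_rate,fp_rate,score_jitter Simulation
#'   parameters (see [simulate_dataset()]).
#' @param rank Rank for taxon aggregation in the report.
#' @param family_classes CAZy class prefixes entering the comparative
#'   profile matrix (GH-only by default).
#' @param reference_profiles Optional path to a TSV of reference family
#'   count profiles to co-cluster with the run's own profile; `NULL`
#'   uses the synthetic reference profiles bundled with the package.
#' @return A `run_config` list.
#' @export
default_config <- function(outdir = tempfile("rumencazy_run_"),
                           seed = 7L, n_contigs = 400L, n_reads = 50000L,
                           simulate = TRUE, ncrna_fraction = 0.184,
                           fn_rate = 0, fp_rate = 0, score_jitter = 0,
                           rank = "kingdom", family_classes = "GH",
                           reference_profiles = NULL) {
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = simulate,
    n_contigs = as.integer(n_contigs),
    n_reads = as.integer(n_reads),
    ncrna_fraction = ncrna_fraction,
    fn_rate = fn_rate, fp_rate = fp_rate, score_jitter = score_jitter,
    thresholds = list(max_evalue = 1e-5, min_bit = 52, min_overlap = 50,
                      min_score = 52, min_len = 500, min_reads = 10000),
    rank = rank,
    family_classes = family_classes,
    reference_profiles = reference_profiles,
    rarefaction = list(fractions = seq(0.05, 1, by = 0.05), n_reps = 5L),
    target_richness = 0.8
  )
  class(cfg) <- "run_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (any(unlist(th) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  stopifnot(cfg$n_contigs >= 1, cfg$n_reads >= 1)
  cfg
}

#' Read / write a run configuration (YAML)
#'
#' Configurations round-trip unchanged through serialisation.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config`; for `write_run_config`,
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$rarefaction$fractions <- as.numeric(cfg$rarefaction$fractions)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialisation; stamped into every TSV/JSON
#' output header so files can be traced to the configuration that
#' produced them.
#'
#' @param cfg A `run_config`.
#' @return A 32-character hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes every stage from one configuration and writes all stage
#' outputs plus a machine-readable JSON report under `cfg$outdir`. Any
#' stage failure aborts with an error naming the failing stage.
#'
#' @param cfg A `run_config` from [default_config()] or
#'   [read_run_config()].
#' @return The report, invisibly (a named list; also written to
#'   `report.json`).
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  hash <- config_hash(cfg)
  hdr <- paste0("config=", hash)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  th <- cfg$thresholds

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- inputs ---------------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", {
      s <- simulate_dataset(
        n_contigs = cfg$n_contigs, n_reads = cfg$n_reads,
        ncrna_fraction = cfg$ncrna_fraction,
        fn_rate = cfg$fn_rate, fp_rate = cfg$fp_rate,
        score_jitter = cfg$score_jitter, seed = cfg$seed)
      write_dataset(s, outdir, comments = hdr)
      s
    })
  } else {
    sim <- stage("load_inputs", {
      needed <- c("contigs.fasta", "reads.fasta", "hits_alignment.tsv",
                  "hits_domain.tsv", "taxonomy.tsv", "truth_reads.tsv",
                  "member_hits.tsv", "families.tsv")
      missing <- needed[!file.exists(file.path(outdir, needed))]
      if (length(missing) > 0) {
        stop("missing input file(s): ", paste(missing, collapse = ", "))
      }
      list(
        contigs = read_fasta(p("contigs.fasta")),
        reads = read_fasta(p("reads.fasta")),
        hits = list(alignment = read_hit_table(p("hits_alignment.tsv"),
                                               "alignment"),
                    domain = read_hit_table(p("hits_domain.tsv"), "domain")),
        taxonomy = read_taxonomy(p("taxonomy.tsv")),
        truth = list(reads = read_tsv(p("truth_reads.tsv"))),
        member_hits = read_tsv(p("member_hits.tsv")),
        family_defs = read_family_defs(p("families.tsv"))
      )
    })
  }
  aln <- sim$hits$alignment
  rrna_hits <- aln[startsWith(aln$subject_id, "SILVA_"), , drop = FALSE]
  prot_hits <- aln[startsWith(aln$subject_id, "NRP_"), , drop = FALSE]
  read_ids <- names(sim$reads)
  contig_ids <- names(sim$contigs)

  # -- ncRNA filter ---------------------------------------------------------
  nc <- stage("filter_ncrna", {
    res <- classify_ncrna(read_ids,
                          rrna_hits[rrna_hits$query_id %in% read_ids, ,
                                    drop = FALSE],
                          max_evalue = th$max_evalue, min_bit = th$min_bit,
                          min_overlap = th$min_overlap)
    write_tsv(res$calls, p("ncrna_calls.tsv"), hdr)
    res
  })
  coding_ids <- nc$calls$read_id[!nc$calls$is_ncrna]

  # -- taxonomic binning ----------------------------------------------------
  bins <- stage("bin_taxa", {
    read_prot <- prot_hits[prot_hits$query_id %in% coding_ids, , drop = FALSE]
    asg <- bin_top_hit(read_prot, sim$taxonomy,
                       max_evalue = th$max_evalue, query_ids = coding_ids)
    agg <- aggregate_rank(asg, sim$taxonomy, cfg$rank)
    write_tsv(asg, p("taxon_assignments.tsv"), hdr)
    write_tsv(agg, p("taxon_bins.tsv"), hdr)
    list(assignments = asg, aggregated = agg)
  })

  # -- CAZy annotation ------------------------------------------------------
  annot <- stage("annotate_cazy", {
    assoc <- build_association_table(sim$family_defs, sim$member_hits)
    calls <- call_modules(sim$hits$domain, assoc = assoc,
                          min_score = th$min_score)
    counts <- count_reads_per_contig(
      sim$truth$reads[sim$truth$reads$origin != "ncRNA", , drop = FALSE][[
        "origin"]], contig_ids)
    contig_info <- data.frame(contig_id = contig_ids,
                              length = Biostrings::width(sim$contigs),
                              stringsAsFactors = FALSE)
    contig_top <- prot_hits[prot_hits$query_id %in% contig_ids, ,
                            drop = FALSE]
    ann <- annotate_contigs(contig_info, calls, top_hits = contig_top,
                            read_counts = counts)
    arch <- resolve_architectures(ann, min_len = th$min_len)
    idb <- bin_identity(ann)
    write_tsv(assoc, p("association_table.tsv"), hdr)
    write_tsv(calls, p("module_calls.tsv"), hdr)
    write_tsv(arch$cooccurrence, p("architecture_cooccurrence.tsv"), hdr)
    write_tsv(arch$label_share, p("architecture_label_share.tsv"), hdr)
    list(assoc = assoc, calls = calls, ann = ann, arch = arch,
         identity_bins = idb, read_counts = counts)
  })

  # -- expression profile ---------------------------------------------------
  expr <- stage("profile_expression", {
    mean_len <- mean(Biostrings::width(sim$reads))
    tab <- annot$ann$contigs
    tab$coverage <- round(coverage(tab$read_count, mean_len, tab$length), 1)
    tab$labels <- vapply(tab$contig_id, function(cg)
      paste(unique(annot$ann$modules$label[
        annot$ann$modules$contig_id == cg]), collapse = ";"), character(1))
    ranked <- rank_by_expression(tab, min_reads = th$min_reads)
    write_tsv(tab[order(-tab$read_count, tab$contig_id), ],
              p("expression.tsv"), hdr)
    write_tsv(ranked, p("expression_ranked.tsv"), hdr)
    list(table = tab, ranked = ranked)
  })

  # -- comparative profile + clustering -------------------------------------
  comp <- stage("cluster_profiles", {
    own <- count_contigs_per_family(annot$ann, min_len = 0,
                                    class_codes = cfg$family_classes)
    ref_path <- cfg$reference_profiles %||%
      system.file("extdata", "synthetic_reference_gh_profiles.tsv",
                  package = "rumencazy")
    refs <- read_profile_counts(ref_path)
    profiles <- c(list(run_sample = own), refs)
    pm <- build_profile_matrix(profiles)
    d <- pearson_distance(pm)
    tree <- upgma(d)
    nwk <- as_newick(tree)
    pct <- data.frame(sample = rownames(pm$percents),
                      round(pm$percents, 2), check.names = FALSE)
    write_tsv(pct, p("profile_percents.tsv"), hdr)
    dd <- as.matrix(d)
    write_tsv(data.frame(sample = rownames(dd), round(dd, 6),
                         check.names = FALSE),
              p("distances.tsv"), hdr)
    writeLines(nwk, p("tree.nwk"))
    list(matrix = pm, dist = d, tree = tree, newick = nwk)
  })

  # -- rarefaction ----------------------------------------------------------
  rar <- stage("rarefy", {
    cats <- sim$truth$reads$origin[sim$truth$reads$origin != "ncRNA"]
    curve <- collectors_curve(cats,
                              fractions = cfg$rarefaction$fractions,
                              n_reps = cfg$rarefaction$n_reps,
                              seed = cfg$seed)
    eff <- effort_at_richness(curve, cfg$target_richness)
    write_tsv(as.data.frame(curve), p("rarefaction.tsv"), hdr)
    list(curve = curve, effort = eff)
  })

  # -- report ---------------------------------------------------------------
  report <- stage("report", {
    summ <- summarize_run(sim$reads, sim$contigs, nc$calls,
                          bins$assignments, sim$taxonomy, cfg$rank)
    rep <- list(
      schema_version = "1.0",
      package_version = as.character(utils::packageVersion("rumencazy")),
      seed = cfg$seed,
      config_hash = hash,
      thresholds = th,
      summary = summ,
      removal_efficiency = if (!is.null(summ$ncrna_percent))
        round(100 * estimate_removal_efficiency(summ$ncrna_percent / 100))
        else NA,
      family_contig_counts = as.list(
        count_contigs_per_family(annot$ann, min_len = th$min_len)),
      n_annotated_contigs = nrow(annot$ann$contigs),
      n_multi_domain = annot$arch$n_multi,
      identity_bins = as.list(annot$identity_bins$counts),
      n_ranked_records = nrow(expr$ranked),
      effort_at_target_richness = rar$effort,
      newick = comp$newick
    )
    jsonlite::write_json(rep, p("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    rep
  })
  invisible(report)
}
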