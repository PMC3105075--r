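# rumencazy

Tools for analysing eukaryotic metatranscriptomes of fibre-degrading gut
communities — rumen anaerobic fungi and ciliate protozoa in particular —
with a focus on discovering plant cell wall degrading enzymes
(carbohydrate-active enzymes, CAZymes).

Deep mRNA sequencing of a rumen community yields tens of millions of short
reads. Before any enzyme mining can happen, the reads that are really
ribosomal or transfer RNA must be identified and set aside, the putative
protein-coding remainder assigned to the organisms they came from, and the
assembled contigs scanned for CAZy modules — glycoside hydrolases (GH),
carbohydrate esterases (CE), polysaccharide lyases (PL), carbohydrate
binding modules (CBM) and accessory proteins such as swollenin. `rumencazy`
implements that whole analysis chain as ordinary, testable R functions,
together with a deterministic synthetic-community generator with planted
truth so every stage can be validated without external databases or search
binaries.

## What the package computes

* **ncRNA filtering** — a read is non-coding when an rRNA-database hit has
  E ≤ 10⁻⁵ (bit score ≥ 52 when the E-value is missing) *and* query overlap
  ≥ 50 bp, or when an external rRNA/tRNA model scan flagged it; the two
  routes combine by union. From the surviving ncRNA share *f* and an assumed
  pre-depletion ncRNA fraction *c₀*, the depletion efficiency is

  ​  r = 1 − [(1 − c₀) · f] / [c₀ · (1 − f)]

  (mRNA assumed fully retained). With c₀ = 0.95 and f = 0.184 this gives
  r ≈ 0.99.
* **Taxonomic binning** — each read takes the taxon of its best significant
  hit (bit score, then E-value); exact ties resolve to the lowest common
  ancestor; counts aggregate at any rank.
* **CAZy annotation** — a staged model-to-family association procedure:
  families with directly usable profile models (Step A); models associated
  by searching all family members against the profile database and accepted
  only when every implicated family reaches 80 % member coverage, single or
  combined "CE2/CE3"-style classes (Step B); families without models called
  from alignments to representative sequences at a bit-score cutoff of 52
  (Step C); externally built profiles for the remainder (Step D). Calls
  below score 52 are dropped, overlapping same-family hits merge,
  stacked distinct modules (e.g. GH48 + CBM10) survive. Multi-domain
  architectures, family tallies on contigs ≥ 500 bp, and best-hit identity
  bins (< 50 %, 50–70 %, > 70 %) follow.
* **Expression & discovery** — reads per contig, fold coverage
  (reads × read length / contig length), ranked high-expression reports
  (≥ 10 000 reads), and discovery rates in genes per gigabase.
* **Comparative profiling** — a samples × GH-families percentage matrix,
  Pearson-correlation distances (d = 1 − r) and UPGMA clustering with
  deterministic tie-breaking, exported as newick.
* **Rarefaction** — replicated collector's curves of category richness
  versus sequencing effort, and the interpolated effort needed for a target
  richness fraction.

## Worked example

```r
library(rumencazy)

sim <- simulate_dataset(n_contigs = 300, n_reads = 30000, seed = 7)

rrna <- subset(sim$hits$alignment, startsWith(subject_id, "SILVA_"))
nc <- classify_ncrna(names(sim$reads), rrna)
cat(sprintf("ncRNA reads: %d (%.1f%%)\n", nc$n_ncrna, 100 * nc$fraction))
cat(sprintf("estimated rRNA removal: %.0f%%\n",
            100 * estimate_removal_efficiency(nc$fraction)))

assoc <- build_association_table(sim$family_defs, sim$member_hits)
calls <- call_modules(sim$hits$domain, assoc = assoc)
info  <- data.frame(contig_id = names(sim$contigs),
                    length = Biostrings::width(sim$contigs))
ann   <- annotate_contigs(info, calls,
                          top_hits = subset(sim$hits$alignment,
                                            query_id %in% info$contig_id))
arch  <- resolve_architectures(ann, min_len = 500)
cat("multi-domain contigs (>=500 bp):", arch$n_multi, "\n")
head(arch$label_share, 3)
```

prints

```
ncRNA reads: 5498 (18.3%)
estimated rRNA removal: 99%
multi-domain contigs (>=500 bp): 8
  label n_contigs percent
1 CBM10         8   100.0
2  GH48         6    75.0
3  GH45         1    12.5
```

— 18.3 % of the simulated reads are ribosomal (the generator's default
emulates a post-depletion library), implying ~99 % of the original rRNA was
removed, and the CBM10 docking module dominates multi-domain contigs, as
expected for anaerobic-fungal cellulases. Clustering the run's GH profile
against bundled synthetic reference guilds places it with the
cellulolytic profiles:

```r
counts <- count_contigs_per_family(ann, class_codes = "GH")
profiles <- c(list(muskox_sim = counts),
              read_profile_counts(system.file("extdata",
                "synthetic_reference_gh_profiles.tsv", package = "rumencazy")))
tree <- upgma(pearson_distance(build_profile_matrix(profiles)))
cat(as_newick(tree))
#> ((synthetic_oligosaccharide_B:...,synthetic_oligosaccharide_A:...):...,
#>  (muskox_sim:...,(synthetic_cellulolytic_B:...,synthetic_cellulolytic_A:...):...):...);

cats  <- subset(sim$truth$reads, origin != "ncRNA")$origin
curve <- collectors_curve(cats, n_reps = 5, seed = 7)
cat(sprintf("80%% of richness reached at %.1f%% of effort\n",
            100 * effort_at_richness(curve, 0.8)))
#> 80% of richness reached at 11.9% of effort
```

The saturating curve — 80 % of the distinct genes found with ~12 % of the
effort — is the signature of a heavy-tailed expression distribution.

`run_pipeline(default_config(outdir = "run", seed = 7))` chains every stage
and writes all intermediate TSVs plus a JSON report;
`inst/cli/rumencazy-pipeline.R` is a thin Rscript wrapper around it.

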