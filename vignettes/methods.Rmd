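---
title: "Methods: CAZyme annotation and profiling for rumen eukaryotic metatranscriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAZyme annotation and profiling for rumen eukaryotic metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumencazy)
```

`rumencazy` re-implements, as a reusable and fully testable pipeline, the
analysis chain used to mine plant cell wall degrading enzymes from a deeply
sequenced eukaryotic gut metatranscriptome. This vignette explains each
stage's model and assumptions, the parameters that matter, the numerical
conventions, and what the synthetic validation data do and do not
establish.

## Coordinates and formats

All coordinates are 1-based inclusive (the BLAST convention): a hit
spanning positions $a..b$ covers $b-a+1$ bases. Alignment evidence uses
the standard 12-column BLAST tabular layout with two trailing columns for
the subject taxon and annotation, so taxonomic binning and report tables
need no second join file. Domain evidence uses a 7-column table (query,
model, score, e-value, start, end, source). Readers reject malformed input
with positional diagnostics and reader/writer pairs are inverse on valid
data; sequence case is normalised to upper on read, and `N` counts toward
neither GC nor AT.

## ncRNA filtering and depletion efficiency

A read is classified non-coding when an alignment against the rRNA
database passes the threshold rule, or when an external rRNA/tRNA model
scan flagged it; the two routes combine by **union** (a read flagged by
either is ncRNA, whatever the other route says). The threshold rule
requires E-value $\le 10^{-5}$ and query overlap $\ge 50$ bp, both
inclusive. The bit-score condition (≥ 52) is stated as the equivalent of
the E-value condition, so it is implemented as a **fallback** used only
when a hit carries no E-value — never as an additional conjunct; making it
a conjunction would silently tighten the rule for ordinary hits.

Depletion efficiency assumes a two-component mixture: before depletion a
fraction $c_0$ of the RNA is ncRNA, mRNA is fully retained, and a fraction
$r$ of the ncRNA is removed. The surviving ncRNA share is then
$f = c_0(1-r)\,/\,(c_0(1-r) + (1-c_0))$, which inverts to

$$r = 1 - \frac{(1-c_0)\,f}{c_0\,(1-f)},$$

clamped to $[0,1]$. $r$ is strictly decreasing in $f$; $f=c_0$ gives
$r=0$ and $f=0$ gives $r=1$. With the conventional $c_0 = 0.95$ for total
RNA and an observed $f = 0.184$, $r \approx 0.988$, reported as 99 %.
The mRNA-fully-retained assumption makes $r$ an upper bound whenever
depletion also loses mRNA.

## Taxonomic binning

Each query takes the taxon of its best significant hit (E ≤ 10⁻⁵), ranked
by bit score descending then E-value ascending. Exact ties pointing at
different taxa resolve to the **lowest common ancestor** rather than
first-in-file order: file order is not reproducible across runs, the LCA
is, and it matches how ambiguous top hits are conventionally handled.
Hits with an empty subject taxon cannot support an assignment and are
dropped up front. Aggregation lifts each assignment to its ancestor at the
requested rank; taxa whose lineage lacks that rank (e.g. an LCA resolved
at kingdom level when aggregating genera) fall into `other`, and
percentages are reported both over the full query universe (summing to
100 with `unassigned`) and over the assigned subset. Reported percentages
follow survey style: whole percent at ≥ 10, one decimal below.

## CAZy module annotation (Steps A–D)

The association of profile models to CAZy families proceeds in four
stages. Families with directly usable profile models enter a direct map
(Step A). For families without one, all reference members are searched
against the profile database and a model is accepted for a family only
conservatively (Step B): at least 80 % of the family's members must
conform to the model, and every family implicated by the model must pass
that coverage. A model whose hits come from one family below coverage is
rejected `low_coverage`; a model spread over several families of which any
fails is rejected `impure`; several families all passing yield a combined
class labelled by the sorted family ids joined with `/` (e.g. `CE2/CE3`).
The strict all-families-pass reading of the combined case is a design
choice: the source procedure names only "closely related groups" without a
threshold, and requiring full coverage of every member family is the
interpretation consistent with a conservative association. The 80 %
boundary is inclusive (16 of 20 members accepts). Association building is
order-independent. Families with neither model nor members are called from
alignments against representative sequences with the same score cutoff
(Step C); externally built profiles for the remainder ride the direct map
flagged Step D — profile training itself (multiple alignment, HMM
estimation) is out of scope and consumed as given model ids.

Module calling discards hits below 52 bits (inclusive cutoff: exactly 52
is retained). Overlapping calls on the same query with the **same** label
merge into their span union with the maximum score — fragmented profile
hits on one domain must not inflate family counts — while overlapping
calls with **different** labels are both retained, so genuinely stacked
modules (a GH48 catalytic domain followed by a CBM10 docking module)
survive. Merging is idempotent. "Multi-domain" means at least two
*distinct* labels on one contig ≥ 500 bp; two GH6 hits alone do not
qualify. Identity bins for the best database hit are $[0,50)$,
$[50,70]$, $(70,100]$: only the outer bins are stated in the source
("less than 50", "more than 70"), so the middle bin is closed on both
sides to make the three exhaustive; bin percentages are over contigs with
a hit, and no-hit contigs are counted separately so that bin counts plus
`no_hit` always balance the annotated set. Read-level and contig-level
family counts are never summed, since whether a family seen on both a
read and its contig should be deduplicated is not specifiable.

## Expression, coverage and discovery rates

Reads per contig is an exact multiset count with explicit zeros. Fold
coverage is `read_count × mean_read_len / contig_len`. Total gigabases
uses read count × mean read length when only summary inputs exist, with an
exact per-read-sum path also provided. Ranked expression reports keep
records with ≥ 10 000 reads, descending, ties broken by contig id.
Discovery rates are genes per gigabase rounded to integers and rate ratios
to one decimal, mirroring how such figures are reported. GC content
excludes `N` from the denominator; category means are read-weighted (each
read contributes equally), and all-`N` sequences are dropped as missing.

## Comparative GH profiling

The profile matrix counts how often each GH family is seen per sample
(one count per contig per family), row-normalised to percentages.
GH-only is the default family universe because the comparison is between
glycoside hydrolase repertoires; the universe is a parameter for callers
who want all classes. Distances are $d = 1 - r$ with $r$ the Pearson
correlation of percentage rows — the minimal monotone transform of $r$,
which preserves the UPGMA topology relative to $(1-r)/2$ — giving
$d \in [0,2]$. Correlation on percentages (not raw counts) makes the
distance invariant to sequencing depth. Zero-variance rows are an error
naming the sample; all-zero rows are flagged and excluded with a warning.

UPGMA repeatedly merges the pair of clusters at minimal distance; the new
cluster's distance to any third is the size-weighted mean of its
constituents' distances, i.e. the average over all between-member pairs.
Merge height is $d_{\min}/2$, so the cophenetic distance between two
leaves equals the average-linkage distance at which they join. Ties break
by the lexicographically smallest pair of cluster representative labels
(each cluster represented by its smallest member), which fixes the
topology across platforms. The test suite checks the implementation
against `stats::hclust(method = "average")` cophenetic distances on 100
seeded random matrices of up to 8 leaves; `hclust` serves purely as the
independent oracle.

## Rarefaction

Collector's curves subsample $\lfloor f N \rfloor$ reads **without
replacement** at each effort fraction $f$ (classic rarefaction; the
subsampling scheme is otherwise unspecified in the source, and replicated
subsampling with reported spread is the defensible default). Within a
replicate the subsamples are prefixes of one permutation, so each
replicate's curve is non-decreasing and each prefix is still a uniform
subset of its size. The curve at $f = 1$ equals total richness with zero
spread. The effort needed for a target richness fraction interpolates
linearly between evaluated points (with an implicit origin), avoiding any
parametric species-accumulation model. Means are cross-checked in tests
against a brute-force resampling oracle and `vegan::rarefy`'s analytic
expectation.

## The synthetic community generator

The generator is the package's validation instrument: it produces data
whose every downstream answer is known.

* **Contigs**: log-normal lengths with median 310 bp (log-sd 0.7, a
  right-skew typical of short-read transcript assemblies), per-contig GC
  around a 0.379 target (sd 0.03), log-normal expression weights with
  $\mu = 3, \sigma = 1.5$ — heavy-tailed enough that a handful of contigs
  capture thousands of reads at $10^5$-read scale, reproducing the
  observed expression skew.
* **Architectures**: each contig draws an ordered module architecture
  (default mixture: ~half with no CAZy module, the rest dominated by
  cellulase families GH6/GH45/GH48 with CBM10, hemicellulases GH10/GH11,
  oligosaccharide degraders GH1, esterases, lyases and swollenin);
  planted coordinates always fit inside the contig.
* **Reads**: 108 nt; coding reads sample contigs proportionally to
  weight × length; ncRNA reads come from a dedicated high-GC (0.51) rRNA
  pool, never from contigs, so the ncRNA truth is unambiguous; the default
  ncRNA fraction 0.184 emulates a post-depletion library.
* **Hit tables**: every planted module emits a domain hit with probability
  $1-\mathrm{fn}$ and score ≥ cutoff; decoys appear at rate
  $\mathrm{fp}$ with scores centred at 40 (sd 8), below the cutoff in
  expectation; ncRNA reads emit rule-passing rRNA hits; coding-read and
  contig protein hits carry the true taxon; contig best-hit identities are
  drawn from a three-bin mixture (46/37/17 % for <50, 50–70, >70) matching
  the identity spectrum of a community dominated by uncharacterised genes.
* **Taxonomy**: a small fixed tree of rumen-typical clades (anaerobic
  fungi, ciliates, parabasalids, amoebae, bacterial and archaeal
  outgroups) with a eukaryote-dominated genus weighting.

Everything is deterministic given the seed, and with zero noise the entire
pipeline must reproduce the planted truth exactly — family counts, taxon
bins and the ncRNA set — which the test suite asserts.

What the generator does **not** emulate: sequencing error and quality
scores, paired-end structure, assembly artefacts (chimeras, collapsed
paralogues), database incompleteness, alignment score correlation with
sequence divergence, or genuine phylogenetic signal in the sequences.
Passing tests therefore demonstrate the correctness of the decision rules
and arithmetic on well-formed evidence, not robustness to real search-tool
noise.

## Problem sizes, tolerances and degenerate inputs

The test suite runs communities of 40–2 000 contigs and $10^3$–$10^5$
reads — sizes chosen so statistical checks (ncRNA share within ±0.5 pp,
depletion round-trip within ±1 pp, GC recovery within ±0.5 pp, Spearman
$\rho > 0.95$ between counts and planted expression) have comfortable
sampling margins at desk scale. Floating-point comparisons use testthat's
default tolerance except the UPGMA-versus-oracle check (10⁻¹⁰ on
cophenetic matrices). Degenerate inputs are defined rather than left to
chance: zero reads give an all-zero summary, empty hit tables give empty
typed results, a single category gives a flat collector's curve, and
duplicated or dangling taxonomy rows, cycles, negative scores, reversed
coordinates and out-of-range identities are hard errors with positions or
names in the message.

## Pipeline and provenance

`run_pipeline()` chains the stages through plain-text files only, so any
stage can be replaced by real search-tool output with the same layout.
Every TSV/JSON output carries the MD5 hash of the canonical YAML
serialisation of the run configuration in a header comment (FASTA has no
comment convention; those files are covered by the hash recorded in the
JSON report). A configuration plus seed reproduces every output file
byte-for-byte. Stage failures abort with the failing stage named, and
input files are checked before any output is written.

## Known limitations

The HMM/covariance models behind the rRNA flag list, profile-HMM scoring,
multiple alignment, and database construction are consumed as inputs, not
implemented. The bacterial/archaeal side of the community is present only
as outgroups. Normalisation schemes such as RPKM/TPM are deliberately
absent — read counts per contig are the expression proxy. The depletion
estimate inherits its two assumptions ($c_0$, full mRNA retention) and
should be read as an upper bound on removal.
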