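---
title: "tRF discovery, seed prediction and target regulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tRF discovery, seed prediction and target regulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trftools)
```

This vignette is the package's own account of its models and the choices
behind them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. Fragment extraction

Reads are adapter-clipped (`clip_adapter()`: the 3'-most exact occurrence
of an adapter prefix of ≥ 7 nt is removed together with everything after
it), filtered to length ≥ 17 nt (`filter_by_length()`; "longer than 16 nt"
is read strictly, and the cutoff is an argument for anyone preferring
≥ 16), and collapsed to unique sequences with counts.

Mapping (`map_reads()`) is deliberately an *exact, full-length, sense-strand
substring* test against mature tRNA sequences with the post-transcriptional
CCA appended. tRFs derive from the mature tRNA transcript, so antisense
matches are meaningless here, and modified-base-induced mismatches are out
of scope. The implementation enumerates every substring (≥ 17 nt) of every
mature tRNA into a hash (`build_trna_index()`); a read maps in O(1)
regardless of library depth, and the test suite checks it against a naive
O(n·m) scan on 1,000 random read/tRNA pairs. Multi-mapping reads are
reported once per matching tRNA gene; called fragments over identical
mature sequences are merged into one record listing all gene ids, because
fragments of duplicated tRNA genes are experimentally indistinguishable.

Classes follow the endpoint geometry: `FIVE_PRIME` starts at position 1,
`THREE_PRIME_CCA` ends at the CCA terminus, everything else is `INTERNAL`;
a read spanning the whole molecule is excluded from fragment sets. 3'U
trailer fragments would require precursor trailer sequences (optional
input, off by default — they are negligible in the data this design
emulates).

Abundance is reads-per-million of the library total (`normalize_counts()`).
The denominator for both RPM and the abundance filter is **all reads in the
library after length filtering** — the closest literal reading of
"normalized by the total number of reads detected" — with a `"mapped"`
mode for those preferring tRNA-mapped totals. A candidate fragment
(aggregated per tRNA gene and class) is retained only when its count
strictly exceeds 0.1 % of the library total in *every* one of the nine
libraries; the representative coordinates are those of the modal (highest
summed count) distinct read, a rule this package makes explicit because a
single coordinate pair per fragment must come from somewhere.

Age patterns (`classify_age_pattern()`) compare per-timepoint means with a
relative tolerance ε = 0.05: a step counts only when it exceeds ε times the
mean of the two values compared. The published analysis classified
trajectories visually; an explicit tolerance makes the call reproducible
and tunable. `FLAT` fragments sit exactly at this boundary under replicate
noise, so calibration claims are made for directional patterns only.

## 2. Seed discovery

For each 7-nt window `w` along a fragment (`sliding_windows()`), the three
canonical target-site types are derived (`site_variants()`):

| type | site sequence |
|------|---------------|
| 7mer-m8 | revcomp(`w`) |
| 7mer-1a | revcomp(`w[1..6]`) + A |
| 8mer-1a | revcomp(`w`) + A |

**Orientation.** The source analysis speaks of "exact matches" of tRF
subsequences to 3'UTRs, yet defines the site types exactly as the miRNA
literature does — on the complementary (mRNA) strand. The default is
therefore `complementary`, with a `direct` dialect for the literal reading;
the two are related by reverse-complementing every UTR, which the test
suite exercises. Neither is presented as the original authors' certified
intent.

**Conservation.** A site occurrence found in the rat (10116) ungapped UTR
is projected onto its alignment columns; it is conserved when the
gap-stripped characters over that span equal the site in ≥ 15 of the 23
aligned vertebrates, always including human, mouse and rat
(`conservation_rule()`). Column anchoring (`aligned_columns`) is the
default because it is the stricter, alignment-respecting reading; an
`anywhere` mode (site present anywhere in the species' UTR) is provided
since the original description does not specify anchoring.

**Counting.** `observed_count()` counts *genes* with ≥ 1 conserved 7mer-m8
or 7mer-1a site (an 8mer-1a occurrence implies both constituent sites, so
gene-level deduplication handles it automatically). Gene-level counting was
chosen over occurrence-level counting for consistency with target-set
construction. A precomputed index of conserved 7-mers per gene
(`conserved_kmer_index()`) makes every window query O(1) per gene; the
naive full-scan oracle lives in the test suite and must agree exactly.

**Two nulls.** `expected_genomic_count()` is `f·N` with `f` the empirical
per-position frequency of the 7mer-m8 site in a user-supplied background
corpus and `N` the scanned reference positions; the original work does not
name its background corpus, so it is an explicit input. When the site never
occurs in the background the expectation is floored at 0 with a warning.
`composition_null()` enumerates all distinct permutations of the window's
nucleotide multiset (≤ 5040 = 7!) and averages their observed counts; the
observed window itself is excluded ("all *other* 7-mers"), falling back to
include-self with a warning for the degenerate single-permutation
compositions (homopolymers).

**Calling.** The original analysis called seeds by visual inspection of the
observed/null profiles. `call_seed()` replaces that with explicit,
reported thresholds: observed ≥ 2× both nulls and ≥ 25 genes. Both numbers
are arguments and appear in every output; they are this package's
stand-ins, not published constants.

**A non-obvious identity.** If a window starts with T, its 7mer-m8 site
ends in A — which is, by construction, the 7mer-1a site of the window one
position downstream. Two adjacent offsets then genuinely match the same UTR
site, and no counter can distinguish them. Exact-offset recovery fixtures
therefore plant windows that do not start with T
(`pick_plantable_offset()`); on real data adjacent called offsets should be
interpreted as one seed region.

## 3. Target regulation

`fold_changes()` normalizes every library column by its total, averages
replicates per timepoint and computes the relative change (O − Y)/Y between
the first and last timepoint; transcripts with a zero young mean are
excluded and counted. Mapping "first/last label" absorbs the differing age
grids of small-RNA (6/14/22 months) and expression (6/12/28 months)
series. Classification at a threshold t is strict: DOWN iff change < −t,
UP iff change > t.

The statistic is the down/up count ratio of a target set versus the ratios
of 1,000 random transcript sets of the same size drawn without replacement
from the same transcriptome (`resample_null()`). Sets with zero
up-regulated members yield an `Inf` sentinel, kept for rank-based
comparison and excluded from moments. Two significance modes are emitted
side by side (`regulation_significance()`): the literal published
procedure — a one-sample two-tailed t-test of the null sample against the
observed ratio, which is statistically unusual since it treats the observed
value as a hypothesized mean — and the recommended rank-based empirical
p-value `2·min(Pr(null ≤ obs), Pr(null ≥ obs))` with add-one correction,
which is well-defined for infinite ratios and degenerate nulls. Tiers
follow the star convention (`***` < 0.005, `**` < 0.01, `*` < 0.05, `#`
otherwise). Change histograms (`change_histogram()`) use half-open 2.5 %
bins aligned at bin multiples and are transcript-count (not
abundance-weighted) densities.

## 4. What the simulator emulates — and what it does not

`sim_config()` fixes the study conditions: 3 timepoints (Y/M/O) × 3
replicates at 10^6 reads each; 3'CCA fragments end exactly at the CCA
terminus with small start jitter (sd 0.5 nt) while 5' fragments start at
position 1 with larger end jitter (sd 3 nt), reproducing the sharp-3' /
diffuse-5' cleavage contrast; age trajectories multiply expected abundance
2-fold per age step (MONO_UP 1:2:4, DIP 1:½:2 — the M < Y < O shape);
planted base abundances (2 % per 3' fragment, 1.2 % per 5') keep every
planted fragment above the 0.1 % filter at all ages; replicate noise is
multiplicative log-normal with CV 0.2, the simplest defensible
overdispersion model for count data (none is published); 5 % of reads are
random internal fragments, 2 % single-mismatch decoys that must fail the
perfect-match rule, and the remainder unrelated filler, so each library has
exactly its nominal depth. UTR blocks span the 23 vertebrate taxa with
i.i.d. 42 % GC background, 2 % gaps outside planted spans, and sites
planted at one shared column span in exactly `conservation_k` species
(human/mouse/rat always included). Expression tables draw log-normal
baselines; non-target old/young ratios are log-normal around 1
(sd(log) 0.15) and targets are shifted down by 15 %.

One master seed feeds an independent child RNG stream per generated
component, so regenerating one library never perturbs another (tested).

Deliberately *not* modeled: RNA-structure-driven cleavage preferences,
sequencing error beyond the decoys, phylogenetic correlation between
species (background rows are independent, which makes chance conservation
across ≥ 15 species essentially impossible — real alignments are far more
correlated, so real-data null counts will be higher than synthetic ones),
alignment-quality artifacts, and expression dispersion trends. Passing
tests therefore demonstrate correctness of the machinery and calibration
under these assumptions, not performance on real libraries.

## 5. Numerical and scale choices

Problem sizes used by the tests and acceptance script — 300 alignment
blocks of width 500 for seed recovery, 100 blocks for oracle equivalence,
nine 10^6-read libraries for extraction, 500 null simulations for type-I
calibration and 100 for power — were chosen as the smallest sizes at which
the planted effects and calibration bands are stable across seeds.
Coordinates are 1-based inclusive throughout, matching the field's
convention for both fragment coordinates and genome loci
(`locate_gene_in_genome()` returns spans whose length equals the query
length). Species lists in site records are serialized ascending by
taxonomy ID for deterministic diffs. Ties in the modal-read rule break
lexicographically. All thresholds (length cutoff, abundance fraction,
ε, seed-call ratio and gene floor, regulation thresholds, resample count,
bin width) are arguments with the defaults stated above.

## 6. Known limitations

The seed-call thresholds and the background corpus for the genomic null are
explicit stand-ins where the original description is silent; conclusions
about marginal seeds depend on them. The t-test significance mode is
reported for fidelity but should not be preferred over the empirical mode.
3'U fragments and tRNA halves are out of scope beyond what the length
filter admits. Reproducing the original published numbers requires the
original external data deposits (small-RNA archive, cortex transcriptome
series, TargetScan alignments), which this package reads but does not
bundle.
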