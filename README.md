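# trftools

Discovery, seed prediction and target-regulation analysis for tRNA-derived
fragments (tRFs) in aging brain small-RNA data.

## The problem

tRFs are short (~16–24 nt) RNAs cleaved from mature tRNAs. Two classes
dominate brain small-RNA libraries: 5' tRFs (from the tRNA 5' end, variable
cleavage site) and 3'CCA tRFs (ending exactly at the post-transcriptional
CCA tail, sharp cleavage site). Their abundance changes with age, and they
appear to act like miRNAs: a 7-nt "seed" on the fragment pairs with
complementary sites in transcript 3'UTRs, and predicted targets shift
toward down-regulation in old animals.

`trftools` implements this analysis end to end for anyone with small-RNA
libraries, a mature-tRNA reference, multi-species 3'UTR alignments and a
transcript expression time course:

1. **tRF extraction** — reads are adapter-clipped, length-filtered
   (≥ 17 nt), collapsed, and mapped as *exact, full-length* substrings of
   mature tRNA sequences with CCA appended. Fragments are classified by
   endpoint (5', 3'CCA, internal), normalized to reads per million (RPM),
   and kept only when their count strictly exceeds 0.1 % of the library
   total in *every* replicate. Per-timepoint means over a young/mid/old
   (Y/M/O) design are labeled MONO_UP, MONO_DOWN, DIP, PEAK or FLAT.
2. **Seed discovery** — a 7-nt window slides along each tRF. For window
   `w`, the canonical miRNA-style target sites are derived:
   7mer-m8 = revcomp(`w`), 7mer-1a = revcomp(`w[1..6]`) + A,
   8mer-1a = 7mer-m8 + A. A site is *conserved* when it occupies the same
   alignment columns in ≥ 15 of 23 vertebrate species, always including
   human (9606), mouse (10090) and rat (10116). The observed count of genes
   carrying a conserved site is compared against two nulls: the expectation
   from background 7-mer frequency, and the mean count over all other
   7-mers with the same nucleotide composition. A window is called a seed
   when it is ≥ 2-fold enriched over both nulls and hits ≥ 25 genes
   (both thresholds configurable and reported).
3. **Target regulation** — for a predicted target set, the ratio of
   transcripts down- vs up-regulated from young to old (at the > 5 %,
   > 10 % and > 20 % thresholds) is compared with the ratio distribution of
   1,000 equally sized random transcript sets from the same transcriptome;
   significance is reported both as the literal one-sample two-tailed
   t-test and as a rank-based empirical p-value (recommended), with the
   usual star tiers (`***` < 0.005, `**` < 0.01, `*` < 0.05, `#` n.s.).

A first-class synthetic-data module (`sim_config()`, `make_trna_set()`,
`simulate_read_libraries()`, `simulate_utr_alignments()`,
`simulate_expression()`) generates all inputs with planted ground truth, so
the whole pipeline is testable offline.

## Worked example

```r
library(trftools)

cfg <- sim_config(seed = 1)          # 3 timepoints x 3 replicates, 10^6 reads each
study <- run_simulation_study(cfg)   # simulate -> extract -> seeds -> regulation
print(study)
```

```
Synthetic end-to-end study
  called tRFs: 8; planted recovered with exact endpoints: 100%
  age-pattern recovery: 100%
  5' vs 3' length variance: 9.14 vs 0.32 (5' broader, as expected)
  planted seed offsets recovered exactly: TRUE; sub-threshold calls: 0
  target sets recovered exactly: TRUE
Target-set regulation test (empirical mode, 1000 resamples)
         set      >5%     >10%      >20%
 3p-trna0001 3.86 *** 5.20 ***    3.67 *
 5p-trna0005 4.67 *** 9.00 *** 17.00 ***
```

All eight planted fragments pass the 0.1 %-per-replicate filter and come
back with exact endpoints and classes; 5' fragment lengths scatter far more
than 3' ones (the two cleavage mechanisms differ); both planted seed
windows are recovered at exactly their planted offsets and nowhere else;
and the planted 15 % target down-regulation is significant at every
threshold (entries are down/up count ratios with their significance tier).

Individual stages are plain functions — `read_trna_fasta()`,
`read_small_rna()`, `map_reads()`, `call_trfs()`, `seed_profile()`
(with a `plot()` method for the observed/expected/composition series),
`predict_targets()`, `regulation_test()`, `write_site_records()` — see the
methods vignette (`vignettes/trftools-methods.Rmd`) for the model, the
parameters and their defaults, and the design choices.

Running against real data requires a mature-tRNA FASTA (gtRNAdb/tRNAdb
header dialects supported), FASTQ or collapsed-FASTA small-RNA libraries,
TargetScan-style multi-species 3'UTR alignments and an expression table;
reproducing the original published analysis additionally needs its
deposited accessions, which are not bundled here.

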