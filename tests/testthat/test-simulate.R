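cfg_small <- sim_config(seed = 11, n_trnas = 10, library_depth = 5e4,
                        n_genes = 20, genes_per_window = 5, utr_width = 200,
                        n_transcripts = 400)

test_that("tRNA set generation is deterministic, CCA-terminated and flaggable", {
  ts1 <- make_trna_set(cfg_small)
  ts2 <- make_trna_set(cfg_small)
  expect_identical(ts1$trnas, ts2$trnas)
  expect_equal(nrow(ts1$trnas), 10)
  expect_true(all(endsWith(ts1$trnas$sequence, "CCA")))
  expect_equal(sum(ts1$trnas$is_mitochondrial), 2)

  cfg_dup <- sim_config(seed = 11, n_trnas = 10, n_duplicate_pairs = 2)
  tsd <- make_trna_set(cfg_dup)
  expect_equal(sum(!is.na(tsd$trnas$duplicate_of)), 2)
  f1 <- tempfile(); f2 <- tempfile()
  write_trna_fasta(ts1$trnas, f1)
  write_trna_fasta(make_trna_set(cfg_small)$trnas, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted trajectories scale expected abundance geometrically", {
  expect_equal(trftools:::trajectory_multipliers("MONO_UP", 2), c(1, 2, 4))
  expect_equal(trftools:::trajectory_multipliers("MONO_DOWN", 2), c(1, 0.5, 0.25))
  expect_equal(trftools:::trajectory_multipliers("DIP", 2), c(1, 0.5, 2))
  # realized counts track expectation when noise is off
  cfg0 <- sim_config(seed = 5, n_trnas = 10, library_depth = 2e5,
                     noise_cv = 0, jitter_3p_sd = 0, jitter_5p_sd = 0)
  ts <- make_trna_set(cfg0)
  sim <- simulate_read_libraries(ts$trnas, cfg0)
  planted <- sim$truth$planted
  up <- planted[planted$trajectory == "MONO_UP", ][1, ]
  counts <- vapply(sim$libraries, function(lb) {
    i <- match(up$sequence, lb$reads$sequence)
    if (is.na(i)) 0L else lb$reads$count[i]
  }, integer(1))
  tp <- vapply(sim$libraries, `[[`, character(1), "timepoint")
  m <- tapply(counts, tp, mean)[c("Y", "M", "O")]
  expected <- up$base_fraction * 2e5 * c(1, 2, 4)
  expect_true(all(abs(m - expected) / expected < 0.05))
})

test_that("zero 3' jitter gives one shared endpoint; jitter widens 5' ends", {
  cfg0 <- sim_config(seed = 6, n_trnas = 10, library_depth = 5e4,
                     jitter_3p_sd = 0)
  ts <- make_trna_set(cfg0)
  sim <- simulate_read_libraries(ts$trnas, cfg0)
  planted <- sim$truth$planted
  p3 <- planted[planted$class == "THREE_PRIME_CCA", ]
  lib <- sim$libraries[[1]]
  idx <- build_trna_index(ts$trnas)
  m <- map_reads(lib$reads, index = idx)
  m3 <- m[m$class == "THREE_PRIME_CCA" & m$trna_id %in% p3$trna_id, ]
  # every 3' read of a planted tRNA shares the planted endpoints exactly
  for (id in unique(m3$trna_id)) {
    expect_equal(unique(m3$start[m3$trna_id == id]),
                 p3$start[p3$trna_id == id])
  }
})

test_that("internal background fraction matches its configuration", {
  cfg <- sim_config(seed = 8, n_trnas = 10, library_depth = 2e5,
                    internal_fraction = 0.05)
  ts <- make_trna_set(cfg)
  sim <- simulate_read_libraries(ts$trnas, cfg)
  idx <- build_trna_index(ts$trnas)
  m <- map_reads(sim$libraries[[1]]$reads, index = idx)
  st <- library_stats(m)
  internal <- st$class_fraction[["INTERNAL"]] * st$mapped_fraction
  expect_lt(abs(internal - 0.05), 0.01)
})

test_that("UTR planting hits exactly k species at shared columns", {
  wp <- data.frame(trf_id = "t1", offset = 3L, window = "ACCTGGA",
                   stringsAsFactors = FALSE)
  utr <- simulate_utr_alignments(cfg_small, wp)
  expect_equal(length(utr$blocks), 20)
  expect_equal(nrow(utr$truth), 5)
  site <- utr$truth$site[1]
  for (i in seq_len(nrow(utr$truth))) {
    b <- utr$blocks[[utr$truth$gene_id[i]]]
    span <- substring(b$rows, utr$truth$msa_start[i], utr$truth$msa_end[i])
    carriers <- names(b$rows)[gsub("-", "", span, fixed = TRUE) == site]
    expect_equal(trftools:::format_species(carriers), utr$truth$species[i])
    expect_equal(length(carriers), cfg_small$conservation_k)
    expect_true(all(c("9606", "10090", "10116") %in% carriers))
  }
  # determinism
  utr2 <- simulate_utr_alignments(cfg_small, wp)
  expect_identical(utr$blocks, utr2$blocks)
})

test_that("chance 7-mer occurrences in background blocks follow the closed form", {
  cfg <- sim_config(seed = 21, n_genes = 60, utr_width = 2000, gap_rate = 0,
                    gc = 0.5)
  utr <- simulate_utr_alignments(cfg, data.frame(trf_id = character(0),
                                                 offset = integer(0),
                                                 window = character(0)))
  kmer <- "ACGTACG"
  L <- 2000
  occ <- vapply(utr$blocks, function(b) {
    length(trftools:::find_all(kmer, b$rows[["10116"]]))
  }, integer(1))
  expected <- (L - 6) * 4^-7
  n <- length(occ)
  se <- sqrt(expected / n)  # Poisson approximation for the mean
  expect_lt(abs(mean(occ) - expected), 4 * se + 1e-9)
})

test_that("expression simulation plants the configured down-regulation", {
  cfg <- sim_config(seed = 31, n_transcripts = 3000,
                    target_downregulation = 0.15)
  targets <- sprintf("tx%05d", 1:200)
  sim <- simulate_expression(cfg, targets)
  expect_identical(sim$table$values,
                   simulate_expression(cfg, targets)$table$values)
  ch <- fold_changes(sim$table)
  med_t <- median(ch[targets])
  med_bg <- median(ch[setdiff(names(ch), targets)])
  expect_lt(abs(med_t - (-0.15)), 0.05)
  expect_lt(abs(med_bg), 0.04)
})

test_that("regenerating one library leaves the others untouched", {
  cfg <- sim_config(seed = 12, n_trnas = 8, library_depth = 2e4)
  ts <- make_trna_set(cfg)
  s1 <- simulate_read_libraries(ts$trnas, cfg)
  cfg2 <- cfg
  cfg2$n_replicates <- 2L  # drop one replicate; shared libraries identical
  s2 <- simulate_read_libraries(ts$trnas, cfg2)
  lab <- function(s) vapply(s$libraries, function(l)
    paste(l$timepoint, l$replicate), character(1))
  shared <- intersect(lab(s1), lab(s2))
  for (l in shared) {
    expect_identical(s1$libraries[[match(l, lab(s1))]]$reads,
                     s2$libraries[[match(l, lab(s2))]]$reads)
  }
})
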