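# Synthetic-data generators. They emit exactly the formats the io module
# reads, with known planted ground truth: tRNA gene sets with anticodon
# labels and CCA, nine read libraries (3 timepoints x 3 replicates) with
# planted cleavage-site distributions and age trajectories, multi-species
# 3'UTR alignment blocks with sites planted in k of the 23 vertebrate taxa,
# and expression tables with planted target down-regulation.
#
# A single integer seed feeds one child RNG stream per generated component
# (derive_seed), so regenerating one library never perturbs the others.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with defaults
#' matching the study design being emulated: 3 age timepoints (Y, M, O) x 3
#' replicates, library depth 10^6 reads, 23-species UTR alignments with
#' sites planted in `conservation_k` species always including human, mouse
#' and rat, and a three-threshold target-regulation analysis.
#'
#' Cleavage geometry: 3' fragments end exactly at the CCA terminus with a
#' small start jitter (`jitter_3p_sd`, default 0.5 nt); 5' fragments start
#' at position 1 with a larger end jitter (`jitter_5p_sd`, default 3 nt).
#' Age trajectories multiply expected abundance by `effect_size` per age
#' step: MONO_UP (1, e, e^2), MONO_DOWN (1, 1/e, 1/e^2), DIP (1, 1/e, e),
#' FLAT (1, 1, 1). Replicate noise is multiplicative log-normal with
#' coefficient of variation `noise_cv`.
#'
#' @param seed master integer seed.
#' @param n_trnas number of tRNA genes to simulate.
#' @param trna_length_range min/max mature body length (nt, before CCA).
#' @param timepoints ordered age labels.
#' @param n_replicates replicates per timepoint.
#' @param library_depth total reads per library.
#' @param jitter_3p_sd,jitter_5p_sd cleavage endpoint jitter (nt sd).
#' @param trf_length_3p,trf_length_5p modal planted fragment lengths (nt).
#' @param effect_size fold-change per age step for planted trajectories.
#' @param noise_cv replicate noise coefficient of variation.
#' @param internal_fraction fraction of reads from random internal fragments.
#' @param decoy_fraction fraction of single-mismatch decoy reads (must not
#'   map under the perfect-match rule).
#' @param n_mito number of tRNAs flagged mitochondrial.
#' @param n_duplicate_pairs pairs of tRNA genes sharing one mature sequence.
#' @param n_genes number of 3'UTR alignment blocks.
#' @param utr_width alignment width (columns).
#' @param conservation_k species carrying each planted site (>= 3; the
#'   human/mouse/rat trio is always included).
#' @param genes_per_window genes carrying each planted seed window.
#' @param gc background GC content of simulated UTRs.
#' @param gap_rate per-cell gap probability outside planted spans.
#' @param n_transcripts transcripts in the simulated expression table.
#' @param expr_timepoints timepoints of the expression table.
#' @param expr_ratio_sdlog sd(log) of the old/young ratio of non-targets.
#' @param target_downregulation fractional down-shift of planted targets.
#' @param expr_base_meanlog,expr_base_sdlog log-normal baseline expression.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_trnas = 20L,
                       trna_length_range = c(70L, 90L),
                       timepoints = c("Y", "M", "O"),
                       n_replicates = 3L,
                       library_depth = 1e6,
                       jitter_3p_sd = 0.5,
                       jitter_5p_sd = 3,
                       trf_length_3p = 18L,
                       trf_length_5p = 30L,
                       effect_size = 2,
                       noise_cv = 0.2,
                       internal_fraction = 0.05,
                       decoy_fraction = 0.02,
                       n_mito = 2L,
                       n_duplicate_pairs = 0L,
                       n_genes = 300L,
                       utr_width = 500L,
                       conservation_k = 16L,
                       genes_per_window = 40L,
                       gc = 0.42,
                       gap_rate = 0.02,
                       n_transcripts = 2000L,
                       expr_timepoints = c("Y", "O"),
                       expr_ratio_sdlog = 0.15,
                       target_downregulation = 0.15,
                       expr_base_meanlog = log(100),
                       expr_base_sdlog = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_trnas > 0, cfg$n_replicates > 0, cfg$library_depth > 0,
    length(cfg$trna_length_range) == 2,
    cfg$trna_length_range[1] <= cfg$trna_length_range[2],
    cfg$trna_length_range[1] >= cfg$trf_length_5p + 5,
    cfg$conservation_k >= 3, cfg$conservation_k <= length(VERTEBRATE_TAXA),
    cfg$n_genes > 0, cfg$utr_width >= 50,
    cfg$noise_cv >= 0, cfg$gc > 0, cfg$gc < 1,
    cfg$gap_rate >= 0, cfg$gap_rate < 0.5,
    cfg$target_downregulation >= 0, cfg$target_downregulation < 1
  )
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# trajectory multipliers across the three age steps
trajectory_multipliers <- function(pattern, effect, n_tp = 3) {
  e <- effect
  base <- switch(pattern,
    MONO_UP = c(1, e, e^2),
    MONO_DOWN = c(1, 1 / e, 1 / e^2),
    DIP = c(1, 1 / e, e),
    FLAT = c(1, 1, 1),
    stop("unknown trajectory: ", pattern, call. = FALSE)
  )
  base[seq_len(n_tp)]
}

# amino-acid label (3-letter) for an anticodon via the standard code
anticodon_to_aa <- function(anticodon) {
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  codon <- revcomp(anticodon)
  aa1 <- as.character(Biostrings::GENETIC_CODE[codon])
  ifelse(is.na(aa1) | aa1 == "*", "Unk", three[aa1])
}

#' Simulate a mature tRNA gene set
#'
#' Random tRNA-like sequences with assigned anticodons and CCA appended.
#' A configurable number of records is flagged mitochondrial and a
#' configurable number of gene pairs share one mature sequence (duplicate
#' flagging exercised downstream).
#'
#' @param config a [sim_config()].
#' @return list with `trnas` (a `trna_set`) and `truth`.
#' @export
make_trna_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "trna"), {
    n <- config$n_trnas
    lens <- sample(config$trna_length_range[1]:config$trna_length_range[2],
                   n, replace = TRUE)
    # sense anticodons only
    all_ac <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                c("A","C","G","T")), 1, paste, collapse = "")
    sense <- all_ac[Biostrings::GENETIC_CODE[revcomp(all_ac)] != "*"]
    acs <- sample(sense, n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) random_dna(1, lens[i]), character(1))
    if (config$n_duplicate_pairs > 0) {
      stopifnot(2 * config$n_duplicate_pairs <= n)
      for (p in seq_len(config$n_duplicate_pairs)) {
        seqs[2 * p] <- seqs[2 * p - 1]
      }
    }
    mito <- seq_len(n) > n - config$n_mito
    ids <- ifelse(mito, sprintf("MtdbD%07d", seq_len(n)),
                  sprintf("trna%04d", seq_len(n)))
    seqs_cca <- ifelse(endsWith(seqs, "CCA"), seqs, paste0(seqs, "CCA"))
    dup <- rep(NA_character_, n)
    first <- !duplicated(seqs_cca)
    dup[!first] <- ids[match(seqs_cca[!first], seqs_cca[first])]
    trnas <- data.frame(
      id = ids,
      amino_acid = anticodon_to_aa(acs),
      anticodon = acs,
      sequence = seqs_cca,
      has_cca = TRUE,
      is_mitochondrial = mito,
      source_db = ifelse(mito, "TRNADB", "GTRNADB"),
      duplicate_of = dup,
      stringsAsFactors = FALSE
    )
    class(trnas) <- c("trna_set", "data.frame")
    list(trnas = trnas, truth = list(body_length = lens))
  })
}

# default planted-tRF plan over a tRNA set: four 3'CCA fragments
# (trajectories MONO_UP x3, FLAT) and four 5' fragments (DIP x2,
# MONO_DOWN, FLAT), base abundance fractions chosen so every planted
# fragment clears the 0.1%-per-replicate filter at all ages
default_trf_plan <- function(trnas) {
  stopifnot(nrow(trnas) >= 8)
  idx <- which(is.na(trnas$duplicate_of))[1:8]
  data.frame(
    trna_id = trnas$id[idx],
    class = rep(c("THREE_PRIME_CCA", "FIVE_PRIME"), each = 4),
    trajectory = c("MONO_UP", "MONO_UP", "MONO_UP", "FLAT",
                   "DIP", "DIP", "MONO_DOWN", "FLAT"),
    base_fraction = c(rep(0.02, 4), rep(0.012, 4)),
    stringsAsFactors = FALSE
  )
}

#' Simulate collapsed small-RNA libraries with planted tRFs
#'
#' For each (timepoint, replicate) a library of exactly
#' `config$library_depth` reads is produced: planted tRF reads with
#' class-specific endpoint jitter, a background of random internal tRNA
#' fragments, single-mismatch decoy reads (which must fail the
#' perfect-match mapper), and unrelated filler sequences. Expected planted
#' abundance follows each tRF's age trajectory; replicate noise is
#' multiplicative log-normal with CV `config$noise_cv`.
#'
#' @param trnas a `trna_set` (CCA-appended).
#' @param config a [sim_config()].
#' @param plan optional data frame (`trna_id`, `class`, `trajectory`,
#'   `base_fraction`) overriding [default_trf_plan()].
#' @return list with `libraries` (list of per-library lists: `timepoint`,
#'   `replicate`, `reads` (`collapsed_reads`), `total_reads`) and `truth`
#'   (planted endpoints, sequences, trajectories, expected fractions).
#' @export
simulate_read_libraries <- function(trnas, config, plan = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(plan)) plan <- default_trf_plan(trnas)
  stopifnot(all(plan$trna_id %in% trnas$id))
  seq_of <- setNames(trnas$sequence, trnas$id)
  L <- nchar(seq_of[plan$trna_id])
  plan$end <- ifelse(plan$class == "THREE_PRIME_CCA", L,
                     config$trf_length_5p)
  plan$start <- ifelse(plan$class == "THREE_PRIME_CCA",
                       L - config$trf_length_3p + 1L, 1L)
  plan$sequence <- substring(seq_of[plan$trna_id], plan$start, plan$end)
  plan$trf_id <- paste0(ifelse(plan$class == "THREE_PRIME_CCA", "3p-", "5p-"),
                        plan$trna_id)

  n_tp <- length(config$timepoints)
  mult <- t(vapply(plan$trajectory, trajectory_multipliers,
                   numeric(n_tp), effect = config$effect_size,
                   n_tp = n_tp))
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  depth <- config$library_depth

  libraries <- list()
  for (ti in seq_len(n_tp)) {
    for (r in seq_len(config$n_replicates)) {
      tp <- config$timepoints[ti]
      lib <- with_seed(derive_seed(config$seed, "lib", tp, r), {
        seq_parts <- character(0)
        cnt_parts <- integer(0)
        total_planted <- 0L
        for (k in seq_len(nrow(plan))) {
          mean_k <- plan$base_fraction[k] * depth * mult[k, ti]
          noise <- if (config$noise_cv > 0) {
            rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
          } else 1
          nk <- rpois(1, mean_k * noise)
          if (nk == 0) next
          tseq <- seq_of[plan$trna_id[k]]
          tl <- nchar(tseq)
          if (plan$class[k] == "THREE_PRIME_CCA") {
            starts <- plan$start[k] + as.integer(round(rnorm(nk, 0, config$jitter_3p_sd)))
            starts <- pmin(pmax(starts, 2L), tl - 16L)
            frag <- substring(tseq, starts, tl)
            key <- starts
          } else {
            ends <- plan$end[k] + as.integer(round(rnorm(nk, 0, config$jitter_5p_sd)))
            ends <- pmin(pmax(ends, 17L), tl - 1L)
            frag <- substring(tseq, 1L, ends)
            key <- ends
          }
          tab <- table(frag)
          seq_parts <- c(seq_parts, names(tab))
          cnt_parts <- c(cnt_parts, as.integer(tab))
          total_planted <- total_planted + nk
        }
        # internal background: perfect-match fragments away from both ends
        n_int <- rpois(1, config$internal_fraction * depth)
        if (n_int > 0) {
          ti_idx <- sample.int(nrow(trnas), n_int, replace = TRUE)
          tl <- nchar(trnas$sequence[ti_idx])
          len <- 17L + (sample.int(8L, n_int, replace = TRUE) - 1L)
          smax <- tl - len  # end <= tl - 1 => start <= tl - len
          s <- 2L + as.integer(floor(runif(n_int) * pmax(smax - 1L, 1L)))
          s <- pmin(s, smax)
          frag <- substring(trnas$sequence[ti_idx], s, s + len - 1L)
          tab <- table(frag)
          seq_parts <- c(seq_parts, names(tab))
          cnt_parts <- c(cnt_parts, as.integer(tab))
        }
        # decoys: tRNA fragments with one substitution (perfect match fails)
        n_dec <- rpois(1, config$decoy_fraction * depth)
        if (n_dec > 0) {
          n_species <- 200L
          src <- sample.int(nrow(trnas), n_species, replace = TRUE)
          tl <- nchar(trnas$sequence[src])
          s <- 2L + (sample.int(10L, n_species, replace = TRUE) - 1L)
          frag <- substring(trnas$sequence[src], s, pmin(s + 19L, tl - 1L))
          pos <- 1L + (sample.int(17L, n_species, replace = TRUE) - 1L)
          old <- substring(frag, pos, pos)
          sub <- vapply(old, function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                        character(1))
          substring(frag, pos, pos) <- sub
          cnts <- tabulate(sample.int(n_species, n_dec, replace = TRUE), n_species)
          keep <- cnts > 0
          tab <- rowsum(cnts[keep], frag[keep])
          seq_parts <- c(seq_parts, rownames(tab))
          cnt_parts <- c(cnt_parts, as.integer(tab[, 1]))
        }
        # unrelated filler up to the exact library depth
        n_fill <- depth - sum(cnt_parts)
        if (n_fill < 0) {
          stop("planted+background fractions exceed library depth", call. = FALSE)
        }
        if (n_fill > 0) {
          n_species <- 1000L
          fill_len <- 17L + (sample.int(8L, n_species, replace = TRUE) - 1L)
          fill_seqs <- vapply(seq_len(n_species),
                              function(i) random_dna(1, fill_len[i]),
                              character(1))
          cnts <- tabulate(sample.int(n_species, n_fill, replace = TRUE), n_species)
          keep <- cnts > 0
          tab <- rowsum(cnts[keep], fill_seqs[keep])
          seq_parts <- c(seq_parts, rownames(tab))
          cnt_parts <- c(cnt_parts, as.integer(tab[, 1]))
        }
        reads <- collapse_reads(data.frame(sequence = seq_parts,
                                           count = cnt_parts,
                                           stringsAsFactors = FALSE))
        list(timepoint = tp, replicate = r,
             reads = as_collapsed_reads(reads),
             total_reads = sum(reads$count))
      })
      libraries[[length(libraries) + 1L]] <- lib
    }
  }
  truth <- list(planted = plan,
                expected_fraction = sweep(mult, 1, plan$base_fraction, `*`),
                timepoints = config$timepoints)
  list(libraries = libraries, truth = truth)
}

#' Simulate multi-species 3'UTR alignment blocks with planted seed sites
#'
#' Generates `config$n_genes` alignment blocks over the 23 vertebrate taxa.
#' For each row of `windows_to_plant`, the corresponding target-site
#' sequence (see [site_variants()]) is inserted at one shared
#' alignment-column span in exactly `config$conservation_k` species per
#' chosen gene, always including human (9606), mouse (10090) and rat
#' (10116). Remaining sequence is i.i.d. background with the configured GC;
#' gaps appear at `config$gap_rate` outside planted spans.
#'
#' @param config a [sim_config()].
#' @param windows_to_plant data frame with columns `trf_id`, `offset`,
#'   `window` (7-mer); optional `match_type` (default `"7mer-m8"`),
#'   `conservation_k`, `genes_per_window` (default from config).
#' @param orientation site orientation convention passed to
#'   [site_variants()].
#' @return list with `blocks` (a `utr_block_set`) and `truth` (planted site
#'   table: gene, tRF, offset, columns, rat UTR coordinates, species).
#' @export
simulate_utr_alignments <- function(config, windows_to_plant,
                                    orientation = c("complementary", "direct")) {
  stopifnot(inherits(config, "sim_config"))
  orientation <- match.arg(orientation)
  wp <- windows_to_plant
  stopifnot(all(c("trf_id", "offset", "window") %in% names(wp)))
  check_dna(wp$window, what = "planted window")
  stopifnot(all(nchar(wp$window) == 7))
  if (is.null(wp$match_type)) wp$match_type <- rep("7mer-m8", nrow(wp))
  if (is.null(wp$conservation_k)) {
    wp$conservation_k <- rep(config$conservation_k, nrow(wp))
  }
  if (is.null(wp$genes_per_window)) {
    wp$genes_per_window <- rep(config$genes_per_window, nrow(wp))
  }
  stopifnot(all(wp$conservation_k >= 3))

  taxa <- VERTEBRATE_TAXA
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  W <- config$utr_width

  # assignment of planted sites to genes
  plant_rows <- with_seed(derive_seed(config$seed, "utr", "plan"), {
    out <- list()
    for (i in seq_len(nrow(wp))) {
      genes <- sample(gene_ids, wp$genes_per_window[i])
      k <- wp$conservation_k[i]
      site <- site_variants(wp$window[i], orientation)[[wp$match_type[i]]]
      for (g in genes) {
        sp <- c(REQUIRED_TAXA,
                sample(setdiff(taxa, REQUIRED_TAXA), k - 3L))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, trf_id = wp$trf_id[i], offset = wp$offset[i],
          window = wp$window[i], match_type = wp$match_type[i],
          site = site, species = format_species(sp),
          stringsAsFactors = FALSE)
      }
    }
    if (length(out) == 0) {
      data.frame(gene_id = character(0), trf_id = character(0),
                 offset = integer(0), window = character(0),
                 match_type = character(0), site = character(0),
                 species = character(0), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, out)
    }
  })

  truth_rows <- list()
  blocks <- lapply(gene_ids, function(g) {
    with_seed(derive_seed(config$seed, "utr", g), {
      rows <- vapply(seq_along(taxa), function(i) {
        s <- random_dna(1, W, gc = config$gc)
        if (config$gap_rate > 0) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          ch[runif(W) < config$gap_rate] <- "-"
          s <- paste(ch, collapse = "")
        }
        s
      }, character(1))
      names(rows) <- as.character(taxa)
      here <- plant_rows[plant_rows$gene_id == g, , drop = FALSE]
      occupied <- integer(0)
      if (nrow(here) > 0) {
        for (j in seq_len(nrow(here))) {
          site <- here$site[j]
          k <- nchar(site)
          placed <- FALSE
          for (try in 1:50) {
            cs <- sample.int(W - k + 1L, 1)
            span <- cs:(cs + k - 1L)
            if (!any(span %in% occupied)) { placed <- TRUE; break }
          }
          if (!placed) {
            stop("could not place planted site without collision in gene ", g,
                 call. = FALSE)
          }
          occupied <- c(occupied, span)
          carriers <- strsplit(here$species[j], ",")[[1]]
          for (sp in names(rows)) {
            if (sp %in% carriers) {
              substring(rows[[sp]], cs, cs + k - 1L) <- site
            } else {
              # non-carriers must not accidentally equal the site there
              while (gsub("-", "", substring(rows[[sp]], cs, cs + k - 1L),
                          fixed = TRUE) == site) {
                substring(rows[[sp]], cs, cs + k - 1L) <- random_dna(1, k, gc = config$gc)
              }
            }
          }
          rat <- rows[[as.character(REFERENCE_TAXON)]]
          pre <- substring(rat, 1L, cs - 1L)
          utr_start <- nchar(gsub("-", "", pre, fixed = TRUE)) + 1L
          truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
            here[j, c("gene_id", "trf_id", "offset", "window",
                      "match_type", "site", "species")],
            msa_start = cs, msa_end = cs + k - 1L,
            utr_start = utr_start, utr_end = utr_start + k - 1L,
            stringsAsFactors = FALSE)
        }
      }
      structure(list(gene_id = g, rows = rows, width = W),
                class = "utr_block")
    })
  })
  names(blocks) <- gene_ids
  class(blocks) <- c("utr_block_set", class(blocks))
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  list(blocks = blocks, truth = truth)
}

#' Simulate a transcript expression table with planted target regulation
#'
#' Non-target transcripts get an old/young expression ratio that is
#' log-normal around 1 (sd(log) `config$expr_ratio_sdlog`); transcripts in
#' `target_sets` have their ratio multiplied by
#' `1 - config$target_downregulation`. Each timepoint gets
#' `config$n_replicates` replicates with multiplicative log-normal noise.
#'
#' @param config a [sim_config()].
#' @param target_sets named list of transcript-id character vectors (or a
#'   single character vector). Ids must be among the simulated transcripts
#'   (`tx0001` ...).
#' @return list with `table` (an `expression_table`) and `truth`
#'   (per-transcript true ratio and target membership).
#' @export
simulate_expression <- function(config, target_sets = list()) {
  stopifnot(inherits(config, "sim_config"))
  if (is.character(target_sets)) target_sets <- list(set1 = target_sets)
  n <- config$n_transcripts
  ids <- sprintf("tx%05d", seq_len(n))
  bad <- setdiff(unlist(target_sets), ids)
  if (length(bad) > 0) stop("unknown target transcript ids: ", bad[1],
                            call. = FALSE)
  tps <- config$expr_timepoints
  n_tp <- length(tps)
  reps <- config$n_replicates
  sdlog_n <- sqrt(log(1 + config$noise_cv^2))
  with_seed(derive_seed(config$seed, "expr"), {
    base <- rlnorm(n, config$expr_base_meanlog, config$expr_base_sdlog)
    ratio <- rlnorm(n, 0, config$expr_ratio_sdlog)
    is_target <- ids %in% unlist(target_sets)
    ratio[is_target] <- ratio[is_target] * (1 - config$target_downregulation)
    # geometric interpolation of the ratio across timepoints
    vals <- matrix(0, n, n_tp * reps)
    col_tp <- character(n_tp * reps)
    col_rep <- character(n_tp * reps)
    j <- 0L
    for (ti in seq_len(n_tp)) {
      frac <- if (n_tp == 1) 0 else (ti - 1) / (n_tp - 1)
      mean_tp <- base * ratio^frac
      for (r in seq_len(reps)) {
        j <- j + 1L
        noise <- if (config$noise_cv > 0) {
          rlnorm(n, -sdlog_n^2 / 2, sdlog_n)
        } else 1
        vals[, j] <- mean_tp * noise
        col_tp[j] <- tps[ti]
        col_rep[j] <- as.character(r)
      }
    }
    rownames(vals) <- ids
    tab <- structure(list(values = vals, timepoints = tps,
                          col_tp = col_tp, col_rep = col_rep),
                     class = "expression_table")
    truth <- data.frame(transcript_id = ids, true_ratio = ratio,
                        is_target = is_target, stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}
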