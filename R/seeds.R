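# Candidate seed discovery on tRFs: slide a 7-nt window along the fragment,
# derive the miRNA-style target-site sequences (7mer-m8, 7mer-1a, 8mer-1a),
# count genes with conserved sites in multi-species 3'UTR alignments
# (conserved = present in >= 15 of 23 species, always including human, mouse
# and rat), and compare the observed count against two nulls: the expected
# count from background 7-mer frequency and the mean count over all 7-mers
# of the same nucleotide composition.

#' Conservation rule for target sites
#'
#' @param min_species minimum number of species carrying a site (default 15).
#' @param universe taxonomy IDs of the alignment species (default the 23
#'   vertebrate set).
#' @param required taxonomy IDs that must always carry the site (default
#'   human 9606, mouse 10090, rat 10116).
#' @param mode `"aligned_columns"` (site must occupy the same alignment
#'   columns in every species; default) or `"anywhere"` (site may occur
#'   anywhere in the species' ungapped UTR).
#' @return a `conservation_rule` list.
#' @export
conservation_rule <- function(min_species = 15L,
                              universe = VERTEBRATE_TAXA,
                              required = REQUIRED_TAXA,
                              mode = c("aligned_columns", "anywhere")) {
  mode <- match.arg(mode)
  stopifnot(all(required %in% universe), min_species <= length(universe),
            min_species >= 1)
  structure(list(min_species = as.integer(min_species),
                 universe = as.integer(universe),
                 required = as.integer(required),
                 mode = mode),
            class = "conservation_rule")
}

#' Sliding 7-mer windows along a tRF
#'
#' @param trf_sequence DNA string of length >= 7.
#' @param k window length (default 7 nt).
#' @return data frame with `offset` (1-based start on the tRF, 5' to 3')
#'   and `kmer`; exactly `L - k + 1` rows.
#' @export
sliding_windows <- function(trf_sequence, k = 7L) {
  stopifnot(is.character(trf_sequence), length(trf_sequence) == 1)
  trf_sequence <- toupper(rna_to_dna(trf_sequence))
  check_dna(trf_sequence, what = "tRF sequence")
  L <- nchar(trf_sequence)
  if (L < k) stop("tRF shorter than the window (", L, " < ", k, ")",
                  call. = FALSE)
  starts <- seq_len(L - k + 1L)
  data.frame(offset = starts,
             kmer = substring(trf_sequence, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Target-site sequence variants of a 7-mer window
#'
#' Under the default complementary convention (miRNA-style target sites on
#' the mRNA strand): the 7mer-m8 site is the reverse complement of the
#' window; the 7mer-1a site is the reverse complement of the window's first
#' 6 nt followed by an A; the 8mer-1a site is the 7mer-m8 site followed by
#' an A. Under the direct convention the literal window subsequences are
#' used instead of their complements.
#'
#' @param window a 7-nt DNA string.
#' @param orientation `"complementary"` (default) or `"direct"`.
#' @return named character vector with elements `7mer-m8`, `7mer-1a`,
#'   `8mer-1a`.
#' @export
site_variants <- function(window, orientation = c("complementary", "direct")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(window), length(window) == 1, nchar(window) == 7)
  window <- toupper(rna_to_dna(window))
  check_dna(window, what = "seed window")
  if (orientation == "complementary") {
    m8 <- revcomp(window)
    m1a <- paste0(revcomp(substring(window, 1, 6)), "A")
  } else {
    m8 <- window
    m1a <- paste0(substring(window, 1, 6), "A")
  }
  c("7mer-m8" = m8, "7mer-1a" = m1a, "8mer-1a" = paste0(m8, "A"))
}

# reference-species view of a block: ungapped sequence plus the alignment
# column of every ungapped position; NULL when the reference is absent
block_ref <- function(block, ref_taxon = REFERENCE_TAXON) {
  i <- match(as.character(ref_taxon), names(block$rows))
  if (is.na(i)) return(NULL)
  ref <- block$rows[[i]]
  ch <- strsplit(ref, "", fixed = TRUE)[[1]]
  cols <- which(ch != "-")
  if (length(cols) == 0) return(NULL)
  list(seq = paste(ch[cols], collapse = ""), cols = cols)
}

# species carrying site `s` over alignment columns [cs, ce] (aligned mode)
# or anywhere in their ungapped sequence (anywhere mode)
species_with_site <- function(block, s, cs, ce, mode) {
  hit <- vapply(block$rows, function(row) {
    if (mode == "aligned_columns") {
      gsub("-", "", substring(row, cs, ce), fixed = TRUE) == s
    } else {
      grepl(s, gsub("-", "", row, fixed = TRUE), fixed = TRUE)
    }
  }, logical(1))
  as.integer(names(block$rows)[hit])
}

is_conserved <- function(taxa, rule) {
  length(taxa) >= rule$min_species && all(rule$required %in% taxa)
}

#' Locate conserved target sites of a window in one alignment block
#'
#' Every occurrence of each site variant in the reference species (rat)
#' ungapped 3'UTR is located; its alignment-column span is projected and
#' the site is scored present in every species whose ungapped characters
#' across that span equal the site (aligned-columns mode) or that contain
#' the site anywhere (anywhere mode). An occurrence is conserved iff it is
#' present in at least `rule$min_species` species including all required
#' species. Blocks lacking the reference species are skipped with a warning.
#'
#' @param variants named site-variant vector from [site_variants()].
#' @param block a `utr_block`.
#' @param rule a [conservation_rule()].
#' @param window_offset 1-based start of the window on the tRF (recorded in
#'   the output).
#' @return a `site_records` data frame (possibly empty), one row per
#'   conserved occurrence, with alignment (MSA) and ungapped reference UTR
#'   coordinates, match type, and the ascending comma-joined taxonomy IDs
#'   of carrying species.
#' @export
find_sites_in_block <- function(variants, block, rule,
                                window_offset = NA_integer_) {
  info <- block_ref(block)
  if (is.null(info)) {
    warning("reference species absent from block ", block$gene_id,
            "; block skipped", call. = FALSE)
    return(empty_site_records())
  }
  out <- list()
  for (mt in names(variants)) {
    s <- variants[[mt]]
    k <- nchar(s)
    starts <- find_all(s, info$seq)
    for (p in starts) {
      cs <- info$cols[p]
      ce <- info$cols[p + k - 1L]
      taxa <- species_with_site(block, s, cs, ce, rule$mode)
      if (is_conserved(taxa, rule)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_name = block$gene_id,
          window_offset = window_offset,
          msa_start = cs, msa_end = ce,
          utr_start = p, utr_end = p + k - 1L,
          match_type = mt,
          species = format_species(taxa),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_site_records())
  rec <- do.call(rbind, out)
  class(rec) <- c("site_records", "data.frame")
  rec
}

empty_site_records <- function() {
  rec <- data.frame(gene_name = character(0), window_offset = integer(0),
                    msa_start = integer(0), msa_end = integer(0),
                    utr_start = integer(0), utr_end = integer(0),
                    match_type = character(0), species = character(0),
                    stringsAsFactors = FALSE)
  class(rec) <- c("site_records", "data.frame")
  rec
}

#' Index conserved 7-mers across alignment blocks
#'
#' Precomputes, for every 7-mer occurring in the reference species of any
#' block, the genes in which it has at least one conserved occurrence under
#' `rule`. Makes [observed_count()], [composition_null()] and
#' [seed_profile()] O(1) per window per gene.
#'
#' @param blocks a `utr_block_set`.
#' @param rule a [conservation_rule()].
#' @param k k-mer length (7 covers all match types: a conserved 8mer-1a
#'   occurrence implies conserved occurrences of both constituent 7-mers).
#' @return a `conserved_kmer_index`.
#' @export
conserved_kmer_index <- function(blocks, rule, k = 7L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  n_pos <- 0
  for (block in blocks) {
    info <- block_ref(block)
    if (is.null(info)) next
    L <- nchar(info$seq)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    n_pos <- n_pos + length(starts)
    kmers <- substring(info$seq, starts, starts + k - 1L)
    cs <- info$cols[starts]
    ce <- info$cols[starts + k - 1L]
    n <- integer(length(starts))
    req_ok <- rep(TRUE, length(starts))
    for (sp in names(block$rows)) {
      if (rule$mode == "aligned_columns") {
        hit <- gsub("-", "", substring(block$rows[[sp]], cs, ce),
                    fixed = TRUE) == kmers
      } else {
        sp_seq <- gsub("-", "", block$rows[[sp]], fixed = TRUE)
        sp_kmers <- unique(substring(sp_seq, seq_len(max(nchar(sp_seq) - k + 1L, 0L)),
                                     seq_len(max(nchar(sp_seq) - k + 1L, 0L)) + k - 1L))
        hit <- kmers %in% sp_kmers
      }
      n <- n + hit
      if (as.integer(sp) %in% rule$required) req_ok <- req_ok & hit
    }
    ok <- n >= rule$min_species & req_ok
    for (km in unique(kmers[ok])) {
      env[[km]] <- c(env[[km]], block$gene_id)
    }
  }
  for (km in ls(env)) env[[km]] <- unique(env[[km]])
  structure(list(env = env, n_genes = length(blocks), k = k,
                 n_ref_positions = n_pos, rule = rule),
            class = "conserved_kmer_index")
}

index_genes <- function(index, kmer) {
  g <- index$env[[kmer]]
  if (is.null(g)) character(0) else g
}

# genes with >= 1 conserved 7mer-m8 or 7mer-1a site for a window
observed_genes <- function(window, blocks = NULL, rule = NULL,
                           orientation = "complementary", index = NULL) {
  v <- site_variants(window, orientation)
  if (is.null(index)) {
    stopifnot(!is.null(blocks), !is.null(rule))
    index <- conserved_kmer_index(blocks, rule)
  }
  sort(union(index_genes(index, v[["7mer-m8"]]),
             index_genes(index, v[["7mer-1a"]])))
}

#' Observed conserved-site gene count for a window
#'
#' Number of distinct genes with at least one conserved 7mer-m8 or 7mer-1a
#' site for the window (an 8mer-1a occurrence implies both and is counted
#' through them); each gene counts once.
#'
#' @param window 7-nt window sequence.
#' @param blocks a `utr_block_set` (ignored when `index` given).
#' @param rule a [conservation_rule()].
#' @param orientation site orientation (see [site_variants()]).
#' @param index optional [conserved_kmer_index()] over the same blocks.
#' @return integer gene count.
#' @export
observed_count <- function(window, blocks = NULL, rule = NULL,
                           orientation = c("complementary", "direct"),
                           index = NULL) {
  orientation <- match.arg(orientation)
  length(observed_genes(window, blocks, rule, orientation, index))
}

#' Expected gene-level site count from background 7-mer frequency
#'
#' The genomic null: `f * N`, where `f` is the empirical per-position
#' frequency of the window's 7mer-m8 site in a background sequence set and
#' `N` the total number of 7-mer positions scanned in the reference-species
#' sequences of the blocks. Deterministic.
#'
#' @param window 7-nt window sequence.
#' @param background character vector of background DNA sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param blocks a `utr_block_set` (or a [conserved_kmer_index()], whose
#'   recorded reference position count is then used).
#' @param rule a [conservation_rule()] (reference projection only).
#' @param orientation site orientation.
#' @return expected count (>= 0). When the site never occurs in the
#'   background a zero expectation is returned with a warning.
#' @export
expected_genomic_count <- function(window, background, blocks,
                                   rule = conservation_rule(),
                                   orientation = c("complementary", "direct")) {
  orientation <- match.arg(orientation)
  s <- site_variants(window, orientation)[["7mer-m8"]]
  if (is.character(background) && length(background) == 1 &&
      file.exists(background)) {
    background <- as.character(Biostrings::readDNAStringSet(background))
  }
  background <- toupper(rna_to_dna(as.character(background)))
  if (length(background) == 0 || sum(nchar(background)) == 0) {
    stop("empty background sequence set", call. = FALSE)
  }
  k <- nchar(s)
  npos <- pmax(nchar(background) - k + 1L, 0L)
  occ <- sum(vapply(background, function(b) length(find_all(s, b)), integer(1)))
  f <- occ / sum(npos)
  if (occ == 0) {
    warning("site ", s, " absent from background; expectation floored at 0",
            call. = FALSE)
  }
  N <- if (inherits(blocks, "conserved_kmer_index")) {
    blocks$n_ref_positions
  } else {
    sum(vapply(blocks, function(b) {
      info <- block_ref(b)
      if (is.null(info)) return(0L)
      max(nchar(info$seq) - k + 1L, 0L)
    }, integer(1)))
  }
  f * N
}

#' All distinct permutations of a k-mer's nucleotide multiset
#'
#' @param kmer DNA string.
#' @return character vector of distinct rearrangements (for a 7-mer, the
#'   multinomial coefficient 7!/(prod of letter multiplicities!), at most
#'   5040).
#' @export
distinct_permutations <- function(kmer) {
  ch <- sort(strsplit(kmer, "", fixed = TRUE)[[1]])
  n <- length(ch)
  res <- character(0)
  rec <- function(prefix, remaining) {
    if (length(remaining) == 0) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in unique(remaining)) {
      i <- match(b, remaining)
      rec(paste0(prefix, b), remaining[-i])
    }
  }
  rec("", ch)
  res
}

#' Composition null: mean conserved-site count over same-composition 7-mers
#'
#' Enumerates all distinct permutations of the window's nucleotide multiset
#' and averages their observed conserved-site gene counts. The observed
#' window itself is excluded ("all other 7-mers with the same
#' composition"); for degenerate compositions with a single permutation the
#' null falls back to including the window, with a warning.
#'
#' @param window 7-nt window sequence.
#' @param blocks a `utr_block_set` (ignored when `index` given).
#' @param rule a [conservation_rule()].
#' @param orientation site orientation.
#' @param exclude_self drop the observed window from the enumeration
#'   (default `TRUE`).
#' @param index optional [conserved_kmer_index()].
#' @return list with `mean`, `n_permutations`, and `counts` (per-permutation
#'   observed counts, named).
#' @export
composition_null <- function(window, blocks = NULL, rule = NULL,
                             orientation = c("complementary", "direct"),
                             exclude_self = TRUE, index = NULL) {
  orientation <- match.arg(orientation)
  window <- toupper(rna_to_dna(window))
  if (is.null(index)) {
    stopifnot(!is.null(blocks), !is.null(rule))
    index <- conserved_kmer_index(blocks, rule)
  }
  perms <- distinct_permutations(window)
  use <- if (exclude_self) setdiff(perms, window) else perms
  if (length(use) == 0) {
    warning("degenerate composition (single permutation); ",
            "composition null includes the window itself", call. = FALSE)
    use <- perms
  }
  counts <- vapply(use, observed_count, integer(1),
                   orientation = orientation, index = index)
  list(mean = mean(counts), n_permutations = length(perms), counts = counts)
}

#' Seed call decision
#'
#' A window is called a candidate seed iff the observed conserved-site gene
#' count is at least `ratio` times both null expectations and reaches the
#' absolute floor `min_genes`. The thresholds are reported in every output;
#' they are this tool's explicit stand-in for a visual peak call.
#'
#' @param observed observed gene count.
#' @param expected_genomic genomic-frequency null expectation.
#' @param composition_mean composition-null mean.
#' @param ratio fold-enrichment threshold over both nulls (default 2).
#' @param min_genes minimum observed gene count (default 25).
#' @return logical.
#' @export
call_seed <- function(observed, expected_genomic, composition_mean,
                      ratio = 2, min_genes = 25) {
  observed >= ratio * expected_genomic &
    observed >= ratio * composition_mean &
    observed >= min_genes
}

#' Per-offset seed profile of a tRF
#'
#' For every 7-mer window along the tRF: the observed conserved-site gene
#' count, the genomic-frequency expectation, the composition-null mean,
#' both enrichment ratios and the seed call — the three series of the
#' classic seed-profile plot.
#'
#' @param trf_sequence tRF DNA sequence (length >= 7).
#' @param blocks a `utr_block_set`.
#' @param background background sequences for [expected_genomic_count()].
#' @param rule a [conservation_rule()].
#' @param orientation site orientation.
#' @param ratio,min_genes seed-call thresholds (see [call_seed()]).
#' @param index optional prebuilt [conserved_kmer_index()] over `blocks`.
#' @param trf_id label recorded in the output.
#' @return a `seed_profile` data frame: `trf_id`, `offset`, `kmer`,
#'   `observed`, `expected_genomic`, `composition_mean`,
#'   `enrichment_vs_expected`, `enrichment_vs_composition`, `called`.
#' @export
seed_profile <- function(trf_sequence, blocks, background,
                         rule = conservation_rule(),
                         orientation = c("complementary", "direct"),
                         ratio = 2, min_genes = 25,
                         index = NULL, trf_id = "tRF") {
  orientation <- match.arg(orientation)
  if (is.null(index)) index <- conserved_kmer_index(blocks, rule)
  win <- sliding_windows(trf_sequence)
  obs <- vapply(win$kmer, observed_count, integer(1),
                orientation = orientation, index = index)
  exp_g <- vapply(win$kmer, expected_genomic_count, numeric(1),
                  background = background, blocks = index,
                  rule = rule, orientation = orientation)
  comp <- vapply(win$kmer, function(k) {
    composition_null(k, orientation = orientation, index = index)$mean
  }, numeric(1))
  out <- data.frame(
    trf_id = trf_id,
    offset = win$offset,
    kmer = win$kmer,
    observed = unname(obs),
    expected_genomic = unname(exp_g),
    composition_mean = unname(comp),
    stringsAsFactors = FALSE
  )
  out$enrichment_vs_expected <- ifelse(out$expected_genomic > 0,
                                       out$observed / out$expected_genomic, Inf)
  out$enrichment_vs_composition <- ifelse(out$composition_mean > 0,
                                          out$observed / out$composition_mean, Inf)
  out$called <- call_seed(out$observed, out$expected_genomic,
                          out$composition_mean, ratio, min_genes)
  attr(out, "trf_sequence") <- toupper(rna_to_dna(trf_sequence))
  attr(out, "orientation") <- orientation
  attr(out, "ratio") <- ratio
  attr(out, "min_genes") <- min_genes
  class(out) <- c("seed_profile", "data.frame")
  out
}

#' Predicted target set of a tRF's called seed windows
#'
#' Union over called windows of the genes with at least one conserved
#' 7mer-m8 or 7mer-1a site; the full conserved-site list (all three match
#' types) is emitted as `site_records` ready for the 8-column writer.
#'
#' @param windows data frame with columns `offset` and `kmer` (e.g. the
#'   called rows of a [seed_profile()]).
#' @param blocks a `utr_block_set`.
#' @param rule a [conservation_rule()].
#' @param orientation site orientation.
#' @return list with `genes` (sorted character vector) and `sites` (a
#'   `site_records` data frame).
#' @export
predict_targets <- function(windows, blocks, rule = conservation_rule(),
                            orientation = c("complementary", "direct")) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("offset", "kmer") %in% names(windows)), nrow(windows) >= 1)
  sites <- list()
  genes <- character(0)
  for (i in seq_len(nrow(windows))) {
    v <- site_variants(windows$kmer[i], orientation)
    for (block in blocks) {
      rec <- find_sites_in_block(v, block, rule,
                                 window_offset = windows$offset[i])
      if (nrow(rec) > 0) {
        sites[[length(sites) + 1L]] <- rec
        if (any(rec$match_type %in% c("7mer-m8", "7mer-1a"))) {
          genes <- c(genes, block$gene_id)
        }
      }
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else empty_site_records()
  class(sites) <- c("site_records", "data.frame")
  list(genes = sort(unique(genes)), sites = sites)
}

#' @export
print.seed_profile <- function(x, ...) {
  cat(sprintf("Seed profile for %s (%d windows, orientation %s): %d called\n",
              x$trf_id[1], nrow(x), attr(x, "orientation"), sum(x$called)))
  NextMethod()
}

#' Plot a seed profile
#'
#' Observed conserved-site counts (red), composition-null mean (blue) and
#' genomic expectation (yellow/orange) against window start position;
#' called windows are marked.
#'
#' @param x a `seed_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.seed_profile <- function(x, ...) {
  ylim <- range(0, x$observed, x$composition_mean, x$expected_genomic)
  graphics::plot(x$offset, x$observed, type = "l", col = "red", lwd = 2,
                 xlab = "7-mer start position on tRF",
                 ylab = "conserved matches (genes)", ylim = ylim, ...)
  graphics::lines(x$offset, x$composition_mean, col = "blue", lwd = 2)
  graphics::lines(x$offset, x$expected_genomic, col = "orange", lwd = 2)
  if (any(x$called)) {
    graphics::points(x$offset[x$called], x$observed[x$called], pch = 19,
                     col = "red")
  }
  graphics::legend("topright", legend = c("observed", "composition null",
                                          "genomic expectation"),
                   col = c("red", "blue", "orange"), lwd = 2, bty = "n")
  invisible(x)
}
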