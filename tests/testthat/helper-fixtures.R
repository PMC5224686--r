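# Shared fixtures and independent oracles. Oracles deliberately use a
# different data flow than the package implementation they check.

DNA <- c("A", "C", "G", "T")

rand_seq <- function(len) paste(sample(DNA, len, replace = TRUE), collapse = "")

# minimal trna_set constructor for hand-built fixtures
make_trnas <- function(seqs, ids = sprintf("trna%03d", seq_along(seqs))) {
  out <- data.frame(
    id = ids, amino_acid = "Unk", anticodon = "NNN",
    sequence = toupper(seqs), has_cca = endsWith(toupper(seqs), "CCA"),
    is_mitochondrial = FALSE, source_db = "GTRNADB",
    duplicate_of = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("trna_set", "data.frame")
  out
}

make_reads <- function(seqs, counts) {
  trftools:::as_collapsed_reads(
    data.frame(sequence = seqs, count = as.integer(counts),
               stringsAsFactors = FALSE))
}

make_block <- function(gene_id, rows) {
  structure(list(gene_id = gene_id, rows = rows,
                 width = unique(nchar(rows))), class = "utr_block")
}

as_block_set <- function(blocks) {
  names(blocks) <- vapply(blocks, `[[`, character(1), "gene_id")
  class(blocks) <- c("utr_block_set", class(blocks))
  blocks
}

# naive O(n*m) substring scan: all exact full-length matches of read in trna
naive_match_scan <- function(read, trna_seq) {
  k <- nchar(read)
  n <- nchar(trna_seq)
  hits <- integer(0)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      if (substr(trna_seq, i, i + k - 1) == read) hits <- c(hits, i)
    }
  }
  hits
}

# independent conserved-site gene counter: for each block, scan the rat
# ungapped UTR for the window's 7mer-m8 and 7mer-1a site strings and test
# each occurrence species by species over the projected columns
naive_observed_count <- function(window, blocks, rule,
                                 orientation = "complementary") {
  sites <- if (orientation == "complementary") {
    c(trftools::revcomp(window),
      paste0(trftools::revcomp(substr(window, 1, 6)), "A"))
  } else {
    c(window, paste0(substr(window, 1, 6), "A"))
  }
  n_genes <- 0L
  for (block in blocks) {
    ref <- block$rows[["10116"]]
    if (is.null(ref)) next
    ref_ch <- strsplit(ref, "")[[1]]
    cols <- which(ref_ch != "-")
    ref_seq <- paste(ref_ch[cols], collapse = "")
    L <- nchar(ref_seq)
    gene_hit <- FALSE
    for (s in sites) {
      if (gene_hit) break
      k <- nchar(s)
      if (L < k) next
      starts <- seq_len(L - k + 1)
      occ <- starts[substring(ref_seq, starts, starts + k - 1) == s]
      for (p in occ) {
        carriers <- integer(0)
        for (sp in names(block$rows)) {
          span <- substr(block$rows[[sp]], cols[p], cols[p + k - 1])
          if (gsub("-", "", span) == s) {
            carriers <- c(carriers, as.integer(sp))
          }
        }
        if (length(carriers) >= rule$min_species &&
            all(rule$required %in% carriers)) {
          gene_hit <- TRUE
          break
        }
      }
    }
    if (gene_hit) n_genes <- n_genes + 1L
  }
  n_genes
}

# Heap's algorithm over character positions: independent enumeration of all
# n! arrangements, uniqued afterwards
heap_permutations <- function(chars) {
  n <- length(chars)
  out <- character(0)
  a <- chars
  c_ <- integer(n)
  out <- c(out, paste(a, collapse = ""))
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      j <- if (i %% 2L == 1L) 1L else c_[i] + 1L
      tmp <- a[j]; a[j] <- a[i]; a[i] <- tmp
      out <- c(out, paste(a, collapse = ""))
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  unique(out)
}

# small deterministic alignment-block generator: plants `site` at the same
# columns of `k` species (always the human/mouse/rat trio first)
plant_block <- function(gene_id, site, k, width = 120, col_start = 40,
                        taxa = trftools:::VERTEBRATE_TAXA,
                        include_trio = TRUE) {
  rows <- vapply(taxa, function(t) rand_seq(width), character(1))
  names(rows) <- as.character(taxa)
  trio <- c("9606", "10090", "10116")
  carriers <- if (include_trio) {
    c(trio, sample(setdiff(names(rows), trio), k - 3))
  } else {
    sample(setdiff(names(rows), "10116"), k)
  }
  for (sp in names(rows)) {
    if (sp %in% carriers) {
      substring(rows[[sp]], col_start, col_start + nchar(site) - 1) <- site
    } else {
      while (substr(rows[[sp]], col_start, col_start + nchar(site) - 1) == site) {
        substring(rows[[sp]], col_start,
                  col_start + nchar(site) - 1) <- rand_seq(nchar(site))
      }
    }
  }
  make_block(gene_id, rows)
}
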