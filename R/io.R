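# Readers and writers for the external formats the pipeline touches:
# mature-tRNA FASTA (two database header dialects), small-RNA FASTQ /
# plain FASTA / collapsed-FASTA, multi-species 3'UTR alignment TSV,
# expression tables, and the 8-column conserved-site TSV.

# --- mature tRNA FASTA ------------------------------------------------------

#' Read mature tRNA sequences from FASTA
#'
#' Parses a tRNA FASTA file in either the gtRNAdb-style header dialect
#' (`>trna3690 Phe GAA`) or the tRNAdb-style dialect
#' (`>tdbD00000658 GluCTC`, also accepted with a `-` separator).
#' Sequences are normalized to DNA (U mapped to T, uppercased) and the
#' post-transcriptional CCA tail is appended unless already present.
#' Records whose mature sequence duplicates an earlier record are kept but
#' flagged in `duplicate_of`; downstream mapping handles multi-matching
#' explicitly.
#'
#' @param path FASTA file.
#' @param source_db `"GTRNADB"` or `"TRNADB"`; selects the header dialect
#'   tried first and is recorded per record.
#' @param append_cca append `CCA` when the sequence does not already end in
#'   it (default `TRUE`). Appending is idempotent.
#' @return a `trna_set` data frame with columns `id`, `amino_acid`,
#'   `anticodon`, `sequence` (mapping-ready, CCA included when requested),
#'   `has_cca`, `is_mitochondrial`, `source_db`, `duplicate_of`.
#' @export
read_trna_fasta <- function(path, source_db = c("GTRNADB", "TRNADB"),
                            append_cca = TRUE) {
  source_db <- match.arg(source_db)
  validate_fasta_lines(path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("empty tRNA FASTA: ", path, call. = FALSE)
  headers <- names(recs)
  seqs <- toupper(rna_to_dna(as.character(recs)))
  check_dna(seqs, what = paste0("tRNA sequence in ", path))
  if (any(!nzchar(seqs))) stop("empty tRNA sequence in ", path, call. = FALSE)

  parsed <- lapply(headers, parse_trna_header, source_db = source_db)
  ids <- vapply(parsed, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate tRNA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (append_cca) {
    no_cca <- !endsWith(seqs, "CCA")
    seqs[no_cca] <- paste0(seqs[no_cca], "CCA")
    has_cca <- rep(TRUE, length(seqs))
  } else {
    has_cca <- endsWith(seqs, "CCA")
  }
  dup <- rep(NA_character_, length(seqs))
  first <- !duplicated(seqs)
  dup[!first] <- ids[match(seqs[!first], seqs[first])]

  out <- data.frame(
    id = ids,
    amino_acid = vapply(parsed, `[[`, character(1), "amino_acid"),
    anticodon = vapply(parsed, `[[`, character(1), "anticodon"),
    sequence = unname(seqs),
    has_cca = has_cca,
    is_mitochondrial = vapply(parsed, `[[`, logical(1), "mito"),
    source_db = source_db,
    duplicate_of = dup,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trna_set", "data.frame")
  out
}

# first line of sequence data must follow a '>' header; report the offending
# line number for malformed files
validate_fasta_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(lines[[1]], ">")) {
    stop(sprintf("malformed FASTA %s: line 1 does not start with '>'", path),
         call. = FALSE)
  }
  invisible(TRUE)
}

parse_trna_header <- function(header, source_db) {
  h <- trimws(sub("^>", "", header))
  mito <- grepl("^Mtdb", h) || grepl("mitochondrial", h, ignore.case = TRUE)
  # ">trna3690 Phe GAA": id, amino acid, anticodon as separate tokens
  m <- regmatches(h, regexec("^(\\S+)\\s+([A-Za-z]{3})\\s+([ACGTUacgtu]{3})\\b", h))[[1]]
  if (length(m) == 4) {
    return(list(id = m[2], amino_acid = m[3],
                anticodon = toupper(rna_to_dna(m[4])), mito = mito))
  }
  # ">tdbD00000658 GluCTC" or ">tdbD00000658-GluCTC": fused label
  m <- regmatches(h, regexec("^([^-[:space:]]+)[-[:space:]]+([A-Za-z]{3})([ACGTUacgtu]{3})\\b", h))[[1]]
  if (length(m) == 4) {
    return(list(id = m[2], amino_acid = m[3],
                anticodon = toupper(rna_to_dna(m[4])), mito = mito))
  }
  id <- strsplit(h, "\\s+")[[1]][1]
  warning("unparseable tRNA header labels, keeping id only: ", h,
          call. = FALSE)
  list(id = id, amino_acid = "Unk", anticodon = "NNN", mito = mito)
}

#' Write a tRNA set as FASTA
#'
#' Headers use the gtRNAdb-style dialect `>id amino_acid anticodon`.
#'
#' @param trnas a `trna_set`.
#' @param path output file.
#' @export
write_trna_fasta <- function(trnas, path) {
  stopifnot(inherits(trnas, "trna_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", trnas$id, " ", trnas$amino_acid, " ",
                    trnas$anticodon, "\n", trnas$sequence),
             con, sep = "\n")
  invisible(path)
}

# --- small RNA reads --------------------------------------------------------

#' Read a small-RNA library and collapse identical reads
#'
#' Accepts FASTQ, plain FASTA, or collapsed-FASTA with the fastx-collapser
#' header dialect `>serial-count`. FASTQ and plain FASTA inputs are
#' collapsed (identical sequences summed); collapsed-FASTA counts are taken
#' from the headers. The total raw read count is preserved and stored in
#' the `total_reads` attribute.
#'
#' @param path input file.
#' @return a `collapsed_reads` data frame with columns `sequence`, `count`.
#' @export
read_small_rna <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop("empty read file: ", path, call. = FALSE)
  if (startsWith(first, "@")) {
    seqs <- read_fastq_checked(path)
    tab <- table(seqs)
    reads <- data.frame(sequence = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  } else if (startsWith(first, ">")) {
    recs <- Biostrings::readBStringSet(path)
    seqs <- toupper(rna_to_dna(as.character(recs)))
    hdr <- trimws(names(recs))
    if (length(hdr) > 0 && all(grepl("^\\S+-\\S+$", hdr))) {
      counts <- sub("^\\S+-", "", hdr)
      if (any(!grepl("^[0-9]+$", counts))) {
        stop("non-numeric count field in collapsed-FASTA header: ",
             hdr[!grepl("^[0-9]+$", counts)][1], call. = FALSE)
      }
      reads <- data.frame(sequence = unname(seqs),
                          count = as.integer(counts),
                          stringsAsFactors = FALSE)
      # the same sequence may appear under several serials; merge
      reads <- collapse_reads(reads)
    } else {
      tab <- table(seqs)
      reads <- data.frame(sequence = names(tab), count = as.integer(tab),
                          stringsAsFactors = FALSE)
    }
  } else {
    stop("unrecognized read file format (expected FASTQ or FASTA): ", path,
         call. = FALSE)
  }
  check_dna(reads$sequence, allow_n = TRUE, what = paste0("read in ", path))
  if (any(reads$count < 1)) stop("read count < 1 in ", path, call. = FALSE)
  as_collapsed_reads(reads)
}

collapse_reads <- function(reads) {
  agg <- rowsum(reads$count, group = reads$sequence)
  data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
             stringsAsFactors = FALSE)
}

as_collapsed_reads <- function(reads) {
  rownames(reads) <- NULL
  attr(reads, "total_reads") <- sum(reads$count)
  class(reads) <- c("collapsed_reads", "data.frame")
  reads
}

read_fastq_checked <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ (record count not a multiple of 4): ", path,
         call. = FALSE)
  }
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop(sprintf("FASTQ quality/sequence length mismatch at record %d in %s",
                 which(bad)[1], path), call. = FALSE)
  }
  toupper(rna_to_dna(seqs))
}

#' Write collapsed reads in the `>serial-count` FASTA dialect
#'
#' @param reads a `collapsed_reads` data frame.
#' @param path output file.
#' @export
write_collapsed_fasta <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", seq_len(nrow(reads)), "-", reads$count, "\n",
                    reads$sequence), con, sep = "\n")
  invisible(path)
}

# --- multi-species 3'UTR alignments -----------------------------------------

#' Read multi-species 3'UTR alignment blocks
#'
#' The simple dialect is a TSV with columns `gene_id`, `taxonomy_id`,
#' `gapped_sequence` (header optional). The `"targetscan"` dialect accepts
#' the TargetScan UTR-sequence column layout and maps gene id, species id
#' and aligned sequence from the first, second-to-last and last columns.
#' Rows are grouped by gene into alignment blocks; within a block all
#' gapped sequences must have equal length. U is mapped to T.
#'
#' @param path TSV file.
#' @param dialect `"simple"` or `"targetscan"`.
#' @return a `utr_block_set`: named list of `utr_block` objects, each a list
#'   with `gene_id`, `rows` (named character vector, names are taxonomy
#'   IDs), and `width`.
#' @export
read_utr_alignments <- function(path, dialect = c("simple", "targetscan")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty UTR alignment file: ", path, call. = FALSE)
  if (dialect == "simple") {
    if (ncol(raw) != 3) {
      stop("simple UTR dialect expects 3 columns, got ", ncol(raw),
           call. = FALSE)
    }
    # header row detection: taxonomy column must be integer
    if (!grepl("^[0-9]+$", raw[1, 2])) raw <- raw[-1, , drop = FALSE]
    df <- data.frame(gene_id = raw[, 1], taxonomy_id = raw[, 2],
                     seq = raw[, 3], stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 4) {
      stop("targetscan UTR dialect expects >= 4 columns", call. = FALSE)
    }
    if (!grepl("^[0-9]+$", raw[1, ncol(raw) - 1])) raw <- raw[-1, , drop = FALSE]
    df <- data.frame(gene_id = raw[, 1], taxonomy_id = raw[, ncol(raw) - 1],
                     seq = raw[, ncol(raw)], stringsAsFactors = FALSE)
  }
  if (any(!grepl("^[0-9]+$", df$taxonomy_id))) {
    stop("non-numeric taxonomy id in ", path, call. = FALSE)
  }
  df$taxonomy_id <- as.integer(df$taxonomy_id)
  unknown <- setdiff(unique(df$taxonomy_id), VERTEBRATE_TAXA)
  if (length(unknown) > 0) {
    warning("taxonomy IDs outside the 23-species universe kept as-is: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  df$seq <- toupper(rna_to_dna(df$seq))
  bad <- !grepl("^[ACGTN-]+$", df$seq)
  if (any(bad)) {
    stop("invalid alignment characters for gene ", df$gene_id[bad][1],
         call. = FALSE)
  }
  blocks <- lapply(split(df, df$gene_id), function(g) {
    if (anyDuplicated(g$taxonomy_id)) {
      stop("duplicate taxonomy id within block ", g$gene_id[1], call. = FALSE)
    }
    w <- unique(nchar(g$seq))
    if (length(w) != 1) {
      stop("unequal gapped lengths within alignment block for gene ",
           g$gene_id[1], call. = FALSE)
    }
    structure(list(gene_id = g$gene_id[1],
                   rows = setNames(g$seq, g$taxonomy_id),
                   width = w),
              class = "utr_block")
  })
  blocks <- blocks[unique(df$gene_id)]  # keep file order
  class(blocks) <- c("utr_block_set", class(blocks))
  blocks
}

#' Write alignment blocks in the simple 3-column TSV dialect
#' @param blocks a `utr_block_set`.
#' @param path output file.
#' @export
write_utr_alignments <- function(blocks, path) {
  rows <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(gene_id = b$gene_id, taxonomy_id = names(b$rows),
               gapped_sequence = unname(b$rows), stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- conserved-site records (deposited 8-column format) ---------------------

#' Write conserved-site records in the deposited 8-column format
#'
#' Tab-separated, one line per site, columns: gene name; 7-mer location on
#' the tRF; alignment (MSA) start; MSA end; 3'UTR start; 3'UTR end; match
#' type; comma-joined taxonomy IDs of species carrying the site (ascending).
#'
#' @param records a `site_records` data frame (see [find_sites_in_block()]).
#' @param path output file.
#' @export
write_site_records <- function(records, path) {
  validate_site_records(records)
  out <- records[, c("gene_name", "window_offset", "msa_start", "msa_end",
                     "utr_start", "utr_end", "match_type", "species")]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read conserved-site records written by [write_site_records()]
#' @param path 8-column TSV file.
#' @return a `site_records` data frame.
#' @export
read_site_records <- function(path) {
  raw <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(raw) != 8) {
    stop("site record file must have 8 columns, got ", ncol(raw),
         call. = FALSE)
  }
  rec <- data.frame(
    gene_name = raw[, 1],
    window_offset = as.integer(raw[, 2]),
    msa_start = as.integer(raw[, 3]),
    msa_end = as.integer(raw[, 4]),
    utr_start = as.integer(raw[, 5]),
    utr_end = as.integer(raw[, 6]),
    match_type = raw[, 7],
    species = raw[, 8],
    stringsAsFactors = FALSE
  )
  validate_site_records(rec)
  class(rec) <- c("site_records", "data.frame")
  rec
}

validate_site_records <- function(rec) {
  need <- c("gene_name", "window_offset", "msa_start", "msa_end",
            "utr_start", "utr_end", "match_type", "species")
  if (!all(need %in% names(rec))) {
    stop("site records missing columns: ",
         paste(setdiff(need, names(rec)), collapse = ", "), call. = FALSE)
  }
  if (nrow(rec) == 0) return(invisible(rec))
  num_ok <- !is.na(rec$window_offset) & !is.na(rec$msa_start) &
    !is.na(rec$msa_end) & !is.na(rec$utr_start) & !is.na(rec$utr_end)
  if (any(!num_ok)) stop("non-numeric coordinate in site records", call. = FALSE)
  if (any(rec$msa_start > rec$msa_end) || any(rec$utr_start > rec$utr_end)) {
    stop("inverted coordinates in site records", call. = FALSE)
  }
  if (any(!rec$match_type %in% MATCH_TYPES)) {
    stop("unknown match type: ",
         paste(setdiff(rec$match_type, MATCH_TYPES), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(rec$species)) || any(!grepl("^[0-9]+(,[0-9]+)*$", rec$species))) {
    stop("malformed species field in site records", call. = FALSE)
  }
  invisible(rec)
}

# comma-joined ascending taxonomy IDs
format_species <- function(taxa) {
  paste(sort(as.integer(taxa)), collapse = ",")
}

# --- expression tables ------------------------------------------------------

#' Read a transcript expression table
#'
#' TSV with a header; first column is the transcript id, remaining columns
#' are labeled `<timepoint>_<replicate>` (e.g. `Y_1`, `O_3`). The replicate
#' structure must be identical across timepoints, values must be
#' non-negative, and transcript ids unique. Values are kept raw;
#' normalization happens downstream.
#'
#' @param path TSV file.
#' @return an `expression_table`: list with `values` (numeric matrix,
#'   transcripts x libraries), `timepoints` (ordered labels), `col_tp`,
#'   `col_rep` (per-column labels).
#' @export
read_expression_table <- function(path) {
  raw <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("expression table needs >= 2 value columns",
                          call. = FALSE)
  ids <- as.character(raw[, 1])
  if (anyDuplicated(ids)) {
    stop("duplicated transcript id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  labs <- names(raw)[-1]
  m <- regmatches(labs, regexec("^(.+)_([^_]+)$", labs))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop("value column not labeled <timepoint>_<replicate>: ", labs[bad][1],
         call. = FALSE)
  }
  col_tp <- vapply(m, `[`, character(1), 2)
  col_rep <- vapply(m, `[`, character(1), 3)
  tps <- unique(col_tp)
  reps_by_tp <- lapply(split(col_rep, factor(col_tp, levels = tps)), sort)
  if (length(unique(reps_by_tp)) != 1) {
    stop("replicate structure differs between timepoints", call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("non-numeric expression value", call. = FALSE)
  if (any(vals < 0)) stop("negative expression value", call. = FALSE)
  rownames(vals) <- ids
  structure(list(values = vals, timepoints = tps,
                 col_tp = col_tp, col_rep = col_rep),
            class = "expression_table")
}

#' Write an expression table as TSV
#' @param table an `expression_table`.
#' @param path output file.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  df <- data.frame(transcript_id = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("transcript_id", paste0(table$col_tp, "_", table$col_rep))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.utr_block <- function(x, ...) {
  cat(sprintf("3'UTR alignment block %s: %d species x %d columns\n",
              x$gene_id, length(x$rows), x$width))
  invisible(x)
}

#' @export
print.trna_set <- function(x, ...) {
  cat(sprintf("Mature tRNA set: %d records (%d mitochondrial, %d duplicate sequences)\n",
              nrow(x), sum(x$is_mitochondrial), sum(!is.na(x$duplicate_of))))
  NextMethod()
}
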