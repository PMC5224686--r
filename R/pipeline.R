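# tRF discovery from collapsed small-RNA reads and a CCA-appended mature
# tRNA set: adapter clipping, length filtering, exact full-length read
# mapping, fragment classification (5' / 3'CCA / internal), reads-per-million
# normalization, per-replicate abundance filtering, and age-pattern labels.

#' Clip 3' adapter sequences from reads
#'
#' Removes, from each read, the 3'-most exact occurrence of an adapter
#' prefix of at least `min_overlap` nucleotides together with everything
#' after it. Reads without an adapter occurrence are kept unchanged; reads
#' that become empty are retained with an empty sequence (the length filter
#' drops them downstream).
#'
#' @param reads a `collapsed_reads` data frame.
#' @param adapter adapter DNA string; empty string is a no-op.
#' @param min_overlap minimum exact overlap with the adapter 5' end.
#' @return a `collapsed_reads` data frame (identical sequences re-merged).
#' @export
clip_adapter <- function(reads, adapter, min_overlap = 7L) {
  stopifnot(is.data.frame(reads))
  if (!nzchar(adapter)) return(as_collapsed_reads(reads))
  adapter <- toupper(rna_to_dna(adapter))
  check_dna(adapter, what = "adapter")
  la <- nchar(adapter)
  clip_one <- function(read) {
    n <- nchar(read)
    if (n < min_overlap) return(read)
    # candidate starts, 3'-most first
    for (i in (n - min_overlap + 1L):1L) {
      ov <- min(n - i + 1L, la)
      if (ov < min_overlap) next
      if (substring(read, i, i + ov - 1L) == substring(adapter, 1L, ov)) {
        return(substring(read, 1L, i - 1L))
      }
    }
    read
  }
  out <- reads
  out$sequence <- vapply(reads$sequence, clip_one, character(1), USE.NAMES = FALSE)
  keep <- nzchar(out$sequence)
  merged <- collapse_reads(out[keep, , drop = FALSE])
  res <- as_collapsed_reads(merged)
  # total raw reads includes clipped-to-empty reads for normalization purposes
  attr(res, "total_reads") <- sum(reads$count)
  res
}

#' Filter reads by minimum length
#'
#' Keeps reads of length at least `min_len` (default 17 nt, the strict
#' reading of "length above 16").
#'
#' @param reads a `collapsed_reads` data frame.
#' @param min_len minimum read length in nt.
#' @return filtered `collapsed_reads`.
#' @export
filter_by_length <- function(reads, min_len = 17L) {
  stopifnot(is.data.frame(reads))
  as_collapsed_reads(reads[nchar(reads$sequence) >= min_len, , drop = FALSE])
}

#' Build an exact-substring index over mature tRNA sequences
#'
#' Enumerates every substring of length `min_len` up to full length of each
#' mature tRNA (CCA included) and hashes it to its (tRNA, start, end)
#' locations. Used by [map_reads()]; build it once when mapping several
#' libraries against the same tRNA set.
#'
#' @param trnas a `trna_set`.
#' @param min_len shortest indexed substring.
#' @return a `trna_index` object.
#' @export
build_trna_index <- function(trnas, min_len = 17L) {
  stopifnot(inherits(trnas, "trna_set"))
  keys <- character(0); tid <- character(0)
  st <- integer(0); en <- integer(0)
  for (i in seq_len(nrow(trnas))) {
    s <- trnas$sequence[i]
    L <- nchar(s)
    if (L < min_len) next
    for (len in min_len:L) {
      starts <- seq_len(L - len + 1L)
      keys <- c(keys, substring(s, starts, starts + len - 1L))
      tid <- c(tid, rep(trnas$id[i], length(starts)))
      st <- c(st, starts)
      en <- c(en, starts + len - 1L)
    }
  }
  env <- list2env(split(seq_along(keys), keys), hash = TRUE)
  structure(list(env = env, trna_id = tid, start = st, end = en,
                 trna_len = setNames(nchar(trnas$sequence), trnas$id),
                 min_len = min_len),
            class = "trna_index")
}

#' Map reads exactly onto mature tRNA sequences
#'
#' Each read is located as an exact, full-length, sense-strand substring of
#' zero or more mature tRNA sequences (CCA included). All matches are
#' reported; reads matching several tRNA genes get one row per gene.
#' Reads with zero matches are returned in the `unmapped` attribute.
#'
#' @param reads a `collapsed_reads` data frame.
#' @param trnas a `trna_set`; ignored when `index` is given.
#' @param index optional prebuilt [build_trna_index()].
#' @return a `trf_matches` data frame with columns `sequence`, `count`,
#'   `trna_id`, `start`, `end`, `class` (see [classify_match()]); attributes
#'   `unmapped` (collapsed unmapped reads) and `total_reads`.
#' @export
map_reads <- function(reads, trnas = NULL, index = NULL) {
  stopifnot(is.data.frame(reads))
  if (is.null(index)) index <- build_trna_index(trnas)
  stopifnot(inherits(index, "trna_index"))
  hits <- mget(reads$sequence, envir = index$env, ifnotfound = list(NULL))
  nhit <- lengths(hits)
  mapped <- nhit > 0
  ridx <- rep(which(mapped), nhit[mapped])
  iidx <- unlist(hits[mapped], use.names = FALSE)
  out <- data.frame(
    sequence = reads$sequence[ridx],
    count = reads$count[ridx],
    trna_id = index$trna_id[iidx],
    start = index$start[iidx],
    end = index$end[iidx],
    stringsAsFactors = FALSE
  )
  out$class <- classify_match(out$start, out$end,
                              unname(index$trna_len[out$trna_id]))
  attr(out, "unmapped") <- as_collapsed_reads(reads[!mapped, , drop = FALSE])
  attr(out, "total_reads") <- sum(reads$count)
  class(out) <- c("trf_matches", "data.frame")
  out
}

#' Classify a read match on a mature tRNA
#'
#' `FIVE_PRIME` iff the match starts at position 1; `THREE_PRIME_CCA` iff it
#' ends at the CCA terminus (the last position of the mature tRNA + CCA);
#' `INTERNAL` otherwise. A read spanning the entire molecule is classified
#' `FULL_LENGTH_EXCLUDED` and is dropped from tRF sets downstream. The
#' `THREE_PRIME_U` class (precursor trailer fragments) requires optional
#' trailer input and is not assigned here.
#'
#' @param start,end 1-based inclusive match coordinates (vectorized).
#' @param trna_len length of the mature tRNA including CCA.
#' @return character vector of class labels.
#' @export
classify_match <- function(start, end, trna_len) {
  stopifnot(all(start >= 1), all(start <= end), all(end <= trna_len))
  ifelse(start == 1L & end == trna_len, "FULL_LENGTH_EXCLUDED",
    ifelse(start == 1L, "FIVE_PRIME",
      ifelse(end == trna_len, "THREE_PRIME_CCA", "INTERNAL")))
}

#' Reads-per-million normalization
#'
#' @param counts read counts.
#' @param total_reads total reads detected in the library (pre-mapping).
#' @return counts scaled by `1e6 / total_reads`.
#' @export
normalize_counts <- function(counts, total_reads) {
  if (length(total_reads) != 1 || is.na(total_reads) || total_reads <= 0) {
    stop("total_reads must be a single positive number", call. = FALSE)
  }
  counts * 1e6 / total_reads
}

#' Call abundance-filtered tRFs across a 9-library age design
#'
#' Aggregates mapped reads per (tRNA gene, fragment class), retains a
#' candidate tRF only if its read count strictly exceeds
#' `min_frac` (default 0.1%) of the library total in every one of the
#' libraries, picks the modal (highest summed count) distinct read as the
#' representative fragment, records per-library abundance in reads per
#' million, and labels the age trajectory of per-timepoint means.
#' Records of tRNA genes sharing an identical mature sequence are merged
#' into one record listing all gene ids.
#'
#' @param libraries list of libraries; each a list with `timepoint`,
#'   `replicate`, `matches` (a `trf_matches` from [map_reads()]) and
#'   `total_reads`. Alternatively `reads` plus a `trnas`/`index` argument.
#' @param trnas,index tRNA set / prebuilt index used when a library carries
#'   raw `reads` instead of `matches`.
#' @param min_frac abundance filter fraction (strict `>`) applied per
#'   replicate.
#' @param denominator `"detected"` (all reads in the library after length
#'   filtering; default) or `"mapped"` (tRNA-mapped reads only), for both
#'   the filter and RPM normalization.
#' @param classes fragment classes eligible as tRFs.
#' @param epsilon relative tolerance of the age-pattern classifier.
#' @param require_nine error when fewer than 9 libraries are supplied
#'   (3 timepoints x 3 replicates); set `FALSE` to override.
#' @return a `trf_set` data frame: `trf_id`, `trna_id` (comma-joined when
#'   merged), `class`, `start`, `end`, `sequence`, one `rpm_<tp>_<rep>`
#'   column per library, per-timepoint `mean_<tp>`, `min_<tp>`, `max_<tp>`,
#'   and `pattern`.
#' @export
call_trfs <- function(libraries, trnas = NULL, index = NULL,
                      min_frac = 0.001,
                      denominator = c("detected", "mapped"),
                      classes = c("FIVE_PRIME", "THREE_PRIME_CCA"),
                      epsilon = 0.05,
                      require_nine = TRUE) {
  denominator <- match.arg(denominator)
  if (require_nine && length(libraries) != 9) {
    stop("expected 9 libraries (3 timepoints x 3 replicates); ",
         "pass require_nine = FALSE to override", call. = FALSE)
  }
  if (is.null(index) && !is.null(trnas)) index <- build_trna_index(trnas)
  libs <- lapply(libraries, function(lb) {
    if (is.null(lb$matches)) {
      if (is.null(index)) {
        stop("library has no matches and no tRNA set/index given", call. = FALSE)
      }
      lb$matches <- map_reads(lb$reads, index = index)
    }
    if (is.null(lb$total_reads)) lb$total_reads <- attr(lb$matches, "total_reads")
    lb
  })
  tp_of <- vapply(libs, function(lb) as.character(lb$timepoint), character(1))
  rep_of <- vapply(libs, function(lb) as.character(lb$replicate), character(1))
  tps <- unique(tp_of)
  lib_lab <- paste0(tp_of, "_", rep_of)

  denom <- vapply(libs, function(lb) {
    if (denominator == "detected") lb$total_reads
    else {
      m <- lb$matches
      sum(m$count[!duplicated(m$sequence)])
    }
  }, numeric(1))
  if (any(denom <= 0)) stop("library with zero total reads", call. = FALSE)

  # aggregate counts per (trna, class) and per distinct read
  per_lib <- lapply(libs, function(lb) {
    m <- lb$matches
    m[m$class %in% classes, , drop = FALSE]
  })
  all_m <- do.call(rbind, lapply(seq_along(per_lib), function(i) {
    m <- per_lib[[i]]
    if (nrow(m) == 0) return(NULL)
    m$lib <- i
    m
  }))
  if (is.null(all_m) || nrow(all_m) == 0) {
    return(empty_trf_set(lib_lab, tps))
  }
  key <- paste(all_m$trna_id, all_m$class, sep = "\r")
  counts <- matrix(0, nrow = length(unique(key)), ncol = length(libs),
                   dimnames = list(unique(key), lib_lab))
  agg <- rowsum(all_m$count, group = paste(key, all_m$lib, sep = "\r"))
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  counts[cbind(match(paste(parts[, 1], parts[, 2], sep = "\r"),
                     rownames(counts)),
               as.integer(parts[, 3]))] <- agg[, 1]

  thresh <- matrix(min_frac * denom, nrow = nrow(counts),
                   ncol = length(libs), byrow = TRUE)
  keep <- rownames(counts)[rowSums(counts > thresh) == length(libs)]
  if (length(keep) == 0) return(empty_trf_set(lib_lab, tps))

  recs <- lapply(keep, function(k) {
    rows <- all_m[key == k, , drop = FALSE]
    # modal distinct read, summed across libraries; ties broken by sequence
    tot <- rowsum(rows$count, rows$sequence)
    rep_seq <- rownames(tot)[order(-tot[, 1], rownames(tot))][1]
    one <- rows[rows$sequence == rep_seq, ][1, ]
    rpm <- counts[k, ] * 1e6 / denom  # per-library RPM
    data.frame(trna_id = one$trna_id, class = one$class,
               start = one$start, end = one$end, sequence = rep_seq,
               t(rpm), check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  names(out)[(ncol(out) - length(libs) + 1):ncol(out)] <- paste0("rpm_", lib_lab)

  # merge records over identical (class, representative sequence): these come
  # from tRNA genes with identical mature sequences
  mkey <- paste(out$class, out$sequence, out$start, out$end, sep = "\r")
  merged <- lapply(split(seq_len(nrow(out)), mkey), function(ii) {
    rec <- out[ii[1], , drop = FALSE]
    rec$trna_id <- paste(sort(unique(out$trna_id[ii])), collapse = ",")
    rec
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out$trf_id <- paste0(ifelse(out$class == "FIVE_PRIME", "tRF-5p-", "tRF-3p-"),
                       sub(",.*$", "", out$trna_id))

  rpm_cols <- paste0("rpm_", lib_lab)
  for (tp in tps) {
    cols <- rpm_cols[tp_of == tp]
    sub <- as.matrix(out[, cols, drop = FALSE])
    out[[paste0("mean_", tp)]] <- rowMeans(sub)
    out[[paste0("min_", tp)]] <- apply(sub, 1, min)
    out[[paste0("max_", tp)]] <- apply(sub, 1, max)
  }
  if (length(tps) == 3) {
    means <- as.matrix(out[, paste0("mean_", tps), drop = FALSE])
    out$pattern <- apply(means, 1, classify_age_pattern, epsilon = epsilon)
  } else {
    out$pattern <- NA_character_
  }
  out <- out[order(out$class, out$trf_id),
             c("trf_id", "trna_id", "class", "start", "end", "sequence",
               rpm_cols, paste0("mean_", tps), paste0("min_", tps),
               paste0("max_", tps), "pattern")]
  rownames(out) <- NULL
  attr(out, "timepoints") <- tps
  attr(out, "min_frac") <- min_frac
  attr(out, "denominator") <- denominator
  class(out) <- c("trf_set", "data.frame")
  out
}

empty_trf_set <- function(lib_lab, tps) {
  out <- data.frame(trf_id = character(0), trna_id = character(0),
                    class = character(0), start = integer(0),
                    end = integer(0), sequence = character(0),
                    stringsAsFactors = FALSE)
  for (cl in c(paste0("rpm_", lib_lab), paste0("mean_", tps),
               paste0("min_", tps), paste0("max_", tps))) {
    out[[cl]] <- numeric(0)
  }
  out$pattern <- character(0)
  attr(out, "timepoints") <- tps
  class(out) <- c("trf_set", "data.frame")
  out
}

#' Classify the age trajectory of per-timepoint mean abundances
#'
#' With relative tolerance `epsilon` (a step counts only when it exceeds
#' `epsilon` times the mean of the two values compared): `MONO_UP` for
#' Y < M < O, `MONO_DOWN` for Y > M > O, `DIP` for M below both Y and O
#' (the M < Y < O shape), `PEAK` for M above both, otherwise `FLAT`.
#'
#' @param means numeric vector of 3 per-timepoint means (Y, M, O order).
#' @param epsilon relative tolerance (default 0.05).
#' @return one of `"MONO_UP"`, `"MONO_DOWN"`, `"DIP"`, `"PEAK"`, `"FLAT"`.
#' @export
classify_age_pattern <- function(means, epsilon = 0.05) {
  stopifnot(length(means) == 3, all(means >= 0))
  exceeds <- function(a, b) (a - b) > epsilon * (a + b) / 2
  y <- means[1]; m <- means[2]; o <- means[3]
  if (exceeds(m, y) && exceeds(o, m)) return("MONO_UP")
  if (exceeds(y, m) && exceeds(m, o)) return("MONO_DOWN")
  if (exceeds(y, m) && exceeds(o, m)) return("DIP")
  if (exceeds(m, y) && exceeds(m, o)) return("PEAK")
  "FLAT"
}

#' Abundance-weighted fragment length distribution per class
#'
#' Frequencies over all distinct mapped reads of a class, weighted by read
#' count, plus the weighted length variance (the 3'-narrower-than-5'
#' comparison).
#'
#' @param matches a `trf_matches` data frame (or several rbind-ed).
#' @param class fragment class to summarize.
#' @return list with `hist` (named frequencies summing to 1) and `variance`.
#' @export
length_distribution <- function(matches, class) {
  m <- matches[matches$class == class, , drop = FALSE]
  m <- m[!duplicated(m$sequence), , drop = FALSE]
  if (nrow(m) == 0) return(list(hist = numeric(0), variance = NA_real_))
  len <- nchar(m$sequence)
  w <- m$count / sum(m$count)
  hist <- vapply(split(w, len), sum, numeric(1))
  mu <- sum(w * len)
  list(hist = hist, variance = sum(w * (len - mu)^2))
}

#' Per-library mapping statistics
#'
#' Totals and per-class fractions of tRNA-mapped reads. Each distinct read
#' is counted once; a read mapping to several tRNA genes with different
#' classes contributes to the class of its first match in class-priority
#' order (5', 3'CCA, internal, full-length).
#'
#' @param matches a `trf_matches` data frame from [map_reads()].
#' @param total_reads library total; defaults to the `total_reads` attribute.
#' @return a `library_stats` list: `total_reads`, `mapped_reads`,
#'   `mapped_fraction`, `class_fraction` (fractions of mapped reads).
#' @export
library_stats <- function(matches, total_reads = attr(matches, "total_reads")) {
  prio <- c("FIVE_PRIME", "THREE_PRIME_CCA", "INTERNAL", "FULL_LENGTH_EXCLUDED")
  m <- matches[order(match(matches$class, prio)), , drop = FALSE]
  m <- m[!duplicated(m$sequence), , drop = FALSE]
  mapped <- sum(m$count)
  cf <- vapply(split(m$count, factor(m$class, levels = prio)), sum, numeric(1))
  structure(list(total_reads = total_reads,
                 mapped_reads = mapped,
                 mapped_fraction = mapped / total_reads,
                 class_fraction = if (mapped > 0) cf / mapped else cf),
            class = "library_stats")
}

#' Locate a tRNA gene body in a genome by exact matching
#'
#' Searches both strands of a genome for exact occurrences of the tRNA body
#' (the trailing CCA, which is added post-transcriptionally and is absent
#' from the genome, is removed first). Coordinates are 1-based inclusive on
#' the forward strand.
#'
#' @param trna_sequence mature tRNA sequence (CCA tolerated and stripped
#'   when `strip_cca` is `TRUE`).
#' @param genome path to a genome FASTA or a `Biostrings::DNAStringSet`.
#' @param strip_cca remove a trailing CCA before searching (default `TRUE`).
#' @return data frame with columns `chrom`, `start`, `end`, `strand`; zero
#'   rows when absent.
#' @export
locate_gene_in_genome <- function(trna_sequence, genome, strip_cca = TRUE) {
  stopifnot(is.character(trna_sequence), length(trna_sequence) == 1)
  body <- toupper(rna_to_dna(trna_sequence))
  if (strip_cca && endsWith(body, "CCA")) {
    body <- substring(body, 1, nchar(body) - 3L)
  }
  check_dna(body, what = "tRNA body")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  pat_f <- Biostrings::DNAString(body)
  pat_r <- Biostrings::reverseComplement(pat_f)
  hits <- list()
  for (i in seq_along(genome)) {
    chrom <- sub("\\s.*$", "", names(genome)[i])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, genome[[i]])
      if (length(m) > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = BiocGenerics::start(m),
          end = BiocGenerics::end(m), strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' @export
print.trf_set <- function(x, ...) {
  cat(sprintf("Called tRFs: %d (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$class)), table(x$class)),
                    collapse = ", ")))
  NextMethod()
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("Library: %d reads, %d mapped (%.1f%%)\n",
              x$total_reads, x$mapped_reads, 100 * x$mapped_fraction))
  for (cl in names(x$class_fraction)) {
    if (x$class_fraction[[cl]] > 0) {
      cat(sprintf("  %-22s %.2f%% of mapped\n", cl,
                  100 * x$class_fraction[[cl]]))
    }
  }
  invisible(x)
}
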