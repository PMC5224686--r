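# Age-related regulation of predicted target sets: per-transcript relative
# change young -> old after per-library total-count normalization and
# replicate averaging, down/up classification at fractional thresholds,
# the down/up count ratio of a target set, and its significance against a
# null of equally sized random transcript sets resampled from the same
# transcriptome.

#' Per-transcript relative expression change, young to old
#'
#' Each library column is normalized by its total (reads-per-million
#' scaling, so the result is depth-invariant), replicates are averaged per
#' timepoint, and the relative change `(O - Y) / Y` is computed between the
#' first and last timepoint. Transcripts with a zero young mean are
#' excluded; their count is recorded in the `excluded_zero_young` attribute.
#'
#' @param table an `expression_table`.
#' @return named numeric vector of relative changes.
#' @export
fold_changes <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  if (length(table$timepoints) < 2) {
    stop("need at least two timepoints for fold changes", call. = FALSE)
  }
  vals <- table$values
  totals <- colSums(vals)
  if (any(totals <= 0)) stop("library with zero total expression", call. = FALSE)
  norm <- sweep(vals, 2, totals, `/`) * 1e6
  tp_first <- table$timepoints[1]
  tp_last <- table$timepoints[length(table$timepoints)]
  y <- rowMeans(norm[, table$col_tp == tp_first, drop = FALSE])
  o <- rowMeans(norm[, table$col_tp == tp_last, drop = FALSE])
  keep <- y > 0
  if (!any(keep)) stop("no transcript with nonzero young-timepoint mean",
                       call. = FALSE)
  changes <- (o[keep] - y[keep]) / y[keep]
  attr(changes, "excluded_zero_young") <- sum(!keep)
  changes
}

#' Classify transcripts as down-, up- or non-regulated at a threshold
#'
#' `DOWN` iff change < -threshold (strict), `UP` iff change > +threshold
#' (strict), `NEUTRAL` otherwise; a change of exactly the threshold is
#' neutral.
#'
#' @param changes named numeric vector from [fold_changes()].
#' @param threshold fraction in (0, 1), e.g. 0.05 for the 5% threshold.
#' @return named character vector over `DOWN`, `UP`, `NEUTRAL`.
#' @export
classify_regulation <- function(changes, threshold) {
  stopifnot(length(threshold) == 1, threshold > 0, threshold < 1)
  out <- ifelse(changes < -threshold, "DOWN",
                ifelse(changes > threshold, "UP", "NEUTRAL"))
  names(out) <- names(changes)
  out
}

#' Down/up-regulated count ratio of a target set
#'
#' Ratio of the number of target transcripts down-regulated beyond the
#' threshold to the number up-regulated beyond it, over the targets present
#' in the classified transcriptome. When no target is up-regulated the
#' ratio is the `Inf` sentinel (counts are always retained).
#'
#' @param target_ids character vector of transcript ids.
#' @param classified classification vector from [classify_regulation()].
#' @return list with `n_down`, `n_up`, `n_neutral`, `n_total`, `ratio`.
#' @export
down_up_ratio <- function(target_ids, classified) {
  cls <- classified[intersect(unique(target_ids), names(classified))]
  if (length(cls) == 0) {
    stop("target set does not intersect the classified transcriptome",
         call. = FALSE)
  }
  n_down <- sum(cls == "DOWN")
  n_up <- sum(cls == "UP")
  list(n_down = n_down, n_up = n_up,
       n_neutral = sum(cls == "NEUTRAL"), n_total = length(cls),
       ratio = if (n_up == 0) Inf else n_down / n_up)
}

#' Resampled null distribution of down/up ratios
#'
#' Draws `n_resamples` uniform without-replacement transcript sets of
#' `set_size` from the classified transcriptome and computes the down/up
#' ratio of each. Draws with zero up-regulated transcripts yield the `Inf`
#' sentinel; they are kept in the returned vector (excluded from moments by
#' the caller) and counted in the `n_infinite` attribute.
#'
#' @param set_size size of each random set.
#' @param classified classification vector from [classify_regulation()].
#' @param n_resamples number of random sets (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of `n_resamples` ratios.
#' @export
resample_null <- function(set_size, classified, n_resamples = 1000L,
                          seed = NULL) {
  n <- length(classified)
  stopifnot(set_size >= 1, set_size <= n, n_resamples >= 1)
  lab <- ifelse(classified == "DOWN", 1L, ifelse(classified == "UP", 2L, 0L))
  draw <- function() {
    idx <- sample.int(n, set_size)
    d <- sum(lab[idx] == 1L)
    u <- sum(lab[idx] == 2L)
    if (u == 0) Inf else d / u
  }
  ratios <- if (is.null(seed)) {
    vapply(seq_len(n_resamples), function(i) draw(), numeric(1))
  } else {
    with_seed(seed, vapply(seq_len(n_resamples), function(i) draw(), numeric(1)))
  }
  attr(ratios, "n_infinite") <- sum(is.infinite(ratios))
  ratios
}

#' Significance of an observed ratio against the resampled null
#'
#' Two modes. `"t_test"` reproduces the literal published procedure: a
#' one-sample two-tailed t-test of the (finite) null-ratio sample against
#' the observed ratio as hypothesized mean. `"empirical"` is the
#' recommended rank-based alternative: two-tailed
#' `p = 2 * min(Pr(null <= obs), Pr(null >= obs))` with add-one correction,
#' capped at 1. Tiers follow the star convention: `***` p < 0.005, `**`
#' p < 0.01, `*` p < 0.05, `#` otherwise.
#'
#' @param observed_ratio observed down/up ratio (may be `Inf`).
#' @param null_ratios vector from [resample_null()].
#' @param test `"empirical"` (default) or `"t_test"`.
#' @return list with `p_value`, `tier`, `test`.
#' @export
regulation_significance <- function(observed_ratio, null_ratios,
                                    test = c("empirical", "t_test")) {
  test <- match.arg(test)
  if (test == "t_test") {
    fin <- null_ratios[is.finite(null_ratios)]
    if (length(fin) < 2 || var(fin) == 0 || !is.finite(observed_ratio)) {
      stop("degenerate null (or infinite observed ratio) for the t-test; ",
           "use test = \"empirical\"", call. = FALSE)
    }
    p <- t.test(fin, mu = observed_ratio)$p.value
  } else {
    n <- length(null_ratios)
    lo <- (1 + sum(null_ratios <= observed_ratio)) / (n + 1)
    hi <- (1 + sum(null_ratios >= observed_ratio)) / (n + 1)
    p <- min(1, 2 * min(lo, hi))
  }
  list(p_value = p, tier = significance_tier(p), test = test)
}

significance_tier <- function(p) {
  if (p < 0.005) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "#"
}

#' Down-regulation analysis of target sets against resampled nulls
#'
#' For each target set and each threshold: the down/up ratio, a resampled
#' null of 1000 (by default) equally sized random transcript sets, and
#' two-tailed significance in both the empirical and t-test modes (the
#' `test` argument selects which drives the reported tier).
#'
#' @param table an `expression_table`.
#' @param target_sets named list of transcript-id vectors (a bare vector is
#'   treated as one set).
#' @param thresholds fractional regulation thresholds (default 5%, 10%, 20%).
#' @param n_resamples random sets per null (default 1000).
#' @param test `"empirical"` (default) or `"t_test"`.
#' @param seed integer seed for the resampling.
#' @return a `regulation_test` object: `results` data frame (`set_id`,
#'   `threshold`, `n_down`, `n_up`, `ratio`, `p_empirical`, `p_ttest`,
#'   `p_value`, `tier`), `nulls` (per set/threshold null ratio vectors),
#'   `changes`, and the configuration.
#' @export
regulation_test <- function(table, target_sets,
                            thresholds = c(0.05, 0.10, 0.20),
                            n_resamples = 1000L,
                            test = c("empirical", "t_test"),
                            seed = 1L) {
  test <- match.arg(test)
  if (is.character(target_sets)) target_sets <- list(targets = target_sets)
  stopifnot(length(target_sets) >= 1, !is.null(names(target_sets)) ||
              length(target_sets) == 1)
  if (is.null(names(target_sets))) names(target_sets) <- "targets"
  changes <- fold_changes(table)
  rows <- list()
  nulls <- list()
  for (th in thresholds) {
    classified <- classify_regulation(changes, th)
    for (set_id in names(target_sets)) {
      obs <- down_up_ratio(target_sets[[set_id]], classified)
      null <- resample_null(obs$n_total, classified, n_resamples,
                            seed = derive_seed(seed, "null", set_id, th))
      emp <- regulation_significance(obs$ratio, null, "empirical")
      tt <- tryCatch(regulation_significance(obs$ratio, null, "t_test"),
                     error = function(e) list(p_value = NA_real_))
      p_sel <- if (test == "empirical") emp$p_value else tt$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = set_id, threshold = th,
        n_down = obs$n_down, n_up = obs$n_up, n_neutral = obs$n_neutral,
        ratio = obs$ratio,
        p_empirical = emp$p_value, p_ttest = tt$p_value,
        p_value = p_sel,
        tier = if (is.na(p_sel)) NA_character_ else significance_tier(p_sel),
        stringsAsFactors = FALSE)
      nulls[[paste(set_id, th, sep = "@")]] <- null
    }
  }
  structure(list(results = do.call(rbind, rows), nulls = nulls,
                 changes = changes, thresholds = thresholds,
                 n_resamples = n_resamples, test = test, seed = seed),
            class = "regulation_test")
}

#' @export
print.regulation_test <- function(x, ...) {
  cat(sprintf("Target-set regulation test (%s mode, %d resamples)\n",
              x$test, x$n_resamples))
  df <- x$results
  df$ratio <- ifelse(is.infinite(df$ratio), "Inf", sprintf("%.2f", df$ratio))
  df$label <- paste0(df$ratio, " ", df$tier)
  wide <- do.call(rbind, lapply(split(df, df$set_id), function(g) {
    g <- g[order(g$threshold), ]
    setNames(data.frame(g$set_id[1], t(g$label), stringsAsFactors = FALSE),
             c("set", paste0(">", 100 * g$threshold, "%")))
  }))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Binned distribution of expression changes
#'
#' Densities of per-transcript relative changes over half-open bins
#' `[lo, lo + bin)` aligned at multiples of the bin width (default 2.5%).
#' Densities sum to 1 per set.
#'
#' @param change_sets named list of change vectors (e.g. all transcripts,
#'   miRNA targets, tRF targets).
#' @param bin bin width as a fraction (default 0.025).
#' @return data frame with `set_id`, `bin_lo`, `bin_hi`, `density`.
#' @export
change_histogram <- function(change_sets, bin = 0.025) {
  if (is.numeric(change_sets)) change_sets <- list(all = change_sets)
  stopifnot(bin > 0)
  out <- lapply(names(change_sets), function(set_id) {
    ch <- change_sets[[set_id]]
    if (length(ch) == 0) return(NULL)
    idx <- floor(ch / bin + 1e-12)
    tab <- table(idx)
    lo <- as.numeric(names(tab)) * bin
    data.frame(set_id = set_id, bin_lo = lo, bin_hi = lo + bin,
               density = as.numeric(tab) / length(ch),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
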