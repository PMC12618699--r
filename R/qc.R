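#' Per-cell fraction of fragments in TSS windows (FRiT)
#'
#' FRiT is the percentage of a cell's unique fragments overlapping at
#' least one oriented TSS window, default -1000..+200 bp around the TSS
#' (0-based half-open; a fragment starting exactly at TSS+200 is outside
#' the window). A fragment overlapping several windows counts once.
#'
#' @param fragments fragments table (chrom, start, end, barcode, ...),
#'   0-based half-open.
#' @param tss TSS table (chrom, start, end, strand; width-1 intervals).
#' @param window oriented window as c(upstream_offset, downstream_offset),
#'   default c(-1000, 200).
#' @return data.table: barcode, n_fragments, n_in_tss, frit (percent).
#'   Cells with zero fragments cannot appear in the input; callers join on
#'   the full cell list if they need them flagged.
#' @export
frit <- function(fragments, tss, window = c(-1000L, 200L)) {
  if (nrow(tss) == 0) stop("empty TSS set")
  w <- tss_windows(tss, upstream = -window[1], downstream = window[2])
  fraction_in_intervals(fragments, w, value_name = "frit",
                        count_name = "n_in_tss")
}

#' Per-cell fraction of fragments in peaks (FRiP)
#'
#' @param fragments fragments table, 0-based half-open.
#' @param peaks peak intervals (chrom, start, end), 0-based half-open.
#' @return data.table: barcode, n_fragments, n_in_peaks, frip (percent).
#' @export
frip <- function(fragments, peaks) {
  if (nrow(peaks) == 0) stop("empty peak set")
  fraction_in_intervals(fragments, peaks, value_name = "frip",
                        count_name = "n_in_peaks")
}

fraction_in_intervals <- function(fragments, intervals, value_name,
                                  count_name) {
  f <- data.table::as.data.table(fragments)
  fg <- GenomicRanges::GRanges(f$chrom,
                               IRanges::IRanges(f$start + 1L, f$end))
  ig <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L,
                                                intervals$end))
  inwin <- GenomicRanges::countOverlaps(fg, ig) > 0
  out <- f[, .(n_fragments = .N, hits = sum(inwin[.I])), by = barcode]
  out[, pct := 100 * hits / n_fragments]
  data.table::setnames(out, c("hits", "pct"), c(count_name, value_name))
  out[]
}

#' Aggregate TSS coverage profile
#'
#' Fragment coverage around TSS, strand-oriented, summed over all TSS and
#' binned at \code{binsize} bp over +/- \code{flank} bp (600 bins at the
#' defaults). Fold enrichment per bin is the bin mean divided by the mean
#' of the outermost 100 bp on each side; the TSS enrichment score is the
#' fold of the central bin.
#'
#' @param fragments fragments table, 0-based half-open.
#' @param tss TSS table with strand.
#' @param flank half-width of the profiled region (bp).
#' @param binsize bin width (bp).
#' @return list of class \code{tss_profile}: \code{bins} (data.table of
#'   bin center, mean coverage, fold), \code{score} (center-bin fold,
#'   \code{NA} when flank coverage is zero), \code{flagged}.
#' @export
tss_profile <- function(fragments, tss, flank = 3000L, binsize = 10L) {
  if (nrow(tss) == 0) stop("at least one TSS is required")
  nbin <- as.integer(2L * flank / binsize)
  f <- data.table::as.data.table(fragments)
  total <- numeric(2L * flank)
  if (nrow(f) > 0) {
    fg <- GenomicRanges::GRanges(f$chrom,
                                 IRanges::IRanges(f$start + 1L, f$end))
    cov <- GenomicRanges::coverage(fg)
    for (i in seq_len(nrow(tss))) {
      ch <- tss$chrom[i]
      if (!ch %in% names(cov)) next
      v <- cov[[ch]]
      lo <- tss$start[i] - flank + 1L          # 1-based window start
      hi <- tss$start[i] + flank
      pad_l <- max(0L, 1L - lo)
      pad_r <- max(0L, hi - length(v))
      vals <- as.numeric(S4Vectors::window(v, max(1L, lo),
                                           min(length(v), hi)))
      vals <- c(numeric(pad_l), vals, numeric(pad_r))
      if (tss$strand[i] == "-") vals <- rev(vals)
      total <- total + vals
    }
  }
  mean_cov <- total / nrow(tss)
  binmean <- colMeans(matrix(mean_cov, nrow = binsize))
  centers <- seq(-flank + binsize / 2, flank - binsize / 2, by = binsize)
  nflank_bins <- as.integer(100L / binsize)
  flank_mean <- mean(c(binmean[seq_len(nflank_bins)],
                       binmean[nbin - nflank_bins + seq_len(nflank_bins)]))
  flagged <- flank_mean == 0
  fold <- if (flagged) rep(NA_real_, nbin) else binmean / flank_mean
  center_bin <- nbin %/% 2L + 1L
  structure(list(bins = data.table::data.table(center = centers,
                                               mean_coverage = binmean,
                                               fold = fold),
                 score = if (flagged) NA_real_ else fold[center_bin],
                 flagged = flagged),
            class = "tss_profile")
}

#' Fragment-length histogram and banded fractions
#'
#' @param fragments fragments table.
#' @param breaks histogram break points (bp); lengths beyond the last
#'   break are pooled into a final open bin.
#' @return list: \code{hist} (bin_lo, bin_hi, count) and \code{bands},
#'   percentages of fragments with length <= 100, 200 and 300 bp.
#' @export
fragment_length_hist <- function(fragments, breaks = seq(0L, 1000L, 10L)) {
  len <- fragments$end - fragments$start
  n <- length(len)
  if (n == 0)
    return(list(hist = data.table::data.table(bin_lo = integer(),
                                              bin_hi = integer(),
                                              count = integer()),
                bands = c(b100 = NA_real_, b200 = NA_real_,
                          b300 = NA_real_)))
  edges <- c(breaks, Inf)
  cuts <- cut(len, edges, right = TRUE, include.lowest = FALSE)
  h <- data.table::data.table(bin_lo = edges[-length(edges)],
                              bin_hi = edges[-1],
                              count = as.integer(table(cuts)))
  bands <- c(b100 = 100 * mean(len <= 100),
             b200 = 100 * mean(len <= 200),
             b300 = 100 * mean(len <= 300))
  list(hist = h, bands = bands)
}

#' Per-cell QC table
#'
#' Combines unique-fragment counts, read totals and duplication rates
#' (from \code{\link{dedup_fragments}} output or a support column), FRiT
#' and optionally FRiP into one table.
#'
#' @param fragments fragments table with a \code{support} column.
#' @param tss TSS table.
#' @param peaks optional peak table; adds FRiP.
#' @return data.table: barcode, unique_fragments, total_reads, dup_rate,
#'   frit, (frip).
#' @export
cell_qc <- function(fragments, tss, peaks = NULL) {
  f <- data.table::as.data.table(fragments)
  base <- f[, .(unique_fragments = .N,
                total_reads = sum(support)), by = barcode]
  base[, dup_rate := 100 * (1 - unique_fragments / total_reads)]
  ft <- frit(f, tss)[, .(barcode, frit)]
  out <- merge(base, ft, by = "barcode")
  if (!is.null(peaks)) {
    fp <- frip(f, peaks)[, .(barcode, frip)]
    out <- merge(out, fp, by = "barcode")
  }
  out[]
}

#' Filter cells by QC preset
#'
#' Presets (strict inequalities unless noted): \code{"mouse"} keeps cells
#' with FRiT > 10 and > 1500 unique fragments; \code{"human"} FRiT > 7 and
#' > 1000 unique fragments; \code{"tss_score"} TSS enrichment score >= 4
#' and >= 1500 unique fragments (the variant used when comparing against
#' standard single-cell ATAC); \code{"custom"} applies the thresholds
#' given.
#'
#' @param qc_table per-cell QC table (see \code{\link{cell_qc}}); must
#'   contain the fields the preset tests.
#' @param preset preset name.
#' @param min_frit,min_fragments,min_tss_score custom thresholds; for
#'   \code{"custom"}, cells pass when \code{frit > min_frit} and
#'   \code{unique_fragments > min_fragments} (and, if
#'   \code{min_tss_score} is given, \code{tss_score >= min_tss_score}).
#' @return character vector of kept cell barcodes.
#' @export
filter_cells <- function(qc_table,
                         preset = c("mouse", "human", "tss_score", "custom"),
                         min_frit = NULL, min_fragments = NULL,
                         min_tss_score = NULL) {
  preset <- match.arg(preset)
  q <- data.table::as.data.table(qc_table)
  need <- function(cols) {
    miss <- setdiff(cols, names(q))
    if (length(miss))
      stop("qc_table lacks fields required by preset '", preset, "': ",
           paste(miss, collapse = ", "))
  }
  keep <- switch(preset,
    mouse = { need(c("frit", "unique_fragments"))
              q$frit > 10 & q$unique_fragments > 1500 },
    human = { need(c("frit", "unique_fragments"))
              q$frit > 7 & q$unique_fragments > 1000 },
    tss_score = { need(c("tss_score", "unique_fragments"))
                  q$tss_score >= 4 & q$unique_fragments >= 1500 },
    custom = {
      need(c(if (!is.null(min_frit)) "frit",
             if (!is.null(min_fragments)) "unique_fragments",
             if (!is.null(min_tss_score)) "tss_score"))
      k <- rep(TRUE, nrow(q))
      if (!is.null(min_frit)) k <- k & q$frit > min_frit
      if (!is.null(min_fragments)) k <- k & q$unique_fragments > min_fragments
      if (!is.null(min_tss_score)) k <- k & q$tss_score >= min_tss_score
      k
    })
  q$barcode[keep]
}
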