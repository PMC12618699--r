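#' Collapse aligned read pairs into unique fragments per cell
#'
#' Two collapsing modes. \code{"pcr_only"} merges records identical on
#' (cell, chrom, start, end, strand) — classic PCR duplicates.
#' \code{"pcr_and_linear"} additionally merges records sharing the
#' (cell, chrom, strand, 5' insertion coordinate) key: linear (in vitro
#' transcription) amplification copies a tagmentation event into molecules
#' with a common insertion-proximal end and variable 3' ends, so all such
#' records describe one fragment; the longest extent is kept as the
#' representative.
#'
#' @param pairs data.frame/data.table of aligned pairs: cell, chrom,
#'   start, end (0-based half-open), strand, and optionally mapq.
#' @param mode \code{"pcr_and_linear"} (default) or \code{"pcr_only"}.
#' @param mapq_min mapping-quality filter (applied when a mapq column is
#'   present; default 30).
#' @return list of class \code{dedup_result}: \code{fragments} (chrom,
#'   start, end, barcode, support; sorted), \code{cell_stats} (per-cell
#'   total reads, unique fragments, duplication rate in percent) and
#'   \code{skipped} (count of malformed records with end <= start).
#' @export
dedup_fragments <- function(pairs, mode = c("pcr_and_linear", "pcr_only"),
                            mapq_min = 30L) {
  mode <- match.arg(mode)
  d <- data.table::as.data.table(pairs)
  req <- c("cell", "chrom", "start", "end", "strand")
  if (!all(req %in% names(d)))
    stop("pairs must have columns: ", paste(req, collapse = ", "))
  if ("mapq" %in% names(d)) d <- d[mapq >= mapq_min]
  bad <- d$end <= d$start
  skipped <- sum(bad)
  d <- d[!bad]

  if (mode == "pcr_only") {
    frag <- d[, .(support = .N),
              by = .(cell, chrom, start, end, strand)]
  } else {
    d[, five_p := ifelse(strand == "+", start, end)]
    frag <- d[, .(start = min(start), end = max(end), support = .N),
              by = .(cell, chrom, strand, five_p)]
    frag[, five_p := NULL]
  }

  totals <- d[, .(total = .N), by = cell]
  uniques <- frag[, .(unique = .N), by = cell]
  stats <- merge(totals, uniques, by = "cell")
  stats[, dup_rate := 100 * (1 - unique / total)]

  out <- frag[, .(chrom, start, end, barcode = cell, support)]
  data.table::setorder(out, chrom, start, end, barcode)
  structure(list(fragments = out[], cell_stats = stats[], skipped = skipped,
                 mode = mode),
            class = "dedup_result")
}

#' Write / read a fragments file
#'
#' Five-column BED-like TSV: chrom, start, end, cell barcode, support
#' (reads collapsed into the fragment), 0-based half-open. Gzip is applied
#' when the path ends in \code{.gz}.
#'
#' @param records fragments table (chrom, start, end, barcode, support).
#' @param path output path.
#' @param sort_on_write sort records instead of erroring on unsorted input.
#' @return the path, invisibly.
#' @export
write_fragments <- function(records, path, sort_on_write = FALSE) {
  d <- data.table::as.data.table(records)
  o <- order(d$chrom, d$start, d$end)
  if (!identical(o, seq_len(nrow(d)))) {
    if (sort_on_write) d <- d[o]
    else stop("records are not sorted by (chrom, start, end); ",
              "use sort_on_write = TRUE")
  }
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  d <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) == 0) data.table::data.table()
    else data.table::fread(text = lines, header = FALSE)
  } else if (file.size(path) == 0) {
    data.table::data.table()
  } else {
    data.table::fread(path, header = FALSE)
  }
  if (nrow(d) > 0)
    data.table::setnames(d, c("chrom", "start", "end", "barcode", "support"))
  if (nrow(d) == 0)
    d <- data.table::data.table(chrom = character(), start = integer(),
                                end = integer(), barcode = character(),
                                support = integer())
  d[]
}
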