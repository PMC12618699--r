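#' Locate the linker anchor in a Read 2 sequence
#'
#' Slides the 17-nt linker over the configured search window and returns
#' the offset minimising the Hamming distance, provided the distance does
#' not exceed \code{max_mismatch} (default 3); ties are broken leftmost.
#'
#' @param r2_sequence a single Read 2 sequence.
#' @param arch a \code{\link{barcode_architecture}}.
#' @param max_mismatch maximum tolerated mismatches to the linker.
#' @param window 0-based inclusive range of linker start offsets searched.
#' @return list with \code{offset} (0-based) and \code{mismatches}, or
#'   \code{NULL} when no acceptable hit exists.
#' @export
find_anchor <- function(r2_sequence, arch, max_mismatch = 3L,
                        window = arch$anchor_window) {
  hit <- anchor_scan(r2_sequence, arch$linker_anchor, max_mismatch, window)
  if (is.na(hit$offset[1])) return(NULL)
  list(offset = hit$offset[1], mismatches = hit$mismatches[1])
}

# Vectorised anchor scan; NA offset where nothing within max_mm (or read
# too short to cover the window).
anchor_scan <- function(seqs, linker, max_mm, window) {
  n <- length(seqs)
  k <- nchar(linker)
  offsets <- seq(window[1], window[2])
  need <- window[2] + k
  lens <- nchar(seqs)
  mat <- char_matrix(seqs, need)
  lchars <- strsplit(linker, "")[[1]]
  dist <- matrix(Inf, n, length(offsets))
  for (j in seq_along(offsets)) {
    o <- offsets[j]
    cols <- (o + 1L):(o + k)
    dist[, j] <- rowSums(mat[, cols, drop = FALSE] !=
                           matrix(lchars, n, k, byrow = TRUE))
  }
  dist[lens < need, ] <- Inf
  best <- max.col(-dist, ties.method = "first")
  mm <- dist[cbind(seq_len(n), best)]
  ok <- is.finite(mm) & mm <= max_mm
  list(offset = ifelse(ok, offsets[best], NA_integer_),
       mismatches = ifelse(ok, as.integer(mm), NA_integer_),
       too_short = lens < need)
}

char_matrix <- function(seqs, width) {
  x <- substr(paste0(seqs, strrep("N", width)), 1L, width)
  matrix(unlist(strsplit(x, ""), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

#' Match an observed 7-mer against a round whitelist
#'
#' Exact full-7 match first; otherwise the last five bases are compared
#' against the whitelist suffixes (which are distinct by construction), the
#' rescue that tolerates errors in the first two barcode bases.
#'
#' @param observed_7mer observed barcode sequence(s).
#' @param whitelist character vector of 7-nt barcodes.
#' @return for a single input, a list with \code{id} (1-based whitelist
#'   index) and \code{tier} (\code{"full7"} or \code{"last5"}), or
#'   \code{NULL}; for vector input, a data.frame of \code{id}, \code{tier}.
#' @export
match_barcode <- function(observed_7mer, whitelist) {
  res <- match_barcodes_vec(observed_7mer, whitelist)
  if (length(observed_7mer) == 1L) {
    if (is.na(res$id)) return(NULL)
    return(list(id = res$id, tier = res$tier))
  }
  res
}

match_barcodes_vec <- function(obs, whitelist) {
  id <- match(obs, whitelist)
  tier <- ifelse(is.na(id), NA_character_, "full7")
  suf <- substr(whitelist, 3L, 7L)
  dup_suf <- unique(suf[duplicated(suf)])
  miss <- is.na(id)
  if (any(miss)) {
    osuf <- substr(obs[miss], 3L, 7L)
    sid <- match(osuf, suf)
    # a suffix occurring more than once in a non-conforming whitelist is
    # ambiguous and yields no match
    sid[osuf %in% dup_suf] <- NA_integer_
    id[miss] <- sid
    tier[miss] <- ifelse(is.na(sid), NA_character_, "last5")
  }
  data.frame(id = id, tier = tier, stringsAsFactors = FALSE)
}

#' Decode one read pair
#'
#' Anchors the linker, reads the three ligation barcodes and the Tn5 index
#' relative to it, extracts the genomic mates (last 50 nt of Read 2; Read 1
#' truncated to 75 nt), trims the reverse-complemented mosaic end and
#' everything 3' of it from both mates, and rejects pairs whose trimmed
#' mates fall below \code{ml}.
#'
#' @param r1,r2 sequences of the pair.
#' @param arch a \code{\link{barcode_architecture}}.
#' @param ml minimum retained read length after trimming (default 17).
#' @param max_mismatch anchor mismatch tolerance.
#' @return one-row data.frame (a decoded-read record): status
#'   (\code{"ok"} or a rejection reason among \code{no_anchor},
#'   \code{bad_barcode}, \code{too_short}), anchor offset/mismatches,
#'   barcode ids and tiers, trimmed mates.
#' @export
decode_read <- function(r1, r2, arch, ml = 17L, max_mismatch = 3L) {
  as.data.frame(decode_pairs(r1, r2, "read1", arch, ml = ml,
                             max_mismatch = max_mismatch))
}

# Vectorised decoder; the workhorse behind decode_read/demux_fastq/ml_sweep.
decode_pairs <- function(r1, r2, ids, arch, ml = 17L, max_mismatch = 3L) {
  n <- length(r2)
  stopifnot(length(r1) == n, length(ids) == n)
  lay <- arch_layout(arch)
  res <- data.table::data.table(
    read_id = ids, status = rep("ok", n), reason = NA_character_,
    anchor_offset = NA_integer_, anchor_mm = NA_integer_,
    tn5 = NA_integer_, bc1 = NA_integer_, bc2 = NA_integer_,
    bc3 = NA_integer_, tier1 = NA_character_, tier2 = NA_character_,
    tier3 = NA_character_, r1_trim = NA_character_, r2_trim = NA_character_,
    r1_len = NA_integer_, r2_len = NA_integer_, cell_key = NA_character_)
  if (n == 0) return(res)

  hit <- anchor_scan(r2, arch$linker_anchor, max_mismatch, arch$anchor_window)
  res$anchor_offset <- hit$offset
  res$anchor_mm <- hit$mismatches
  no_anchor <- is.na(hit$offset)
  res$status[no_anchor] <- "rejected"
  res$reason[no_anchor] <- ifelse(hit$too_short[no_anchor],
                                  "too_short", "no_anchor")
  ok <- !no_anchor
  if (any(ok)) {
    a <- hit$offset[ok] + 1L                     # anchor start, 1-based
    b1 <- substr(r2[ok], 1L, 7L)
    b2 <- substr(r2[ok], a - 7L, a - 1L)
    b3 <- substr(r2[ok], a + 17L, a + 23L)
    t5 <- substr(r2[ok], a + lay$tn5_rel, a + lay$tn5_rel + 2L)
    m1 <- match_barcodes_vec(b1, arch$round_whitelists[[1]])
    m2 <- match_barcodes_vec(b2, arch$round_whitelists[[2]])
    m3 <- match_barcodes_vec(b3, arch$round_whitelists[[3]])
    mt <- match(t5, arch$tn5_indexes)
    res$bc1[ok] <- m1$id; res$tier1[ok] <- m1$tier
    res$bc2[ok] <- m2$id; res$tier2[ok] <- m2$tier
    res$bc3[ok] <- m3$id; res$tier3[ok] <- m3$tier
    res$tn5[ok] <- mt
    bad <- is.na(m1$id) | is.na(m2$id) | is.na(m3$id) | is.na(mt)
    w <- which(ok)[bad]
    res$status[w] <- "rejected"
    res$reason[w] <- "bad_barcode"
  }

  ok <- res$status == "ok"
  if (any(ok)) {
    rc_me <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(arch$me_sequence)))
    l2 <- nchar(r2[ok])
    g2 <- substr(r2[ok], pmax(1L, l2 - arch$r2_genomic_len + 1L), l2)
    g1 <- substr(r1[ok], 1L, arch$r1_truncate_to)
    t2 <- trim_adaptor(g2, rc_me)
    t1 <- trim_adaptor(g1, rc_me)
    res$r2_trim[ok] <- t2; res$r1_trim[ok] <- t1
    res$r2_len[ok] <- nchar(t2); res$r1_len[ok] <- nchar(t1)
    short <- pmin(nchar(t1), nchar(t2)) < ml
    w <- which(ok)[short]
    res$status[w] <- "rejected"
    res$reason[w] <- "too_short"
  }
  keep <- res$status == "ok"
  res$cell_key[keep] <- paste(res$bc1[keep], res$bc2[keep], res$bc3[keep],
                              res$tn5[keep], sep = "-")
  res
}

# Remove the rightmost full-length occurrence of `adapter` (<= 1 mismatch)
# and everything 3' of it. Partial end-of-read occurrences shorter than the
# adapter are left in place (they never match a full-length scan).
trim_adaptor <- function(seqs, adapter, max_mm = 1L) {
  k <- nchar(adapter)
  achars <- strsplit(adapter, "")[[1]]
  lens <- nchar(seqs)
  w <- max(lens)
  if (w < k) return(seqs)
  mat <- char_matrix(seqs, w)
  n <- length(seqs)
  cut <- lens                        # default: keep everything
  found <- logical(n)
  for (p in (w - k + 1L):1L) {       # rightmost occurrence wins
    rows <- !found & (p + k - 1L) <= lens
    if (!any(rows)) next
    mm <- rowSums(mat[rows, p:(p + k - 1L), drop = FALSE] !=
                    matrix(achars, sum(rows), k, byrow = TRUE))
    hit <- mm <= max_mm
    if (any(hit)) {
      idx <- which(rows)[hit]
      cut[idx] <- p - 1L
      found[idx] <- TRUE
    }
  }
  substr(seqs, 1L, cut)
}

#' Demultiplex paired FASTQ files
#'
#' Decodes every read pair, writes one paired FASTQ set per Tn5 index with
#' the cell barcode carried in the header
#' (\code{@orig_id|bc1-bc2-bc3-tn5}, 1-based whitelist indices), and
#' returns a decode report.
#'
#' @param r1_path,r2_path paired FASTQ files (gzip or plain).
#' @param arch a \code{\link{barcode_architecture}}.
#' @param ml minimum retained read length after trimming.
#' @param out_dir output directory for per-Tn5 FASTQ and report files;
#'   \code{NULL} skips writing.
#' @param max_mismatch anchor mismatch tolerance.
#' @return list of class \code{demux_report}: totals, decode rate (%),
#'   rejection-reason counts, per-tier counts, and the per-read decode
#'   table (\code{$reads}).
#' @export
demux_fastq <- function(r1_path, r2_path, arch = barcode_architecture(),
                        ml = 17L, out_dir = NULL, max_mismatch = 3L) {
  f1 <- read_fastq(r1_path)
  f2 <- read_fastq(r2_path)
  if (length(f1$id) != length(f2$id))
    stop("R1 and R2 record counts differ (", length(f1$id), " vs ",
         length(f2$id), ")")
  res <- decode_pairs(f1$seq, f2$seq, f1$id, arch, ml = ml,
                      max_mismatch = max_mismatch)

  report <- summarize_decode(res, ml)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    keep <- which(res$status == "ok")
    q1 <- substr(f1$qual[keep], 1L, res$r1_len[keep])
    q2l <- nchar(f2$seq[keep])
    q2 <- substr(substr(f2$qual[keep],
                        pmax(1L, q2l - arch$r2_genomic_len + 1L), q2l),
                 1L, res$r2_len[keep])
    hdr <- paste0(res$read_id[keep], "|", res$cell_key[keep])
    for (t in sort(unique(res$tn5[keep]))) {
      i <- res$tn5[keep] == t
      base <- sprintf("tn5_%02d", t)
      write_fastq_q(hdr[i], res$r1_trim[keep][i], q1[i],
                    file.path(out_dir, paste0(base, "_R1.fastq.gz")))
      write_fastq_q(hdr[i], res$r2_trim[keep][i], q2[i],
                    file.path(out_dir, paste0(base, "_R2.fastq.gz")))
    }
    jsonlite::write_json(report[setdiff(names(report), "reads")],
                         file.path(out_dir, "demux_report.json"),
                         auto_unbox = TRUE, digits = NA)
    data.table::fwrite(res, file.path(out_dir, "demux_reads.tsv.gz"),
                       sep = "\t")
  }
  report$reads <- res
  class(report) <- "demux_report"
  report
}

write_fastq_q <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq", compress = TRUE,
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

summarize_decode <- function(res, ml) {
  total <- nrow(res)
  decoded <- sum(res$status == "ok")
  reasons <- table(res$reason[res$status != "ok"])
  tiers <- lapply(paste0("tier", 1:3), function(cn)
    as.list(table(res[[cn]][res$status == "ok"])))
  names(tiers) <- paste0("round", 1:3)
  list(total = total, decoded = decoded,
       decode_rate = if (total > 0) 100 * decoded / total else 0,
       ml = ml, rejections = as.list(reasons), tiers = tiers)
}

#' @export
print.demux_report <- function(x, ...) {
  cat(sprintf("demux_report: %d/%d decoded (%.2f%%), ml=%d\n",
              x$decoded, x$total, x$decode_rate, x$ml))
  if (length(x$rejections))
    cat("  rejections:",
        paste(names(x$rejections), unlist(x$rejections),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Minimum-retained-length sweep
#'
#' Decodes the pairs once and evaluates the \code{ml} gate at each
#' requested threshold, reporting decoded-read counts and retained
#' fractions. Counts are non-increasing in \code{ml}.
#'
#' @param r1_path,r2_path paired FASTQ files.
#' @param arch a \code{\link{barcode_architecture}}.
#' @param ml_values positive integer thresholds to evaluate.
#' @param out_tsv optional path for a TSV of the table.
#' @param max_mismatch anchor mismatch tolerance.
#' @return data.table with ml, decoded_reads, retained_fraction.
#' @export
ml_sweep <- function(r1_path, r2_path, arch = barcode_architecture(),
                     ml_values = c(14L, 17L, 20L, 30L, 40L, 50L),
                     out_tsv = NULL, max_mismatch = 3L) {
  if (any(ml_values <= 0)) stop("ml values must be positive")
  f1 <- read_fastq(r1_path)
  f2 <- read_fastq(r2_path)
  res <- decode_pairs(f1$seq, f2$seq, f1$id, arch, ml = 1L,
                      max_mismatch = max_mismatch)
  decodable <- res$status == "ok"
  minlen <- pmin(res$r1_len, res$r2_len)
  total <- nrow(res)
  out <- data.table::data.table(ml = as.integer(ml_values))
  out[, decoded_reads := vapply(ml, function(m)
    sum(decodable & minlen >= m), integer(1))]
  out[, retained_fraction := decoded_reads / total]
  if (!is.null(out_tsv)) data.table::fwrite(out, out_tsv, sep = "\t")
  out[]
}
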