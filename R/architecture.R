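#' Barcode architecture for split-pool single-cell ATAC reads
#'
#' A \code{barcode_architecture} object describes the layout of the barcode
#' region at the start of Read 2: a 7-nt first-round ligation barcode at
#' offset 0, a staggered spacer, the 7-nt second-round barcode, a fixed
#' 17-nt linker (used as the demultiplexing anchor), the 7-nt third-round
#' barcode, a second spacer, the 3-nt Tn5 sample index, and the 19-nt Tn5
#' mosaic-end (ME) sequence, followed by genomic bases.
#'
#' Positional stagger: the second-round barcode start is drawn per read from
#' \code{bc2_start_range} (0-based), so the full barcode region spans 88 to
#' 91 nt. All downstream segments are located relative to the linker anchor,
#' so only the anchor search window matters for decoding.
#'
#' @param tn5_indexes character vector of 3-nt Tn5 sample indexes (default:
#'   all 64 possible 3-mers, lexicographic).
#' @param round_whitelists list of three character vectors of 7-nt ligation
#'   barcodes (96 each). Within each round the barcodes and their last-5-nt
#'   suffixes must be distinct (the suffixes carry the error tolerance of
#'   the matcher).
#' @param linker_anchor 17-nt linker between the round-2 and round-3
#'   barcodes.
#' @param me_sequence Tn5 mosaic-end sequence trimmed from genomic reads.
#' @param bc2_start_range integer length-2, 0-based inclusive range of the
#'   round-2 barcode start (the stagger).
#' @param spacer2_len length of the fixed spacer between the round-3
#'   barcode and the Tn5 index.
#' @param anchor_window integer length-2, 0-based inclusive range of linker
#'   start offsets searched by the demultiplexer.
#' @param r2_genomic_len number of bases taken from the 3' end of Read 2 as
#'   the genomic mate (50, per the assay read structure).
#' @param r1_truncate_to Read 1 is truncated to this length before adaptor
#'   trimming.
#' @param spacer1_seq,spacer2_seq fixed spacer sequences used by the read
#'   simulator (the demultiplexer never reads them). \code{spacer1_seq} is
#'   truncated from its 3' end to the per-read stagger length.
#' @param adaptor_seq downstream sequencing adaptor used by the simulator to
#'   fill reads that run past the insert.
#' @return object of class \code{barcode_architecture}.
#' @export
barcode_architecture <- function(tn5_indexes = default_tn5_indexes(),
                                 round_whitelists = default_round_whitelists(),
                                 linker_anchor = "GTGGCCGATGTTTCGCA",
                                 me_sequence = "AGATGTGTATAAGAGACAG",
                                 bc2_start_range = c(22L, 25L),
                                 spacer2_len = 13L,
                                 anchor_window = c(20L, 40L),
                                 r2_genomic_len = 50L,
                                 r1_truncate_to = 75L,
                                 spacer1_seq = "TCAGCATGCGGCTACGCT",
                                 spacer2_seq = "GTGGAGTCGTGAT",
                                 adaptor_seq = "ATCGGAAGAGCACACGTCTGAACTCCAGTCACGGAACTTGATCTCGTATG") {
  arch <- structure(list(
    tn5_indexes = toupper(tn5_indexes),
    round_whitelists = lapply(round_whitelists, toupper),
    linker_anchor = toupper(linker_anchor),
    me_sequence = toupper(me_sequence),
    bc2_start_range = as.integer(bc2_start_range),
    spacer2_len = as.integer(spacer2_len),
    anchor_window = as.integer(anchor_window),
    r2_genomic_len = as.integer(r2_genomic_len),
    r1_truncate_to = as.integer(r1_truncate_to),
    spacer1_seq = toupper(spacer1_seq),
    spacer2_seq = toupper(spacer2_seq),
    adaptor_seq = toupper(adaptor_seq)
  ), class = "barcode_architecture")
  validate_architecture(arch)
  arch
}

#' @rdname barcode_architecture
#' @param arch object to validate.
#' @export
validate_architecture <- function(arch) {
  stopifnot(inherits(arch, "barcode_architecture"))
  if (nchar(arch$linker_anchor) != 17L)
    stop("linker_anchor must be exactly 17 nt")
  if (any(nchar(arch$tn5_indexes) != 3L))
    stop("Tn5 indexes must be exactly 3 nt")
  if (anyDuplicated(arch$tn5_indexes))
    stop("Tn5 indexes must be distinct")
  if (length(arch$round_whitelists) != 3L)
    stop("exactly three ligation-round whitelists are required")
  for (r in seq_along(arch$round_whitelists)) {
    wl <- arch$round_whitelists[[r]]
    if (any(nchar(wl) != 7L))
      stop(sprintf("round %d: barcodes must be exactly 7 nt", r))
    if (anyDuplicated(wl))
      stop(sprintf("round %d: barcodes must be distinct", r))
    suf <- substr(wl, 3L, 7L)
    if (anyDuplicated(suf))
      stop(sprintf("round %d: last-5-nt suffixes must be distinct", r))
  }
  if (nchar(arch$spacer1_seq) < arch$bc2_start_range[2] - 7L)
    stop("spacer1_seq too short for the configured stagger")
  if (nchar(arch$spacer2_seq) != arch$spacer2_len)
    stop("spacer2_seq length must equal spacer2_len")
  invisible(arch)
}

#' @rdname barcode_architecture
#' @export
default_tn5_indexes <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Deterministic 96-barcode whitelists with distinct last-5 suffixes
#'
#' The published whitelists are not reproduced in the text, so the default
#' whitelists are generated deterministically: per round, 96 distinct 5-nt
#' suffixes are taken on a stride through the 4^5 suffix space (guaranteeing
#' suffix uniqueness) and prefixed with a varying 2-mer.
#'
#' @return list of three character vectors (96 barcodes of 7 nt each).
#' @export
default_round_whitelists <- function() {
  b <- c("A", "C", "G", "T")
  to_seq <- function(code, ndigits) {
    digits <- integer(ndigits)
    for (i in ndigits:1) {
      digits[i] <- code %% 4L
      code <- code %/% 4L
    }
    paste(b[digits + 1L], collapse = "")
  }
  lapply(1:3, function(r) {
    vapply(0:95, function(i) {
      suffix <- to_seq((i * 10L + (r - 1L) * 3L) %% 1024L, 5L)
      prefix <- to_seq((i * 5L + r) %% 16L, 2L)
      paste0(prefix, suffix)
    }, character(1))
  })
}

# Derived layout offsets (0-based), all relative to the linker anchor start.
arch_layout <- function(arch) {
  list(
    bc1_start = 0L,
    anchor_offsets = arch$bc2_start_range + 7L,
    bc2_rel = -7L,              # bc2 start relative to anchor start
    bc3_rel = 17L,              # bc3 start relative to anchor start
    tn5_rel = 17L + 7L + arch$spacer2_len,
    me_rel = 17L + 7L + arch$spacer2_len + 3L,
    region_len_for = function(bc2_start)
      bc2_start + 31L + arch$spacer2_len + 3L + nchar(arch$me_sequence)
  )
}

#' Write / load a barcode architecture as plain-text files
#'
#' Whitelists are stored one sequence per line (`tn5.txt`, `round1.txt`,
#' `round2.txt`, `round3.txt`); scalar layout settings go into a YAML-like
#' `config.yml` (simple `key: value` lines).
#'
#' @param arch a \code{barcode_architecture}.
#' @param dir directory to write to / read from.
#' @return \code{write_architecture} returns \code{dir} invisibly;
#'   \code{load_architecture} returns a validated
#'   \code{barcode_architecture}.
#' @export
write_architecture <- function(arch, dir) {
  validate_architecture(arch)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(arch$tn5_indexes, file.path(dir, "tn5.txt"))
  for (r in 1:3)
    writeLines(arch$round_whitelists[[r]],
               file.path(dir, sprintf("round%d.txt", r)))
  scalars <- c(
    linker_anchor = arch$linker_anchor,
    me_sequence = arch$me_sequence,
    bc2_start_min = arch$bc2_start_range[1],
    bc2_start_max = arch$bc2_start_range[2],
    spacer2_len = arch$spacer2_len,
    anchor_window_min = arch$anchor_window[1],
    anchor_window_max = arch$anchor_window[2],
    r2_genomic_len = arch$r2_genomic_len,
    r1_truncate_to = arch$r1_truncate_to,
    spacer1_seq = arch$spacer1_seq,
    spacer2_seq = arch$spacer2_seq,
    adaptor_seq = arch$adaptor_seq
  )
  writeLines(paste0(names(scalars), ": ", scalars),
             file.path(dir, "config.yml"))
  invisible(dir)
}

#' @rdname write_architecture
#' @export
load_architecture <- function(dir) {
  cfg_lines <- readLines(file.path(dir, "config.yml"))
  kv <- regmatches(cfg_lines, regexec("^([^:]+): *(.*)$", cfg_lines))
  cfg <- stats::setNames(vapply(kv, `[`, character(1), 3L),
                         vapply(kv, `[`, character(1), 2L))
  barcode_architecture(
    tn5_indexes = readLines(file.path(dir, "tn5.txt")),
    round_whitelists = lapply(1:3, function(r)
      readLines(file.path(dir, sprintf("round%d.txt", r)))),
    linker_anchor = cfg[["linker_anchor"]],
    me_sequence = cfg[["me_sequence"]],
    bc2_start_range = as.integer(c(cfg[["bc2_start_min"]],
                                   cfg[["bc2_start_max"]])),
    spacer2_len = as.integer(cfg[["spacer2_len"]]),
    anchor_window = as.integer(c(cfg[["anchor_window_min"]],
                                 cfg[["anchor_window_max"]])),
    r2_genomic_len = as.integer(cfg[["r2_genomic_len"]]),
    r1_truncate_to = as.integer(cfg[["r1_truncate_to"]]),
    spacer1_seq = cfg[["spacer1_seq"]],
    spacer2_seq = cfg[["spacer2_seq"]],
    adaptor_seq = cfg[["adaptor_seq"]]
  )
}

#' @export
print.barcode_architecture <- function(x, ...) {
  cat("barcode_architecture\n")
  cat(sprintf("  Tn5 indexes : %d x %d nt\n", length(x$tn5_indexes), 3L))
  cat(sprintf("  rounds      : %s barcodes x 7 nt\n",
              paste(lengths(x$round_whitelists), collapse = "/")))
  cat(sprintf("  linker      : %s (17 nt anchor)\n", x$linker_anchor))
  cat(sprintf("  ME          : %s\n", x$me_sequence))
  cat(sprintf("  stagger     : bc2 start in [%d, %d] (0-based)\n",
              x$bc2_start_range[1], x$bc2_start_range[2]))
  cat(sprintf("  barcode space: %s combinations\n",
              format(total_barcode_space(length(x$tn5_indexes),
                                         lengths(x$round_whitelists)),
                     big.mark = ",")))
  invisible(x)
}
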