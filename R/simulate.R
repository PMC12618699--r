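#' Simulate a small reference genome with TSS and peak annotations
#'
#' Generates a random genome (uniform base composition), a set of
#' transcription start sites and a set of accessibility peaks, laid out on a
#' regular grid of well-separated slots so that TSS windows, TSS profile
#' flanks and peaks never overlap each other. Coordinates are 0-based
#' half-open throughout.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_tss,n_peaks number of TSS (width-1, stranded) and peak
#'   intervals to place.
#' @param peak_width width of each peak (bp).
#' @param spacing minimum distance between feature slots (bp); must leave
#'   room for the widest window drawn around a feature.
#' @param margin distance kept free at chromosome ends (bp).
#' @param seed integer seed; all output is deterministic given the seed.
#' @param out_dir optional directory; when given, writes \code{genome.fa},
#'   \code{tss.bed} and \code{peaks.bed}.
#' @return object of class \code{synthetic_genome}: list with \code{seqs}
#'   (a \code{DNAStringSet}), \code{chrom_lengths}, \code{tss} and
#'   \code{peaks} (data.tables with 0-based half-open \code{start}/\code{end}).
#' @export
simulate_reference <- function(chrom_lengths = c(chr1 = 300000L, chr2 = 300000L),
                               n_tss = 20L, n_peaks = 50L,
                               peak_width = 400L, spacing = 7000L,
                               margin = 5000L, seed, out_dir = NULL) {
  stopifnot(!missing(seed))
  set.seed(seed)
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be named")
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   names(chrom_lengths))
  bases <- c("A", "C", "G", "T")
  seqs <- Biostrings::DNAStringSet(vapply(chrom_lengths, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1)))
  names(seqs) <- names(chrom_lengths)

  slots <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (L < 2 * margin + spacing)
      stop("chromosome ", ch, " too short for the requested feature layout")
    data.table::data.table(chrom = ch,
                           pos = seq(margin, L - margin, by = spacing))
  }))
  n_feat <- n_tss + n_peaks
  if (n_feat > nrow(slots))
    stop("not enough room: ", n_feat, " features requested, ",
         nrow(slots), " slots available")
  picked <- slots[sample.int(nrow(slots), n_feat), ]

  tss <- peaks <- data.table::data.table(chrom = character(),
                                         start = integer(), end = integer(),
                                         strand = character())
  if (n_tss > 0) {
    t <- picked[seq_len(n_tss)]
    tss <- data.table::data.table(chrom = t$chrom, start = t$pos,
                                  end = t$pos + 1L,
                                  strand = sample(c("+", "-"), n_tss,
                                                  replace = TRUE))
    data.table::setorder(tss, chrom, start)
  }
  if (n_peaks > 0) {
    p <- picked[n_tss + seq_len(n_peaks)]
    half <- peak_width %/% 2L
    peaks <- data.table::data.table(chrom = p$chrom, start = p$pos - half,
                                    end = p$pos - half + as.integer(peak_width),
                                    strand = "*")
    data.table::setorder(peaks, chrom, start)
  }
  for (tab in list(tss, peaks)) {
    if (nrow(tab) &&
        any(tab$start < 0L | tab$end > chrom_lengths[tab$chrom]))
      stop("feature outside chromosome bounds")
  }

  genome <- structure(list(seqs = seqs, chrom_lengths = chrom_lengths,
                           tss = tss, peaks = peaks),
                      class = "synthetic_genome")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(seqs, file.path(out_dir, "genome.fa"))
    write_bed(tss, file.path(out_dir, "tss.bed"))
    write_bed(peaks, file.path(out_dir, "peaks.bed"))
  }
  genome
}

write_bed <- function(tab, path) {
  out <- data.table::data.table(tab$chrom, tab$start, tab$end,
                                name = if (nrow(tab)) paste0("f", seq_len(nrow(tab))) else character(),
                                score = if (nrow(tab)) 0L else integer(),
                                strand = if ("strand" %in% names(tab)) tab$strand else "*")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals (0-based half-open)
#'
#' @param path BED3+ file; column 6, when present, is taken as strand.
#' @return data.table with chrom, start, end, strand.
#' @export
read_bed <- function(path) {
  b <- data.table::fread(path, header = FALSE)
  out <- data.table::data.table(chrom = as.character(b[[1]]),
                                start = as.integer(b[[2]]),
                                end = as.integer(b[[3]]),
                                strand = if (ncol(b) >= 6) as.character(b[[6]]) else "*")
  out
}

#' Simulate barcoded cells
#'
#' Assigns each cell a (Tn5 index, round-1, round-2, round-3) barcode
#' tuple, a cell type, a condition and a target fragment count. By default
#' tuples are sampled without replacement from the full combinatorial
#' space; collision mode instead draws tuples uniformly with replacement
#' from the first \code{collision_space} tuples (lexicographic), emulating
#' the birthday-paradox setting.
#'
#' @param n_cells number of cells.
#' @param arch a \code{\link{barcode_architecture}}.
#' @param celltype_props named numeric vector of cell-type proportions.
#' @param condition_props named numeric vector of condition proportions.
#' @param fragments_per_cell scalar or length-\code{n_cells} vector of
#'   target fragment counts.
#' @param allow_collisions draw tuples with replacement (see above).
#' @param collision_space size D of the tuple space used in collision mode.
#' @param seed integer seed.
#' @return data.table of class \code{cell_truth} with 1-based whitelist
#'   indices \code{tn5}, \code{bc1}, \code{bc2}, \code{bc3}.
#' @export
simulate_cells <- function(n_cells, arch = barcode_architecture(),
                           celltype_props = c(typeA = 0.5, typeB = 0.5),
                           condition_props = c(cond1 = 1),
                           fragments_per_cell = 200L,
                           allow_collisions = FALSE, collision_space = NULL,
                           seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  n1 <- length(arch$round_whitelists[[1]])
  n2 <- length(arch$round_whitelists[[2]])
  n3 <- length(arch$round_whitelists[[3]])
  nt <- length(arch$tn5_indexes)
  space <- total_barcode_space(nt, c(n1, n2, n3))

  if (allow_collisions) {
    D <- if (is.null(collision_space)) space else as.numeric(collision_space)
    if (D < 1 || D > space) stop("collision_space must be in [1, total space]")
    idx <- sample.int(D, n_cells, replace = TRUE) - 1
    # lexicographic decomposition: tn5 slowest, bc3 fastest
    bc3 <- idx %% n3; idx <- idx %/% n3
    bc2 <- idx %% n2; idx <- idx %/% n2
    bc1 <- idx %% n1; idx <- idx %/% n1
    tn5 <- idx
    tup <- data.table::data.table(tn5 = as.integer(tn5) + 1L,
                                  bc1 = as.integer(bc1) + 1L,
                                  bc2 = as.integer(bc2) + 1L,
                                  bc3 = as.integer(bc3) + 1L)
  } else {
    if (n_cells > space)
      stop("n_cells exceeds the barcode space; enable allow_collisions")
    tup <- data.table::data.table(tn5 = sample.int(nt, n_cells, TRUE),
                                  bc1 = sample.int(n1, n_cells, TRUE),
                                  bc2 = sample.int(n2, n_cells, TRUE),
                                  bc3 = sample.int(n3, n_cells, TRUE))
    key <- function(x) paste(x$tn5, x$bc1, x$bc2, x$bc3)
    dup <- duplicated(key(tup))
    while (any(dup)) {
      nd <- sum(dup)
      tup[dup, c("tn5", "bc1", "bc2", "bc3") :=
            list(sample.int(nt, nd, TRUE), sample.int(n1, nd, TRUE),
                 sample.int(n2, nd, TRUE), sample.int(n3, nd, TRUE))]
      dup <- duplicated(key(tup))
    }
  }

  cells <- data.table::data.table(
    cell = sprintf("cell%05d", seq_len(n_cells)),
    tup,
    cell_type = sample(names(celltype_props), n_cells, replace = TRUE,
                       prob = celltype_props),
    condition = sample(names(condition_props), n_cells, replace = TRUE,
                       prob = condition_props),
    n_fragments = as.integer(rep_len(fragments_per_cell, n_cells))
  )
  data.table::setattr(cells, "class", c("cell_truth", class(cells)))
  cells
}

#' Fragment-length models
#'
#' \code{"ffpe"}: truncated lognormal with mode around 60 bp and a hard
#' floor of 20 bp, mimicking heavily degraded FFPE inserts (the bulk of the
#' mass below 100-300 bp). \code{"fresh"}: nucleosomal mixture with
#' sub-nucleosomal, mono- and di-nucleosomal components. \code{"custom"}
#' takes a user sampler \code{function(n)} returning integer lengths.
#'
#' @param preset one of \code{"ffpe"}, \code{"fresh"}, \code{"custom"}.
#' @param sampler custom length sampler (required for \code{"custom"}).
#' @return list with a \code{sample(n)} function.
#' @export
frag_model <- function(preset = c("ffpe", "fresh", "custom"), sampler = NULL) {
  preset <- match.arg(preset)
  fn <- switch(preset,
    ffpe = function(n) {
      len <- round(stats::rlnorm(n, meanlog = log(60) + 0.36, sdlog = 0.6))
      pmin(pmax(len, 20L), 1000L)
    },
    fresh = function(n) {
      comp <- sample.int(3L, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
      mu <- c(80, 200, 380)[comp]
      len <- round(stats::rnorm(n, mean = mu, sd = mu * 0.15))
      pmin(pmax(len, 25L), 1000L)
    },
    custom = {
      if (is.null(sampler)) stop("custom frag_model needs a sampler")
      sampler
    })
  list(preset = preset, sample = fn)
}

#' Duplicate-structure model
#'
#' Each tagmentation event yields \code{n_ivt} in-vitro-transcription (IVT)
#' copies (shared 5' insertion coordinate, independent 3' ends) and each
#' molecule is further amplified into \code{n_pcr} exact PCR copies. Both
#' counts are 1 + geometric, parameterised by their means; a mean of 1
#' gives the degenerate all-ones model (no duplicates).
#'
#' @param ivt_mean,pcr_mean mean copy numbers (>= 1).
#' @return list with \code{ivt(n)} and \code{pcr(n)} samplers.
#' @export
dup_model <- function(ivt_mean = 2, pcr_mean = 1.5) {
  stopifnot(ivt_mean >= 1, pcr_mean >= 1)
  geom1 <- function(n, m)
    if (m == 1) rep(1L, n) else 1L + stats::rgeom(n, prob = 1 / m)
  list(ivt_mean = ivt_mean, pcr_mean = pcr_mean,
       ivt = function(n) geom1(n, ivt_mean),
       pcr = function(n) geom1(n, pcr_mean))
}

#' Simulate per-cell chromatin fragments with duplicate structure
#'
#' Places fragments on the synthetic genome. Per cell, an exact share of
#' fragments is planted inside oriented TSS windows (-1000..+200) and
#' inside peaks (restricted to the cell type's accessible peaks when
#' \code{celltype_peaks} is given); the remainder is placed uniformly on
#' the genome, rejected away from TSS windows and peaks so the planted
#' fractions are the ground truth for FRiT/FRiP. Each fragment carries IVT
#' and PCR copy counts; within a cell no two fragments share a
#' (chrom, strand, 5' insertion) key, so unique-fragment counts per cell
#' are exactly recoverable after deduplication.
#'
#' @param genome a \code{synthetic_genome}.
#' @param cells a \code{cell_truth} table.
#' @param frag_model,dup_model see \code{\link{frag_model}},
#'   \code{\link{dup_model}}.
#' @param tss_frac,peak_frac per-cell fractions of fragments planted in
#'   TSS windows / peaks (exact up to rounding).
#' @param celltype_peaks optional named list: cell type -> peak row indices
#'   accessible to that type.
#' @param seed integer seed.
#' @return data.table of class \code{fragment_truth}: fragment id, cell,
#'   chrom, start, end, strand, n_ivt, n_pcr, ivt_len (list column of IVT
#'   copy lengths, first entry the full molecule), placement.
#' @export
simulate_fragments <- function(genome, cells,
                               frag_model = scSplitPool::frag_model("ffpe"),
                               dup_model = scSplitPool::dup_model(),
                               tss_frac = 0, peak_frac = 0.5,
                               celltype_peaks = NULL, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  if (peak_frac > 0 && nrow(genome$peaks) == 0)
    stop("peak-biased placement requested but the genome has no peaks")
  if (tss_frac > 0 && nrow(genome$tss) == 0)
    stop("TSS-biased placement requested but the genome has no TSS")

  tssw <- tss_windows(genome$tss)                      # oriented -1000..+200
  excl <- data.table::rbindlist(list(
    tssw[, c("chrom", "start", "end")],
    genome$peaks[, c("chrom", "start", "end")]))
  chrlen <- genome$chrom_lengths

  per_cell <- lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n_fragments[i]
    nt <- round(tss_frac * n)
    np <- round(peak_frac * n)
    if (nt + np > n) np <- n - nt
    nb <- n - nt - np
    len <- frag_model$sample(n)
    start <- integer(n); chrom <- character(n)
    k <- 0L
    if (nt > 0) {
      rows <- sample.int(nrow(tssw), nt, replace = TRUE)
      lo <- tssw$start[rows]; hi <- tssw$end[rows]
      L <- pmin(len[k + seq_len(nt)], hi - lo)
      len[k + seq_len(nt)] <- L
      start[k + seq_len(nt)] <- lo + floor(stats::runif(nt) * (hi - lo - L + 1))
      chrom[k + seq_len(nt)] <- tssw$chrom[rows]
      k <- k + nt
    }
    if (np > 0) {
      pk_rows <- seq_len(nrow(genome$peaks))
      if (!is.null(celltype_peaks)) {
        pk_rows <- celltype_peaks[[cells$cell_type[i]]]
        if (is.null(pk_rows) || !length(pk_rows))
          stop("no accessible peaks for cell type ", cells$cell_type[i])
      }
      rows <- pk_rows[sample.int(length(pk_rows), np, replace = TRUE)]
      lo <- genome$peaks$start[rows]; hi <- genome$peaks$end[rows]
      L <- pmin(len[k + seq_len(np)], hi - lo)
      len[k + seq_len(np)] <- L
      start[k + seq_len(np)] <- lo + floor(stats::runif(np) * (hi - lo - L + 1))
      chrom[k + seq_len(np)] <- genome$peaks$chrom[rows]
      k <- k + np
    }
    if (nb > 0) {
      idx <- k + seq_len(nb)
      chrom[idx] <- names(chrlen)[sample.int(length(chrlen), nb, replace = TRUE)]
      start[idx] <- place_background(chrom[idx], len[idx], chrlen, excl)
    }
    data.table::data.table(
      cell = cells$cell[i], chrom = chrom, start = start,
      end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      placement = rep(c("tss", "peak", "background"), c(nt, np, nb)))
  })
  frags <- data.table::rbindlist(per_cell)

  # within-cell 5'-key uniqueness (retry placement for the rare clashes)
  fp <- function(d) ifelse(d$strand == "+", d$start, d$end)
  key <- function(d) paste(d$cell, d$chrom, d$strand, fp(d))
  dup <- duplicated(key(frags))
  tries <- 0L
  while (any(dup) && tries < 100L) {
    idx <- which(dup)
    len <- frags$end[idx] - frags$start[idx]
    for (j in seq_along(idx)) {
      i <- idx[j]
      pl <- frags$placement[i]
      if (pl == "tss") {
        r <- sample.int(nrow(tssw), 1L)
        L <- min(len[j], tssw$end[r] - tssw$start[r])
        frags$chrom[i] <- tssw$chrom[r]
        frags$start[i] <- tssw$start[r] +
          floor(stats::runif(1) * (tssw$end[r] - tssw$start[r] - L + 1))
        frags$end[i] <- frags$start[i] + L
      } else if (pl == "peak") {
        r <- sample.int(nrow(genome$peaks), 1L)
        pk <- genome$peaks[r]
        L <- min(len[j], pk$end - pk$start)
        frags$chrom[i] <- pk$chrom
        frags$start[i] <- pk$start +
          floor(stats::runif(1) * (pk$end - pk$start - L + 1))
        frags$end[i] <- frags$start[i] + L
      } else {
        frags$chrom[i] <- names(chrlen)[sample.int(length(chrlen), 1L)]
        frags$start[i] <- place_background(frags$chrom[i], len[j], chrlen,
                                           excl)
        frags$end[i] <- frags$start[i] + len[j]
      }
    }
    dup <- duplicated(key(frags))
    tries <- tries + 1L
  }
  if (any(dup)) stop("could not enforce unique insertion keys")

  n <- nrow(frags)
  frags[, `:=`(fragment = sprintf("frag%07d", seq_len(n)),
               n_ivt = dup_model$ivt(n),
               n_pcr = dup_model$pcr(n))]
  L <- frags$end - frags$start
  frags[, ivt_len := lapply(seq_len(n), function(j) {
    extra <- frags$n_ivt[j] - 1L
    if (extra <= 0) return(L[j])
    c(L[j], pmax(20L, round(L[j] * stats::runif(extra, 0.3, 1))))
  })]
  data.table::setcolorder(frags, c("fragment", "cell", "chrom", "start",
                                   "end", "strand", "n_ivt", "n_pcr",
                                   "ivt_len", "placement"))
  data.table::setattr(frags, "class", c("fragment_truth", class(frags)))
  frags
}

# Oriented TSS windows, 0-based half-open: upstream 1000, downstream 200.
tss_windows <- function(tss, upstream = 1000L, downstream = 200L) {
  pos <- tss$start
  minus <- tss$strand == "-"
  data.table::data.table(
    chrom = tss$chrom,
    start = ifelse(minus, pos + 1L - downstream, pos - upstream),
    end = ifelse(minus, pos + 1L + upstream, pos + downstream),
    strand = tss$strand)
}

# Uniform placement avoiding an exclusion interval set (rejection sampling).
place_background <- function(chrom, len, chrlen, excl) {
  n <- length(chrom)
  start <- floor(stats::runif(n) * (chrlen[chrom] - len))
  if (nrow(excl) == 0) return(as.integer(start))
  eg <- GenomicRanges::GRanges(excl$chrom,
                               IRanges::IRanges(excl$start + 1L, excl$end))
  for (it in 1:50) {
    fg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, start + len))
    bad <- GenomicRanges::countOverlaps(fg, eg) > 0
    if (!any(bad)) break
    start[bad] <- floor(stats::runif(sum(bad)) * (chrlen[chrom[bad]] - len[bad]))
  }
  as.integer(start)
}

#' Expand fragment truth into aligned read pairs
#'
#' Produces the alignment-level record stream the deduplicator consumes:
#' one row per sequenced molecule copy. IVT copies of a fragment share its
#' 5' insertion coordinate and differ at the 3' end (copy lengths from
#' \code{ivt_len}); PCR copies are exact coordinate duplicates.
#'
#' @param frag_truth a \code{fragment_truth} table.
#' @param mapq mapping quality to assign.
#' @param shuffle randomly permute the output rows.
#' @param seed seed for the shuffle.
#' @return data.table of aligned pairs: cell, chrom, start, end, strand,
#'   mapq, fragment, ivt_copy.
#' @export
simulate_aligned_pairs <- function(frag_truth, mapq = 60L, shuffle = TRUE,
                                   seed = 1L) {
  ivt <- frag_truth[, .(ivt_copy = seq_len(n_ivt[1]),
                        len = ivt_len[[1]],
                        cell = cell[1], chrom = chrom[1], start = start[1],
                        end = end[1], strand = strand[1], n_pcr = n_pcr[1]),
                    by = "fragment"]
  five_p <- ifelse(ivt$strand == "+", ivt$start, ivt$end)
  ivt[, `:=`(start = as.integer(ifelse(strand == "+", five_p, five_p - len)),
             end = as.integer(ifelse(strand == "+", five_p + len, five_p)))]
  pairs <- ivt[rep(seq_len(.N), n_pcr)]
  pairs[, `:=`(mapq = as.integer(mapq), n_pcr = NULL, len = NULL)]
  data.table::setcolorder(pairs, c("cell", "chrom", "start", "end", "strand",
                                   "mapq", "fragment", "ivt_copy"))
  if (shuffle) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs))]
  }
  pairs[]
}
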