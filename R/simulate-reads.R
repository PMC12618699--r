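#' Emit paired reads from simulated fragments
#'
#' Builds one read pair per sequenced molecule copy (IVT copies x PCR
#' copies). Read 2 carries the staggered barcode region (88-91 nt: round-1
#' barcode, spacer, round-2 barcode, 17-nt linker, round-3 barcode, spacer,
#' Tn5 index, mosaic end) followed by 50 genomic bases; Read 1 is 91 nt of
#' genomic sequence read from the opposite end of the molecule. Molecules
#' shorter than the read length run through the reverse-complemented mosaic
#' end into the downstream adaptor, exactly what the demultiplexer's
#' adaptor trimming removes. Substitution errors are applied at separate
#' rates to the barcode region and the genomic bases.
#'
#' @param frag_truth a \code{fragment_truth} table.
#' @param cells the \code{cell_truth} table the fragments were drawn for.
#' @param genome the \code{synthetic_genome} supplying sequence.
#' @param arch a \code{\link{barcode_architecture}}.
#' @param error_rate named numeric: per-base substitution rates for the
#'   \code{barcode} region of Read 2 and for \code{genomic} bases.
#' @param seed integer seed.
#' @return object of class \code{read_set}: list with \code{id}, \code{r1},
#'   \code{r2} (character vectors) and \code{truth} (read id -> cell,
#'   fragment, molecule length).
#' @export
emit_reads <- function(frag_truth, cells, genome, arch = barcode_architecture(),
                       error_rate = c(barcode = 0, genomic = 0), seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  lay <- arch_layout(arch)

  mol <- simulate_aligned_pairs(frag_truth, shuffle = FALSE)
  n <- nrow(mol)
  if (n == 0) stop("no molecules to emit")
  ids <- sprintf("read%07d", seq_len(n))

  # genomic molecule sequences, oriented 5'->3' from the insertion end
  mseq <- character(n)
  for (ch in unique(mol$chrom)) {
    i <- which(mol$chrom == ch)
    v <- Biostrings::extractAt(genome$seqs[[ch]],
                               IRanges::IRanges(mol$start[i] + 1L, mol$end[i]))
    v <- as.character(v)
    minus <- mol$strand[i] == "-"
    if (any(minus))
      v[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(v[minus])))
    mseq[i] <- v
  }

  idx <- match(mol$cell, cells$cell)
  if (anyNA(idx)) stop("fragment truth references unknown cells")
  bc1 <- arch$round_whitelists[[1]][cells$bc1[idx]]
  bc2 <- arch$round_whitelists[[2]][cells$bc2[idx]]
  bc3 <- arch$round_whitelists[[3]][cells$bc3[idx]]
  tn5 <- arch$tn5_indexes[cells$tn5[idx]]

  rng <- arch$bc2_start_range
  bc2_start <- sample(seq(rng[1], rng[2]), n, replace = TRUE)
  if (any(bc2_start - 7L > nchar(arch$spacer1_seq)))
    stop("stagger exceeds the configured spacer length")
  spacer1 <- substr(rep(arch$spacer1_seq, n), 1L, bc2_start - 7L)

  rc_me <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(arch$me_sequence)))
  fill <- paste0(rc_me, strrep(arch$adaptor_seq,
                               ceiling(120 / nchar(arch$adaptor_seq))))

  gen2 <- substr(paste0(mseq, fill), 1L, arch$r2_genomic_len)
  r1_raw <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(mseq)))
  r1 <- substr(paste0(r1_raw, fill), 1L, 91L)
  barcode_region <- paste0(bc1, spacer1, bc2, arch$linker_anchor, bc3,
                           arch$spacer2_seq, tn5, arch$me_sequence)
  stopifnot(all(nchar(barcode_region) == lay$region_len_for(bc2_start)))

  if (error_rate[["barcode"]] > 0)
    barcode_region <- substitute_bases(barcode_region, error_rate[["barcode"]])
  if (error_rate[["genomic"]] > 0) {
    gen2 <- substitute_bases(gen2, error_rate[["genomic"]])
    r1 <- substitute_bases(r1, error_rate[["genomic"]])
  }
  r2 <- paste0(barcode_region, gen2)

  truth <- data.table::data.table(read_id = ids, cell = mol$cell,
                                  fragment = mol$fragment,
                                  ivt_copy = mol$ivt_copy,
                                  molecule_len = mol$end - mol$start,
                                  bc2_start = bc2_start)
  structure(list(id = ids, r1 = r1, r2 = r2, truth = truth, arch = arch),
            class = "read_set")
}

# iid per-base substitutions (to a uniformly chosen different base)
substitute_bases <- function(seqs, rate) {
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Write a read set as paired FASTQ plus a truth table
#'
#' @param reads a \code{read_set} from \code{\link{emit_reads}}.
#' @param dir output directory; writes \code{R1.fastq.gz},
#'   \code{R2.fastq.gz} and \code{truth.tsv}.
#' @param gzip compress the FASTQ files.
#' @return named character vector of the three paths, invisibly.
#' @export
write_reads <- function(reads, dir, gzip = TRUE) {
  stopifnot(inherits(reads, "read_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0("R1", ext))
  p2 <- file.path(dir, paste0("R2", ext))
  pt <- file.path(dir, "truth.tsv")
  write_fastq(reads$id, reads$r1, p1, gzip)
  write_fastq(reads$id, reads$r2, p2, gzip)
  data.table::fwrite(reads$truth, pt, sep = "\t")
  invisible(c(r1 = p1, r2 = p2, truth = pt))
}

write_fastq <- function(ids, seqs, path, gzip = grepl("\\.gz$", path)) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", compress = gzip,
                              qualities = quals)
  invisible(path)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = sub(" .*$", "", names(x)),
       seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}
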