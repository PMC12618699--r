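#' Build a sparse peak-by-cell count matrix
#'
#' Entry (p, c) is the number of unique fragments of cell c overlapping
#' peak p (any shared base, half-open arithmetic). Overlapping peaks are
#' allowed but warned about, since a fragment can then count in several
#' peaks.
#'
#' @param fragments fragments table (chrom, start, end, barcode), 0-based
#'   half-open.
#' @param peaks peak intervals, 0-based half-open.
#' @return \code{dgCMatrix}, peaks x cells, dimnames
#'   \code{chrom:start-end} x barcode.
#' @export
build_peak_cell_matrix <- function(fragments, peaks) {
  f <- data.table::as.data.table(fragments)
  p <- data.table::as.data.table(peaks)
  pg <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
  if (nrow(p) > 1 && !IRanges::isDisjoint(pg))
    warning("peaks overlap; a fragment may be counted in more than one peak")
  fg <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start + 1L, f$end))
  ov <- GenomicRanges::findOverlaps(fg, pg)
  cells <- sort(unique(f$barcode))
  ci <- match(f$barcode[S4Vectors::queryHits(ov)], cells)
  m <- Matrix::sparseMatrix(i = S4Vectors::subjectHits(ov), j = ci,
                            x = 1, dims = c(nrow(p), length(cells)),
                            dimnames = list(paste0(p$chrom, ":", p$start,
                                                   "-", p$end),
                                            cells))
  methods::as(m, "CsparseMatrix")
}

#' Depth-normalise a peak-by-cell matrix
#'
#' Each cell's column is divided by the cell's total count and scaled by
#' 1e4. Cells with zero total are dropped with a warning.
#'
#' @param mat peak x cell matrix (sparse or dense).
#' @return normalised matrix of the same class family.
#' @export
normalize_depth <- function(mat) {
  totals <- Matrix::colSums(mat)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " zero-total cell(s) excluded from normalisation")
    mat <- mat[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  out <- mat %*% Matrix::Diagonal(x = 1e4 / totals)
  dimnames(out) <- dimnames(mat)
  out
}

#' Pseudo-bulk replicate profiles for one group of cells
#'
#' Each replicate samples \code{min(n_cells, group size)} cells without
#' replacement (with replacement, flagged, when the group is smaller than
#' \code{n_cells}) and records the mean normalised accessibility per peak.
#'
#' @param mat normalised peak x cell matrix.
#' @param cells cell barcodes of the group (columns of \code{mat}).
#' @param R number of replicates (>= 2).
#' @param n_cells target cells per replicate (500 by default, matching the
#'   pseudo-bulk construction used for sparse single-cell accessibility).
#' @param seed integer seed.
#' @return matrix peaks x R of replicate means; attributes
#'   \code{sampled} (list of sampled barcodes) and \code{with_replacement}.
#' @export
make_pseudobulks <- function(mat, cells, R = 5L, n_cells = 500L, seed) {
  stopifnot(!missing(seed))
  if (length(cells) == 0) stop("empty group")
  if (R < 2) stop("at least two replicates are required for testing")
  missing_cells <- setdiff(cells, colnames(mat))
  if (length(missing_cells))
    stop("cells absent from matrix: ", missing_cells[1], " ...")
  set.seed(seed)
  replace <- length(cells) < n_cells
  if (replace)
    warning("group smaller than n_cells; sampling with replacement")
  k <- min(n_cells, length(cells))
  sampled <- vector("list", R)
  out <- matrix(0, nrow(mat), R)
  rownames(out) <- rownames(mat)
  for (r in seq_len(R)) {
    pick <- sample(cells, if (replace) n_cells else k, replace = replace)
    sampled[[r]] <- pick
    out[, r] <- Matrix::rowMeans(mat[, pick, drop = FALSE])
  }
  attr(out, "sampled") <- sampled
  attr(out, "with_replacement") <- replace
  out
}

#' Differential accessibility between two conditions
#'
#' Pseudo-bulk resampling test: per condition, \code{R} replicate profiles
#' are formed by averaging random samples of cells
#' (\code{\link{make_pseudobulks}}); each peak is then tested with a
#' two-sided Welch t-test across the R-vs-R replicate means,
#' Benjamini-Hochberg corrected over peaks. A peak passes when q < fdr and
#' the (epsilon-padded, direction-symmetric) fold change is at least
#' \code{min_fold}. Peaks constant across all replicates get p = 1.
#'
#' @param mat peak x cell count matrix (normalised internally unless
#'   \code{normalize = FALSE}).
#' @param groupA,groupB cell barcodes of the two conditions.
#' @param R replicates per condition (5 in the mouse setting, 10 for the
#'   human clinical setting).
#' @param n_cells cells sampled per replicate.
#' @param seed integer seed.
#' @param fdr,min_fold pass gates (defaults 0.05 and 2).
#' @param eps pad added to both means before the ratio.
#' @param normalize depth-normalise \code{mat} first.
#' @return data.table of class \code{differential_result}: peak, mean_a,
#'   mean_b, fold (>= 1, direction-symmetric), direction ("A" or "B"),
#'   p, q, pass.
#' @export
condition_differential_peaks <- function(mat, groupA, groupB, R = 5L,
                                         n_cells = 500L, seed,
                                         fdr = 0.05, min_fold = 2,
                                         eps = 1e-6, normalize = TRUE) {
  stopifnot(!missing(seed))
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("both groups must be nonempty")
  if (normalize) mat <- normalize_depth(mat)
  groupA <- intersect(groupA, colnames(mat))
  groupB <- intersect(groupB, colnames(mat))
  pbA <- make_pseudobulks(mat, groupA, R = R, n_cells = n_cells, seed = seed)
  pbB <- make_pseudobulks(mat, groupB, R = R, n_cells = n_cells,
                          seed = seed + 1L)
  welch_rows_test(pbA, pbB, fdr = fdr, min_fold = min_fold, eps = eps)
}

# Row-wise Welch t-tests of two replicate-mean matrices + BH + fold gate.
welch_rows_test <- function(pbA, pbB, fdr = 0.05, min_fold = 2, eps = 1e-6) {
  npeak <- nrow(pbA)
  p <- vapply(seq_len(npeak), function(i) {
    a <- pbA[i, ]; b <- pbB[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) return(1)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  mean_a <- rowMeans(pbA)
  mean_b <- rowMeans(pbB)
  ratio <- (mean_a + eps) / (mean_b + eps)
  fold <- pmax(ratio, 1 / ratio)
  res <- data.table::data.table(
    peak = if (is.null(rownames(pbA))) as.character(seq_len(npeak))
           else rownames(pbA),
    mean_a = mean_a, mean_b = mean_b, fold = fold,
    direction = ifelse(ratio >= 1, "A", "B"),
    p = p, q = q,
    pass = q < fdr & fold >= min_fold)
  data.table::setattr(res, "class", c("differential_result", class(res)))
  res
}

#' Cell-type-specific peaks (one-vs-rest with exclusivity)
#'
#' For each cell type, runs the pseudo-bulk differential test of that type
#' against all remaining cells and keeps peaks enriched toward the target
#' type (direction "A", q < fdr, fold >= min_fold). Peaks passing in more
#' than one cell type are then removed from every final set, so the
#' resulting sets are pairwise disjoint.
#'
#' @param mat peak x cell count matrix.
#' @param cell_types named character vector: barcode -> cell type.
#' @param R,n_cells,seed,fdr,min_fold,eps,normalize see
#'   \code{\link{condition_differential_peaks}}.
#' @return list of class \code{celltype_peaks}: \code{results} (per-type
#'   \code{differential_result}), \code{specific} (per-type character
#'   vectors of exclusive peak names), \code{excluded} (peaks removed by
#'   the exclusivity rule).
#' @export
celltype_specific_peaks <- function(mat, cell_types, R = 5L, n_cells = 500L,
                                    seed, fdr = 0.05, min_fold = 2,
                                    eps = 1e-6, normalize = TRUE) {
  stopifnot(!missing(seed))
  types <- sort(unique(cell_types))
  if (length(types) < 2) stop("at least two cell types are required")
  if (normalize) mat <- normalize_depth(mat)
  cell_types <- cell_types[intersect(names(cell_types), colnames(mat))]
  results <- list()
  passing <- list()
  for (k in seq_along(types)) {
    ty <- types[k]
    inset <- names(cell_types)[cell_types == ty]
    rest <- names(cell_types)[cell_types != ty]
    res <- condition_differential_peaks(mat, inset, rest, R = R,
                                        n_cells = n_cells,
                                        seed = seed + k, fdr = fdr,
                                        min_fold = min_fold, eps = eps,
                                        normalize = FALSE)
    res[, pass := pass & direction == "A"]
    results[[ty]] <- res
    passing[[ty]] <- res$peak[res$pass]
  }
  all_pass <- unlist(passing, use.names = FALSE)
  multi <- unique(all_pass[duplicated(all_pass)])
  specific <- lapply(passing, setdiff, y = multi)
  structure(list(results = results, specific = specific, excluded = multi),
            class = "celltype_peaks")
}
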