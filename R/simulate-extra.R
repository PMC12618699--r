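#' Simulate a peak-by-cell count matrix with planted differential peaks
#'
#' Poisson counts with per-peak baseline rates, per-cell depth factors and
#' a set of planted peaks whose rate is multiplied by \code{fold} in the
#' target group (or cell type). Ground truth (planted indices, labels) is
#' returned alongside the matrix.
#'
#' @param n_cells named integer vector: group label -> number of cells.
#' @param n_null,n_planted numbers of null and planted peaks.
#' @param fold rate multiplier of planted peaks in the target group.
#' @param target group receiving the planted signal (default: first).
#' @param base_mean baseline Poisson rate scale.
#' @param depth_range per-cell depth factors drawn uniformly from this
#'   range.
#' @param seed integer seed.
#' @return list: \code{mat} (sparse peaks x cells), \code{labels} (named
#'   character vector, barcode -> group), \code{planted} (row indices of
#'   planted peaks).
#' @export
simulate_peak_cell_counts <- function(n_cells = c(groupA = 2000L,
                                                  groupB = 2000L),
                                      n_null = 500L, n_planted = 50L,
                                      fold = 8, target = names(n_cells)[1],
                                      base_mean = 1, depth_range = c(0.5, 2),
                                      seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  npeak <- n_null + n_planted
  ncell <- sum(n_cells)
  labels <- rep(names(n_cells), n_cells)
  barcodes <- sprintf("bc%05d", seq_len(ncell))
  names(labels) <- barcodes

  lambda_p <- base_mean * stats::runif(npeak, 0.5, 1.5)
  planted <- sort(sample.int(npeak, n_planted))
  depth <- stats::runif(ncell, depth_range[1], depth_range[2])

  lam <- outer(lambda_p, depth)
  boost <- matrix(1, npeak, ncell)
  boost[planted, labels == target] <- fold
  counts <- matrix(stats::rpois(npeak * ncell, lam * boost), npeak, ncell)
  dimnames(counts) <- list(sprintf("peak%04d", seq_len(npeak)), barcodes)
  list(mat = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                         "CsparseMatrix"),
       labels = labels, planted = planted)
}

#' Simulate a clean bifurcating trajectory
#'
#' Cells are Gaussian blobs at the waypoints of a Y-shaped skeleton: a
#' root cluster, a shared intermediate cluster and two branch tips. The
#' per-cell planted pseudotime is the arc length of the cell's realised
#' position projected onto the generating skeleton of each lineage it
#' belongs to.
#'
#' @param n_per_cluster cells per cluster.
#' @param noise isotropic Gaussian SD around the waypoints.
#' @param centers 4 x 2 matrix of waypoints, rownames are cluster labels;
#'   the default forms a Y rooted at C0 splitting after C1 into C2/C3.
#' @param seed integer seed.
#' @return list: \code{embedding} (cells x 2), \code{clusters} (named),
#'   \code{truth} (cells x 2 matrix of planted pseudotimes, NA
#'   off-lineage), \code{lineages} (list of cluster paths),
#'   \code{start_cluster}.
#' @export
simulate_bifurcation <- function(n_per_cluster = 100L, noise = 0.35,
                                 centers = rbind(C0 = c(0, 0), C1 = c(3, 0),
                                                 C2 = c(6, 2), C3 = c(6, -2)),
                                 seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  labs <- rownames(centers)
  n <- n_per_cluster * length(labs)
  clusters <- rep(labs, each = n_per_cluster)
  embedding <- centers[clusters, , drop = FALSE] +
    matrix(stats::rnorm(n * 2, sd = noise), n, 2)
  rownames(embedding) <- sprintf("cell%05d", seq_len(n))
  names(clusters) <- rownames(embedding)

  lineages <- list(Lineage1 = c("C0", "C1", "C2"),
                   Lineage2 = c("C0", "C1", "C3"))
  truth <- matrix(NA_real_, n, 2,
                  dimnames = list(rownames(embedding), names(lineages)))
  for (l in seq_along(lineages)) {
    path <- lineages[[l]]
    onpath <- clusters %in% path
    truth[onpath, l] <- project_polyline(embedding[onpath, , drop = FALSE],
                                         centers[path, , drop = FALSE])
  }
  list(embedding = embedding, clusters = clusters, truth = truth,
       lineages = lineages, start_cluster = "C0")
}
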