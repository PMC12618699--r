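#' Minimal lineage engine: MST over cluster centroids
#'
#' Builds a minimum spanning tree over cluster centroids (Euclidean
#' distance), takes the root-to-leaf cluster paths from the start cluster
#' as lineages, and assigns each cell a pseudotime equal to the arc length
#' of its orthogonal projection onto the piecewise-linear centroid path of
#' every lineage containing its cluster. This is a deliberately simple,
#' pluggable engine; the bootstrap layer accepts any function with the
#' same signature.
#'
#' @param embedding numeric matrix, cells x dimensions (>= 2 dims);
#'   rownames are cell ids (generated when absent).
#' @param clusters character vector of cluster labels, one per row.
#' @param start_cluster label of the root cluster.
#' @return object of class \code{lineage_result}: \code{lineages} (named
#'   list of ordered cluster-label vectors, all starting at the start
#'   cluster), \code{pseudotime} (cells x lineages, NA off-lineage),
#'   \code{centroids}.
#' @export
default_lineage_engine <- function(embedding, clusters, start_cluster) {
  embedding <- as.matrix(embedding)
  if (ncol(embedding) < 2) stop("embedding must have >= 2 dimensions")
  if (is.null(rownames(embedding)))
    rownames(embedding) <- sprintf("cell%05d", seq_len(nrow(embedding)))
  labs <- sort(unique(clusters))
  if (length(labs) < 2) stop("at least two clusters are required")
  if (!start_cluster %in% labs)
    stop("start_cluster '", start_cluster, "' not present")

  centroids <- rowsum(embedding, clusters) / as.vector(table(clusters)[labs])
  centroids <- centroids[labs, , drop = FALSE]
  adj <- unclass(ape::mst(stats::dist(centroids)))

  # root-to-leaf paths by depth-first walk from the start cluster
  k <- length(labs)
  root <- match(start_cluster, labs)
  paths <- list()
  walk <- function(node, visited, path) {
    nbr <- setdiff(which(adj[node, ] == 1), visited)
    if (length(nbr) == 0) {
      if (length(path) > 1) paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (nx in nbr) walk(nx, c(visited, nx), c(path, nx))
  }
  walk(root, root, root)
  if (length(paths) == 0) paths <- list(root)   # single connected pair edge case
  lineages <- lapply(paths, function(p) labs[p])
  names(lineages) <- paste0("Lineage", seq_along(lineages))

  pt <- matrix(NA_real_, nrow(embedding), length(lineages),
               dimnames = list(rownames(embedding), names(lineages)))
  for (l in seq_along(lineages)) {
    path <- lineages[[l]]
    onpath <- clusters %in% path
    verts <- centroids[path, , drop = FALSE]
    pt[onpath, l] <- project_polyline(embedding[onpath, , drop = FALSE],
                                      verts)
  }
  structure(list(lineages = lineages, pseudotime = pt,
                 centroids = centroids, start_cluster = start_cluster),
            class = "lineage_result")
}

# Arc length of the orthogonal projection of each point onto a polyline.
project_polyline <- function(points, verts) {
  points <- as.matrix(points)
  n <- nrow(points)
  nseg <- nrow(verts) - 1L
  seglen <- sqrt(rowSums((verts[-1, , drop = FALSE] -
                            verts[-nrow(verts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  best_d2 <- rep(Inf, n)
  best_arc <- numeric(n)
  for (j in seq_len(nseg)) {
    A <- verts[j, ]; B <- verts[j + 1L, ]
    ab <- B - A
    len2 <- sum(ab^2)
    rel <- sweep(points, 2, A)
    t <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, as.vector(rel %*% ab) / len2))
    proj <- outer(t, ab)
    d2 <- rowSums((rel - proj)^2)
    better <- d2 < best_d2
    best_d2[better] <- d2[better]
    best_arc[better] <- cum[j] + t[better] * seglen[j]
  }
  best_arc
}

#' Bootstrap resampling of lineage inference
#'
#' Resamples cells with replacement \code{B} times, reruns the lineage
#' engine on each resample, maps every bootstrap lineage back to the
#' reference lineage it reproduces, and stores the re-aligned pseudotimes
#' in a cells x lineages x bootstraps array. A cell drawn several times in
#' a resample contributes one pseudotime value in that slice; a cell
#' absent from the resample is missing there. Replicates whose resample
#' lost the start cluster (or all but one cluster) are flagged invalid and
#' excluded from support denominators.
#'
#' @param embedding,clusters,start_cluster as in
#'   \code{\link{default_lineage_engine}}.
#' @param engine lineage engine function.
#' @param B number of bootstrap replicates.
#' @param seed integer seed; the resamples are deterministic given it.
#' @param match \code{"strict"} maps a bootstrap lineage to a reference
#'   lineage only when their ordered cluster sequences are identical;
#'   \code{"terminal"} relaxes this to equality of the terminal cluster.
#' @param indices optional list of index vectors overriding the resampling
#'   (mainly for identity-resample checks).
#' @return object of class \code{bootstrap_pseudotime}: \code{array}
#'   (cells x lineages x B), \code{recovered} (B x lineages logical),
#'   \code{valid} (logical B), \code{unmapped} (per-replicate count of
#'   bootstrap lineages matching no reference lineage),
#'   \code{reference} (the reference \code{lineage_result}).
#' @export
bootstrap_lineages <- function(embedding, clusters, start_cluster,
                               engine = default_lineage_engine,
                               B = 1000L, seed,
                               match = c("strict", "terminal"),
                               indices = NULL) {
  stopifnot(!missing(seed))
  match <- match.arg(match)
  embedding <- as.matrix(embedding)
  if (is.null(rownames(embedding)))
    rownames(embedding) <- sprintf("cell%05d", seq_len(nrow(embedding)))
  n <- nrow(embedding)
  reference <- engine(embedding, clusters, start_cluster)
  L <- length(reference$lineages)
  cells <- rownames(embedding)

  set.seed(seed)
  if (!is.null(indices)) B <- length(indices)
  arr <- array(NA_real_, c(n, L, B),
               dimnames = list(cells, names(reference$lineages), NULL))
  recovered <- matrix(FALSE, B, L,
                      dimnames = list(NULL, names(reference$lineages)))
  valid <- logical(B)
  unmapped <- integer(B)

  ref_keys <- vapply(reference$lineages, paste, character(1), collapse = ">")
  ref_term <- vapply(reference$lineages, function(x) x[length(x)],
                     character(1))

  for (b in seq_len(B)) {
    idx <- if (is.null(indices)) sample.int(n, n, replace = TRUE)
           else indices[[b]]
    cl_b <- clusters[idx]
    if (!start_cluster %in% cl_b || length(unique(cl_b)) < 2) {
      valid[b] <- FALSE
      next
    }
    fit <- engine(embedding[idx, , drop = FALSE], cl_b, start_cluster)
    valid[b] <- TRUE
    first <- !duplicated(idx)
    ucells <- cells[idx[first]]
    for (bl in seq_along(fit$lineages)) {
      key <- paste(fit$lineages[[bl]], collapse = ">")
      ref_l <- if (match == "strict") base::match(key, ref_keys)
               else base::match(fit$lineages[[bl]][length(fit$lineages[[bl]])],
                                ref_term)
      if (is.na(ref_l)) {
        unmapped[b] <- unmapped[b] + 1L
        next
      }
      recovered[b, ref_l] <- TRUE
      arr[ucells, ref_l, b] <- fit$pseudotime[first, bl]
    }
  }
  structure(list(array = arr, recovered = recovered, valid = valid,
                 unmapped = unmapped, reference = reference, match = match),
            class = "bootstrap_pseudotime")
}

#' Branch support from a bootstrap pseudotime array
#'
#' Support of a reference lineage is the proportion of valid bootstrap
#' replicates in which a lineage with the same ordered cluster sequence
#' (or terminal cluster, under relaxed matching) was recovered.
#'
#' @param bp a \code{bootstrap_pseudotime} object.
#' @return named numeric vector of supports in [0, 1].
#' @export
branch_support <- function(bp) {
  stopifnot(inherits(bp, "bootstrap_pseudotime"))
  if (!any(bp$valid)) stop("no valid bootstrap replicates")
  colMeans(bp$recovered[bp$valid, , drop = FALSE])
}

#' Per-cell pseudotime medians and 95% confidence intervals
#'
#' Summarises the bootstrap distribution per (cell, lineage): median,
#' 2.5th and 97.5th percentiles over non-missing replicate values, and the
#' number of replicates used; cells observed in fewer than
#' \code{min_replicates} replicates are flagged low-confidence.
#'
#' @param bp a \code{bootstrap_pseudotime} object.
#' @param min_replicates flag threshold.
#' @return data.table: cell, lineage, median, ci_lo, ci_hi, n_replicates,
#'   low_confidence.
#' @export
pseudotime_summary <- function(bp, min_replicates = 20L) {
  stopifnot(inherits(bp, "bootstrap_pseudotime"))
  arr <- bp$array
  dims <- dim(arr)
  out <- data.table::rbindlist(lapply(seq_len(dims[2]), function(l) {
    vals <- arr[, l, , drop = FALSE]
    dim(vals) <- c(dims[1], dims[3])
    n_obs <- rowSums(!is.na(vals))
    med <- apply(vals, 1, stats::median, na.rm = TRUE)
    qs <- t(apply(vals, 1, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(c(NA_real_, NA_real_))
      stats::quantile(v, c(0.025, 0.975), names = FALSE)
    }))
    data.table::data.table(cell = rownames(arr),
                           lineage = colnames(arr)[l],
                           median = med, ci_lo = qs[, 1], ci_hi = qs[, 2],
                           n_replicates = n_obs,
                           low_confidence = n_obs < min_replicates)
  }))
  out[]
}
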