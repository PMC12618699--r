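test_that("peak-by-cell counting equals the brute-force overlap matrix", {
  f1 <- data.table::data.table(chrom = "chr1", start = 120L, end = 180L,
                               barcode = "c1")
  p1 <- data.table::data.table(chrom = "chr1", start = 100L, end = 300L)
  m <- build_peak_cell_matrix(f1, p1)
  expect_equal(as.matrix(m), matrix(1, 1, 1, dimnames = list("chr1:100-300",
                                                             "c1")))
  f2 <- data.table::data.table(chrom = "chr1", start = 400L, end = 450L,
                               barcode = "c1")
  expect_equal(sum(build_peak_cell_matrix(f2, p1)), 0)

  arch <- barcode_architecture()
  genome <- simulate_reference(seed = 401)
  cells <- simulate_cells(12, arch, seed = 402, fragments_per_cell = 90L)
  frags <- simulate_fragments(genome, cells, peak_frac = 0.5, seed = 403)
  fr <- data.table::data.table(chrom = frags$chrom, start = frags$start,
                               end = frags$end, barcode = frags$cell)
  m <- build_peak_cell_matrix(fr, genome$peaks)
  dense <- as.matrix(m)
  for (ci in colnames(dense)) {
    sub <- fr[barcode == ci]
    for (pi in sample(nrow(genome$peaks), 10)) {
      pk <- genome$peaks[pi]
      want <- sum(sub$chrom == pk$chrom & sub$start < pk$end &
                    sub$end > pk$start)
      expect_equal(dense[pi, ci], want)
    }
  }
  expect_warning(
    build_peak_cell_matrix(f1, rbind(p1, data.table::data.table(
      chrom = "chr1", start = 200L, end = 400L))),
    "overlap")
})

test_that("depth normalisation scales cells to 1e4 and is depth-invariant", {
  m <- Matrix::Matrix(c(10, 990, 20, 1980), 2, 2, sparse = TRUE,
                      dimnames = list(c("p1", "p2"), c("c1", "c2")))
  nm <- normalize_depth(m)
  expect_equal(nm[1, "c1"], 100)
  expect_equal(unname(nm[, "c1"]), unname(nm[, "c2"]))  # c2 = 2x depth of c1
  m0 <- cbind(m, c0 = c(0, 0))
  expect_warning(nm0 <- normalize_depth(m0), "zero-total")
  expect_equal(ncol(nm0), 2L)
})

test_that("pseudobulk replicates are seeded, sized and degenerate-safe", {
  sim <- simulate_peak_cell_counts(c(g1 = 600L), n_null = 40, n_planted = 0,
                                   seed = 410)
  nm <- normalize_depth(sim$mat)
  cells <- colnames(nm)
  pb1 <- make_pseudobulks(nm, cells, R = 4, n_cells = 100, seed = 5)
  pb2 <- make_pseudobulks(nm, cells, R = 4, n_cells = 100, seed = 5)
  expect_identical(pb1, pb2)
  expect_equal(dim(pb1), c(40L, 4L))
  expect_false(attr(pb1, "with_replacement"))

  # replicate means concentrate around the group mean
  gm <- Matrix::rowMeans(nm)
  expect_lt(max(abs(pb1 - gm) / gm), 0.5)

  # group exactly the sample size: every replicate is the full-group mean
  pb3 <- make_pseudobulks(nm, cells[1:100], R = 3, n_cells = 100, seed = 6)
  expect_equal(pb3[, 1], pb3[, 2])
  expect_warning(make_pseudobulks(nm, cells[1:50], R = 2, n_cells = 100,
                                  seed = 7), "replacement")
  expect_error(make_pseudobulks(nm, cells, R = 1, n_cells = 100, seed = 8),
               "two replicates")
  expect_error(make_pseudobulks(nm, character(), R = 5, n_cells = 100,
                                seed = 9), "empty")
})

test_that("planted differential peaks pass and the fold gate blocks sub-2x effects", {
  sim <- simulate_peak_cell_counts(c(groupA = 800L, groupB = 800L),
                                   n_null = 120, n_planted = 15, fold = 8,
                                   seed = 420)
  ga <- names(sim$labels)[sim$labels == "groupA"]
  gb <- names(sim$labels)[sim$labels == "groupB"]
  res <- condition_differential_peaks(sim$mat, ga, gb, R = 5,
                                      n_cells = 400, seed = 421)
  expect_gte(mean(res$pass[sim$planted]), 0.9)
  expect_true(all(res$direction[sim$planted] == "A"))
  expect_lte(mean(res$pass[-sim$planted]), 0.05)

  # constant peaks get p = 1; q is the BH step-up of p over peaks
  pbA <- matrix(c(rep(1, 5), stats::rnorm(45, 10)), 10, 5, byrow = TRUE)
  pbB <- matrix(c(rep(1, 5), stats::rnorm(45, 5)), 10, 5, byrow = TRUE)
  wr <- scSplitPool:::welch_rows_test(pbA, pbB)
  expect_equal(wr$p[1], 1)
  expect_equal(wr$q, oracle_bh(wr$p))

  # strong separation at fold 1.9 is significant but fails the fold gate
  pbA <- matrix(stats::rnorm(40, 19, 0.01), 2, 20, byrow = TRUE)
  pbB <- matrix(stats::rnorm(40, 10, 0.01), 2, 20, byrow = TRUE)
  wr <- scSplitPool:::welch_rows_test(pbA, pbB)
  expect_true(all(wr$q < 0.05))
  expect_true(all(!wr$pass))
  expect_true(all(wr$fold < 2))
})

test_that("label permutation keeps the pass rate at the nominal level", {
  sim <- simulate_peak_cell_counts(c(groupA = 500L, groupB = 500L),
                                   n_null = 150, n_planted = 0, seed = 430)
  nm <- normalize_depth(sim$mat)
  cells <- colnames(nm)
  set.seed(431)
  rate <- vapply(1:40, function(i) {
    perm <- sample(cells)
    ga <- perm[1:500]; gb <- perm[501:1000]
    res <- condition_differential_peaks(nm, ga, gb, R = 5, n_cells = 400,
                                        seed = 1000 + i, normalize = FALSE)
    mean(res$pass)
  }, numeric(1))
  se <- stats::sd(rate) / sqrt(length(rate))
  expect_lte(mean(rate), 0.05 + 3 * max(se, 1e-3))
})

test_that("one-vs-rest sets are exclusive across cell types", {
  # 4 cell types; peak 1 boosted in A and B, peak 2 only in A
  set.seed(440)
  n_per <- 250L; npeak <- 60L
  types <- rep(c("A", "B", "C", "D"), each = n_per)
  bcs <- sprintf("cell%04d", seq_along(types))
  names(types) <- bcs
  lam <- matrix(1, npeak, length(types))
  lam[1, types %in% c("A", "B")] <- 10
  lam[2, types == "A"] <- 10
  counts <- matrix(stats::rpois(length(lam), lam), npeak,
                   dimnames = list(sprintf("peak%02d", 1:npeak), bcs))
  res <- celltype_specific_peaks(Matrix::Matrix(counts, sparse = TRUE),
                                 types, R = 5, n_cells = 200, seed = 441)
  expect_true("peak01" %in% res$excluded)
  expect_false("peak01" %in% unlist(res$specific))
  expect_true("peak02" %in% res$specific$A)
  expect_false("peak02" %in% res$specific$B)
  # final sets are pairwise disjoint by construction
  all_final <- unlist(res$specific)
  expect_equal(anyDuplicated(all_final), 0L)
  expect_error(celltype_specific_peaks(counts, types[types == "A"],
                                       seed = 1), "two cell types")
})
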