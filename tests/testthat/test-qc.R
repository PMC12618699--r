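test_that("FRiT follows the oriented -1000..+200 window with half-open edges", {
  tss <- data.table::data.table(chrom = "chr1", start = 10000L,
                                end = 10001L, strand = "+")
  frag <- function(start, end, bc = "A")
    data.table::data.table(chrom = "chr1", start = start, end = end,
                           barcode = bc)
  # 3 of 10 fragments overlap the window [9000, 10200)
  f <- rbind(frag(9100L, 9150L), frag(9999L, 10050L), frag(10199L, 10260L),
             frag(10200L, 10290L),           # starts at the open end: out
             frag(8900L, 9000L),             # ends at the closed start: out
             frag(20000L + 100L * (1:5), 20040L + 100L * (1:5)))
  res <- frit(f, tss)
  expect_equal(res$frit, 30)
  expect_equal(res$n_in_tss, 3L)

  # minus strand: window lies upstream to the right
  tss_m <- data.table::data.table(chrom = "chr1", start = 10000L,
                                  end = 10001L, strand = "-")
  f2 <- rbind(frag(10500L, 10550L),          # inside [9801, 11001)
              frag(9500L, 9550L))            # outside on the minus strand
  res2 <- frit(f2, tss_m)
  expect_equal(res2$frit, 50)
  expect_error(frit(f, tss[0]), "empty")
})

test_that("FRiT and FRiP agree with the quadratic overlap oracle", {
  arch <- barcode_architecture()
  genome <- simulate_reference(seed = 301)
  cells <- simulate_cells(10, arch, seed = 302, fragments_per_cell = 100L)
  frags <- simulate_fragments(genome, cells, tss_frac = 0.25,
                              peak_frac = 0.25, seed = 303)
  fr <- data.table::data.table(chrom = frags$chrom, start = frags$start,
                               end = frags$end, barcode = frags$cell)
  w <- scSplitPool:::tss_windows(genome$tss)
  in_tss <- oracle_overlap_any(as.data.frame(fr), w)
  in_peak <- oracle_overlap_any(as.data.frame(fr), genome$peaks)
  want_frit <- tapply(in_tss, fr$barcode, function(x) 100 * mean(x))
  want_frip <- tapply(in_peak, fr$barcode, function(x) 100 * mean(x))
  got_frit <- frit(fr, genome$tss)
  got_frip <- frip(fr, genome$peaks)
  expect_equal(got_frit$frit, as.vector(want_frit[got_frit$barcode]))
  expect_equal(got_frip$frip, as.vector(want_frip[got_frip$barcode]))
  # planted fractions recovered
  expect_true(all(abs(got_frit$frit - 25) <= 1))
  expect_true(all(abs(got_frip$frip - 25) <= 1))
})

test_that("the TSS profile is flat at fold 1 under uniform coverage", {
  genome <- simulate_reference(seed = 311, n_tss = 5, n_peaks = 5)
  # tile chr1 completely with abutting fragments: coverage exactly 1
  starts <- seq(0L, genome$chrom_lengths[["chr1"]] - 100L, by = 100L)
  f <- data.table::data.table(chrom = "chr1", start = starts,
                              end = starts + 100L, barcode = "A")
  tss1 <- genome$tss[chrom == "chr1"]
  pr <- tss_profile(f, tss1)
  expect_equal(nrow(pr$bins), 600L)
  expect_false(pr$flagged)
  expect_true(all(abs(pr$bins$fold - 1) < 1e-9))
  expect_equal(pr$score, 1)
})

test_that("planted promoter enrichment appears as the center-bin fold", {
  genome <- simulate_reference(seed = 321, n_tss = 4, n_peaks = 4)
  tss1 <- genome$tss[chrom == "chr1"]
  starts <- seq(0L, genome$chrom_lengths[["chr1"]] - 100L, by = 100L)
  base <- data.table::data.table(chrom = "chr1", start = starts,
                                 end = starts + 100L, barcode = "A")
  extra <- data.table::rbindlist(lapply(seq_len(nrow(tss1)), function(i)
    data.table::data.table(chrom = "chr1",
                           start = rep(tss1$start[i] - 50L, 4L),
                           end = rep(tss1$start[i] + 50L, 4L),
                           barcode = "A")))
  pr <- tss_profile(rbind(base, extra), tss1)
  expect_equal(pr$score, 5, tolerance = 0.05)
  expect_lt(max(pr$bins$fold[abs(pr$bins$center) > 500]), 1.5)

  empty <- base[0]
  pr0 <- tss_profile(empty, tss1)
  expect_true(pr0$flagged)
  expect_true(is.na(pr0$score))
  expect_true(all(pr0$bins$mean_coverage == 0))
})

test_that("fragment-length bands summarise the histogram mass", {
  f <- data.table::data.table(chrom = "chr1", start = 0L, end = 80L,
                              barcode = "A")[rep(1, 50)]
  h <- fragment_length_hist(f)
  expect_equal(unname(h$bands), c(100, 100, 100))
  expect_equal(sum(h$hist$count), 50L)

  arch <- barcode_architecture()
  genome <- simulate_reference(seed = 331)
  cells <- simulate_cells(5, arch, seed = 332, fragments_per_cell = 400L)
  fr <- simulate_fragments(genome, cells, seed = 333)
  h2 <- fragment_length_hist(data.table::data.table(
    chrom = fr$chrom, start = fr$start, end = fr$end, barcode = fr$cell))
  expect_gte(h2$bands[["b300"]], 90)
  h3 <- fragment_length_hist(f[0])
  expect_equal(nrow(h3$hist), 0L)
  expect_true(all(is.na(h3$bands)))
})

test_that("cell filters apply the preset thresholds strictly", {
  q <- data.table::data.table(
    barcode = c("a", "b", "c", "d"),
    frit = c(10.1, 10.0, 7.5, 12),
    unique_fragments = c(1501L, 1501L, 1000L, 1500L))
  expect_equal(filter_cells(q, "mouse"), "a")
  expect_equal(filter_cells(q, "human"), c("a", "b", "d"))
  q$tss_score <- c(4, 3.9, 5, 4)
  # non-strict >= on both axes for this variant: d (score 4, 1500) passes
  expect_equal(filter_cells(q, "tss_score"), c("a", "d"))
  expect_equal(filter_cells(q, "custom", min_frit = 7, min_fragments = 1400),
               c("a", "b", "d"))
  expect_error(filter_cells(q[, .(barcode, frit)], "mouse"), "lacks")
})

test_that("raising any filter threshold never adds cells", {
  set.seed(341)
  q <- data.table::data.table(
    barcode = sprintf("c%03d", 1:200),
    frit = stats::runif(200, 0, 25),
    unique_fragments = as.integer(stats::runif(200, 0, 4000)))
  for (i in 1:20) {
    f1 <- stats::runif(1, 0, 15); f2 <- f1 + stats::runif(1, 0, 5)
    n1 <- stats::runif(1, 0, 2500); n2 <- n1 + stats::runif(1, 0, 1000)
    keep_loose <- filter_cells(q, "custom", min_frit = f1,
                               min_fragments = n1)
    keep_tight <- filter_cells(q, "custom", min_frit = f2,
                               min_fragments = n2)
    expect_true(all(keep_tight %in% keep_loose))
  }
})

test_that("a fixture with planted passing cells is recovered exactly", {
  set.seed(351)
  pass <- data.table::data.table(
    barcode = sprintf("pass%03d", 1:120),
    frit = stats::runif(120, 10.5, 30),
    unique_fragments = as.integer(stats::runif(120, 1600, 5000)))
  fail_frit <- data.table::data.table(
    barcode = sprintf("lofrit%03d", 1:40),
    frit = stats::runif(40, 0, 9.5),
    unique_fragments = as.integer(stats::runif(40, 1600, 5000)))
  fail_count <- data.table::data.table(
    barcode = sprintf("locount%03d", 1:40),
    frit = stats::runif(40, 10.5, 30),
    unique_fragments = as.integer(stats::runif(40, 100, 1400)))
  q <- rbind(pass, fail_frit, fail_count)
  kept <- filter_cells(q, "mouse")
  expect_setequal(kept, pass$barcode)
  expect_length(kept, 120L)
})

test_that("cell_qc assembles counts, duplication and in-window rates", {
  arch <- barcode_architecture()
  genome <- simulate_reference(seed = 361)
  cells <- simulate_cells(8, arch, seed = 362, fragments_per_cell = 80L)
  frags <- simulate_fragments(genome, cells, dup_model = dup_model(2, 1.5),
                              tss_frac = 0.3, seed = 363)
  dd <- dedup_fragments(simulate_aligned_pairs(frags, seed = 364))
  qc <- cell_qc(dd$fragments, genome$tss, genome$peaks)
  expect_setequal(qc$barcode, cells$cell)
  expect_true(all(qc$unique_fragments == 80L))
  expect_true(all(qc$dup_rate >= 0 & qc$dup_rate <= 100))
  expect_true(all(abs(qc$frit - 30) <= 1))
  expect_true(all(c("frit", "frip") %in% names(qc)))
})
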