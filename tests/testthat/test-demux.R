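arch <- barcode_architecture()

test_that("anchor search finds the linker and honours the mismatch bound", {
  set.seed(7)
  mk <- function(offset, n_mut = 0) {
    linker <- arch$linker_anchor
    if (n_mut > 0) linker <- mutate_at(linker, sample(17, n_mut))
    paste0(random_dna(1, offset), linker, random_dna(1, 120 - offset - 17))
  }
  r2 <- mk(28)
  expect_equal(find_anchor(r2, arch), list(offset = 28L, mismatches = 0L))
  for (i in 1:20) {
    off <- sample(20:35, 1)
    nm <- sample(0:3, 1)
    r2 <- mk(off, nm)
    got <- find_anchor(r2, arch)
    want <- oracle_find_anchor(r2, arch$linker_anchor, arch$anchor_window)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$offset, want$offset)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
  # four substitutions anywhere exceed the tolerance
  for (i in 1:10) {
    r2 <- mk(sample(20:35, 1), 4)
    want <- oracle_find_anchor(r2, arch$linker_anchor, arch$anchor_window)
    # (a chance sub-4 match elsewhere is possible in principle; oracle decides)
    expect_identical(is.null(find_anchor(r2, arch)), is.null(want))
  }
  expect_null(find_anchor(random_dna(1, 30), arch))   # too short to cover window
})

test_that("barcode matching is exact-7 first, then unique last-5 rescue", {
  wl <- arch$round_whitelists[[1]]
  expect_equal(match_barcode(wl[10], wl), list(id = 10L, tier = "full7"))
  mutated <- paste0("NN", substr(wl[25], 3, 7))
  expect_equal(match_barcode(mutated, wl), list(id = 25L, tier = "last5"))
  # a suffix absent from the whitelist matches nothing
  suffixes <- substr(wl, 3, 7)
  novel <- "AAAAAAA"
  while (substr(novel, 3, 7) %in% suffixes)
    novel <- random_dna(1, 7)
  expect_null(match_barcode(novel, wl))
  # non-conforming whitelist: duplicated suffix is ambiguous
  bad_wl <- c("AACGTAC", "CCCGTAC", "GGTTTTT")
  expect_null(match_barcode("TTCGTAC", bad_wl))
  expect_equal(match_barcode("TTTTTTT", bad_wl)$id, 3L)
})

test_that("error-free simulated pairs decode to the correct cells", {
  batch <- make_read_batch(25, 20, seed = 50)
  res <- scSplitPool:::decode_pairs(batch$reads$r1, batch$reads$r2,
                                    batch$reads$id, arch, ml = 17)
  expect_true(all(res$status == "ok"))
  expect_identical(res$cell_key, unname(truth_keys(batch)[res$read_id]))
  expect_true(all(res$anchor_mm == 0))
  expect_true(all(res$r2_len <= 50))
  expect_true(all(res$tier1 == "full7"))
})

test_that("up to three linker mismatches leave assignment unchanged; four reject", {
  batch <- make_read_batch(10, 10, seed = 60)
  r2 <- batch$reads$r2
  anchor0 <- batch$reads$truth$bc2_start + 7L   # 0-based linker start
  set.seed(61)
  r2_3 <- vapply(seq_along(r2), function(i)
    mutate_at(r2[i], anchor0[i] + sample(17, 3)), character(1))
  r2_4 <- vapply(seq_along(r2), function(i)
    mutate_at(r2[i], anchor0[i] + sample(17, 4)), character(1))
  clean <- scSplitPool:::decode_pairs(batch$reads$r1, r2, batch$reads$id,
                                      arch, ml = 17)
  m3 <- scSplitPool:::decode_pairs(batch$reads$r1, r2_3, batch$reads$id,
                                   arch, ml = 17)
  m4 <- scSplitPool:::decode_pairs(batch$reads$r1, r2_4, batch$reads$id,
                                   arch, ml = 17)
  expect_identical(m3$cell_key, clean$cell_key)
  expect_true(all(m3$anchor_mm == 3))
  expect_true(all(m4$status == "rejected"))
  expect_true(all(m4$reason == "no_anchor"))
})

test_that("decoder equals the brute-force oracle field for field", {
  batch <- make_read_batch(30, 12, seed = 70,
                           error_rate = c(barcode = 0.05, genomic = 0.02))
  n_sim <- min(800, length(batch$reads$r1))
  r1 <- c(batch$reads$r1[seq_len(n_sim)], random_dna(100, 91))
  set.seed(71)
  r2 <- c(batch$reads$r2[seq_len(n_sim)], random_dna(100, 140))
  ids <- sprintf("r%04d", seq_along(r1))
  res <- scSplitPool:::decode_pairs(r1, r2, ids, arch, ml = 17)
  for (i in seq_along(r1)) {
    want <- oracle_decode(r1[i], r2[i], arch, ml = 17)
    expect_identical(res$status[i], want$status)
    expect_identical(res$reason[i], want$reason)
    if (want$status == "ok") {
      expect_identical(res$anchor_offset[i], as.integer(want$anchor_offset))
      expect_identical(res$anchor_mm[i], as.integer(want$anchor_mm))
      expect_identical(
        list(res$bc1[i], res$bc2[i], res$bc3[i], res$tn5[i]),
        list(as.integer(want$bc1), as.integer(want$bc2),
             as.integer(want$bc3), as.integer(want$tn5)))
      expect_identical(
        c(res$tier1[i], res$tier2[i], res$tier3[i]),
        c(want$tier1, want$tier2, want$tier3))
      expect_identical(res$r1_trim[i], want$r1_trim)
      expect_identical(res$r2_trim[i], want$r2_trim)
    }
  }
  # conservation: every read is decoded or rejected, never both
  expect_equal(sum(res$status == "ok") + sum(res$status == "rejected"),
               length(r1))
})

test_that("demux_fastq writes per-index files whose headers reproduce assignments", {
  batch <- make_read_batch(12, 10, seed = 80)
  dir <- withr::local_tempdir()
  paths <- write_reads(batch$reads, dir)
  out <- file.path(dir, "demux")
  rep <- demux_fastq(paths[["r1"]], paths[["r2"]], arch, ml = 17,
                     out_dir = out)
  expect_equal(rep$decode_rate, 100)
  expect_equal(rep$total, length(batch$reads$r1))
  keys <- truth_keys(batch)
  fq <- list.files(out, pattern = "_R1\\.fastq\\.gz$", full.names = TRUE)
  expect_gt(length(fq), 0)
  seen <- 0L
  for (f in fq) {
    x <- Biostrings::readDNAStringSet(f, format = "fastq")
    hdr <- strsplit(names(x), "|", fixed = TRUE)
    for (h in hdr) {
      expect_identical(h[2], unname(keys[h[1]]))
      seen <- seen + 1L
    }
  }
  expect_equal(seen, rep$decoded)
  expect_true(file.exists(file.path(out, "demux_report.json")))
})

test_that("demultiplexing an empty run yields an empty zero-count report", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "R1.fastq"); p2 <- file.path(dir, "R2.fastq")
  file.create(p1); file.create(p2)
  rep <- demux_fastq(p1, p2, arch, out_dir = file.path(dir, "out"))
  expect_equal(rep$total, 0L)
  expect_equal(rep$decoded, 0L)
  expect_equal(rep$decode_rate, 0)
})

test_that("mismatched R1/R2 record counts are fatal", {
  batch <- make_read_batch(5, 5, seed = 90)
  dir <- withr::local_tempdir()
  paths <- write_reads(batch$reads, dir)
  short <- batch$reads
  short$id <- short$id[-1]; short$r1 <- short$r1[-1]; short$r2 <- short$r2[-1]
  short$truth <- short$truth[-1]
  write_reads(short, file.path(dir, "b"))
  expect_error(demux_fastq(paths[["r1"]],
                           file.path(dir, "b", "R2.fastq.gz"), arch),
               "differ")
})

test_that("the ml gate is monotone and recovers planted short-fragment truth", {
  # 20% of molecules shorter than 30 nt, the rest comfortably long
  lengths_pool <- c(20:29, 60:100)
  sampler <- function(n) sample(lengths_pool, n, replace = TRUE,
                                prob = c(rep(0.02, 10), rep(0.8 / 41, 41)))
  batch <- make_read_batch(20, 25, seed = 100,
                           frag_len = frag_model("custom", sampler = sampler))
  dir <- withr::local_tempdir()
  paths <- write_reads(batch$reads, dir)
  sw <- ml_sweep(paths[["r1"]], paths[["r2"]], arch,
                 ml_values = c(14, 17, 30, 50))
  expect_true(all(diff(sw$decoded_reads) <= 0))
  truth_len <- batch$reads$truth$molecule_len
  for (i in seq_len(nrow(sw)))
    expect_equal(sw$decoded_reads[i],
                 sum(pmin(truth_len, 50) >= sw$ml[i]))
  expect_equal(sw$retained_fraction,
               sw$decoded_reads / length(truth_len))
  expect_error(ml_sweep(paths[["r1"]], paths[["r2"]], arch,
                        ml_values = c(0, 17)), "positive")
})
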