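# Independent brute-force oracles. Deliberately naive (character loops,
# quadratic scans) and kept free of any code path they are used to check.

oracle_hamming <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  sum(sa != sb)
}

# Exhaustive sliding-window anchor scan: leftmost offset of minimal
# distance, NULL when min distance > max_mm or read too short.
oracle_find_anchor <- function(r2, linker, window, max_mm = 3) {
  k <- nchar(linker)
  if (nchar(r2) < window[2] + k) return(list(too_short = TRUE))
  offs <- window[1]:window[2]
  dists <- vapply(offs, function(o)
    oracle_hamming(substr(r2, o + 1, o + k), linker), numeric(1))
  best <- which.min(dists)
  if (dists[best] > max_mm) return(NULL)
  list(offset = offs[best], mismatches = dists[best], too_short = FALSE)
}

# Linear whitelist scan with last-5 rescue
oracle_match_barcode <- function(obs, whitelist) {
  for (i in seq_along(whitelist))
    if (obs == whitelist[i]) return(list(id = i, tier = "full7"))
  hits <- integer()
  for (i in seq_along(whitelist))
    if (substr(obs, 3, 7) == substr(whitelist[i], 3, 7)) hits <- c(hits, i)
  if (length(hits) == 1) return(list(id = hits, tier = "last5"))
  NULL
}

# Rightmost full-length adapter occurrence with <= 1 mismatch
oracle_trim <- function(seq, adapter) {
  k <- nchar(adapter)
  L <- nchar(seq)
  if (L >= k) {
    for (p in (L - k + 1):1) {
      if (oracle_hamming(substr(seq, p, p + k - 1), adapter) <= 1)
        return(substr(seq, 1, p - 1))
    }
  }
  seq
}

# Full brute-force decoder for one read pair; mirrors the published
# algorithm from first principles.
oracle_decode <- function(r1, r2, arch, ml = 17) {
  rej <- function(reason) list(status = "rejected", reason = reason)
  hit <- oracle_find_anchor(r2, arch$linker_anchor, arch$anchor_window)
  if (is.null(hit)) return(rej("no_anchor"))
  if (isTRUE(hit$too_short)) return(rej("too_short"))
  a <- hit$offset + 1
  m1 <- oracle_match_barcode(substr(r2, 1, 7), arch$round_whitelists[[1]])
  m2 <- oracle_match_barcode(substr(r2, a - 7, a - 1),
                             arch$round_whitelists[[2]])
  m3 <- oracle_match_barcode(substr(r2, a + 17, a + 23),
                             arch$round_whitelists[[3]])
  trel <- 17 + 7 + arch$spacer2_len
  tn5 <- match(substr(r2, a + trel, a + trel + 2), arch$tn5_indexes)
  if (is.null(m1) || is.null(m2) || is.null(m3) || is.na(tn5))
    return(rej("bad_barcode"))
  rc_me <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(arch$me_sequence)))
  g2 <- substr(r2, nchar(r2) - arch$r2_genomic_len + 1, nchar(r2))
  g1 <- substr(r1, 1, arch$r1_truncate_to)
  t2 <- oracle_trim(g2, rc_me)
  t1 <- oracle_trim(g1, rc_me)
  if (min(nchar(t1), nchar(t2)) < ml) return(rej("too_short"))
  list(status = "ok", reason = NA_character_,
       anchor_offset = hit$offset, anchor_mm = hit$mismatches,
       bc1 = m1$id, bc2 = m2$id, bc3 = m3$id, tn5 = tn5,
       tier1 = m1$tier, tier2 = m2$tier, tier3 = m3$tier,
       r1_trim = t1, r2_trim = t2)
}

# Quadratic interval-overlap oracle (0-based half-open)
oracle_overlap_any <- function(frag, intervals) {
  vapply(seq_len(nrow(frag)), function(i) {
    any(intervals$chrom == frag$chrom[i] &
          intervals$start < frag$end[i] &
          intervals$end > frag$start[i])
  }, logical(1))
}

# Hash-grouping dedup oracle
oracle_dedup <- function(pairs, mode = "pcr_and_linear") {
  key <- if (mode == "pcr_only")
    paste(pairs$cell, pairs$chrom, pairs$start, pairs$end, pairs$strand)
  else
    paste(pairs$cell, pairs$chrom, pairs$strand,
          ifelse(pairs$strand == "+", pairs$start, pairs$end))
  split_idx <- split(seq_len(nrow(pairs)), key)
  do.call(rbind, lapply(split_idx, function(ii) {
    data.frame(cell = pairs$cell[ii[1]], chrom = pairs$chrom[ii[1]],
               start = min(pairs$start[ii]), end = max(pairs$end[ii]),
               strand = pairs$strand[ii[1]], support = length(ii))
  }))
}

# Benjamini-Hochberg step-up oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Expected collision quantities by exhaustive enumeration of all D^N
# equally likely assignments (tiny N, D only)
oracle_collision_enum <- function(N, D) {
  grids <- rep(list(seq_len(D)), N)
  combos <- as.matrix(expand.grid(grids))
  distinct <- apply(combos, 1, function(x) length(unique(x)))
  # cells losing uniqueness in the birthday-paradox sense: N - #distinct
  list(expected_unique = mean(distinct),
       collision_rate = 100 * mean(N - distinct) / N)
}
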