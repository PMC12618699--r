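#' Combinatorial barcode space
#'
#' Total number of distinct cell barcodes available from one Tn5 index set
#' and the split-pool ligation rounds: \code{n_tn5 * prod(rounds)}. The
#' standard configuration (64 Tn5 indexes, three rounds of 96 barcodes)
#' yields 56,623,104 combinations per run.
#'
#' @param n_tn5 number of Tn5 sample indexes.
#' @param rounds integer vector of per-round whitelist sizes.
#' @return total number of barcode combinations (numeric, exact for the
#'   magnitudes involved).
#' @examples
#' total_barcode_space(64, c(96, 96, 96))
#' @export
total_barcode_space <- function(n_tn5, rounds) {
  n_tn5 <- as.numeric(n_tn5)
  rounds <- as.numeric(rounds)
  if (length(n_tn5) != 1L || !is.finite(n_tn5) || n_tn5 < 1 ||
      n_tn5 != floor(n_tn5))
    stop("n_tn5 must be a positive integer count")
  if (length(rounds) < 1L || any(!is.finite(rounds) | rounds < 1 |
                                 rounds != floor(rounds)))
    stop("rounds must be positive integer counts")
  n_tn5 * prod(rounds)
}

#' Expected number of distinct barcodes drawn by N cells
#'
#' When N cells independently pick one of D equally likely barcode
#' combinations, the expected number of distinct combinations used is
#' \eqn{D (1 - ((D-1)/D)^N)}. This is the intermediate quantity behind the
#' birthday-paradox collision rate.
#'
#' @param N number of cells (>= 0).
#' @param D number of barcode combinations in the sub-library (>= 1).
#' @return expected count of distinct barcodes, in \code{[0, min(N, D)]}.
#' @export
expected_unique_barcodes <- function(N, D) {
  N <- as.numeric(N); D <- as.numeric(D)
  if (length(D) != 1L || !is.finite(D) || D < 1)
    stop("D must be a count >= 1")
  if (any(!is.finite(N) | N < 0))
    stop("N must be a count >= 0")
  # ((D-1)/D)^N in log space: exp(N * log1p(-1/D)) is stable for large N, D
  D * (1 - exp(N * log1p(-1 / D)))
}

#' Birthday-paradox barcode collision rate
#'
#' Expected percentage of cells that do not receive a unique barcode
#' combination when \code{N} cells draw uniformly from \code{D}
#' combinations:
#' \deqn{100 \times \frac{N - D + D((D-1)/D)^N}{N}.}
#' Note this is the expected fraction of cells losing uniqueness (an
#' expectation over cells), not the probability of observing at least one
#' collision. With a sub-library of \eqn{D = 96^3} combinations and
#' \eqn{N = 50{,}000} input cells the rate is 2.77\%.
#'
#' @param N number of cells (>= 1). Vectorised.
#' @param D number of barcode combinations in the sub-library (>= 1).
#' @return collision rate in percent, clamped to \code{[0, 100]}.
#' @examples
#' round(collision_rate(50000, 96^3), 2)  # 2.77
#' @export
collision_rate <- function(N, D) {
  N <- as.numeric(N); D <- as.numeric(D)
  if (length(D) != 1L || !is.finite(D) || D < 1)
    stop("D must be a count >= 1")
  if (any(!is.finite(N) | N < 1))
    stop("N must be a count >= 1")
  rate <- 100 * (N - expected_unique_barcodes(N, D)) / N
  pmin(100, pmax(0, rate))
}
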