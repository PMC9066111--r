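# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges <- function(df) {
  GenomicRanges::GRanges(as.character(df$chrom),
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Count interval overlaps
#'
#' For each interval in `a`, the number of intervals in `b` overlapping it by
#' at least 1 bp (0-based half-open coordinates on both sides).
#'
#' @param a,b interval data.frames with `chrom`, `start`, `end`.
#' @return integer vector of length `nrow(a)`.
#' @export
overlap_counts <- function(a, b) {
  if (nrow(a) == 0L) return(integer(0))
  if (nrow(b) == 0L) return(integer(nrow(a)))
  GenomicRanges::countOverlaps(as_granges(a), as_granges(b))
}

# index of the b-interval containing each point (chrom, pos in 0-based bp), NA if none
point_in_interval <- function(chrom, pos, b) {
  if (length(chrom) == 0L) return(integer(0))
  q <- GenomicRanges::GRanges(as.character(chrom), IRanges::IRanges(pos + 1L, pos + 1L))
  hit <- GenomicRanges::findOverlaps(q, as_granges(b), select = "first")
  as.integer(hit)
}

#' Vectorised exact two-sided binomial test
#'
#' Exact two-sided binomial p-values for many (x, n) observations sharing one
#' null proportion, using the same minimum-likelihood two-sided rule as
#' [stats::binom.test()]: the p-value sums `P(K = k)` over all outcomes `k`
#' whose point probability does not exceed that of the observed `x` (up to a
#' relative tolerance of 1e-7). Observations are grouped by `n` so the
#' binomial density for each distinct trial count is computed once, which
#' makes the test usable over hundreds of thousands of bin pairs or windows.
#'
#' @param x integer vector of successes.
#' @param n integer vector of trials (same length as `x`).
#' @param p0 null success probability (scalar).
#' @return numeric vector of two-sided p-values.
#' @export
binom_test_vec <- function(x, n, p0) {
  stopifnot(length(x) == length(n), p0 > 0, p0 < 1)
  p <- numeric(length(x))
  rel <- 1 + 1e-07
  for (nn in unique(n)) {
    idx <- which(n == nn)
    d <- dbinom(0:nn, nn, p0)
    o <- order(d)
    ds <- d[o]
    dc <- cumsum(ds)
    pos <- findInterval(d[x[idx] + 1L] * rel, ds)
    p[idx] <- dc[pmax(pos, 1L)]
  }
  pmin(p, 1)
}

stop_named <- function(stage, msg) stop(sprintf("[%s] %s", stage, msg), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
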