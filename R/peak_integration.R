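#' Annotate peaks by distance to the nearest TSS
#'
#' Each peak is anchored at its summit (midpoint when the narrowPeak summit
#' offset is -1) and assigned the signed distance to the nearest TSS, with
#' the sign following gene strand (negative = upstream of the TSS). Classes:
#' `promoter` when `|d| <= promoter_bp`, `proximal` when
#' `promoter_bp < |d| <= proximal_bp`, `distal` otherwise. Peaks on
#' chromosomes absent from the gene model are classed distal with a warning.
#'
#' @param peaks narrowPeak data.frame.
#' @param genes gene model with `chrom`, `start`, `end`, `strand` (non-empty).
#' @param promoter_bp promoter cutoff (default 2000).
#' @param proximal_bp proximal cutoff (default 10000).
#' @return object of class `annotation_table`: data.frame with `name`,
#'   `chrom`, `summit`, `tss_distance`, `class`; class fractions in the
#'   `fractions` attribute.
#' @export
annotate_peaks <- function(peaks, genes, promoter_bp = 2000L,
                           proximal_bp = 10000L) {
  stopifnot(nrow(genes) > 0L, promoter_bp < proximal_bp)
  s <- peak_summit(peaks)
  d <- rep(NA_real_, nrow(peaks))
  tss <- gene_tss(genes)
  for (ch in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0L) {
      warning(sprintf("chromosome %s absent from gene model; peaks classed distal", ch))
      next
    }
    dd <- outer(s[pk], tss[gi], "-")
    nearest <- apply(abs(dd), 1, which.min)
    raw <- dd[cbind(seq_along(pk), nearest)]
    d[pk] <- ifelse(genes$strand[gi][nearest] == "+", raw, -raw)
  }
  cls <- ifelse(is.na(d), "distal",
                ifelse(abs(d) <= promoter_bp, "promoter",
                       ifelse(abs(d) <= proximal_bp, "proximal", "distal")))
  out <- data.frame(name = peaks$name, chrom = peaks$chrom, summit = s,
                    tss_distance = d, class = cls, stringsAsFactors = FALSE)
  lv <- c("promoter", "proximal", "distal")
  attr(out, "fractions") <- vapply(lv, function(l) mean(cls == l), numeric(1))
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Peak enrichment profile around TAD boundaries
#'
#' Counts peak summits per `step_bp` bin across +/- `span_bp` around each
#' boundary midpoint, averaged over boundaries (counts divided by the number
#' of boundaries used). Boundaries whose window would be truncated by a
#' chromosome edge are excluded.
#'
#' @param peaks narrowPeak data.frame.
#' @param tads a `tad_set` with boundary regions.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param span_bp half-window (default 5e5).
#' @param step_bp bin width (default 25000).
#' @return data.frame with `offset_start`, `offset_end` (bp relative to the
#'   boundary midpoint) and `count_per_boundary`; attributes `n_boundaries`
#'   and `n_peaks_counted`.
#' @export
boundary_enrichment_profile <- function(peaks, tads, chrom_lengths,
                                        span_bp = 500000L, step_bp = 25000L) {
  bd <- tads$boundaries[tads$boundaries$kind == "boundary", , drop = FALSE]
  if (nrow(bd) == 0L) stop_named("peaks", "no boundaries to profile")
  stopifnot((2L * span_bp) %% step_bp == 0)
  nb <- as.integer(2L * span_bp %/% step_bp)
  mids <- (bd$start + bd$end) %/% 2L
  keep <- mids - span_bp >= 0 & mids + span_bp <= chrom_lengths[bd$chrom]
  bd <- bd[keep, , drop = FALSE]; mids <- mids[keep]
  if (nrow(bd) == 0L) stop_named("peaks", "all boundaries truncated by chromosome edges")
  s <- peak_summit(peaks)
  counts <- integer(nb)
  used <- 0L
  for (k in seq_len(nrow(bd))) {
    off <- s[peaks$chrom == bd$chrom[k]] - mids[k]
    off <- off[off >= -span_bp & off < span_bp]
    if (length(off)) {
      idx <- floor((off + span_bp) / step_bp) + 1L
      tb <- tabulate(idx, nb)
      counts <- counts + tb
      used <- used + sum(tb)
    }
  }
  out <- data.frame(offset_start = seq(-span_bp, span_bp - step_bp, by = step_bp),
                    offset_end = seq(-span_bp + step_bp, span_bp, by = step_bp),
                    count_per_boundary = counts / nrow(bd))
  attr(out, "n_boundaries") <- nrow(bd)
  attr(out, "n_peaks_counted") <- used
  out
}

#' Peak / boundary overlap fractions
#'
#' The >= 1 bp overlap rule applied in both directions: the fraction of
#' peaks located at boundary regions, and the fraction of boundaries bound
#' by at least one peak.
#'
#' @param peaks narrowPeak data.frame.
#' @param tads a `tad_set`.
#' @return named numeric: `n_peaks`, `n_boundaries`, `peaks_at_boundaries`,
#'   `boundaries_bound`, `fraction_peaks`, `fraction_boundaries`.
#' @export
peaks_at_boundaries <- function(peaks, tads) {
  bd <- tads$boundaries[tads$boundaries$kind == "boundary", , drop = FALSE]
  pk <- sum(overlap_counts(peaks, bd) >= 1L)
  bb <- sum(overlap_counts(bd, peaks) >= 1L)
  c(n_peaks = nrow(peaks), n_boundaries = nrow(bd),
    peaks_at_boundaries = pk, boundaries_bound = bb,
    fraction_peaks = if (nrow(peaks)) pk / nrow(peaks) else 0,
    fraction_boundaries = if (nrow(bd)) bb / nrow(bd) else 0)
}

#' Anchor-centred signal matrix
#'
#' For each anchor interval, the mean bedGraph signal (per-bp, piecewise
#' constant, 0 where uncovered) per `step_bp` bin over +/- `span_bp` around
#' the anchor midpoint — the substrate for boundary- or peak-centred
#' heatmaps. Row order follows the anchors.
#'
#' @param track bedGraph data.frame (`chrom`, `start`, `end`, `value`), or a
#'   named list of them.
#' @param anchors interval data.frame.
#' @param span_bp half-window.
#' @param step_bp bin width.
#' @return anchors x bins numeric matrix (or a named list of matrices).
#' @export
signal_heatmap_matrix <- function(track, anchors, span_bp, step_bp) {
  if (is.list(track) && !is.data.frame(track))
    return(lapply(track, signal_heatmap_matrix, anchors = anchors,
                  span_bp = span_bp, step_bp = step_bp))
  stopifnot(nrow(anchors) > 0L, (2L * span_bp) %% step_bp == 0)
  if (!all(unique(anchors$chrom) %in% unique(track$chrom)))
    stop_named("peaks", "track and anchors disagree on chromosomes")
  nb <- as.integer(2L * span_bp %/% step_bp)
  mids <- (anchors$start + anchors$end) %/% 2L
  cell_start <- rep(mids, each = nb) - span_bp +
    rep(seq_len(nb) - 1L, nrow(anchors)) * step_bp
  cells <- data.frame(chrom = rep(anchors$chrom, each = nb),
                      start = pmax(cell_start, 0L),
                      end = pmax(cell_start + step_bp, 0L))
  ok <- cells$end > cells$start
  M <- matrix(0, nrow(anchors), nb)
  if (any(ok)) {
    cg <- as_granges(cells[ok, ])
    tg <- as_granges(track)
    ov <- GenomicRanges::findOverlaps(cg, tg)
    if (length(ov)) {
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        cg[S4Vectors::queryHits(ov)], tg[S4Vectors::subjectHits(ov)]))
      contrib <- w * track$value[S4Vectors::subjectHits(ov)]
      tot <- tapply(contrib, S4Vectors::queryHits(ov), sum)
      vals <- numeric(sum(ok))
      vals[as.integer(names(tot))] <- tot / step_bp
      Mv <- numeric(length(ok)); Mv[ok] <- vals
      M <- matrix(Mv, nrow(anchors), nb, byrow = TRUE)
    }
  }
  rownames(M) <- if (!is.null(anchors$name)) anchors$name else
    paste0(anchors$chrom, ":", anchors$start)
  M
}
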