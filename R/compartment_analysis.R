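#' A/B compartment calling from 500-kb matrices
#'
#' Computes the compartment signal as the leading eigenvector (PC1) of the
#' per-chromosome Pearson correlation matrix of the observed/expected
#' contact map, the standard eigenvector-based compartment convention. The
#' PC1 sign is oriented per chromosome so the gene-dense half of the
#' unmasked bins has positive mean PC1 (A = gene-dense, open chromatin);
#' bins with PC1 > 0 are labelled A, PC1 < 0 labelled B, and PC1 exactly 0
#' (or masked bins) are labelled `masked`. Chromosomes whose correlation
#' matrix is degenerate (constant rows) are masked with a warning.
#'
#' @param cm a balanced [contact_matrix()] at 500 kb resolution (an error is
#'   raised at any other resolution); an `oe` layer is added if absent. Each
#'   chromosome needs at least 10 unmasked bins.
#' @param genes gene model data.frame (BED-like with `chrom`, `start`,
#'   `end`) used as the sign-orientation anchor.
#' @return object of class `compartment_track`: a data.frame with columns
#'   `chrom`, `start`, `end`, `pc1`, `label` (A/B/masked).
#' @export
compartment_pc1 <- function(cm, genes) {
  if (resolution_of(cm$bins) != COMPARTMENT_RES)
    stop_named("compartments",
               sprintf("compartment analysis requires 500 kb matrices, got %d bp",
                       resolution_of(cm$bins)))
  if (is.null(cm$layers$balanced))
    stop_named("compartments", "balanced layer missing; run ice_balance() first")
  if (is.null(cm$layers$oe)) cm <- oe_transform(cm)
  bt <- cm$bins
  out <- data.frame(chrom = bt$chrom, start = bt$start, end = bt$end,
                    pc1 = NA_real_, label = "masked",
                    stringsAsFactors = FALSE)
  ggr <- if (nrow(genes)) as_granges(genes) else NULL
  for (ch in names(cm$layers$oe)) {
    Z <- cm$layers$oe[[ch]]
    keep <- !cm$mask[[ch]]
    if (sum(keep) < 10L)
      stop_named("compartments",
                 sprintf("%s has %d unmasked bins; need >= 10", ch, sum(keep)))
    Zk <- Z[keep, keep, drop = FALSE]
    sds <- apply(Zk, 2, stats::sd, na.rm = TRUE)
    if (any(!is.finite(sds)) || any(sds == 0)) {
      warning(sprintf("degenerate correlation matrix on %s; chromosome masked", ch))
      next
    }
    C <- stats::cor(Zk, use = "pairwise.complete.obs")
    if (anyNA(C)) {
      warning(sprintf("degenerate correlation matrix on %s; chromosome masked", ch))
      next
    }
    pc1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
    rows <- which(bt$chrom == ch)
    kept_rows <- rows[keep]
    # orient: gene-dense half of unmasked bins gets positive mean PC1
    gdens <- rep(0, length(kept_rows))
    if (!is.null(ggr)) {
      bgr <- GenomicRanges::GRanges(ch, IRanges::IRanges(bt$start[kept_rows] + 1L,
                                                         bt$end[kept_rows]))
      ov <- GenomicRanges::findOverlaps(bgr, ggr)
      if (length(ov)) {
        w <- GenomicRanges::width(GenomicRanges::pintersect(
          bgr[S4Vectors::queryHits(ov)], ggr[S4Vectors::subjectHits(ov)]))
        gdens <- as.numeric(tapply(w, factor(S4Vectors::queryHits(ov),
                                             levels = seq_along(kept_rows)), sum))
        gdens[is.na(gdens)] <- 0
      }
    }
    dense_half <- gdens >= stats::median(gdens)
    if (mean(pc1[dense_half]) < 0) pc1 <- -pc1
    out$pc1[kept_rows] <- pc1
    out$label[kept_rows] <- ifelse(pc1 > 0, "A", ifelse(pc1 < 0, "B", "masked"))
  }
  class(out) <- c("compartment_track", "data.frame")
  out
}

check_same_bins <- function(a, b, stage) {
  if (nrow(a) != nrow(b) || any(a$chrom != b$chrom) || any(a$start != b$start))
    stop_named(stage, "bin tables of the two tracks do not match")
}

#' Compartment switching between conditions
#'
#' Classifies each 500-kb bin by its (control, treated) label pair into
#' A->A, B->B, A->B or B->A; bins masked in either track are `masked`.
#' Genome fractions are computed over jointly unmasked bins and sum to 1.
#'
#' @param track_control,track_treated [compartment_pc1()] tracks on the same
#'   bin table.
#' @return object of class `switch_table`: data.frame with `chrom`, `start`,
#'   `end`, `class`, plus a `fractions` attribute (named numeric over the
#'   four classes).
#' @export
switch_classify <- function(track_control, track_treated) {
  check_same_bins(track_control, track_treated, "switch")
  cls <- ifelse(track_control$label == "masked" | track_treated$label == "masked",
                "masked",
                paste0(track_control$label, "->", track_treated$label))
  out <- data.frame(chrom = track_control$chrom, start = track_control$start,
                    end = track_control$end, class = cls,
                    stringsAsFactors = FALSE)
  lv <- c("A->A", "B->B", "A->B", "B->A")
  n <- sum(cls != "masked")
  fr <- vapply(lv, function(l) sum(cls == l) / n, numeric(1))
  attr(out, "fractions") <- fr
  class(out) <- c("switch_table", "data.frame")
  out
}

#' PC1 correlation between two tracks
#'
#' Pearson correlation of PC1 values over jointly unmasked bins, the
#' replicate/condition concordance statistic of eigenvector-based
#' compartment analysis.
#'
#' @param track_a,track_b [compartment_pc1()] tracks on the same bin table.
#' @return list with `r` and `scatter` (data.frame of the paired PC1 values).
#' @export
pc1_correlation <- function(track_a, track_b) {
  check_same_bins(track_a, track_b, "pc1_correlation")
  ok <- !is.na(track_a$pc1) & !is.na(track_b$pc1)
  if (sum(ok) < 3L)
    stop_named("pc1_correlation", "fewer than 3 jointly unmasked bins")
  list(r = stats::cor(track_a$pc1[ok], track_b$pc1[ok]),
       scatter = data.frame(chrom = track_a$chrom[ok], start = track_a$start[ok],
                            pc1_a = track_a$pc1[ok], pc1_b = track_b$pc1[ok]))
}

#' Peaks by compartment-switching class
#'
#' Assigns each peak the switching class of the 500-kb bin containing its
#' summit and reports both directions of the contingency: the composition of
#' peaks across classes, and per class the fraction of bins containing at
#' least one overlapping peak (the "bound" fraction).
#'
#' @param peaks narrowPeak data.frame.
#' @param switch a [switch_classify()] table.
#' @return list with `peak_class` (per-peak class, `unassigned` when the
#'   summit falls outside every bin), `composition` (fractions over assigned
#'   peaks), and `bound_fraction` (per class, fraction of its bins with >= 1
#'   peak overlap).
#' @export
peaks_by_compartment <- function(peaks, switch) {
  lv <- c("A->A", "B->B", "A->B", "B->A")
  if (nrow(peaks) == 0L) {
    return(list(peak_class = character(0),
                composition = stats::setNames(rep(0, 4), lv),
                bound_fraction = stats::setNames(rep(0, 4), lv)))
  }
  s <- peak_summit(peaks)
  idx <- point_in_interval(peaks$chrom, s, switch)
  cls <- ifelse(is.na(idx), "unassigned", switch$class[idx])
  assigned <- cls[cls != "unassigned" & cls != "masked"]
  comp <- vapply(lv, function(l)
    if (length(assigned)) sum(assigned == l) / length(assigned) else 0, numeric(1))
  nov <- overlap_counts(switch, peaks)
  bound <- vapply(lv, function(l) {
    sel <- switch$class == l
    if (!any(sel)) return(0)
    mean(nov[sel] >= 1L)
  }, numeric(1))
  list(peak_class = cls, composition = comp, bound_fraction = bound)
}
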