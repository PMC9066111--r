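#' Construct a methylation window-count track
#'
#' Fixed-width windows tiling the genome with raw MeDIP fragment counts per
#' sample. Normally produced by [simulate_medip_tracks()] or read back from
#' per-sample bedGraph files with [read_medip()].
#'
#' @param windows data.frame `chrom`, `start`, `end` (uniform width).
#' @param counts windows x samples matrix of non-negative integer counts.
#' @param condition character vector per sample (`control` / `treated`).
#' @param replicate integer vector per sample.
#' @return object of class `methylation_track`.
#' @export
methylation_track <- function(windows, counts, condition, replicate) {
  counts <- as.matrix(counts)
  stopifnot(nrow(windows) == nrow(counts), ncol(counts) == length(condition),
            length(condition) == length(replicate), all(counts >= 0))
  structure(list(windows = windows, counts = counts,
                 condition = condition, replicate = replicate,
                 lib_size = colSums(counts),
                 window = as.integer(max(windows$end - windows$start))),
            class = "methylation_track")
}

#' @rdname methylation_track
#' @param track a `methylation_track`.
#' @param dir output directory; one bedGraph per sample
#'   (`medip_<condition>_<replicate>.bedgraph`).
#' @export
write_medip <- function(track, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(track$condition)) {
    write_bedgraph(data.frame(chrom = track$windows$chrom,
                              start = track$windows$start,
                              end = track$windows$end,
                              value = track$counts[, k]),
                   file.path(dir, sprintf("medip_%s_%d.bedgraph",
                                          track$condition[k], track$replicate[k])))
  }
  invisible(dir)
}

#' @rdname methylation_track
#' @param paths bedGraph files, one per sample, on identical windows.
#' @export
read_medip <- function(paths, condition, replicate) {
  dfs <- lapply(paths, read_bedgraph)
  w <- dfs[[1]][, c("chrom", "start", "end")]
  for (d in dfs[-1])
    if (nrow(d) != nrow(w) || any(d$start != w$start) || any(d$chrom != w$chrom))
      stop_named("medip", "samples are not on identical windows")
  counts <- vapply(dfs, function(d) d$value, numeric(nrow(w)))
  methylation_track(w, counts, condition, replicate)
}

#' Metagene methylation profile
#'
#' Averages library-size-normalised signal over genes in a strand-aware
#' metagene coordinate system: 50 bins over the upstream flank (5' of the
#' TSS), 100 bins over the length-scaled gene body, and 50 bins over the
#' downstream flank (3' of the TES) — 200 bins in total. Genes shorter than
#' 100 bp, or whose flanks leave the chromosome, are skipped.
#'
#' @param track a [methylation_track()].
#' @param genes gene model data.frame with `chrom`, `start`, `end`, `strand`.
#' @param flank_bp flank width in bp (default 2000).
#' @param condition restrict to one condition's samples (default: all).
#' @return object of class `metagene_profile`: data.frame with `bin` (1-200),
#'   `region` (upstream/body/downstream) and `signal` (mean normalised
#'   per-bp intensity), plus `n_genes` attribute.
#' @export
metagene_profile <- function(track, genes, flank_bp = 2000L, condition = NULL) {
  stopifnot(flank_bp > 0)
  sel <- if (is.null(condition)) seq_along(track$condition) else
    which(track$condition == condition)
  norm <- track$counts[, sel, drop = FALSE]
  norm <- sweep(norm, 2, track$lib_size[sel], "/")
  v <- rowMeans(norm)
  W <- track$window
  # per-chromosome cumulative integral of the piecewise-constant per-bp signal
  chroms <- unique(track$windows$chrom)
  cums <- list(); lens <- list()
  for (ch in chroms) {
    vi <- v[track$windows$chrom == ch]
    cums[[ch]] <- c(0, cumsum(vi))
    lens[[ch]] <- length(vi) * W
  }
  integral <- function(ch, x) {
    x <- pmax(pmin(x, lens[[ch]]), 0)
    k <- floor(x / W)
    vi <- v[track$windows$chrom == ch]
    cums[[ch]][k + 1L] + (x - k * W) * vi[pmin(k + 1L, length(vi))] / W
  }
  prof <- numeric(200); used <- 0L
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (g$end - g$start < 100L) {
      message(sprintf("metagene_profile: gene %s shorter than 100 bp, skipped",
                      g$name %||% gi))
      next
    }
    if (g$start - flank_bp < 0 || g$end + flank_bp > lens[[g$chrom]]) next
    if (g$strand == "+") {
      edges <- c(seq(g$start - flank_bp, g$start, length.out = 51)[1:50],
                 seq(g$start, g$end, length.out = 101)[1:100],
                 seq(g$end, g$end + flank_bp, length.out = 51))
    } else {
      edges <- c(seq(g$end + flank_bp, g$end, length.out = 51)[1:50],
                 seq(g$end, g$start, length.out = 101)[1:100],
                 seq(g$start, g$start - flank_bp, length.out = 51))
    }
    a <- edges[-length(edges)]; b <- edges[-1]
    lo <- pmin(a, b); hi <- pmax(a, b)
    vals <- (integral(g$chrom, hi) - integral(g$chrom, lo)) / (hi - lo)
    prof <- prof + vals
    used <- used + 1L
  }
  if (used == 0L) stop_named("medip", "no usable genes for the metagene profile")
  out <- data.frame(bin = 1:200,
                    region = rep(c("upstream", "body", "downstream"),
                                 c(50, 100, 50)),
                    signal = prof / used)
  attr(out, "n_genes") <- used
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Call differentially methylated regions (DMRs)
#'
#' Window-level exact binomial test of pooled treated vs control counts
#' under the library-size null (the same engine as the differential-
#' interaction caller), BH correction over tested windows, then merging of
#' significant windows of the same direction lying within `merge_gap` of
#' each other. Direction is relative to the treated condition: hyper means
#' log2FC > 0. Windows with summed count below `min_count` are not tested.
#'
#' @param track a [methylation_track()] with both conditions.
#' @param fdr q-value threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @param merge_gap maximum gap in bp between merged windows (default 1000).
#' @param min_count minimum summed count per window (default 10).
#' @return object of class `dmr_set`: data.frame with `chrom`, `start`,
#'   `end`, `direction` (hyper/hypo), `log2fc` (from the merged counts),
#'   `q_min`, `n_windows`; the per-window test table in attribute `windows`.
#' @export
call_dmrs <- function(track, fdr = 0.05, lfc = 1, merge_gap = 1000L,
                      min_count = 10L) {
  ic <- track$condition == "control"; it <- track$condition == "treated"
  stopifnot(any(ic), any(it))
  xc <- rowSums(track$counts[, ic, drop = FALSE])
  xt <- rowSums(track$counts[, it, drop = FALSE])
  s_c <- sum(track$lib_size[ic]); s_t <- sum(track$lib_size[it])
  testable <- which(xc + xt >= min_count)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), log2fc = numeric(),
                      q_min = numeric(), n_windows = integer())
  class(empty) <- c("dmr_set", "data.frame")
  if (length(testable) == 0L) {
    warning("no testable windows; empty DMR set")
    return(empty)
  }
  p0 <- s_t / (s_t + s_c)
  S <- (s_c + s_t) / 2
  p <- binom_test_vec(xt[testable], xt[testable] + xc[testable], p0)
  q <- p.adjust(p, "BH")
  l2 <- log2((xt[testable] / s_t * S + 0.5) / (xc[testable] / s_c * S + 0.5))
  wt <- data.frame(track$windows[testable, ], count_control = xc[testable],
                   count_treated = xt[testable], log2fc = l2, p = p, q = q)
  sig <- wt[wt$q < fdr & abs(wt$log2fc) > lfc, , drop = FALSE]
  if (nrow(sig) == 0L) {
    attr(empty, "windows") <- wt
    return(empty)
  }
  sig$direction <- ifelse(sig$log2fc > 0, "hyper", "hypo")
  sig <- sig[order(sig$chrom, sig$start), ]
  regs <- list()
  cur <- sig[1, ]
  members <- list(cur)
  flush <- function(members) {
    m <- do.call(rbind, members)
    ct <- sum(m$count_treated); cc <- sum(m$count_control)
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               direction = m$direction[1],
               log2fc = log2((ct / s_t * S + 0.5) / (cc / s_c * S + 0.5)),
               q_min = min(m$q), n_windows = nrow(m),
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(sig))[-1]) {
    nxt <- sig[k, ]
    if (nxt$chrom == cur$chrom && nxt$direction == cur$direction &&
        nxt$start - cur$end <= merge_gap) {
      members[[length(members) + 1L]] <- nxt
    } else {
      regs[[length(regs) + 1L]] <- flush(members)
      members <- list(nxt)
    }
    cur <- nxt
  }
  regs[[length(regs) + 1L]] <- flush(members)
  out <- do.call(rbind, regs)
  rownames(out) <- NULL
  attr(out, "windows") <- wt
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Annotate DMRs by genomic feature
#'
#' Labels each DMR by its midpoint with precedence
#' promoter (TSS +/- `promoter_bp`) > exon > intron > intergenic, using the
#' exon blocks of a BED12 gene model.
#'
#' @param dmrs a [call_dmrs()] result (or any interval data.frame).
#' @param genes BED12 gene-model data.frame.
#' @param promoter_bp promoter half-width around the TSS (default 2000).
#' @return list with `feature` (per-DMR label) and `composition` (named
#'   fractions summing to 1).
#' @export
annotate_dmrs <- function(dmrs, genes, promoter_bp = 2000L) {
  lv <- c("promoter", "exon", "intron", "intergenic")
  if (nrow(dmrs) == 0L)
    return(list(feature = character(0),
                composition = stats::setNames(rep(0, 4), lv)))
  validate_bed12(genes)
  mid <- (dmrs$start + dmrs$end) %/% 2L
  tss <- gene_tss(genes)
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(tss - promoter_bp, 0L),
                     end = tss + promoter_bp)
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    sizes <- as.integer(strsplit(genes$blockSizes[i], ",")[[1]])
    offs <- as.integer(strsplit(genes$blockStarts[i], ",")[[1]])
    data.frame(chrom = genes$chrom[i], start = genes$start[i] + offs,
               end = genes$start[i] + offs + sizes)
  }))
  in_prom <- !is.na(point_in_interval(dmrs$chrom, mid, prom))
  in_exon <- !is.na(point_in_interval(dmrs$chrom, mid, exons))
  in_gene <- !is.na(point_in_interval(dmrs$chrom, mid,
                                      genes[, c("chrom", "start", "end")]))
  feature <- ifelse(in_prom, "promoter",
                    ifelse(in_exon, "exon",
                           ifelse(in_gene, "intron", "intergenic")))
  comp <- vapply(lv, function(l) mean(feature == l), numeric(1))
  list(feature = feature, composition = comp)
}

#' DMR / peak overlap
#'
#' Fraction of DMRs with >= 1 bp intersection with any peak, plus the Venn
#' counts in both directions.
#'
#' @param dmrs interval data.frame.
#' @param peaks narrowPeak data.frame.
#' @return named numeric: `n_dmrs`, `n_peaks`, `dmrs_overlapping`,
#'   `peaks_overlapping`, `fraction` (of DMRs overlapping).
#' @export
dmr_peak_overlap <- function(dmrs, peaks) {
  do <- sum(overlap_counts(dmrs, peaks) >= 1L)
  c(n_dmrs = nrow(dmrs), n_peaks = nrow(peaks),
    dmrs_overlapping = do,
    peaks_overlapping = sum(overlap_counts(peaks, dmrs) >= 1L),
    fraction = if (nrow(dmrs)) do / nrow(dmrs) else 0)
}

#' @rdname call_dmrs
#' @param dmrs a `dmr_set`.
#' @param path output BED path (direction, log2fc, q in columns 4-6).
#' @export
write_dmrs <- function(dmrs, path) {
  write_bed(data.frame(dmrs$chrom, dmrs$start, dmrs$end, dmrs$direction,
                       round(dmrs$log2fc, 4), signif(dmrs$q_min, 6)),
            path)
}
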