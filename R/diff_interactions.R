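#' Differential interaction calling at the bin-pair level
#'
#' Compares two conditions with replicated raw cis contact matrices (20 kb
#' in the standard pipeline). Replicates are summed per condition and
#' library-size factors taken as the total cis counts. For every bin pair
#' (`i <= j`) whose summed raw count across all samples reaches `min_count`,
#' the treated count `x_t` is tested against `n = x_t + x_c` with an exact
#' two-sided binomial test under the library-size null proportion
#' `s_t / (s_t + s_c)`; p-values are BH-corrected over tested pairs. The
#' fold change is computed from size-factor-scaled counts with pseudocount
#' 0.5: `log2FC = log2((x_t/s_t * S + 0.5) / (x_c/s_c * S + 0.5))` with `S`
#' the mean library size. A pair is significant when `q < fdr` and
#' `|log2FC| > lfc`.
#'
#' @param control,treated lists of raw [contact_matrix()] replicates (>= 2
#'   each) sharing one bin table.
#' @param min_count minimum summed raw count across all samples (default 10).
#' @param fdr BH q-value threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @return object of class `diff_interaction_table`: data.frame with
#'   `chrom`, `start_i`, `end_i`, `start_j`, `end_j`, `bin_i`, `bin_j`
#'   (per-chromosome indices), `count_control`, `count_treated`, `log2fc`,
#'   `p`, `q`, `significant`; thresholds in attributes.
#' @export
call_differential <- function(control, treated, min_count = 10L,
                              fdr = 0.05, lfc = 1) {
  stopifnot(length(control) >= 2L, length(treated) >= 2L)
  all_cm <- c(control, treated)
  bt <- all_cm[[1]]$bins
  for (cm in all_cm[-1]) {
    if (nrow(cm$bins) != nrow(bt) || any(cm$bins$start != bt$start) ||
        any(cm$bins$chrom != bt$chrom))
      stop_named("diffint", "all matrices must share one bin table")
  }
  sum_cond <- function(cms) {
    out <- lapply(names(cms[[1]]$layers$raw), function(ch)
      Reduce(`+`, lapply(cms, function(cm) cm$layers$raw[[ch]])))
    stats::setNames(out, names(cms[[1]]$layers$raw))
  }
  Mc <- sum_cond(control); Mt <- sum_cond(treated)
  s_c <- sum(vapply(Mc, function(m) sum(m[upper.tri(m, diag = TRUE)]), numeric(1)))
  s_t <- sum(vapply(Mt, function(m) sum(m[upper.tri(m, diag = TRUE)]), numeric(1)))
  if (s_c == 0 || s_t == 0) stop_named("diffint", "zero library size")
  p0 <- s_t / (s_t + s_c)
  S <- (s_c + s_t) / 2
  res <- resolution_of(bt)
  tabs <- list()
  for (ch in names(Mc)) {
    xc <- Mc[[ch]]; xt <- Mt[[ch]]
    ut <- which(upper.tri(xc, diag = TRUE) & (xc + xt) >= min_count, arr.ind = TRUE)
    if (nrow(ut) == 0L) next
    cc <- xc[ut]; tt <- xt[ut]
    tabs[[ch]] <- data.frame(
      chrom = ch, bin_i = ut[, 1], bin_j = ut[, 2],
      start_i = (ut[, 1] - 1L) * res, end_i = ut[, 1] * res,
      start_j = (ut[, 2] - 1L) * res, end_j = ut[, 2] * res,
      count_control = cc, count_treated = tt,
      log2fc = log2((tt / s_t * S + 0.5) / (cc / s_c * S + 0.5)),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs)
  if (is.null(tab))
    tab <- data.frame(chrom = character(), bin_i = integer(), bin_j = integer(),
                      start_i = integer(), end_i = integer(),
                      start_j = integer(), end_j = integer(),
                      count_control = numeric(), count_treated = numeric(),
                      log2fc = numeric())
  rownames(tab) <- NULL
  tab$p <- if (nrow(tab)) binom_test_vec(tab$count_treated,
                                         tab$count_treated + tab$count_control,
                                         p0) else numeric(0)
  tab$q <- p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < fdr & abs(tab$log2fc) > lfc
  attr(tab, "thresholds") <- c(min_count = min_count, fdr = fdr, lfc = lfc)
  attr(tab, "lib_sizes") <- c(control = s_c, treated = s_t)
  class(tab) <- c("diff_interaction_table", "data.frame")
  tab
}

#' Differentially interacting bins and their peak overlap
#'
#' `differential_bins()` returns the union of endpoint bins of significant
#' pairs as intervals. `overlap_with_peaks()` reports the Venn counts of a
#' bin set against a peak set under the >= 1 bp overlap rule.
#'
#' @param table a [call_differential()] result.
#' @return data.frame of bins (`chrom`, `start`, `end`) participating in at
#'   least one significant pair.
#' @export
differential_bins <- function(table) {
  sig <- table[table$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  bins <- rbind(data.frame(chrom = sig$chrom, start = sig$start_i, end = sig$end_i),
                data.frame(chrom = sig$chrom, start = sig$start_j, end = sig$end_j))
  bins <- unique(bins)
  bins <- bins[order(bins$chrom, bins$start), ]
  rownames(bins) <- NULL
  bins
}

#' @rdname differential_bins
#' @param bins interval data.frame (e.g. from [differential_bins()]).
#' @param peaks narrowPeak data.frame.
#' @return `overlap_with_peaks()`: named numeric with `n_bins`, `n_peaks`,
#'   `peaks_overlapping` (peaks touching >= 1 bin), `bins_overlapping`
#'   (bins touching >= 1 peak).
#' @export
overlap_with_peaks <- function(bins, peaks) {
  c(n_bins = nrow(bins), n_peaks = nrow(peaks),
    peaks_overlapping = sum(overlap_counts(peaks, bins) >= 1L),
    bins_overlapping = sum(overlap_counts(bins, peaks) >= 1L))
}

#' Significant-pair counts by peak binding
#'
#' Labels every tested bin as peak-bound (>= 1 bp overlap with any peak) or
#' unbound, counts the significant pairs each bin participates in, and
#' contrasts the two groups with a two-sided Mann-Whitney test.
#'
#' @param table a [call_differential()] result.
#' @param peaks narrowPeak data.frame.
#' @return list with `bins` (data.frame `chrom`, `start`, `end`, `n_sig`,
#'   `bound`) and `p` (NA with a message when a group is empty).
#' @export
counts_by_binding <- function(table, peaks) {
  ends <- rbind(data.frame(chrom = table$chrom, start = table$start_i,
                           end = table$end_i, sig = table$significant),
                data.frame(chrom = table$chrom, start = table$start_j,
                           end = table$end_j, sig = table$significant))
  key <- paste(ends$chrom, ends$start)
  n_sig <- tapply(ends$sig, key, sum)
  first <- !duplicated(key)
  bins <- data.frame(chrom = ends$chrom[first], start = ends$start[first],
                     end = ends$end[first], stringsAsFactors = FALSE)
  bins$n_sig <- as.integer(n_sig[paste(bins$chrom, bins$start)])
  bins$bound <- overlap_counts(bins, peaks) >= 1L
  bins <- bins[order(bins$chrom, bins$start), ]
  rownames(bins) <- NULL
  p <- if (any(bins$bound) && any(!bins$bound)) {
    wilcox.test(bins$n_sig[bins$bound], bins$n_sig[!bins$bound],
                exact = FALSE)$p.value
  } else {
    message("counts_by_binding: empty group, comparison skipped")
    NA_real_
  }
  list(bins = bins, p = p)
}

#' Write a differential-interaction table
#'
#' Tab-delimited BEDPE-like text with a header line.
#'
#' @param table a [call_differential()] result.
#' @param path output path.
#' @export
write_diff_table <- function(table, path) {
  out <- data.frame(chrom1 = table$chrom, start1 = table$start_i,
                    end1 = table$end_i, chrom2 = table$chrom,
                    start2 = table$start_j, end2 = table$end_j,
                    count_control = table$count_control,
                    count_treated = table$count_treated,
                    log2fc = round(table$log2fc, 6),
                    p = signif(table$p, 6), q = signif(table$q, 6),
                    significant = table$significant)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
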