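#' Directionality index
#'
#' For each bin, contrasts the balanced contacts to bins within `window` bp
#' upstream (sum `A`) against those within `window` bp downstream (sum `B`):
#' with `E = (A + B) / 2`,
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`.
#' Positive DI marks downstream-biased bins (domain starts), negative DI
#' upstream-biased bins (domain ends). Bins closer than `window` to a
#' chromosome edge are computed over the available span and flagged
#' `partial`. Masked bins get `NA`; so do bins with `A + B = 0`.
#'
#' @param cm balanced [contact_matrix()] (40 kb resolution in the standard
#'   pipeline).
#' @param window half-window in bp (default 2 Mb); must be a positive
#'   multiple of the resolution.
#' @return object of class `di_vector`: data.frame with `chrom`, `start`,
#'   `end`, `A`, `B`, `E`, `di`, `partial`.
#' @export
directionality_index <- function(cm, window = 2e6) {
  res <- resolution_of(cm$bins)
  if (window < res) stop_named("tads", "window must be >= the bin size")
  if (window %% res != 0) stop_named("tads", "window must be a multiple of the bin size")
  if (is.null(cm$layers$balanced))
    stop_named("tads", "balanced layer missing; run ice_balance() first")
  w <- as.integer(window %/% res)
  out <- list()
  for (ch in names(cm$layers$balanced)) {
    M <- cm$layers$balanced[[ch]]
    M[is.na(M)] <- 0
    n <- nrow(M)
    A <- B <- numeric(n)
    for (i in seq_len(n)) {
      up <- seq(max(1L, i - w), i - 1L)
      dn <- seq(i + 1L, min(n, i + w))
      A[i] <- if (i > 1L) sum(M[i, up]) else 0
      B[i] <- if (i < n) sum(M[i, dn]) else 0
    }
    E <- (A + B) / 2
    di <- ifelse(A + B > 0,
                 sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E),
                 NA_real_)
    di[cm$mask[[ch]]] <- NA_real_
    bt <- cm$bins[cm$bins$chrom == ch, ]
    out[[ch]] <- data.frame(chrom = ch, start = bt$start, end = bt$end,
                            A = A, B = B, E = E, di = di,
                            partial = seq_len(n) <= w | seq_len(n) > n - w,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("di_vector", "data.frame")
  out
}

#' Segment the DI track with a 3-state Gaussian HMM
#'
#' Fits one genome-wide 3-state Gaussian HMM to the finite DI values (each
#' chromosome's maximal finite runs are independent sequences) and Viterbi-
#' decodes each chromosome. States are ordered by mean: 1 = upstream-biased,
#' 2 = unbiased, 3 = downstream-biased. Same seed, same path.
#'
#' @param di a [directionality_index()] result; every chromosome must have
#'   at least 50 finite DI values.
#' @param seed seed for the EM restart (default 13).
#' @param ... passed to [fit_gaussian_hmm()].
#' @return the input data.frame with an integer `state` column (`NA` at bins
#'   without DI) and the fitted model in attribute `hmm`.
#' @export
fit_hmm_and_decode <- function(di, seed = 13L, ...) {
  per_chrom <- split(di$di, di$chrom)[unique(di$chrom)]
  nf <- vapply(per_chrom, function(x) sum(is.finite(x)), integer(1))
  if (any(nf < 50L))
    stop_named("tads", sprintf("chromosome %s has %d finite DI values; need >= 50",
                               names(nf)[which.min(nf)], min(nf)))
  fin <- unlist(per_chrom)[is.finite(unlist(per_chrom))]
  if (stats::sd(fin) == 0) {
    # no directional information anywhere: everything is unbiased
    di$state <- ifelse(is.finite(di$di), 2L, NA_integer_)
    attr(di, "hmm") <- NULL
    return(di)
  }
  seqs <- list()
  runs_by_chrom <- lapply(per_chrom, function(x) {
    r <- rle(is.finite(x))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  })
  for (ch in names(per_chrom))
    for (k in seq_len(nrow(runs_by_chrom[[ch]]))) {
      sp <- runs_by_chrom[[ch]][k, ]
      seqs[[length(seqs) + 1L]] <- per_chrom[[ch]][sp[1]:sp[2]]
    }
  model <- fit_gaussian_hmm(seqs, n_states = 3L, seed = seed, ...)
  di$state <- NA_integer_
  for (ch in names(per_chrom)) {
    rows <- which(di$chrom == ch)
    # decode the whole chromosome in one pass; bins without DI are missing
    # emissions, so the state path stays continuous across masked bins
    di$state[rows] <- viterbi_decode(model, per_chrom[[ch]])
  }
  attr(di, "hmm") <- model
  di
}

#' Assemble TAD domains and boundaries from a decoded state path
#'
#' A domain opens at the first bin of a downstream-biased run (state 3) and
#' closes at the last bin of the next upstream-biased run (state 1);
#' unbiased or further downstream-biased bins in between stay inside the
#' domain, and a domain left open at the chromosome end is discarded. Gaps
#' between consecutive domains become `boundary` regions when shorter than
#' 400 kb and `unorganized` regions otherwise; adjacent domains (zero gap)
#' produce a 1-bp boundary at the shared edge.
#'
#' @param states a [fit_hmm_and_decode()] result (or any data.frame with
#'   `chrom`, `start`, `end`, `state`).
#' @param max_boundary_bp boundary/unorganized cutoff in bp (default 4e5).
#' @return object of class `tad_set`: list with `domains` (data.frame) and
#'   `boundaries` (data.frame with `kind` and a strength column `S`, `NA`
#'   until [boundary_strength()] is run).
#' @export
assemble_domains <- function(states, max_boundary_bp = 400000L) {
  doms <- list()
  for (ch in unique(states$chrom)) {
    sub <- states[states$chrom == ch, ]
    s <- sub$state
    s[is.na(s)] <- 2L
    r <- rle(s)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    in_dom <- FALSE; dstart <- NA_integer_
    for (k in seq_along(r$values)) {
      if (!in_dom && r$values[k] == 3L) {
        in_dom <- TRUE; dstart <- starts[k]
      } else if (in_dom && r$values[k] == 1L) {
        doms[[length(doms) + 1L]] <- data.frame(
          chrom = ch, start = sub$start[dstart], end = sub$end[ends[k]],
          stringsAsFactors = FALSE)
        in_dom <- FALSE
      }
    }
  }
  domains <- if (length(doms)) do.call(rbind, doms) else
    data.frame(chrom = character(), start = integer(), end = integer())
  bnds <- list()
  for (ch in unique(domains$chrom)) {
    d <- domains[domains$chrom == ch, ]
    if (nrow(d) < 2L) next
    for (k in seq_len(nrow(d) - 1L)) {
      gap <- d$start[k + 1L] - d$end[k]
      bnds[[length(bnds) + 1L]] <- data.frame(
        chrom = ch,
        start = d$end[k],
        end = if (gap == 0L) d$end[k] + 1L else d$start[k + 1L],
        kind = if (gap < max_boundary_bp) "boundary" else "unorganized",
        stringsAsFactors = FALSE)
    }
  }
  boundaries <- if (length(bnds)) do.call(rbind, bnds) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               kind = character())
  boundaries$S <- rep(NA_real_, nrow(boundaries))
  structure(list(domains = domains, boundaries = boundaries),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("<tad_set> %d domains, %d boundaries (%d < 400 kb)\n",
              nrow(x$domains), nrow(x$boundaries),
              sum(x$boundaries$kind == "boundary")))
  invisible(x)
}

#' Boundary strength score
#'
#' Insulation log-contrast at each boundary: with `m` the bin containing the
#' boundary midpoint and flank width `w` bins,
#' `S = log2( mean(Z in the left and right w x w intra blocks) /
#'            mean(Z in the w x w cross block spanning m) )`
#' on the observed/expected layer, diagonals excluded. Higher S = stronger
#' insulation; on the noise-free expected map of the generator, S equals
#' `-log2(f)` at an isolated planted boundary with retention factor `f`.
#' Boundaries within `w` bins of a chromosome edge are left unscored.
#'
#' @param cm [contact_matrix()] with an `oe` layer.
#' @param tads a [assemble_domains()] `tad_set`.
#' @param w flank width in bins (default 10, i.e. 400 kb at 40 kb); must be
#'   >= 2.
#' @return the `tad_set` with the `S` column of `boundaries` filled in for
#'   regions of kind `boundary`.
#' @export
boundary_strength <- function(cm, tads, w = 10L) {
  stopifnot(w >= 2L)
  if (is.null(cm$layers$oe))
    stop_named("tads", "oe layer missing; run oe_transform() first")
  res <- resolution_of(cm$bins)
  bd <- tads$boundaries
  for (k in seq_len(nrow(bd))) {
    if (bd$kind[k] != "boundary") next
    ch <- bd$chrom[k]
    Z <- cm$layers$oe[[ch]]
    if (is.null(Z)) next
    n <- nrow(Z)
    mid <- (bd$start[k] + bd$end[k]) %/% 2L
    m <- mid %/% res + 1L
    if (m - w < 1L || m + w > n) next   # unscored: too close to chromosome edge
    L <- (m - w):(m - 1L); R <- (m + 1L):(m + w)
    intra <- c(Z[L, L][upper.tri(Z[L, L])], Z[R, R][upper.tri(Z[R, R])])
    cross <- Z[L, R]
    bd$S[k] <- log2(mean(intra, na.rm = TRUE) / mean(cross, na.rm = TRUE))
  }
  tads$boundaries <- bd
  tads
}

#' Intra-TAD interaction level
#'
#' Mean off-diagonal observed/expected value over each domain's bin block;
#' domains spanning fewer than 3 bins are skipped. `compare_conditions()`
#' contrasts two per-TAD mean vectors with the median difference
#' (treated - control) and a two-sided Mann-Whitney test; with
#' `paired = TRUE` (for TAD sets matched one-to-one, e.g. a shared domain
#' set) it uses the Wilcoxon signed-rank test instead, which is far more
#' powerful when the between-TAD spread is common to both conditions.
#'
#' @param cm [contact_matrix()] with an `oe` layer.
#' @param tads a `tad_set`.
#' @return data.frame with `chrom`, `start`, `end`, `n_bins`, `mean_z`.
#' @export
intra_tad_interaction <- function(cm, tads) {
  if (is.null(cm$layers$oe))
    stop_named("tads", "oe layer missing; run oe_transform() first")
  res <- resolution_of(cm$bins)
  d <- tads$domains
  out <- d
  out$n_bins <- NA_integer_; out$mean_z <- NA_real_
  for (k in seq_len(nrow(d))) {
    Z <- cm$layers$oe[[d$chrom[k]]]
    if (is.null(Z)) next
    n <- nrow(Z)
    # bins whose midpoints fall inside the domain
    idx <- which((seq_len(n) - 0.5) * res >= d$start[k] &
                   (seq_len(n) - 0.5) * res < d$end[k])
    if (length(idx) < 3L) next
    blk <- Z[idx, idx]
    out$n_bins[k] <- length(idx)
    out$mean_z[k] <- mean(blk[upper.tri(blk)], na.rm = TRUE)
  }
  out
}

#' @rdname intra_tad_interaction
#' @param control,treated numeric vectors of per-TAD means.
#' @param paired set `TRUE` when the vectors are matched element-wise.
#' @export
compare_conditions <- function(control, treated, paired = FALSE) {
  if (paired) {
    ok <- is.finite(control) & is.finite(treated)
    control <- control[ok]; treated <- treated[ok]
  } else {
    control <- control[is.finite(control)]
    treated <- treated[is.finite(treated)]
  }
  p <- if (stats::sd(c(control, treated)) == 0) 1 else
    wilcox.test(treated, control, exact = FALSE, paired = paired)$p.value
  list(median_diff = median(treated) - median(control), p = p)
}

#' TAD compartment scores and switching
#'
#' A 500-kb bin is located in a TAD when its midpoint falls inside the
#' domain; the TAD compartment score is the mean PC1 over located unmasked
#' bins, with label A for positive and B for negative score (score 0 or no
#' located bins leaves the TAD unscored). `tad_switch()` matches TADs across
#' conditions by >= 50 percent reciprocal overlap and reports the fraction
#' of matched, scored pairs whose labels differ.
#'
#' @param tads a `tad_set`.
#' @param track a [compartment_pc1()] track at 500 kb.
#' @return data.frame `chrom`, `start`, `end`, `score`, `label`.
#' @export
tad_compartment_scores <- function(tads, track) {
  d <- tads$domains
  out <- d
  out$score <- NA_real_; out$label <- NA_character_
  mid <- (track$start + track$end) / 2
  for (k in seq_len(nrow(d))) {
    sel <- track$chrom == d$chrom[k] & mid >= d$start[k] & mid < d$end[k] &
      !is.na(track$pc1)
    if (!any(sel)) next
    sc <- mean(track$pc1[sel])
    out$score[k] <- sc
    if (sc != 0) out$label[k] <- if (sc > 0) "A" else "B"
  }
  out
}

#' @rdname tad_compartment_scores
#' @param scores_a,scores_b [tad_compartment_scores()] results for the two
#'   conditions.
#' @return `tad_switch()`: list with `switched_fraction`, `n_matched`, and
#'   the matched pair table.
#' @export
tad_switch <- function(scores_a, scores_b) {
  ga <- as_granges(scores_a); gb <- as_granges(scores_b)
  ov <- GenomicRanges::findOverlaps(ga, gb)
  qa <- S4Vectors::queryHits(ov); qb <- S4Vectors::subjectHits(ov)
  wi <- GenomicRanges::width(GenomicRanges::pintersect(ga[qa], gb[qb]))
  recip <- wi >= 0.5 * GenomicRanges::width(ga[qa]) &
    wi >= 0.5 * GenomicRanges::width(gb[qb])
  qa <- qa[recip]; qb <- qb[recip]
  ok <- !is.na(scores_a$label[qa]) & !is.na(scores_b$label[qb])
  pairs <- data.frame(a = qa[ok], b = qb[ok],
                      label_a = scores_a$label[qa[ok]],
                      label_b = scores_b$label[qb[ok]])
  list(switched_fraction = if (nrow(pairs)) mean(pairs$label_a != pairs$label_b) else NA_real_,
       n_matched = nrow(pairs),
       pairs = pairs)
}

#' Boundary-strength strata
#'
#' Groups each condition's scored boundaries two ways: `overlapping` vs
#' condition-specific (>= 1 bp overlap with the other condition's boundary
#' regions) and peak-`bound` vs unbound (>= 1 overlapping peak). Reports the
#' per-boundary table per condition and two-sided Mann-Whitney p-values for
#' both contrasts (NA, with a message, when a group is empty).
#'
#' @param tads_a,tads_b scored `tad_set`s for the two conditions.
#' @param peaks narrowPeak data.frame.
#' @return list with `a`, `b` (boundary tables with `overlapping`, `bound`)
#'   and `p` (matrix of p-values, rows bound/overlap, columns a/b).
#' @export
boundary_strength_strata <- function(tads_a, tads_b, peaks) {
  grp <- function(x, other) {
    bd <- x$boundaries[x$boundaries$kind == "boundary", , drop = FALSE]
    obd <- other$boundaries[other$boundaries$kind == "boundary", , drop = FALSE]
    bd$overlapping <- overlap_counts(bd, obd) >= 1L
    bd$bound <- overlap_counts(bd, peaks) >= 1L
    bd
  }
  a <- grp(tads_a, tads_b); b <- grp(tads_b, tads_a)
  mw <- function(x, g) {
    x1 <- x[g & is.finite(x)]; x0 <- x[!g & is.finite(x)]
    if (!length(x1) || !length(x0)) {
      message("boundary_strength_strata: empty group, comparison skipped")
      return(NA_real_)
    }
    wilcox.test(x1, x0, exact = FALSE)$p.value
  }
  p <- matrix(c(mw(a$S, a$bound), mw(b$S, b$bound),
                mw(a$S, a$overlapping), mw(b$S, b$overlapping)),
              2, 2, byrow = TRUE,
              dimnames = list(c("bound_vs_unbound", "overlapping_vs_specific"),
                              c("a", "b")))
  list(a = a, b = b, p = p)
}

#' Write a TAD set as BED files
#'
#' Domains as BED3; boundaries as BED5 with the kind in column 4 and the
#' strength score in column 5.
#'
#' @param tads a `tad_set`.
#' @param domains_path,boundaries_path output paths.
#' @export
write_tads <- function(tads, domains_path, boundaries_path) {
  write_bed(tads$domains, domains_path)
  bd <- tads$boundaries
  write_bed(data.frame(bd$chrom, bd$start, bd$end, bd$kind,
                       ifelse(is.na(bd$S), ".", format(bd$S, digits = 6))),
            boundaries_path)
  invisible(NULL)
}
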