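#' Bin tables: fixed-resolution genome tilings
#'
#' A bin table tiles each chromosome with consecutive fixed-width bins
#' (0-based half-open) and maps each bin to a global 1-based integer ID in
#' genome order, the convention used by HiC-Pro style `.matrix`/`.bed` file
#' pairs.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param resolution bin width in bp.
#' @return object of class `bin_table`: a data.frame with columns `chrom`,
#'   `start`, `end`, `id`, plus a `resolution` attribute.
#' @export
bin_table <- function(chrom_lengths, resolution) {
  stopifnot(resolution > 0, all(chrom_lengths > 0))
  rows <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = resolution)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + resolution, len)),
               stringsAsFactors = FALSE)
  })
  bt <- do.call(rbind, rows)
  bt$id <- seq_len(nrow(bt))
  attr(bt, "resolution") <- as.integer(resolution)
  class(bt) <- c("bin_table", "data.frame")
  bt
}

resolution_of <- function(bt) attr(bt, "resolution")

chrom_lengths_of <- function(bt) {
  tapply(bt$end, bt$chrom, max)[unique(bt$chrom)]
}

#' @rdname bin_table
#' @param path BED file of bins (chrom, start, end[, id]).
#' @export
read_bins <- function(path) {
  df <- read_bed(path)
  res <- as.integer(max(df$end - df$start))
  lens <- tapply(df$end, df$chrom, max)[unique(df$chrom)]
  bt <- bin_table(lens, res)
  if (nrow(bt) != nrow(df) || any(bt$start != df$start) ||
      any(bt$chrom != df$chrom))
    stop_named("io", paste0("bin file ", path, " is not a uniform tiling"))
  bt
}

#' @rdname bin_table
#' @param bt a `bin_table`.
#' @export
write_bins <- function(bt, path) {
  write_bed(data.frame(bt$chrom, bt$start, bt$end, bt$id), path)
}

#' Cis contact matrices
#'
#' Container for binned intra-chromosomal (cis) Hi-C contact counts: one
#' symmetric dense matrix per chromosome, with up to three layers — `raw`
#' integer counts, ICE-`balanced` counts, and observed/expected (`oe`) — a
#' per-chromosome mask of filtered bins, and the ICE bias vector once
#' [ice_balance()] has run. Masked bins carry `NA` in the balanced and oe
#' layers and are excluded from all downstream statistics.
#'
#' @param bt a [bin_table()].
#' @param mats named list (by chromosome) of symmetric matrices for the raw
#'   layer.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(bt, mats) {
  chroms <- unique(bt$chrom)
  stopifnot(identical(sort(names(mats)), sort(chroms)))
  for (ch in chroms) {
    m <- mats[[ch]]
    nb <- sum(bt$chrom == ch)
    if (!is.matrix(m) || nrow(m) != nb || ncol(m) != nb)
      stop_named("contact", sprintf("matrix for %s is not %d x %d", ch, nb, nb))
    if (any(m < 0)) stop_named("contact", paste0("negative counts on ", ch))
    if (!isTRUE(all.equal(m, t(m), tolerance = 0)))
      stop_named("contact", paste0("matrix for ", ch, " is not symmetric"))
  }
  structure(list(bins = bt,
                 layers = list(raw = mats[chroms]),
                 mask = lapply(stats::setNames(chroms, chroms),
                               function(ch) rep(FALSE, sum(bt$chrom == ch))),
                 bias = NULL),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins @ %d bp, %d chromosome(s); layers: %s\n",
              nrow(x$bins), resolution_of(x$bins),
              length(x$layers$raw), paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

chrom_ids <- function(bt) split(bt$id, bt$chrom)[unique(bt$chrom)]

#' Read / write contact matrices in HiC-Pro triplet format
#'
#' The `.matrix` file holds one upper-triangle record per line,
#' `bin_i<TAB>bin_j<TAB>count` with 1-based global bin IDs (`i <= j`); the
#' companion `.bed` file lists the bins (0-based half-open). Records with
#' unknown bin IDs, negative counts, or duplicate pairs (including the
#' symmetric duplicate) are rejected with the offending line number.
#'
#' @param matrix_path path to the triplet `.matrix` file.
#' @param bins_path path to the companion bin BED file.
#' @return [read_matrix()] returns a `contact_matrix` with a raw layer;
#'   [write_matrix()] returns the paths invisibly.
#' @export
read_matrix <- function(matrix_path, bins_path) {
  bt <- read_bins(bins_path)
  trip <- read_tsv_checked(matrix_path, 3L, "matrix")
  chroms <- unique(bt$chrom)
  idsplit <- chrom_ids(bt)
  offs <- vapply(idsplit, function(v) v[1] - 1L, integer(1))
  nbin <- vapply(idsplit, length, integer(1))
  mats <- lapply(stats::setNames(chroms, chroms),
                 function(ch) matrix(0, nbin[[ch]], nbin[[ch]]))
  if (nrow(trip) > 0L) {
    names(trip)[1:3] <- c("i", "j", "count")
    n <- nrow(bt)
    bad <- which(trip$i < 1 | trip$i > n | trip$j < 1 | trip$j > n)
    if (length(bad))
      stop_named("io", sprintf("%s line %d: unknown bin ID", matrix_path, bad[1]))
    bad <- which(trip$count < 0)
    if (length(bad))
      stop_named("io", sprintf("%s line %d: negative count", matrix_path, bad[1]))
    lo <- pmin(trip$i, trip$j); hi <- pmax(trip$i, trip$j)
    key <- paste(lo, hi)
    if (anyDuplicated(key))
      stop_named("io", sprintf("%s line %d: duplicate record for bin pair",
                               matrix_path, which(duplicated(key))[1]))
    chr_i <- bt$chrom[lo]; chr_j <- bt$chrom[hi]
    keep <- chr_i == chr_j   # cis-only model
    for (ch in chroms) {
      sel <- keep & chr_i == ch
      if (!any(sel)) next
      ii <- lo[sel] - offs[[ch]]; jj <- hi[sel] - offs[[ch]]
      m <- mats[[ch]]
      m[cbind(ii, jj)] <- trip$count[sel]
      m[cbind(jj, ii)] <- trip$count[sel]
      mats[[ch]] <- m
    }
  }
  contact_matrix(bt, mats)
}

#' @rdname read_matrix
#' @param cm a `contact_matrix`.
#' @param layer which layer to write.
#' @export
write_matrix <- function(cm, matrix_path, bins_path = NULL, layer = "raw") {
  bt <- cm$bins
  idsplit <- chrom_ids(bt)
  recs <- lapply(names(cm$layers[[layer]]), function(ch) {
    m <- cm$layers[[layer]][[ch]]
    ut <- which(upper.tri(m, diag = TRUE) & m != 0 & !is.na(m), arr.ind = TRUE)
    off <- idsplit[[ch]][1] - 1L
    data.frame(i = ut[, 1] + off, j = ut[, 2] + off, count = m[ut])
  })
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$i, recs$j), ]
  write.table(format(recs, scientific = FALSE, trim = TRUE, digits = 15),
              matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(bins_path)) write_bins(bt, bins_path)
  invisible(matrix_path)
}

#' Iterative correction (ICE) balancing
#'
#' Removes multiplicative per-bin biases from a raw cis contact matrix by
#' iterative correction: each chromosome's matrix is repeatedly divided by
#' its row/column marginals (renormalised to mean 1 over unmasked bins) until
#' the coefficient of variation (CV) of the unmasked row sums falls below
#' `tol` or `max_iter` is reached. Every fifth iteration the log-bias vector
#' is Aitken-extrapolated, which accelerates the smooth bias modes that
#' converge slowly on strongly insulated (near block-diagonal) maps without
#' changing the fixed point. The lowest-coverage `mask_fraction` of
#' bins (plus all zero-coverage bins) are masked beforehand. The returned
#' bias vector is normalised to geometric mean 1 over unmasked bins so the
#' balanced layer `N_ij = O_ij / (b_i b_j)` keeps the raw count scale.
#'
#' @param cm `contact_matrix` with a raw layer.
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance on the row-sum CV (default 1e-5).
#' @param mask_fraction fraction of lowest-coverage bins to mask (default
#'   0.02); must be in `[0, 1)`.
#' @return the input with a `balanced` layer, updated mask, per-chromosome
#'   `bias` vectors (`NA` at masked bins) and a `ice_cv` attribute with the
#'   achieved CV per chromosome. Non-convergence raises a warning and
#'   returns the achieved CV.
#' @export
ice_balance <- function(cm, max_iter = 200L, tol = 1e-5, mask_fraction = 0.02) {
  stopifnot(inherits(cm, "contact_matrix"), mask_fraction >= 0, mask_fraction < 1)
  chroms <- names(cm$layers$raw)
  cm$layers$balanced <- list()
  cm$bias <- list()
  cvs <- numeric(0)
  for (ch in chroms) {
    O <- cm$layers$raw[[ch]]
    n <- nrow(O)
    cov <- rowSums(O)
    mask <- cov == 0
    k <- floor(mask_fraction * n)
    if (k > 0) {
      ord <- order(cov)
      mask[ord[seq_len(k)]] <- TRUE
    }
    if (all(mask)) stop_named("ice", paste0("all bins masked on ", ch))
    # iterative correction on the log-bias, with periodic Aitken delta-squared
    # extrapolation: strongly insulated (near block-diagonal) maps make the
    # smooth bias modes converge slowly under plain iteration
    lb <- numeric(n)
    hist <- list()
    cv <- Inf
    for (it in seq_len(max_iter)) {
      b <- exp(lb)
      W <- O / outer(b, b)
      W[mask, ] <- 0; W[, mask] <- 0
      s <- rowSums(W)
      su <- s[!mask]
      cv <- stats::sd(su) / mean(su)
      if (is.na(cv)) cv <- 0
      if (cv < tol) break
      d <- log(s / mean(su))
      d[mask | !is.finite(d)] <- 0
      lb <- lb + d
      hist[[length(hist) + 1L]] <- lb
      if (length(hist) >= 3L && it %% 5L == 0L) {
        l2 <- hist[[length(hist)]]
        d1 <- hist[[length(hist) - 1L]] - hist[[length(hist) - 2L]]
        d2 <- l2 - hist[[length(hist) - 1L]]
        den <- d2 - d1
        ok <- is.finite(den) & abs(den) > 1e-12
        lb <- l2
        lb[ok] <- l2[ok] - d2[ok]^2 / den[ok]
        lb[!is.finite(lb)] <- l2[!is.finite(lb)]
        hist <- list()
      }
    }
    b <- exp(lb)
    if (cv >= tol)
      warning(sprintf("ICE did not converge on %s: row-sum CV %.3g after %d iterations",
                      ch, cv, max_iter))
    # renormalise bias to geometric mean 1 over unmasked bins
    g <- exp(mean(log(b[!mask])))
    b <- b / g
    N <- O / outer(b, b)
    N[mask, ] <- NA; N[, mask] <- NA
    b[mask] <- NA
    cm$layers$balanced[[ch]] <- N
    cm$bias[[ch]] <- b
    cm$mask[[ch]] <- mask
    cvs[ch] <- cv
  }
  attr(cm, "ice_cv") <- cvs
  cm
}

#' Distance-decay expected profile and O/E transform
#'
#' `expected_profile()` computes, per chromosome, the mean balanced contact
#' `E(s)` over all unmasked bin pairs at each bin distance `s`, plus the
#' frequency density of balanced contacts over log10 genomic distance (bins
#' of width 0.1, normalised to sum 1). `oe_transform()` divides the balanced
#' layer by `E(|i - j|)` to give the observed/expected layer `Z`; entries at
#' distances with no unmasked pairs, and masked rows/columns, are `NA`.
#'
#' @param cm `contact_matrix` with a balanced layer.
#' @return `expected_profile()`: object of class `expected_profile` — a list
#'   with `expected` (per-chromosome numeric vector indexed by bin distance
#'   `s = 0 ..`) and `density` (data.frame `log10_bp`, `density`).
#'   `oe_transform()`: the input `contact_matrix` with an `oe` layer.
#' @export
expected_profile <- function(cm) {
  stopifnot(!is.null(cm$layers$balanced))
  res <- resolution_of(cm$bins)
  exp_list <- list()
  dens_num <- list()
  for (ch in names(cm$layers$balanced)) {
    N <- cm$layers$balanced[[ch]]
    n <- nrow(N)
    mask <- cm$mask[[ch]]
    keep <- !mask
    Es <- rep(NA_real_, n)
    ut <- which(upper.tri(N, diag = TRUE), arr.ind = TRUE)
    ok <- keep[ut[, 1]] & keep[ut[, 2]]
    s <- ut[ok, 2] - ut[ok, 1]
    v <- N[ut[ok, , drop = FALSE]]
    sums <- tapply(v, s, sum)
    cnts <- tapply(v, s, length)
    Es[as.integer(names(sums)) + 1L] <- sums / cnts
    exp_list[[ch]] <- Es
    pos <- s > 0
    dens_num[[ch]] <- data.frame(lg = log10(s[pos] * res), w = v[pos])
  }
  all <- do.call(rbind, dens_num)
  bin <- floor(all$lg / 0.1) * 0.1
  dens <- tapply(all$w, bin, sum)
  dens <- dens / sum(dens)
  structure(list(expected = exp_list,
                 density = data.frame(log10_bp = as.numeric(names(dens)),
                                      density = as.numeric(dens))),
            class = "expected_profile")
}

#' @rdname expected_profile
#' @param expected optionally, a precomputed `expected_profile` (e.g. an
#'   analytic decay) to divide by instead of the empirical one.
#' @export
oe_transform <- function(cm, expected = NULL) {
  ep <- expected %||% expected_profile(cm)
  cm$layers$oe <- list()
  for (ch in names(cm$layers$balanced)) {
    N <- cm$layers$balanced[[ch]]
    n <- nrow(N)
    Es <- ep$expected[[ch]]
    D <- abs(outer(seq_len(n), seq_len(n), "-")) + 1L
    Emat <- matrix(Es[D], n, n)
    Z <- N / Emat
    Z[Emat == 0] <- NA
    mask <- cm$mask[[ch]]
    Z[mask, ] <- NA; Z[, mask] <- NA
    cm$layers$oe[[ch]] <- Z
  }
  cm
}
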