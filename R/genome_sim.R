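#' Simulation configuration
#'
#' Bundles the parameters of the synthetic chromatin-architecture generator.
#' The defaults encode the reference conditions every planted structure is
#' generated under: power-law distance decay, checkerboard A/B compartments
#' at megabase scale, block-diagonal TADs whose boundaries retain only a
#' fraction `insulation` of cross-boundary contacts, multiplicative per-bin
#' biases, Poisson count noise, and two replicates per condition.
#'
#' @param decay_exponent alpha in `P(s) ~ s^-alpha` (bin-distance decay),
#'   default 1.
#' @param compartment_contrast delta in `[0, 1)`: same-compartment pairs get
#'   intensity factor `1 + delta`, cross-compartment `1 - delta`. Default 0.4.
#' @param tad_enrichment gamma >= 1: within-domain intensity multiplier,
#'   default 3.
#' @param insulation default per-boundary retention factor `f` in `(0, 1]`:
#'   the fraction of cross-boundary expected contacts retained (smaller =
#'   stronger boundary). Default 0.3.
#' @param sequencing_depth expected total cis contact count per replicate,
#'   default 2e7 (chosen so the planted differential-interaction design is
#'   well powered at 20 kb on the toy genome).
#' @param replicate_count replicates per condition, default 2.
#' @param dmr_fold_change fold change of planted DMRs, default 4
#'   (|log2 FC| = 2 >= 1).
#' @param n_hyper,n_hypo numbers of planted hyper-/hypo-methylated regions,
#'   defaults 20 and 10.
#' @param dmr_width planted DMR width in bp (multiple of `medip_window`),
#'   default 5000.
#' @param medip_depth expected total MeDIP window counts per replicate,
#'   default 2e6.
#' @param medip_window MeDIP counting window in bp, default 1000.
#' @param peak_count named integer vector: peaks per placement class
#'   `c(boundary =, promoter =, random =)`.
#' @param peak_width peak width range in bp.
#' @param peak_pos_sd s.d. (bp) of boundary-class summit placement around the
#'   planted boundary (truncated at one 40-kb bin), default 15000.
#' @param bias_sd log-sd of the lognormal per-bin bias, default 0.25.
#' @param tss_dip multiplicative methylation level at the TSS (\eqn{<1} gives
#'   the TSS dip), default 0.25.
#' @param tes_rise multiplicative methylation level at the TES (\eqn{>1}
#'   gives the TES rise), default 2.
#' @param diag_intensity intensity used on the matrix diagonal in place of
#'   the singular `s^-alpha` at `s = 0`, default 2.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(decay_exponent = 1, compartment_contrast = 0.4,
                       tad_enrichment = 3, insulation = 0.3,
                       sequencing_depth = 2e7, replicate_count = 2L,
                       dmr_fold_change = 4, n_hyper = 20L, n_hypo = 10L,
                       dmr_width = 5000L, medip_depth = 2e6,
                       medip_window = 1000L,
                       peak_count = c(boundary = 100L, promoter = 100L, random = 100L),
                       peak_width = c(200L, 800L), peak_pos_sd = 15000,
                       bias_sd = 0.25, tss_dip = 0.25, tes_rise = 2,
                       diag_intensity = 2) {
  stopifnot(decay_exponent > 0,
            compartment_contrast >= 0, compartment_contrast < 1,
            tad_enrichment >= 1, insulation > 0, insulation <= 1,
            sequencing_depth > 0, replicate_count >= 1,
            dmr_fold_change > 0, abs(log2(dmr_fold_change)) >= 1,
            all(peak_count >= 0))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

COMPARTMENT_RES <- 500000L
TAD_RES <- 40000L

#' Synthetic toy genome
#'
#' Builds a small genome (default two 20-Mb chromosomes) whose lengths are
#' multiples of the coarsest bin size (500 kb), with genes placed by
#' [place_genes()]. The TSS of each gene is its `start` on the + strand and
#' its `end` on the - strand.
#'
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_length length of each chromosome in bp (default 20 Mb; must
#'   be a positive multiple of 500 kb).
#' @param genes_per_chrom genes per chromosome (default 200); gene bodies are
#'   5-50 kb with 1-6 exons.
#' @param seed RNG seed.
#' @param truth optional [simulate_truth()] object: when given, gene starts
#'   are sampled with `gene_density_ratio`-fold higher density in
#'   A-compartment bins (A = gene-dense, the orientation anchor for
#'   compartment calling).
#' @param gene_density_ratio A:B gene-density ratio used when `truth` is
#'   supplied, default 3.
#' @return object of class `synthetic_genome`: list with `chromosomes`
#'   (data.frame `name`, `length`), `genes` (BED12 data.frame) and `seed`.
#' @export
simulate_genome <- function(n_chrom = 2L, chrom_length = 2e7,
                            genes_per_chrom = 200L, seed = 1L,
                            truth = NULL, gene_density_ratio = 3) {
  stopifnot(chrom_length %% COMPARTMENT_RES == 0, chrom_length > 0)
  chroms <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                       length = rep(as.integer(chrom_length), n_chrom),
                       stringsAsFactors = FALSE)
  g <- structure(list(chromosomes = chroms,
                      genes = stats::setNames(
                        data.frame(matrix(nrow = 0, ncol = 12)), bed12_cols),
                      seed = seed),
                 class = "synthetic_genome")
  if (genes_per_chrom > 0)
    g <- place_genes(g, truth = truth, genes_per_chrom = genes_per_chrom,
                     gene_density_ratio = gene_density_ratio, seed = seed)
  g
}

#' @rdname simulate_genome
#' @param genome a `synthetic_genome`.
#' @export
place_genes <- function(genome, truth = NULL, genes_per_chrom = 200L,
                        gene_density_ratio = 3, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (ci in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$name[ci]
    len <- genome$chromosomes$length[ci]
    glen <- as.integer(round(runif(genes_per_chrom, 5000, 50000)))
    if (is.null(truth)) {
      starts <- as.integer(floor(runif(genes_per_chrom, 0, len - max(glen))))
    } else {
      comp <- truth$compartments[truth$compartments$chrom == ch, ]
      w <- ifelse(comp$label == "A", gene_density_ratio, 1)
      bin <- sample(nrow(comp), genes_per_chrom, replace = TRUE, prob = w)
      starts <- as.integer(comp$start[bin] +
                             floor(runif(genes_per_chrom, 0,
                                         comp$end[bin] - comp$start[bin])))
      starts <- pmin(starts, len - glen - 1L)
    }
    strand <- sample(c("+", "-"), genes_per_chrom, replace = TRUE)
    for (k in seq_len(genes_per_chrom)) {
      nex <- sample(1:6, 1)
      blk <- gene_blocks(glen[k], nex)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = starts[k], end = starts[k] + glen[k],
        name = sprintf("gene_%s_%03d", ch, k), score = 0L,
        strand = strand[k], thickStart = starts[k],
        thickEnd = starts[k] + glen[k], itemRgb = "0",
        blockCount = nex,
        blockSizes = paste(blk$sizes, collapse = ","),
        blockStarts = paste(blk$starts, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  genome$genes <- genes
  genome
}

# split a gene of length len into nex exons separated by introns;
# first block starts at 0 and last block ends at len (BED12 contract)
gene_blocks <- function(len, nex) {
  if (nex == 1L) return(list(sizes = len, starts = 0L))
  nseg <- 2L * nex - 1L
  w <- runif(nseg, 0.5, 1.5)
  seg <- pmax(floor(len * w / sum(w)), 10L)
  seg[nseg] <- len - sum(seg[-nseg])
  starts <- cumsum(c(0L, seg[-nseg]))
  ex <- seq(1L, nseg, by = 2L)
  list(sizes = as.integer(seg[ex]), starts = as.integer(starts[ex]))
}

# TSS/TES in 0-based bp by strand
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end - 1L)
gene_tes <- function(genes) ifelse(genes$strand == "+", genes$end - 1L, genes$start)

#' Planted ground truth for the synthetic genome
#'
#' Draws the structures the pipeline is later asked to recover: alternating
#' A/B compartment blocks (1-3 Mb) labelled per 500-kb bin, a tiling of TAD
#' domains (0.8-1.6 Mb, i.e. 20-40 bins at 40 kb, at least 15 per 20-Mb
#' chromosome), insulated boundaries at the internal domain edges (retention
#' factor `f = insulation`), hyper-/hypo-methylated regions with the
#' configured fold change, and a lognormal multiplicative per-bin bias stored
#' at 20 kb (coarser resolutions use the geometric mean of member bins).
#'
#' @param genome a [simulate_genome()] object.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return object of class `synthetic_truth` with data.frame fields
#'   `compartments` (500-kb bins, `label` in A/B), `domains`, `boundaries`
#'   (`pos` in bp, insulation `f`), `dmrs` (`direction`, `fold`), `bias`
#'   (20-kb bins) and `diff_blocks` (empty until [plant_diff_block()]).
#' @export
simulate_truth <- function(genome, config = sim_config(), seed = 1L) {
  set.seed(seed)
  comp <- list(); doms <- list(); bnds <- list(); bias <- list()
  for (ci in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$name[ci]
    len <- genome$chromosomes$length[ci]
    nb <- len %/% COMPARTMENT_RES
    lab <- character(0)
    cur <- sample(c("A", "B"), 1)
    while (length(lab) < nb) {
      lab <- c(lab, rep(cur, sample(2:6, 1)))
      cur <- if (cur == "A") "B" else "A"
    }
    lab <- lab[seq_len(nb)]
    comp[[ch]] <- data.frame(chrom = ch,
                             start = (seq_len(nb) - 1L) * COMPARTMENT_RES,
                             end = seq_len(nb) * COMPARTMENT_RES,
                             label = lab, stringsAsFactors = FALSE)
    ntb <- len %/% TAD_RES
    sizes <- integer(0)
    while (sum(sizes) < ntb) sizes <- c(sizes, sample(20:40, 1))
    sizes[length(sizes)] <- ntb - sum(sizes[-length(sizes)])
    if (sizes[length(sizes)] < 10L) {
      sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] + sizes[length(sizes)]
      sizes <- sizes[-length(sizes)]
    }
    edges <- cumsum(c(0L, sizes)) * TAD_RES
    doms[[ch]] <- data.frame(chrom = ch, start = edges[-length(edges)],
                             end = edges[-1], stringsAsFactors = FALSE)
    inner <- edges[-c(1, length(edges))]
    bnds[[ch]] <- data.frame(chrom = ch, pos = inner,
                             f = rep(config$insulation, length(inner)),
                             stringsAsFactors = FALSE)
    n20 <- len %/% 20000L
    bias[[ch]] <- data.frame(chrom = ch, start = (seq_len(n20) - 1L) * 20000L,
                             end = seq_len(n20) * 20000L,
                             bias = if (config$bias_sd > 0)
                               rlnorm(n20, 0, config$bias_sd) else rep(1, n20),
                             stringsAsFactors = FALSE)
  }
  dmrs <- plant_dmrs(genome, config)
  structure(list(compartments = do.call(rbind, comp),
                 domains = do.call(rbind, doms),
                 boundaries = do.call(rbind, bnds),
                 dmrs = dmrs,
                 bias = do.call(rbind, bias),
                 diff_blocks = data.frame(chrom = character(), start = integer(),
                                          end = integer(), fold = numeric()),
                 seed = seed),
            class = "synthetic_truth")
}

plant_dmrs <- function(genome, config) {
  n <- config$n_hyper + config$n_hypo
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), fold = numeric()))
  w <- config$dmr_width
  stopifnot(w %% config$medip_window == 0)
  placed <- list()
  for (k in seq_len(n)) {
    repeat {
      ci <- sample(nrow(genome$chromosomes), 1)
      len <- genome$chromosomes$length[ci]
      start <- sample.int(len %/% config$medip_window - w %/% config$medip_window, 1) *
        config$medip_window
      ok <- TRUE
      for (p in placed)
        if (p$chrom == genome$chromosomes$name[ci] &&
            start < p$end + 10000 && start + w > p$start - 10000) ok <- FALSE
      if (ok) break
    }
    placed[[k]] <- list(chrom = genome$chromosomes$name[ci],
                        start = start, end = start + w)
  }
  df <- do.call(rbind, lapply(placed, as.data.frame))
  df$direction <- c(rep("hyper", config$n_hyper), rep("hypo", config$n_hypo))
  df$fold <- config$dmr_fold_change
  df$chrom <- as.character(df$chrom)
  df[order(df$chrom, df$start), ]
}

#' Derive a treated-condition truth
#'
#' `switch_compartments()` flips the planted compartment label of a chosen
#' fraction of 500-kb bins from A to B (and optionally B to A), flipping
#' contiguous segments taken from existing blocks so the checkerboard
#' structure stays megabase-scaled. `plant_diff_block()` records a genomic
#' block whose within-block contact intensity is multiplied by `fold` when a
#' contact map is simulated from the returned truth (the planted differential
#' interactions of the treated condition).
#'
#' @param truth a [simulate_truth()] object.
#' @param frac_ab,frac_ba fractions of all 500-kb bins to switch A to B and
#'   B to A.
#' @param seed RNG seed.
#' @return a modified `synthetic_truth`.
#' @export
switch_compartments <- function(truth, frac_ab = 0.05, frac_ba = 0, seed = 1L) {
  set.seed(seed)
  comp <- truth$compartments
  for (dir in c("AB", "BA")) {
    frac <- if (dir == "AB") frac_ab else frac_ba
    from <- if (dir == "AB") "A" else "B"
    k <- round(frac * nrow(comp))
    if (k == 0) next
    r <- rle(paste(comp$chrom, comp$label))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    blocks <- which(grepl(paste0(" ", from, "$"), r$values))
    blocks <- sample(blocks)
    flip <- integer(0)
    for (b in blocks) {
      if (length(flip) >= k) break
      take <- min(r$lengths[b], k - length(flip))
      flip <- c(flip, seq(starts[b], starts[b] + take - 1L))
    }
    comp$label[flip] <- if (from == "A") "B" else "A"
  }
  truth$compartments <- comp
  truth
}

#' @rdname switch_compartments
#' @param chrom,start,end block coordinates (bp, 0-based half-open).
#' @param fold within-block intensity multiplier.
#' @export
plant_diff_block <- function(truth, chrom, start, end, fold) {
  truth$diff_blocks <- rbind(truth$diff_blocks,
                             data.frame(chrom = chrom, start = start,
                                        end = end, fold = fold))
  truth
}

check_alignment <- function(truth, resolution) {
  grid <- min(resolution, TAD_RES)
  iv <- rbind(truth$domains[, c("chrom", "start", "end")],
              data.frame(chrom = truth$boundaries$chrom,
                         start = truth$boundaries$pos,
                         end = truth$boundaries$pos))
  bad <- which(iv$start %% grid != 0 | iv$end %% grid != 0)
  if (length(bad))
    stop_named("simulate",
               sprintf("truth interval %s:%d-%d is not aligned to %d bp",
                       iv$chrom[bad[1]], iv$start[bad[1]], iv$end[bad[1]], grid))
  invisible(TRUE)
}

# per-bin multiplicative bias at the requested resolution
# (geometric mean of the 20-kb master bias over each bin)
bias_at_resolution <- function(truth, chrom, n, resolution) {
  b20 <- truth$bias$bias[truth$bias$chrom == chrom]
  if (resolution == 20000L) return(b20[seq_len(n)])
  if (resolution > 20000L) {
    grp <- rep(seq_len(n), each = resolution %/% 20000L)[seq_along(b20)]
    return(as.numeric(exp(tapply(log(b20), grp, mean)))[seq_len(n)])
  }
  rep(b20, each = 20000L %/% resolution)[seq_len(n)]
}

#' Expected contact intensity table
#'
#' The noise-free generative intensity of the contact-map simulator: for bins
#' i, j of one chromosome,
#' `lambda_ij = depth_scale * s^-alpha * c_ij * t_ij * f_ij * b_i * b_j`,
#' where `s` is the bin-centre distance in bins (the diagonal uses the fixed
#' `diag_intensity` instead of the singular `s^-alpha`), `c_ij` is
#' `1 + delta` for same-compartment pairs and `1 - delta` otherwise, `t_ij`
#' is `gamma` when both bin midpoints fall in the same planted domain,
#' `f_ij` is the product of the insulation factors of all planted boundaries
#' strictly between the two bin centres, `b` is the planted bias vector, and
#' the global scale is set so the expected total count over all cis pairs
#' (upper triangle including the diagonal) equals `sequencing_depth`.
#' Pairs with both bins inside a planted differential block are additionally
#' multiplied by the block's fold change.
#'
#' Structures are planted only at resolutions that resolve them: the domain
#' enrichment `t_ij` and boundary insulation `f_ij` are applied when the
#' resolution is at or below the 40-kb domain grid, and skipped at coarser
#' (compartment-scale) resolutions, where 0.8-1.6 Mb domains span only 2-3
#' bins and the per-crossed-boundary product would otherwise compound into
#' an unphysical long-range cutoff (real sub-megabase insulation does not
#' suppress compartmental contacts at 10 Mb).
#'
#' @inheritParams simulate_truth
#' @param resolution bin size in bp.
#' @return named list of per-chromosome intensity matrices.
#' @export
expected_lambda <- function(genome, truth, config, resolution) {
  check_alignment(truth, resolution)
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  if (any(lens %% resolution != 0))
    stop_named("simulate", "resolution must divide all chromosome lengths")
  lam <- list()
  for (ch in names(lens)) {
    n <- as.integer(lens[[ch]] %/% resolution)
    centers <- (seq_len(n) - 0.5) * resolution
    s <- abs(outer(seq_len(n), seq_len(n), "-"))
    decay <- ifelse(s == 0, config$diag_intensity, s^(-config$decay_exponent))
    comp <- truth$compartments[truth$compartments$chrom == ch, ]
    lab <- comp$label[pmin(floor(centers / COMPARTMENT_RES) + 1L, nrow(comp))]
    cfac <- ifelse(outer(lab, lab, "=="),
                   1 + config$compartment_contrast,
                   1 - config$compartment_contrast)
    if (resolution <= TAD_RES) {
      dom <- truth$domains[truth$domains$chrom == ch, ]
      didx <- point_in_interval(rep(ch, n), floor(centers), dom)
      tfac <- matrix(1, n, n)
      same <- outer(didx, didx, function(a, b) !is.na(a) & !is.na(b) & a == b)
      tfac[same] <- config$tad_enrichment
      bd <- truth$boundaries[truth$boundaries$chrom == ch, ]
      cum <- if (nrow(bd)) {
        vapply(centers, function(p) sum(log(bd$f[bd$pos < p])), numeric(1))
      } else rep(0, n)
      ffac <- exp(-abs(outer(cum, cum, "-")))
    } else {
      tfac <- 1
      ffac <- 1
    }
    b <- bias_at_resolution(truth, ch, n, resolution)
    L <- decay * cfac * tfac * ffac * outer(b, b)
    if (nrow(truth$diff_blocks)) {
      db <- truth$diff_blocks[truth$diff_blocks$chrom == ch, ]
      for (r in seq_len(nrow(db))) {
        inb <- centers >= db$start[r] & centers < db$end[r]
        L[inb, inb] <- L[inb, inb] * db$fold[r]
      }
    }
    lam[[ch]] <- L
  }
  tot <- sum(vapply(lam, function(L) sum(L[upper.tri(L, diag = TRUE)]), numeric(1)))
  lapply(lam, function(L) L * config$sequencing_depth / tot)
}

#' Simulate a cis contact map
#'
#' Draws a raw contact matrix with independent Poisson counts around the
#' [expected_lambda()] intensity: upper-triangle entries are sampled and
#' mirrored so the matrix is exactly symmetric. Identical genome, truth,
#' config, resolution and seed give byte-identical output.
#'
#' @inheritParams expected_lambda
#' @param seed RNG seed (use a different seed per replicate).
#' @return a [contact_matrix()] with a raw layer.
#' @export
simulate_contact_map <- function(genome, truth, config, resolution, seed = 1L) {
  lam <- expected_lambda(genome, truth, config, resolution)
  set.seed(seed)
  mats <- lapply(lam, function(L) {
    n <- nrow(L)
    ut <- upper.tri(L, diag = TRUE)
    M <- matrix(0, n, n)
    M[ut] <- rpois(sum(ut), L[ut])
    M <- M + t(M)
    diag(M) <- diag(M) / 2
    M
  })
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  contact_matrix(bin_table(lens, resolution), mats)
}

#' Simulate MeDIP methylation tracks
#'
#' Window counts for two conditions with replicates. The expected intensity
#' is flat at baseline, multiplied near each gene by a Gaussian TSS dip
#' (level `tss_dip` at the TSS, s.d. 1 kb) and a Gaussian TES rise (level
#' `tes_rise`, s.d. 2 kb); in the treated condition only, windows inside
#' planted DMRs are multiplied by the DMR fold change (hyper) or its inverse
#' (hypo). Each replicate's expected total equals `medip_depth`; counts are
#' Poisson.
#'
#' @inheritParams expected_lambda
#' @param window counting window in bp (must divide chromosome lengths).
#' @param seed RNG seed.
#' @return object of class `methylation_track`: list with `windows`
#'   (data.frame `chrom`, `start`, `end`), `counts` (windows x samples
#'   integer matrix), `condition` and `replicate` per sample, `lib_size`, and
#'   `window`.
#' @export
simulate_medip_tracks <- function(genome, truth, config,
                                  window = config$medip_window, seed = 1L) {
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  if (any(lens %% window != 0))
    stop_named("simulate", "window must divide all chromosome lengths")
  wins <- list(); base <- list()
  for (ch in names(lens)) {
    n <- as.integer(lens[[ch]] %/% window)
    centers <- (seq_len(n) - 0.5) * window
    mu <- rep(1, n)
    genes <- genome$genes[genome$genes$chrom == ch, ]
    if (nrow(genes)) {
      tss <- gene_tss(genes); tes <- gene_tes(genes)
      for (k in seq_len(nrow(genes))) {
        near <- which(abs(centers - tss[k]) < 5000)
        mu[near] <- mu[near] *
          (1 - (1 - config$tss_dip) * exp(-((centers[near] - tss[k])^2) / (2 * 1000^2)))
        near <- which(abs(centers - tes[k]) < 10000)
        mu[near] <- mu[near] *
          (1 + (config$tes_rise - 1) * exp(-((centers[near] - tes[k])^2) / (2 * 2000^2)))
      }
    }
    wins[[ch]] <- data.frame(chrom = ch, start = (seq_len(n) - 1L) * window,
                             end = seq_len(n) * window, stringsAsFactors = FALSE)
    base[[ch]] <- mu
  }
  windows <- do.call(rbind, wins)
  mu_ctrl <- unlist(base, use.names = FALSE)
  mu_trt <- mu_ctrl
  if (nrow(truth$dmrs)) {
    centers <- (windows$start + windows$end) / 2
    hit <- point_in_interval(windows$chrom, floor(centers), truth$dmrs)
    inside <- !is.na(hit)
    fold <- ifelse(truth$dmrs$direction[hit[inside]] == "hyper",
                   truth$dmrs$fold[hit[inside]],
                   1 / truth$dmrs$fold[hit[inside]])
    mu_trt[inside] <- mu_trt[inside] * fold
  }
  mu_ctrl <- mu_ctrl * config$medip_depth / sum(mu_ctrl)
  mu_trt <- mu_trt * config$medip_depth / sum(mu_trt)
  set.seed(seed)
  R <- config$replicate_count
  counts <- matrix(0L, nrow(windows), 2L * R)
  cond <- c(rep("control", R), rep("treated", R))
  repl <- c(seq_len(R), seq_len(R))
  for (r in seq_len(R)) counts[, r] <- rpois(nrow(windows), mu_ctrl)
  for (r in seq_len(R)) counts[, R + r] <- rpois(nrow(windows), mu_trt)
  colnames(counts) <- paste(cond, repl, sep = "_")
  structure(list(windows = windows, counts = counts, condition = cond,
                 replicate = repl, lib_size = colSums(counts),
                 window = as.integer(window)),
            class = "methylation_track")
}

#' Simulate ChIP-seq peaks
#'
#' Places peaks of three classes: `boundary` peaks with summits within one
#' 40-kb bin of a planted TAD boundary (Gaussian offset, s.d.
#' `peak_pos_sd`, truncated), `promoter` peaks with summits within 1 kb of a
#' gene TSS, and `random` peaks uniform over the genome. Widths are uniform
#' over `peak_width`. Every placement is recorded in the returned truth
#' table.
#'
#' @inheritParams expected_lambda
#' @param seed RNG seed.
#' @return list with `peaks` (narrowPeak data.frame) and `truth` (data.frame
#'   `chrom`, `start`, `end`, `summit` bp, `class`).
#' @export
simulate_peaks <- function(genome, truth, config, seed = 1L) {
  set.seed(seed)
  cnt <- config$peak_count
  stopifnot(all(c("boundary", "promoter", "random") %in% names(cnt)))
  if (cnt[["boundary"]] > 0 && nrow(truth$boundaries) == 0L)
    stop_named("simulate", "boundary-class peaks requested but truth has no boundaries")
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  rows <- list()
  add <- function(chrom, summit, class) {
    w <- as.integer(round(runif(1, config$peak_width[1], config$peak_width[2])))
    start <- max(0L, as.integer(summit - w %/% 2L))
    end <- min(as.integer(lens[[chrom]]), start + w)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, class = class,
      summit = as.integer(summit), stringsAsFactors = FALSE)
  }
  for (k in seq_len(cnt[["boundary"]])) {
    b <- truth$boundaries[sample(nrow(truth$boundaries), 1), ]
    off <- round(rnorm(1, 0, config$peak_pos_sd))
    off <- max(min(off, TAD_RES - 1), -(TAD_RES - 1))
    add(b$chrom, min(max(b$pos + off, 1), lens[[b$chrom]] - 1), "boundary")
  }
  if (cnt[["promoter"]] > 0 && nrow(genome$genes) == 0L)
    stop_named("simulate", "promoter-class peaks requested but genome has no genes")
  for (k in seq_len(cnt[["promoter"]])) {
    g <- genome$genes[sample(nrow(genome$genes), 1), ]
    tss <- gene_tss(g)
    add(g$chrom, min(max(tss + round(runif(1, -1000, 1000)), 1),
                     lens[[g$chrom]] - 1), "promoter")
  }
  for (k in seq_len(cnt[["random"]])) {
    ci <- sample(length(lens), 1)
    add(names(lens)[ci], sample.int(lens[[ci]] - 1L, 1), "random")
  }
  tr <- do.call(rbind, rows)
  if (is.null(tr))
    tr <- data.frame(chrom = character(), start = integer(), end = integer(),
                     class = character(), summit = integer())
  o <- order(tr$chrom, tr$start)
  tr <- tr[o, ]; rownames(tr) <- NULL
  peaks <- data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                      name = sprintf("peak_%04d", seq_len(nrow(tr))),
                      score = if (nrow(tr)) as.integer(round(runif(nrow(tr), 200, 1000))) else integer(),
                      strand = rep(".", nrow(tr)),
                      signalValue = if (nrow(tr)) round(runif(nrow(tr), 5, 50), 3) else numeric(),
                      pValue = rep(-1, nrow(tr)), qValue = rep(-1, nrow(tr)),
                      summit = tr$summit - tr$start,
                      stringsAsFactors = FALSE)
  list(peaks = peaks, truth = tr)
}

#' Write / read the planted truth as plain-text files
#'
#' Serialises every field of a `synthetic_truth` to standard text formats
#' (BED for intervals, bedGraph for the bias) so that the ground truth
#' round-trips losslessly through the same readers the pipeline uses.
#'
#' @param truth a [simulate_truth()] object.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp <- truth$compartments
  write_bed(data.frame(comp$chrom, comp$start, comp$end, comp$label),
            file.path(dir, "truth_compartments.bed"))
  write_bed(truth$domains[, c("chrom", "start", "end")],
            file.path(dir, "truth_domains.bed"))
  bd <- truth$boundaries
  write_bed(data.frame(bd$chrom, bd$pos, bd$pos + 1L, "boundary", bd$f),
            file.path(dir, "truth_boundaries.bed"))
  dm <- truth$dmrs
  write_bed(data.frame(dm$chrom, dm$start, dm$end, dm$direction, dm$fold),
            file.path(dir, "truth_dmrs.bed"))
  write_bedgraph(data.frame(chrom = truth$bias$chrom, start = truth$bias$start,
                            end = truth$bias$end, value = truth$bias$bias),
                 file.path(dir, "truth_bias.bedgraph"))
  db <- truth$diff_blocks
  write_bed(data.frame(db$chrom, db$start, db$end, db$fold),
            file.path(dir, "truth_diff_blocks.bed"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  comp <- read_bed(file.path(dir, "truth_compartments.bed"), "label")
  bd <- read_bed(file.path(dir, "truth_boundaries.bed"), c("name", "f"))
  dm <- read_bed(file.path(dir, "truth_dmrs.bed"), c("direction", "fold"))
  bias <- read_bedgraph(file.path(dir, "truth_bias.bedgraph"))
  db <- read_bed(file.path(dir, "truth_diff_blocks.bed"), "fold")
  structure(list(compartments = comp,
                 domains = read_bed(file.path(dir, "truth_domains.bed")),
                 boundaries = data.frame(chrom = bd$chrom, pos = bd$start,
                                         f = as.numeric(bd$f),
                                         stringsAsFactors = FALSE),
                 dmrs = dm,
                 bias = data.frame(chrom = bias$chrom, start = bias$start,
                                   end = bias$end, bias = bias$value,
                                   stringsAsFactors = FALSE),
                 diff_blocks = db,
                 seed = NA_integer_),
            class = "synthetic_truth")
}
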