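flat_track <- function(n_windows = 2000L, window = 1000L, value = 50L,
                       chrom = "chr1") {
  w <- data.frame(chrom = rep(chrom, n_windows),
                  start = (seq_len(n_windows) - 1L) * window,
                  end = seq_len(n_windows) * window, stringsAsFactors = FALSE)
  counts <- matrix(value, n_windows, 4)
  methylation_track(w, counts, c("control", "control", "treated", "treated"),
                    c(1L, 2L, 1L, 2L))
}

one_gene <- function(start, end, strand, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, name = "g1", score = 0L,
             strand = strand, thickStart = start, thickEnd = end,
             itemRgb = "0", blockCount = 1L,
             blockSizes = as.character(end - start), blockStarts = "0",
             stringsAsFactors = FALSE)
}

test_that("a uniform track gives a flat metagene profile, invariant to library size", {
  tr <- flat_track()
  g <- one_gene(5e5, 6e5, "+")
  prof <- metagene_profile(tr, g)
  expect_equal(nrow(prof), 200L)
  expect_lt(diff(range(prof$signal)), 1e-9 * mean(prof$signal))
  tr2 <- tr
  tr2$counts[, 1] <- tr2$counts[, 1] * 10L
  tr2$lib_size <- colSums(tr2$counts)
  prof2 <- metagene_profile(tr2, g)
  expect_equal(prof2$signal, prof$signal, tolerance = 1e-12)
})

test_that("minus-strand genes mirror the plus-strand computation", {
  set.seed(11)
  tr <- flat_track()
  tr$counts[, ] <- rpois(length(tr$counts), 50)
  tr$lib_size <- colSums(tr$counts)
  gp <- one_gene(5e5, 6e5, "+")
  gm <- one_gene(5e5, 6e5, "-")
  pp <- metagene_profile(tr, gp)
  pm <- metagene_profile(tr, gm)
  expect_equal(pm$signal, rev(pp$signal), tolerance = 1e-12)
})

test_that("simulated tracks dip at the TSS and rise at the TES", {
  cfg <- sim_config()
  g <- simulate_genome(n_chrom = 1L, chrom_length = 8e6, genes_per_chrom = 120L,
                       seed = 3)
  tr <- simulate_truth(g, cfg, seed = 3)
  md <- simulate_medip_tracks(g, tr, cfg, seed = 4)
  prof <- metagene_profile(md, g$genes, condition = "control")
  expect_true(which.min(prof$signal) %in% 45:60)
  expect_true(which.max(prof$signal) %in% 140:155)
})

test_that("identical conditions yield zero DMRs", {
  tr <- flat_track()
  expect_equal(nrow(call_dmrs(tr)), 0L)
})

test_that("planted DMRs are recovered with the right direction, and labels swap cleanly", {
  cfg <- sim_config(n_hyper = 8L, n_hypo = 4L, medip_depth = 2e6)
  g <- simulate_genome(n_chrom = 1L, chrom_length = 8e6, genes_per_chrom = 0L,
                       seed = 5)
  tr <- simulate_truth(g, cfg, seed = 5)
  md <- simulate_medip_tracks(g, tr, cfg, seed = 6)
  dmrs <- call_dmrs(md)
  hits <- brute_overlap_counts(tr$dmrs, dmrs)
  expect_gte(mean(hits >= 1), 0.9)                       # recall
  expect_gte(mean(brute_overlap_counts(dmrs, tr$dmrs) >= 1), 0.9)  # precision
  idx <- brute_point_in(dmrs$chrom, (dmrs$start + dmrs$end) %/% 2L, tr$dmrs)
  expect_true(all(dmrs$direction[!is.na(idx)] == tr$dmrs$direction[idx[!is.na(idx)]]))
  # swapping condition labels flips every direction, coordinates unchanged
  md_sw <- md
  md_sw$condition <- ifelse(md$condition == "control", "treated", "control")
  dmrs_sw <- call_dmrs(md_sw)
  expect_equal(dmrs_sw$start, dmrs$start)
  expect_equal(dmrs_sw$end, dmrs$end)
  expect_true(all(dmrs_sw$direction != dmrs$direction))
  expect_equal(dmrs_sw$log2fc, -dmrs$log2fc, tolerance = 1e-12)
})

test_that("adjacent significant windows of opposite direction are not merged", {
  tr <- flat_track(n_windows = 100L, value = 100L)
  # two adjacent windows, one strongly up, one strongly down in treated
  tr$counts[50, 3:4] <- 600L
  tr$counts[51, 3:4] <- 12L
  tr$lib_size <- colSums(tr$counts)
  dmrs <- call_dmrs(tr)
  expect_equal(nrow(dmrs), 2L)
  expect_setequal(dmrs$direction, c("hyper", "hypo"))
})

test_that("DMR recall is monotone in fold change", {
  g <- simulate_genome(n_chrom = 1L, chrom_length = 8e6, genes_per_chrom = 0L,
                       seed = 7)
  rec <- sapply(c(2, 4, 8), function(fold) {
    cfg <- sim_config(n_hyper = 8L, n_hypo = 4L, dmr_fold_change = fold,
                      medip_depth = 5e5)
    tr <- simulate_truth(g, cfg, seed = 7)
    md <- simulate_medip_tracks(g, tr, cfg, seed = 8)
    mean(brute_overlap_counts(tr$dmrs, call_dmrs(md)) >= 1)
  })
  expect_true(all(diff(rec) >= 0))
})

test_that("DMR feature annotation follows the precedence rule and the brute-force scan", {
  genes <- rbind(one_gene(10000, 30000, "+"),
                 one_gene(50000, 80000, "-"))
  genes$name <- c("g1", "g2")
  genes$blockCount <- c(2L, 1L)
  genes$blockSizes <- c("5000,5000", "30000")
  genes$blockStarts <- c("0,15000", "0")
  # midpoint at the TSS -> promoter
  d1 <- data.frame(chrom = "chr1", start = 9900, end = 10100)
  expect_equal(annotate_dmrs(d1, genes)$feature, "promoter")
  # inside an exon but within 2 kb of a TSS -> promoter wins
  d2 <- data.frame(chrom = "chr1", start = 11000, end = 11200)
  expect_equal(annotate_dmrs(d2, genes)$feature, "promoter")
  # exon beyond the promoter window
  d3 <- data.frame(chrom = "chr1", start = 25500, end = 25700)
  expect_equal(annotate_dmrs(d3, genes)$feature, "exon")
  # intron
  d4 <- data.frame(chrom = "chr1", start = 17000, end = 17500)
  expect_equal(annotate_dmrs(d4, genes)$feature, "intron")
  # composition on a random fixture equals the brute-force midpoint rule
  set.seed(13)
  dm <- random_intervals(30, seed = 13, max_len = 2000, genome_bp = 1e5)
  dm$chrom <- "chr1"
  ann <- annotate_dmrs(dm, genes)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  prom <- data.frame(chrom = genes$chrom, start = tss - 2000L, end = tss + 2000L)
  ex <- data.frame(chrom = rep("chr1", 3),
                   start = c(10000, 25000, 50000),
                   end = c(15000, 30000, 80000))
  mid <- (dm$start + dm$end) %/% 2L
  oracle <- ifelse(!is.na(brute_point_in(dm$chrom, mid, prom)), "promoter",
                   ifelse(!is.na(brute_point_in(dm$chrom, mid, ex)), "exon",
                          ifelse(!is.na(brute_point_in(dm$chrom, mid,
                                                       genes[, c("chrom", "start", "end")])),
                                 "intron", "intergenic")))
  expect_identical(ann$feature, oracle)
  expect_equal(sum(ann$composition), 1)
})

test_that("DMR/peak overlap fractions match brute force at the fixed points", {
  dm <- data.frame(chrom = "chr1", start = c(0, 10000, 20000),
                   end = c(1000, 11000, 21000))
  pk_far <- data.frame(chrom = "chr1", start = 5e5, end = 5e5 + 100, name = "p",
                       score = 0L, strand = ".", signalValue = 1, pValue = -1,
                       qValue = -1, summit = -1L)
  expect_equal(unname(dmr_peak_overlap(dm, pk_far)["fraction"]), 0)
  pk_all <- data.frame(chrom = "chr1", start = 0L, end = 30000L, name = "p",
                       score = 0L, strand = ".", signalValue = 1, pValue = -1,
                       qValue = -1, summit = -1L)
  expect_equal(unname(dmr_peak_overlap(dm, pk_all)["fraction"]), 1)
  pk <- random_intervals(40, seed = 17, max_len = 1500, genome_bp = 3e4)
  pk$chrom <- "chr1"
  pk <- data.frame(pk, name = "p", score = 0L, strand = ".", signalValue = 1,
                   pValue = -1, qValue = -1, summit = -1L)
  expect_equal(unname(dmr_peak_overlap(dm, pk)["dmrs_overlapping"]),
               sum(brute_overlap_counts(dm, pk) >= 1))
})
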