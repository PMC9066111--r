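test_that("contact-map simulation is deterministic, symmetric and depth-conserving", {
  s <- small_sim(seed = 11)
  cm1 <- simulate_contact_map(s$genome, s$truth, s$cfg, 40000, seed = 5)
  cm2 <- simulate_contact_map(s$genome, s$truth, s$cfg, 40000, seed = 5)
  expect_identical(cm1$layers$raw, cm2$layers$raw)
  M <- cm1$layers$raw$chr1
  expect_identical(M, t(M))
  expect_true(all(M == floor(M)) && all(M >= 0))
  total <- sum(M[upper.tri(M, diag = TRUE)])
  expect_lt(abs(total - s$cfg$sequencing_depth), 3 * sqrt(s$cfg$sequencing_depth))
  # byte-identical files from identical seeds
  d <- withr::local_tempdir()
  write_matrix(cm1, file.path(d, "a.matrix"))
  write_matrix(cm2, file.path(d, "b.matrix"))
  expect_identical(readLines(file.path(d, "a.matrix")),
                   readLines(file.path(d, "b.matrix")))
})

test_that("the generative intensity matches the naive per-pair oracle", {
  cfg <- sim_config(sequencing_depth = 1e5)
  g <- simulate_genome(n_chrom = 1L, chrom_length = 2e6, genes_per_chrom = 0L)
  tr <- simulate_truth(g, cfg, seed = 3)
  lam <- expected_lambda(g, tr, cfg, 40000)
  oracle <- brute_lambda(g, tr, cfg, 40000)
  expect_equal(lam$chr1, oracle$chr1, tolerance = 1e-12)
  # and at compartment scale, where sub-bin domain structure is not planted
  lam5 <- expected_lambda(g, tr, cfg, 500000)
  oracle5 <- brute_lambda(g, tr, cfg, 500000)
  expect_equal(lam5$chr1, oracle5$chr1, tolerance = 1e-12)
})

test_that("structureless maps have flat distance bands up to Poisson error", {
  cfg <- sim_config(tad_enrichment = 1, insulation = 1, compartment_contrast = 0,
                    bias_sd = 0, sequencing_depth = 2e6)
  g <- simulate_genome(n_chrom = 1L, chrom_length = 8e6, genes_per_chrom = 0L)
  tr <- simulate_truth(g, cfg, seed = 2)
  cm <- simulate_contact_map(g, tr, cfg, 40000, seed = 6)
  lam <- expected_lambda(g, tr, cfg, 40000)
  M <- cm$layers$raw$chr1
  n <- nrow(M)
  for (s_ in c(1, 5, 20)) {
    idx <- cbind(seq_len(n - s_), seq_len(n - s_) + s_)
    m_obs <- mean(M[idx])
    m_exp <- mean(lam$chr1[idx])
    se <- sqrt(m_exp / (n - s_))
    expect_lt(abs(m_obs - m_exp), 4 * se)
  }
})

test_that("domain enrichment gamma is recovered against the analytic table", {
  cfg <- sim_config(tad_enrichment = 3, insulation = 1, compartment_contrast = 0,
                    bias_sd = 0, sequencing_depth = 5e6)
  g <- simulate_genome(n_chrom = 1L, chrom_length = 8e6, genes_per_chrom = 0L)
  tr <- simulate_truth(g, cfg, seed = 2)
  # a single planted 2-Mb domain, nothing else
  tr$domains <- data.frame(chrom = "chr1", start = 3e6, end = 5e6)
  tr$boundaries <- tr$boundaries[0, ]
  cm <- simulate_contact_map(g, tr, cfg, 40000, seed = 12)
  M <- cm$layers$raw$chr1
  n <- nrow(M)
  dom_bins <- 76:125                      # midpoints inside [3, 5) Mb
  s_ <- 10L
  idx_all <- cbind(seq_len(n - s_), seq_len(n - s_) + s_)
  inside <- idx_all[, 1] >= min(dom_bins) & idx_all[, 2] <= max(dom_bins)
  ratio <- mean(M[idx_all[inside, , drop = FALSE]]) /
    mean(M[idx_all[!inside, , drop = FALSE]])
  expect_equal(ratio, 3, tolerance = 0.1)
})

test_that("replicates agree per distance band within sampling error", {
  s <- small_sim(seed = 13, sequencing_depth = 2e6)
  cm1 <- simulate_contact_map(s$genome, s$truth, s$cfg, 40000, seed = 21)
  cm2 <- simulate_contact_map(s$genome, s$truth, s$cfg, 40000, seed = 22)
  M1 <- cm1$layers$raw$chr1; M2 <- cm2$layers$raw$chr1
  n <- nrow(M1)
  for (s_ in c(1, 3, 10)) {
    idx <- cbind(seq_len(n - s_), seq_len(n - s_) + s_)
    m1 <- mean(M1[idx]); m2 <- mean(M2[idx])
    se <- sqrt((m1 + m2) / (n - s_))
    expect_lt(abs(m1 - m2), 3 * se)
  }
})

test_that("misaligned truth intervals are rejected with the offending interval", {
  s <- small_sim(seed = 1)
  s$truth$domains$start[2] <- s$truth$domains$start[2] + 13L
  expect_error(simulate_contact_map(s$genome, s$truth, s$cfg, 40000, seed = 1),
               "chr1:.*not aligned")
})

test_that("MeDIP simulation: flat baseline without genes or DMRs", {
  cfg <- sim_config(n_hyper = 0L, n_hypo = 0L, medip_depth = 1e6)
  g <- simulate_genome(n_chrom = 1L, chrom_length = 4e6, genes_per_chrom = 0L)
  tr <- simulate_truth(g, cfg, seed = 2)
  tr$dmrs <- tr$dmrs[0, ]
  md <- simulate_medip_tracks(g, tr, cfg, seed = 9)
  mu <- 1e6 / nrow(md$windows)
  m <- colMeans(md$counts)
  expect_true(all(abs(m - mu) < 4 * sqrt(mu / nrow(md$windows))))
  # window-to-window variation is Poisson-like around a flat intensity
  v <- apply(md$counts, 2, var)
  expect_true(all(v / m > 0.8 & v / m < 1.2))
})

test_that("a planted hyper DMR shifts the treated/control ratio by its fold change", {
  cfg <- sim_config(n_hyper = 1L, n_hypo = 0L, dmr_fold_change = 4,
                    medip_depth = 4e6)
  g <- simulate_genome(n_chrom = 1L, chrom_length = 4e6, genes_per_chrom = 0L)
  tr <- simulate_truth(g, cfg, seed = 7)
  md <- simulate_medip_tracks(g, tr, cfg, seed = 10)
  inside <- md$windows$start >= tr$dmrs$start & md$windows$end <= tr$dmrs$end &
    md$windows$chrom == tr$dmrs$chrom
  it <- md$condition == "treated"
  ratio <- (sum(md$counts[inside, it]) / sum(md$lib_size[it])) /
    (sum(md$counts[inside, !it]) / sum(md$lib_size[!it]))
  expect_equal(ratio, 4, tolerance = 0.15)
})

test_that("peak simulation respects class counts and boundary placement", {
  s <- small_sim(seed = 4, peak_count = c(boundary = 100L, promoter = 0L, random = 0L))
  pk <- simulate_peaks(s$genome, s$truth, s$cfg, seed = 3)
  expect_equal(nrow(pk$peaks), 100L)
  # every summit within one 40-kb bin of a planted boundary
  ok <- vapply(seq_len(nrow(pk$truth)), function(i) {
    min(abs(pk$truth$summit[i] -
              s$truth$boundaries$pos[s$truth$boundaries$chrom == pk$truth$chrom[i]])) <= 40000
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(pk$peaks$summit >= 0 &
                    pk$peaks$summit < pk$peaks$end - pk$peaks$start))
  # mixed classes: composition matches the config exactly
  g2 <- place_genes(s$genome, truth = s$truth, genes_per_chrom = 50L, seed = 8)
  cfg2 <- sim_config(peak_count = c(boundary = 10L, promoter = 20L, random = 30L))
  pk2 <- simulate_peaks(g2, s$truth, cfg2, seed = 3)
  expect_equal(as.vector(table(pk2$truth$class)[c("boundary", "promoter", "random")]),
               c(10L, 20L, 30L))
  # empty request gives a valid empty narrowPeak body
  cfg3 <- sim_config(peak_count = c(boundary = 0L, promoter = 0L, random = 0L))
  pk3 <- simulate_peaks(s$genome, s$truth, cfg3, seed = 3)
  expect_equal(nrow(pk3$peaks), 0L)
  d <- withr::local_tempdir()
  write_narrowpeak(pk3$peaks, file.path(d, "empty.narrowPeak"))
  expect_equal(nrow(read_narrowpeak(file.path(d, "empty.narrowPeak"))), 0L)
  # boundary peaks without planted boundaries are impossible
  s2 <- small_sim(seed = 4)
  s2$truth$boundaries <- s2$truth$boundaries[0, ]
  expect_error(simulate_peaks(s2$genome, s2$truth, s$cfg, seed = 1),
               "no boundaries")
})

test_that("genome invariants hold: bounds, strand-aware TSS, compartment-weighted genes", {
  s <- small_sim(seed = 6)
  g <- place_genes(s$genome, truth = s$truth, genes_per_chrom = 300L,
                   gene_density_ratio = 3, seed = 2)
  expect_true(all(g$genes$start >= 0))
  expect_true(all(g$genes$end <= 8e6))
  # genes land in A bins roughly 3x as densely as in B bins
  comp <- s$truth$compartments
  ing <- brute_point_in(g$genes$chrom,
                        ifelse(g$genes$strand == "+", g$genes$start, g$genes$end - 1L),
                        comp)
  fa <- mean(comp$label == "A")
  obs_a <- mean(comp$label[ing] == "A")
  exp_a <- 3 * fa / (3 * fa + (1 - fa))
  expect_lt(abs(obs_a - exp_a), 0.1)
})
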