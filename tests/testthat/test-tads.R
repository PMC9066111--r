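balanced_cm <- function(M, res = 40000L, chrom = "chr1") {
  cm <- contact_matrix(bin_table(stats::setNames(nrow(M) * res, chrom), res),
                       stats::setNames(list(round(M)), chrom))
  cm$layers$balanced <- stats::setNames(list(M), chrom)
  cm
}

states_df <- function(states, res = 40000L, chrom = "chr1") {
  n <- length(states)
  data.frame(chrom = rep(chrom, n), start = (seq_len(n) - 1L) * res,
             end = seq_len(n) * res, state = states, stringsAsFactors = FALSE)
}

test_that("directionality index reproduces hand-computed values", {
  # uniform matrix: interior bins have A = B, DI = 0
  M <- matrix(1, 20, 20)
  di <- directionality_index(balanced_cm(M), window = 2e5)
  expect_equal(di$di[6:15], rep(0, 10))
  expect_true(di$partial[1] && di$partial[20] && !di$partial[10])
  # bin with A = 2, B = 8 within a 1-bin window: E = 5, DI = +3.6
  M <- matrix(0, 5, 5)
  M[2, 1] <- M[1, 2] <- 2
  M[2, 3] <- M[3, 2] <- 8
  di <- directionality_index(balanced_cm(M), window = 40000)
  expect_equal(di$di[2], (2 - 5)^2 / 5 + (8 - 5)^2 / 5)
  expect_gt(di$di[2], 0)
  expect_equal(di$A[2], 2); expect_equal(di$B[2], 8); expect_equal(di$E[2], 5)
  # a 20-Mb chromosome at 40 kb yields exactly 500 DI values
  M <- matrix(1, 500, 500)
  expect_equal(nrow(directionality_index(balanced_cm(M))), 500L)
  expect_error(directionality_index(balanced_cm(M), window = 20000), ">=")
})

test_that("reversing bin order negates the DI bin-for-bin", {
  s <- small_sim(seed = 3)
  cm <- ice_balance(simulate_contact_map(s$genome, s$truth, s$cfg, 40000, seed = 4))
  di <- directionality_index(cm)
  M <- cm$layers$balanced$chr1
  n <- nrow(M)
  M0 <- M; M0[is.na(M0)] <- 0
  cmr <- balanced_cm(M0[n:1, n:1])
  cmr$layers$balanced$chr1 <- M[n:1, n:1]
  cmr$mask$chr1 <- rev(cm$mask$chr1)
  dir_ <- directionality_index(cmr)
  expect_equal(dir_$di, -rev(di$di), tolerance = 1e-12)
})

test_that("HMM segmentation recovers clean run structure and is seed-stable", {
  set.seed(8)
  runs <- rep(c(-5, 0, 5, 0), 6)
  x <- unlist(lapply(runs, function(m) rnorm(15, m, 0.5)))
  di <- states_df(rep(NA_integer_, length(x)))
  di$di <- x
  dec1 <- fit_hmm_and_decode(di)
  dec2 <- fit_hmm_and_decode(di)
  expect_identical(dec1$state, dec2$state)
  truth <- unlist(lapply(runs, function(m) rep(2L + sign(m), 15)))
  expect_equal(mean(dec1$state == truth), 1)
  # constant DI: no directional information, everything unbiased
  di0 <- di; di0$di <- rep(0, nrow(di))
  dec0 <- fit_hmm_and_decode(di0)
  expect_true(all(dec0$state == 2L))
})

test_that("domain assembly follows the state machine and the 400-kb rule", {
  res <- 40000L
  # domain = downstream run ... next upstream run; 5-bin (200 kb) gap -> boundary
  st <- c(3, 3, 2, 1, 1, rep(2, 5), 3, 3, 2, 2, 1)
  ts <- assemble_domains(states_df(st))
  expect_equal(nrow(ts$domains), 2L)
  expect_equal(ts$domains$start, c(0, 10) * res)
  expect_equal(ts$domains$end, c(5, 15) * res)
  expect_equal(ts$boundaries$kind, "boundary")
  expect_equal(ts$boundaries$end - ts$boundaries$start, 5L * res)
  # 600-kb gap -> unorganized, excluded from boundary counts
  st <- c(3, 1, rep(2, 15), 3, 1)
  ts <- assemble_domains(states_df(st))
  expect_equal(ts$boundaries$kind, "unorganized")
  # adjacent domains -> 1-bp boundary at the shared edge
  st <- c(3, 3, 1, 3, 3, 1)
  ts <- assemble_domains(states_df(st))
  expect_equal(nrow(ts$domains), 2L)
  expect_equal(ts$boundaries$start, 3L * res)
  expect_equal(ts$boundaries$end, 3L * res + 1L)
  expect_equal(ts$boundaries$kind, "boundary")
  # invariant to flanking unbiased runs; trailing open domains are dropped
  st2 <- c(2, 2, 2, st, 2, 2)
  expect_equal(assemble_domains(states_df(st2))$domains$end -
                 assemble_domains(states_df(st2))$domains$start,
               ts$domains$end - ts$domains$start)
  st3 <- c(st, 3, 3)   # opens but never closes
  expect_equal(nrow(assemble_domains(states_df(st3))$domains), 2L)
  expect_equal(nrow(assemble_domains(states_df(integer(0)))$domains), 0L)
})

test_that("boundary strength is 0 on structureless maps and -log2(f) on the expected map", {
  n <- 60L
  cm <- balanced_cm(matrix(1, n, n))
  cm$layers$oe <- list(chr1 = matrix(1, n, n))
  tads <- as_tad_set(data.frame(chrom = "chr1", start = c(0, 30) * 4e4,
                                end = c(30, 60) * 4e4),
                     data.frame(chrom = "chr1", start = 30L * 4e4,
                                end = 30L * 4e4 + 1L, kind = "boundary"))
  ts <- boundary_strength(cm, tads, w = 10)
  expect_equal(ts$boundaries$S, 0)
  # analytic map with a single isolated boundary of f = 0.5
  for (f in c(0.2, 0.5, 0.8)) {
    Z <- matrix(1, n, n)
    cross <- outer(seq_len(n) <= 30, seq_len(n) > 30, "&")
    Z[cross | t(cross)] <- f
    cm$layers$oe <- list(chr1 = Z)
    ts <- boundary_strength(cm, tads, w = 10)
    expect_equal(ts$boundaries$S, -log2(f), tolerance = 1e-9)
  }
  # boundary too close to the chromosome edge stays unscored
  tads2 <- as_tad_set(tads$domains,
                      data.frame(chrom = "chr1", start = 2L * 4e4,
                                 end = 2L * 4e4 + 1L, kind = "boundary"))
  expect_true(is.na(boundary_strength(cm, tads2, w = 10)$boundaries$S))
})

test_that("intra-TAD means match a brute-force scan and flag degenerate domains", {
  n <- 20L
  set.seed(5)
  Z <- matrix(runif(n * n, 0.5, 2), n, n); Z <- (Z + t(Z)) / 2
  cm <- balanced_cm(matrix(1, n, n))
  cm$layers$oe <- list(chr1 = Z)
  tads <- as_tad_set(data.frame(chrom = "chr1", start = c(0, 5, 18) * 4e4,
                                end = c(5, 18, 20) * 4e4),
                     data.frame(chrom = character(), start = integer(),
                                end = integer(), kind = character()))
  it <- intra_tad_interaction(cm, tads)
  # brute force on the 5-bin domain
  acc <- c()
  for (i in 1:5) for (j in 1:5) if (i < j) acc <- c(acc, Z[i, j])
  expect_equal(it$mean_z[1], mean(acc))
  expect_true(is.na(it$mean_z[3]))   # 2-bin domain skipped
  # structureless: every mean 1, comparison flat
  cm$layers$oe <- list(chr1 = matrix(1, n, n))
  it1 <- intra_tad_interaction(cm, tads)
  expect_equal(it1$mean_z[1:2], c(1, 1))
  cmp <- compare_conditions(it1$mean_z, it1$mean_z)
  expect_equal(cmp$median_diff, 0)
  expect_gt(cmp$p, 0.9)
})

test_that("a planted within-TAD enrichment drop is detected on matched domains", {
  g0 <- simulate_genome(genes_per_chrom = 0L)
  cfg_c <- sim_config(tad_enrichment = 3)
  cfg_t <- sim_config(tad_enrichment = 2)
  tr <- simulate_truth(g0, cfg_c, seed = 2)
  tads <- as_tad_set(tr$domains,
                     data.frame(chrom = character(), start = integer(),
                                end = integer(), kind = character()))
  cm_c <- oe_transform(ice_balance(simulate_contact_map(g0, tr, cfg_c, 40000,
                                                        seed = 61)))
  cm_t <- oe_transform(ice_balance(simulate_contact_map(g0, tr, cfg_t, 40000,
                                                        seed = 62)))
  it_c <- intra_tad_interaction(cm_c, tads)$mean_z
  it_t <- intra_tad_interaction(cm_t, tads)$mean_z
  cmp <- compare_conditions(it_c, it_t, paired = TRUE)
  expect_lt(cmp$median_diff, 0)
  expect_lt(cmp$p, 0.01)
})

test_that("TAD compartment scores follow the sign rule and switching is 0 at fixed points", {
  trk <- data.frame(chrom = "chr1", start = (0:3) * 5e5, end = (1:4) * 5e5,
                    pc1 = c(0.5, 0.5, 0.3, -0.3),
                    label = c("A", "A", "A", "B"), stringsAsFactors = FALSE)
  tads <- as_tad_set(data.frame(chrom = "chr1", start = c(0, 1e6),
                                end = c(1e6, 2e6)),
                     data.frame(chrom = character(), start = integer(),
                                end = integer(), kind = character()))
  sc <- tad_compartment_scores(tads, trk)
  expect_equal(sc$score, c(0.5, 0))
  expect_equal(sc$label, c("A", NA))
  sw <- tad_switch(sc, sc)
  expect_equal(sw$switched_fraction, 0)
  expect_equal(sw$n_matched, 1L)   # only the labelled TAD is scored
})

test_that("boundary strata: overlap and binding groups behave at the fixed points", {
  bd <- data.frame(chrom = "chr1", start = c(1e6, 2e6, 3e6),
                   end = c(1e6, 2e6, 3e6) + 1L, kind = "boundary")
  tads <- as_tad_set(data.frame(chrom = "chr1", start = 0, end = 4e6), bd)
  tads$boundaries$S <- c(1, 2, 3)
  pk_all <- data.frame(chrom = "chr1", start = bd$start - 100L, end = bd$end + 100L,
                       name = "p", score = 0L, strand = ".", signalValue = 1,
                       pValue = -1, qValue = -1, summit = -1L)
  expect_message(st <- boundary_strength_strata(tads, tads, pk_all), "skipped")
  expect_true(all(st$a$overlapping))          # identical sets: 100% overlapping
  expect_true(all(st$a$bound))                # unbound group empty -> skipped
  expect_true(is.na(st$p["bound_vs_unbound", "a"]))
})
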