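# Independent brute-force oracles and small fixtures shared across tests.
# Oracles are deliberately naive (explicit loops / outer products) so they
# stay independent of the package's GenomicRanges-based implementations.

# O(n*m) overlap counts between 0-based half-open interval sets
brute_overlap_counts <- function(a, b) {
  out <- integer(nrow(a))
  for (i in seq_len(nrow(a))) {
    n <- 0L
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) n <- n + 1L
    }
    out[i] <- n
  }
  out
}

# index of the interval containing each point, NA if none (first match)
brute_point_in <- function(chrom, pos, b) {
  out <- rep(NA_integer_, length(chrom))
  for (i in seq_along(chrom)) {
    for (j in seq_len(nrow(b))) {
      if (chrom[i] == b$chrom[j] && pos[i] >= b$start[j] && pos[i] < b$end[j]) {
        out[i] <- j
        break
      }
    }
  }
  out
}

# naive per-pair generative intensity, independent of expected_lambda():
# explicit loops over bin pairs and boundaries
brute_lambda <- function(genome, truth, config, resolution) {
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  lam <- list()
  for (ch in names(lens)) {
    n <- lens[[ch]] %/% resolution
    L <- matrix(0, n, n)
    comp <- truth$compartments[truth$compartments$chrom == ch, ]
    dom <- truth$domains[truth$domains$chrom == ch, ]
    bnd <- truth$boundaries[truth$boundaries$chrom == ch, ]
    bias <- truth$bias[truth$bias$chrom == ch, ]
    bin_bias <- function(i) {
      c0 <- (i - 1) * resolution; c1 <- i * resolution
      sel <- bias$start < c1 & bias$end > c0
      exp(mean(log(bias$bias[sel])))
    }
    bb <- vapply(seq_len(n), bin_bias, numeric(1))
    lab_of <- function(i) {
      ctr <- (i - 0.5) * resolution
      comp$label[ctr >= comp$start & ctr < comp$end]
    }
    dom_of <- function(i) {
      ctr <- (i - 0.5) * resolution
      w <- which(ctr >= dom$start & ctr < dom$end)
      if (length(w)) w else NA_integer_
    }
    for (i in seq_len(n)) for (j in i:n) {
      s <- j - i
      v <- if (s == 0) config$diag_intensity else s^(-config$decay_exponent)
      v <- v * (if (lab_of(i) == lab_of(j)) 1 + config$compartment_contrast
                else 1 - config$compartment_contrast)
      if (resolution <= 40000) {
        di_ <- dom_of(i); dj_ <- dom_of(j)
        if (!is.na(di_) && !is.na(dj_) && di_ == dj_)
          v <- v * config$tad_enrichment
        ci <- (i - 0.5) * resolution; cj <- (j - 0.5) * resolution
        for (k in seq_len(nrow(bnd)))
          if (bnd$pos[k] > ci && bnd$pos[k] < cj) v <- v * bnd$f[k]
      }
      v <- v * bb[i] * bb[j]
      L[i, j] <- v; L[j, i] <- v
    }
    lam[[ch]] <- L
  }
  tot <- sum(vapply(lam, function(L) sum(L[upper.tri(L, diag = TRUE)]), numeric(1)))
  lapply(lam, function(L) L * config$sequencing_depth / tot)
}

# recall of planted boundary positions: matched when the gap between the
# planted position and a called boundary region is at most tol bp
boundary_recall <- function(truth, boundaries, tol = 40000) {
  bd <- boundaries[boundaries$kind == "boundary", , drop = FALSE]
  hit <- vapply(seq_len(nrow(truth$boundaries)), function(k) {
    sel <- bd$chrom == truth$boundaries$chrom[k]
    if (!any(sel)) return(FALSE)
    p <- truth$boundaries$pos[k]
    gap <- pmax(bd$start[sel] - p, p - bd$end[sel], 0)
    min(gap) <= tol
  }, logical(1))
  mean(hit)
}

# symmetric circulant matrix: equal row sums by construction (independent
# of any balancing code), used as an exactly balanced base; vals[d+1] is the
# value at circular distance d and must cover d = 0 .. floor(n/2)
circulant_sym <- function(vals, n = 2L * length(vals) - 1L) {
  stopifnot(length(vals) >= n %/% 2L + 1L)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- min(abs(i - j), n - abs(i - j))
    M[i, j] <- vals[d + 1L]
  }
  M
}

# random interval fixture on two chromosomes
random_intervals <- function(n, seed, max_len = 5000, genome_bp = 4e6) {
  set.seed(seed)
  start <- floor(runif(n, 0, genome_bp - max_len))
  data.frame(chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
             start = start,
             end = start + floor(runif(n, 1, max_len)),
             stringsAsFactors = FALSE)
}

# small fast simulation context for module tests: one 8-Mb chromosome
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(...)
  g <- simulate_genome(n_chrom = 1L, chrom_length = 8e6, genes_per_chrom = 0L,
                       seed = seed)
  tr <- simulate_truth(g, cfg, seed = seed)
  list(cfg = cfg, genome = g, truth = tr)
}

as_tad_set <- function(domains, boundaries) {
  boundaries$S <- rep(NA_real_, nrow(boundaries))
  structure(list(domains = domains, boundaries = boundaries), class = "tad_set")
}
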