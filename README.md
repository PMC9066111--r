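# chromarch

Integrative analysis of three-dimensional chromatin architecture and DNA
methylation from binned sequencing data, for studies that ask how a
chromatin factor reshapes genome organisation: a replicated two-condition
design combining Hi-C contact maps, MeDIP-seq methylation tracks and
ChIP-seq peaks. The package was built around the kind of question asked of
germline stem cells in which overexpressing or knocking out a single
chromatin protein changes DNA methylation, intra-TAD contact frequency and
TAD boundary strength — but every stage is generic.

It provides, as composable R functions plus an end-to-end pipeline:

* **Contact-matrix core** — HiC-Pro-style sparse triplet I/O, iterative
  correction (ICE) balancing with low-coverage masking, distance-decay
  profiles *E(s)* and the observed/expected transform
  *Z<sub>ij</sub> = N<sub>ij</sub> / E(|i−j|)*.
* **A/B compartments (500 kb)** — PC1 of the per-chromosome Pearson
  correlation of the O/E map, sign-oriented so gene-dense = A (PC1 > 0 is
  A, PC1 < 0 is B), bin-level compartment switching between conditions, and
  PC1 condition/replicate correlations.
* **TADs (40 kb)** — directionality index
  DI = sign(B−A)·[(A−E)²/E + (B−E)²/E] with a 2-Mb window, 3-state Gaussian
  HMM segmentation, domain/boundary assembly with the <400 kb boundary
  rule, an insulation log-contrast boundary-strength score
  S = log₂(mean intra-flank Z / mean cross-boundary Z) calibrated so
  S = −log₂ f for a boundary retaining a fraction f of cross contacts,
  per-TAD mean O/E with condition comparisons, TAD compartment scores, and
  boundary strata (overlapping vs condition-specific, peak-bound vs
  unbound).
* **Differential interactions (20 kb)** — exact binomial test of pooled
  replicate counts per bin pair under a library-size null,
  Benjamini–Hochberg correction, significance at q < 0.05 and
  |log₂FC| > 1, with summaries by differential bins and peak binding.
* **MeDIP analysis** — strand-aware 200-bin metagene profiles over gene
  bodies and 2-kb flanks, window-based DMR calling (same binomial engine)
  with hyper/hypo direction and merging, genomic-feature annotation, and
  DMR/peak overlap.
* **Peak integration** — nearest-TSS annotation (promoter / proximal /
  distal at 2 kb / 10 kb), peak-summit enrichment profiles across ±0.5 Mb
  of TAD boundaries in 25-kb steps, and anchor-centred signal matrices for
  heatmaps.
* **Synthetic genome generator** — plants power-law decay, checkerboard
  compartments, insulated TAD tilings, per-bin biases, differential
  blocks, DMRs and class-placed peaks with Poisson noise and two replicates
  per condition, and writes the ground truth, so every stage above is
  validated against known answers.

## Worked example

Simulate the default toy genome (2 × 20 Mb, ~16 planted TADs per
chromosome, boundary retention f = 0.3), balance it, and call TADs:

```r
library(chromarch)

cfg    <- sim_config()
genome <- simulate_genome(seed = 1)
truth  <- simulate_truth(genome, cfg, seed = 1)

hic  <- simulate_contact_map(genome, truth, cfg, resolution = 40000, seed = 2)
hic  <- oe_transform(ice_balance(hic))
di   <- fit_hmm_and_decode(directionality_index(hic, window = 2e6))
tads <- boundary_strength(hic, assemble_domains(di))

print(tads)
bd <- tads$boundaries[tads$boundaries$kind == "boundary", ]
cat(sprintf("planted boundaries: %d   mean strength S: %.2f\n",
            nrow(truth$boundaries), mean(bd$S, na.rm = TRUE)))
recall <- mean(sapply(seq_len(nrow(truth$boundaries)), function(k) {
  sel <- bd$chrom == truth$boundaries$chrom[k]
  p <- truth$boundaries$pos[k]
  any(sel) && min(pmax(bd$start[sel] - p, p - bd$end[sel], 0)) <= 40000
}))
cat(sprintf("boundary recall within one bin: %.1f%%\n", 100 * recall))
```

```
<tad_set> 47 domains, 45 boundaries (45 < 400 kb)
planted boundaries: 32   mean strength S: 2.26
boundary recall within one bin: 100.0%
```

All 32 planted boundaries are recovered within one 40-kb bin (the caller
also emits some weak extra splits — see the vignette); the mean boundary
strength of 2.26 sits above the −log₂(0.3) ≈ 1.74 an isolated boundary of
retention 0.3 would give, because planted domain enrichment (γ = 3)
steepens the intra/cross contrast.

The full pipeline — simulation, ICE at the three resolutions, compartments,
TADs, differential interactions, DMRs and peak integration, with all stage
outputs and a JSON report:

```r
run_pipeline(list(seed = 7, out_dir = "chromarch_out"))
```

A thin command-line wrapper lives at `inst/cli/chromarch.R`
(`Rscript chromarch.R run --out chromarch_out --seed 7`).

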