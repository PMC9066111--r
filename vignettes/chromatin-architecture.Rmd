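---
title: "Methods: integrative Hi-C and MeDIP-seq chromatin architecture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative Hi-C and MeDIP-seq chromatin architecture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`chromarch` analyses binned chromosome-conformation (Hi-C) contact maps
together with MeDIP-seq methylation tracks and ChIP-seq peaks for a
two-condition, replicated design. The pipeline is cis-only: each chromosome
contributes one symmetric matrix of intra-chromosomal contact counts, read
and written in the sparse triplet dialect (`bin_i<TAB>bin_j<TAB>count`,
1-based global bin IDs, upper triangle only) with a companion 0-based
half-open bin BED file. Three resolutions carry the three analysis scales:
**500 kb** for A/B compartments, **40 kb** for TAD calling, **20 kb** for
differential interactions. The compartment resolution is validated, not
assumed: passing a 40 kb matrix to the compartment caller is an error.

Every analysis stage is paired with a synthetic-data generator that plants
the structure the stage claims to detect, so the whole pipeline is testable
without external data. The generator's defaults are the package's reference
simulation conditions and are held fixed across the test suite.

# The contact-map generator

Expected intensity for bins $i \le j$ of one chromosome:

$$\lambda_{ij} \;=\; C \cdot s^{-\alpha}\, c_{ij}\, t_{ij}\, f_{ij}\, b_i b_j$$

* $s = |i-j|$ is the bin-centre distance in bins; $\alpha$ (default 1) is
  the decay exponent. The diagonal ($s=0$) would be singular under
  $s^{-\alpha}$ and instead uses a fixed intensity (default 2), and is
  excluded from decay fitting.
* $c_{ij} = 1+\delta$ for same-compartment pairs, $1-\delta$ otherwise;
  compartment labels are planted per 500-kb bin in alternating blocks of
  1–3 Mb ($\delta$ default 0.4).
* $t_{ij} = \gamma$ (default 3) when both bin midpoints fall in the same
  planted domain; domains tile each chromosome with sizes 0.8–1.6 Mb
  (20–40 bins at 40 kb), at least 15 per 20-Mb chromosome.
* $f_{ij}$ is the product of the insulation (retention) factors
  $f \in (0,1]$ of all planted boundaries strictly between the two bin
  centres (default $f = 0.3$; smaller = stronger boundary). The
  multiplicative-per-crossed-boundary form keeps the model composable: a
  monotonicity test can vary one boundary at a time.
* $b_i$ is a lognormal per-bin bias (log-sd 0.25), stored on a 20-kb master
  grid; coarser bins take the geometric mean of their members.
* $C$ is set so the expected total count over all cis pairs equals the
  configured depth per replicate (default $2\times10^7$). Counts are
  independent Poisson draws on the upper triangle, mirrored exactly.

**Scale rule.** Domain and boundary factors are applied only at resolutions
that resolve them (40 kb and finer). At 500 kb a 0.8–1.6 Mb domain spans 2–3
bins, and the per-crossed-boundary product — roughly one boundary per bin —
would compound into an exponential long-range cutoff ($f^{16}$ over a 20-Mb
chromosome), extinguishing exactly the long-range compartmental signal the
500-kb analysis relies on. Real sub-megabase insulation does not suppress
contacts at 10 Mb, so compartment-scale maps are simulated from decay,
compartment contrast and bias alone.

**Depth.** The default depth powers the planted analyses at desk scale; it
is a statistical choice, not a fidelity claim. At $2\times10^7$ cis
contacts per replicate the planted 4-fold differential block at 20 kb is
detected with high power; proportionally smaller depths are used inside
unit tests where only calibration, not power, is at stake.

The MeDIP generator emits Poisson window counts (1-kb windows) around a flat
baseline multiplied, near each gene, by a Gaussian TSS dip (level 0.25,
s.d. 1 kb) and a Gaussian TES rise (level 2, s.d. 2 kb); planted DMRs
(default 20 hyper + 10 hypo, 5 kb wide, fold 4) multiply the treated
condition only. The peak generator places boundary-class summits within one
40-kb bin of a planted boundary (truncated Gaussian, s.d. 15 kb),
promoter-class summits within 1 kb of a TSS, and random-class summits
uniformly; every placement is recorded in a truth table.

What the generator does **not** emulate: read-level artefacts (the pipeline
starts from binned counts), restriction-fragment geometry,
trans-chromosomal contacts, copy-number structure, correlated (over-
dispersed) noise between replicates, and CpG-density-dependent MeDIP
efficiency. Passing recovery tests on these simulations therefore
demonstrates correctness of the estimators under the stated generative
model, not robustness to every artefact of real libraries.

# ICE balancing

Multiplicative per-bin biases are removed by iterative correction: each
chromosome's matrix is repeatedly divided by its row/column marginals
(renormalised to mean 1 over unmasked bins) until the coefficient of
variation of unmasked row sums drops below `tol` (default 1e-5, max 200
iterations). The lowest-coverage 2% of bins, and all zero-coverage bins,
are masked first. The bias vector is normalised to geometric mean 1 so the
balanced layer keeps the raw count scale, which keeps intra-TAD means
comparable across conditions after depth scaling.

Plain iterative correction converges slowly on strongly insulated maps:
near block-diagonal structure gives the iteration a smooth, slowly decaying
bias mode (we observed row-sum CVs plateauing near $10^{-2}$ after 200
iterations on default simulations). Every fifth iteration the log-bias
vector is therefore Aitken-$\Delta^2$ extrapolated. The fixed point is
unchanged — the extrapolation only accelerates the linear tail — and the
balanced decomposition of a positive matrix is unique up to scale, which is
what the bias-recovery tests assert (recovery of planted 20-bin biases to
within 1e-6 of proportionality).

Non-convergence is a warning, not an error: the achieved CV is recorded in
the `ice_cv` attribute and echoed in the pipeline report.

# Distance decay and O/E

`expected_profile()` gives the per-chromosome mean balanced contact
$E(s)$ at each bin distance and the frequency density of contacts over
$\log_{10}$ genomic distance (bins of width 0.1, normalised to sum 1).
`oe_transform()` divides by $E(|i-j|)$; entries at distances with no
unmasked pairs are undefined (`NA`) rather than zero-filled. An optional
precomputed profile can be supplied — used, for example, to form the
observed/expected layer of an analytic (noise-free) intensity table against
the true decay when calibrating the boundary score.

# A/B compartments

Per chromosome, the O/E matrix over unmasked bins is reduced to its Pearson
correlation matrix and the compartment signal is the leading eigenvector
(PC1) — the Lieberman-Aiden convention. Published compartment analyses
vary between correlation-matrix and raw-O/E eigenvectors and often do not
say which they used; the correlation-matrix form is adopted here as the
standard interpretation. The eigenvector sign is arbitrary, so each chromosome is
oriented so that the gene-dense half of its unmasked bins (total gene bp
overlap at or above the median) has positive mean PC1; A = gene-dense is
the orientation anchor. Bins with PC1 exactly 0 are treated as masked
rather than arbitrarily labelled, which keeps tie-breaking noise out of the
switch fractions. A chromosome whose correlation matrix is degenerate
(constant rows) is masked with a warning. At least 10 unmasked bins per
chromosome are required.

Switching classifies each bin by its (control, treated) label pair; the
four class fractions are computed over jointly unmasked bins and sum to 1.
`pc1_correlation()` is the Pearson correlation over jointly unmasked bins
and also emits the paired scatter table for plotting.

# TAD calling

The directionality index of bin $i$ with half-window $W$ (default 2 Mb = 50
bins at 40 kb):

$$\mathrm{DI}_i = \mathrm{sign}(B-A)\left(\frac{(A-E)^2}{E} +
\frac{(B-E)^2}{E}\right), \quad E = \frac{A+B}{2},$$

with $A$ and $B$ the balanced contact sums to bins within $W$ upstream and
downstream, following the original directionality-index method; the 40-kb
binning and 2-Mb window are its standard settings. $A$, $B$ and $E$ are retained per bin so the formula can be
swapped without re-decoding. Edge bins are computed over the available span
and flagged.

A 3-state Gaussian HMM is fitted genome-wide by EM (quantile-based initial
means at the 0.1/0.5/0.9 quantiles, tolerance 1e-4, at most 200 iterations,
one seeded perturbed restart on degeneracy; seed 13 by default) and states
are relabelled by increasing mean: upstream-biased, unbiased,
downstream-biased. Decoding is per chromosome in a single Viterbi pass in
which masked bins are missing emissions — every state equally likely — so
the path stays continuous across them. This matters in practice: masked
(lowest-coverage) bins cluster at strong boundaries, and restarting the
decoder there mis-places domain edges by one bin through the initial-state
distribution. A DI track with zero variance carries no directional
information and short-circuits to an all-unbiased path.

Domains open at the first bin of a downstream-biased run and close at the
last bin of the next upstream-biased run; a domain left open at the
chromosome end is discarded. Gaps between consecutive domains shorter than
400 kb are **boundary** regions; longer gaps are **unorganized**; adjacent
domains produce a 1-bp boundary at the shared edge. Recovery of a planted
boundary is scored as a gap of at most one bin between the planted position
and the called boundary region.

**Boundary strength** is the package's own definition — published
"boundary intensity scores" are rarely specified precisely — isolated
behind one operation so it can be swapped: with $m$ the bin containing the boundary
midpoint and flank $w$ (default 10 bins = 400 kb),

$$S = \log_2 \frac{\text{mean } Z \text{ in the left and right } w \times w
\text{ intra blocks}}{\text{mean } Z \text{ in the } w \times w
\text{ cross block spanning } m},$$

diagonals excluded, unscored within $w$ bins of a chromosome edge. On the
noise-free expected map with an isolated boundary of retention $f$ (and the
O/E layer formed against the true decay), $S = -\log_2 f$ exactly; forming
O/E against the empirically estimated $E(s)$ instead biases $S$ by
$O(s_{\max}/N)$ because the boundary leaks into $E(s)$ itself — the
calibration tests therefore use the analytic route, while all
condition-comparison statistics use the empirical pipeline.

**Intra-TAD interaction** is the per-TAD mean off-diagonal O/E over the
domain's bins (domains under 3 bins are skipped). Two caveats discovered on
planted data and worth stating plainly. First, each condition's own O/E
normalisation absorbs most of a *uniform* within-TAD enrichment change:
within a domain $Z \approx \gamma/(w\gamma + (1-w)q)$, where $w$ is the
within-domain fraction of pairs at that distance and $q$ the insulated
cross-boundary level, which tends to $1/w$ — independent of $\gamma$ — as
insulation strengthens. Second, the per-TAD spread that remains is
dominated by TAD-size structure shared by both conditions. Consequently the
unpaired Mann-Whitney comparison of per-TAD means detects a planted
$\gamma: 3 \to 2$ reduction only weakly, while the matched-domain
(paired Wilcoxon signed-rank) comparison detects it decisively;
`compare_conditions(..., paired = TRUE)` exposes the paired form and the
pipeline reports the unpaired form for condition-called (unmatched) TAD
sets. TAD compartment scores average PC1 over 500-kb bins whose midpoints
fall in the domain (score 0 or no located bins leaves the TAD unscored);
cross-condition TAD matching uses 50% reciprocal overlap, boundary matching
1 bp — both chosen to be brute-force checkable.

# Differential interactions at 20 kb

Replicates are summed per condition; library sizes are total cis counts.
Each bin pair with at least `min_count` (default 10) summed raw counts is
tested with an exact two-sided binomial test of the treated count against
the pooled total under the library-size null proportion, BH-corrected over
tested pairs. With two replicates per condition, a dispersion-modelling
count regression has too few degrees of freedom to estimate biological
variance per pair; pooled exact testing is the defensible default and
replicate concordance is reported as a diagnostic instead. Fold changes
use size-factor-scaled counts with pseudocount 0.5; significance means
$q < 0.05$ and $|\log_2 FC| > 1$, the conventional differential thresholds. The same binomial engine drives the DMR
caller, vectorised by grouping observations on the trial count so hundreds
of thousands of pairs test in seconds; it reproduces `stats::binom.test`
(minimum-likelihood two-sided rule, relative tolerance 1e-7) exactly.

Swapping condition labels negates every fold change and preserves p-values
to numerical precision; the planted-block power and the Monte-Carlo type-I
calibration of the test are asserted in the acceptance suite.

# MeDIP analysis

Metagene profiles average library-size-normalised per-bp signal over genes
in a strand-aware 200-bin coordinate system (50 upstream-flank bins, 100
length-scaled body bins, 50 downstream-flank bins; flank 2 kb). Windows are
treated as piecewise-constant per-bp intensity and integrated exactly over
each metagene bin, so the profile is invariant to library rescaling and
mirror-symmetric for minus-strand genes.

DMRs: per-window pooled binomial test as above (windows with summed count
below 10 untested), then significant windows of the same direction within
`merge_gap` (default 1 kb) are merged; a region's fold change is recomputed
from its members' summed counts and its q is the member minimum. Hyper
means higher in treated. Adjacent significant windows of opposite direction
are never merged. Feature annotation labels each DMR by its midpoint with
precedence promoter (TSS ± 2 kb; there is no universal promoter window, so
it is a flag) > exon > intron > intergenic, a single-label composition that
sums to 1 and is checkable by a quadratic scan.

# Peak integration

Peaks are anchored at their narrowPeak summit (midpoint fallback). Nearest-
TSS distances are signed by gene strand (negative = upstream) and classed
promoter / proximal / distal at 2 kb and 10 kb; no universal cutoffs
exist, so both are flags. Boundary
enrichment counts summits per 25-kb step across ±0.5 Mb of each boundary
midpoint, normalised per boundary, excluding
boundaries truncated by chromosome edges. All overlap statistics use the
1-bp rule in both directions, and every overlap, annotation and enrichment
operation is tested against an $O(nm)$ brute-force scan.

# Pipeline

`run_pipeline()` drives simulate → ICE → compartments → TADs → differential
→ methylation → peak integration from a strict-schema configuration
(unknown keys are errors; every resolved value is echoed into the output
directory, so there are no silent defaults). Replicates are pooled before
ICE for the compartment and TAD stages; the differential stage consumes the
raw replicate matrices. The JSON report contains only values recomputable
from the written stage outputs and no timestamps, so runs with equal seeds
are byte-identical; stage timers go to the message log. Seeds for each
simulated artefact are derived from the master seed by a fixed affine map
kept below $2^{31}$.

Problem sizes: the default toy genome is 2 chromosomes × 20 Mb with 200
genes per chromosome — small enough that the full pipeline runs in well
under a minute per condition on one CPU, large enough for ≥ 15 planted TADs
per chromosome and ~80 compartment bins. Unit tests use an 8-Mb
single-chromosome genome where only calibration is at stake.

# Known limitations

* The DI+HMM caller over-segments somewhat relative to the planted tiling
  (extra weak boundaries); recovery statistics are therefore reported as
  recall against planted boundaries, with precision exercised only for
  DMRs, where the planted structure is sparse.
* Boundary regions between adjacent called domains are 1 bp wide, so
  "peak overlaps boundary" statistics are conservative for sharply called
  maps; the enrichment profile (summits per step-bin around midpoints) is
  the scale-free view.
* The exact binomial differential test conditions on pooled counts and
  treats replicates as technical; biological overdispersion would inflate
  its false-positive rate on real data.
* MeDIP signal is enrichment-based; the DMR caller works on window counts
  and makes no absolute-methylation calibration.
* Compartment orientation assumes A = gene-dense; on genomes where that
  anchor fails, orient with a custom gene model.
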