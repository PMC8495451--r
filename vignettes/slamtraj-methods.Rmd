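---
title: "slamtraj: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slamtraj: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slamtraj)
```

slamtraj re-implements, as a tested and reusable pipeline, the computational
backbone of a single-cell metabolic-labeling (scSLAM-seq) trajectory analysis
of colorectal cancer organoids and primary tumors: molecule-level nascent/old
RNA classification, a two-layer kinetic ("RNA velocity") model with
root-prior-regularized latent time, clone-wise somatic copy-number (SCNA)
scoring from transcriptomes, a shared-neighbor condition-similarity statistic,
and signature-gradient binning statistics. This vignette explains the models,
the tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the procedure
was genuinely open.

## 1. Nascent/old molecule classification

During a 4sU labeling window (200 µM for 2 h in the source protocol),
newly transcribed RNA incorporates 4-thio-uridine; alkylation chemistry makes
these uridines read as T→C mismatches. Classification is molecule-level and
deliberately simple:

1. per read, covered reference-T positions and T→C conversions are counted,
   **excluding positions with common SNPs** (any minimal VCF; dbSNP in the
   original study);
2. reads sharing one (cell barcode, UMI, gene) key are collapsed; a position
   observed as converted in one read and as reference T in an overlapping
   read is **discordant** and excluded from both counts;
3. a molecule is **nascent** iff it retains ≥ 1 conversion, **old**
   otherwise.

No statistical correction for incomplete labeling is applied (no binomial
mixture estimation); the hard ≥ 1-conversion rule is implemented as stated.
Consequences worth knowing: with per-T conversion probability $p_c$ and $m$
usable T positions, a labeled molecule is detected with probability
$1-(1-p_c)^m$; sensitivity therefore degrades for short or T-poor molecules,
and sequencing errors at T positions create false positives that only the
discordance rule (given ≥ 2 overlapping reads) or SNP masking can remove.

Design choices in this module:

* **Gene-aware molecule keys.** The collapsing key includes the gene: reads
  sharing (barcode, UMI) but mapped to different genes cannot be assigned a
  count-matrix row and are discarded and tallied in a report. The source
  procedure does not state how such reads were handled; discarding is the
  conservative reading.
* **Molecules without usable T** are labeled old (the literal "old
  otherwise") but flagged `no_T` in the audit output so users can filter.
* **Discordance needs disagreement**: only positions covered by ≥ 2 reads can
  be discordant; single-read evidence stands.
* **Strand handling**: for minus-strand genes the T→C event appears as A→G on
  the reference-forward strand; the SAM reader applies this rule. Because no
  reference FASTA is consumed, the SAM text dialect must carry covered
  sense-strand T positions in a `TP:Z` tag — mismatch strings alone cannot
  reconstruct which matched bases were T.

## 2. The two-layer kinetic model and latent time

With u the nascent and s the old layer (the two SLAM layers take the roles
that unspliced/spliced play in the classical velocity model — a modeling
convention, not a biological claim), each gene follows

$$\frac{du}{dt} = \alpha - \beta u, \qquad \frac{ds}{dt} = \beta u - \gamma s,$$

with transcription switched off ($\alpha = 0$) after a gene-specific switch
time $t_s$. The closed-form solution (`solve_kinetics()`) handles the
removable $\beta = \gamma$ singularity by its analytic limit (the
$\alpha(e^{-\gamma t}-e^{-\beta t})/(\gamma-\beta)$ term tends to
$-\alpha t e^{-\gamma t}$; the sign follows from solving the ODE directly
with $\beta=\gamma$), guarded at $|\gamma-\beta| < 10^{-6}\gamma$.

**Identifiability.** Multiplying $(\alpha, \beta, \gamma)$ by a constant and
dividing all times by the same constant reproduces identical curves. The
fitter works in the gauge $\beta = 1$: fitted $\gamma$ estimates the
identifiable ratio $\gamma/\beta$, fitted $\alpha$ estimates $\alpha/\beta$,
and fitted times are in units of $1/\beta$. Tests assert only these ratios.

**Fitting** (`fit_gene_kinetics()`). A Nelder-Mead search over
$(\log\alpha, \log\gamma, \log t_s)$ in which *every* objective evaluation
re-assigns each cell the branch and time minimizing squared distance to the
phase curve — a dense 512-point grid, then golden-section refinement for the
final assignment. This profile variant of the assign-then-update alternating
scheme is strictly stronger per iteration and much harder to trap in the
poor local optima that a single alternation sweep can create; it is
deterministic (two fixed switch-time starts, then a polish pass on the
refined assignment, which removes the small grid-discretization bias; on
noise-free data the total squared loss reaches below 1e-6). Constant input
is flagged `degenerate` and returns a steady-state-only fit. Cells are fitted
on KNN-smoothed moments (30 PCs, 30 neighbors by default, computed separately
per condition so no smoothing crosses condition boundaries).

**One-sided genes and the root prior.** Most real genes are observed on one
kinetic branch only; a one-branch arc fits almost equally well in either
time direction (the mirror ambiguity). A gene is called one-sided when the
unconstrained fit places > 90 % of cells on a single branch; the two
constrained mirror candidates are then scored as

$$\text{loss} + \lambda \cdot \big(\text{fraction of root cells with gene-local time above the } \theta\text{-quantile of all cells' times}\big),$$

where the root prior is a user-asserted set of origin cells. The source
text names only "penalizing the number of cells that are assigned a higher
latent time than a given root prior" without defining the penalty's domain,
weight, or whether the prior is a set or a time value; the form above is this
package's operationalization — per gene, scale-free, reducing exactly to the
unregularized comparison at $\lambda = 0$. Defaults: $\theta = 0.5$,
$\lambda = 10\times$ the median per-gene loss.

**Latent time.** Gene-local times are min-max normalized per gene and
combined per cell by a weighted median with goodness-of-fit weights
$w_g = \max(0, 1-\mathrm{loss}_g/\mathrm{var}_g)$; the aggregate is rescaled
to $[0, 1]$. Cells with no informative gene are flagged `NA`. Velocity is
$\beta u - \gamma s$ on the smoothed values; the velocity graph scores each
KNN edge by the cosine between the cell's velocity vector and the expression
displacement towards the neighbor.

## 3. Clone-wise SCNA scoring

The copy-number module is a deliberately *simplified* smoothing substrate —
not an inferCNV re-implementation (no HMM, no denoising): genes are ordered
along the genome, centered by the reference-cell mean, averaged over a
101-gene window within each chromosome (truncated at ends, implemented as a
banded operator so a perturbed gene provably cannot affect smoothed values
beyond half a window), and clipped at ±3. On these profiles:

* clones are cut at k = 2 from a Ward-linkage dendrogram (per patient/sample);
* the **SCNA score** of a clone is the mean over its cells of the per-cell SD
  across genomic positions, divided by the same quantity averaged over all
  normal-sample cells pooled. Whether the "average standard deviation" is
  taken per cell across positions or per position across cells is not stated
  in the source; the per-cell reading is used because it is the only one for
  which "of all normal samples taken together" parses as a pooled
  denominator. A reference-distributed clone scores 1 in expectation and the
  score is invariant to a global scale factor;
* a clone is **aberrant** iff its score strictly exceeds the highest score
  observed among normal samples;
* CNA-region enrichment of deregulated genes uses an upper-tail
  hypergeometric probability with Bonferroni multiplication across regions
  (chromosome arms in the source), capped at 1.

## 4. Condition similarity and gradient statistics

**Shared neighbors.** The similarity between two treatment conditions is the
average fraction of a cell's k nearest neighbors (k = 30 to match the
moments graph; the KNN graph is built on the pooled dataset) carrying the
other condition's label, symmetrized by averaging the two directions.
"Shared neighbors" could also be read as a Jaccard overlap of neighborhood
sets; the composition reading is the default because it behaves sensibly for
unequal condition sizes, and a `metric = "jaccard"` alternative is provided.
Conditions are clustered by average linkage on 1 − similarity.

**Gradient binning.** Cells are ordered by decreasing signature score
(module scores against expression-matched controls: 25 mean-bins, 100
controls per set gene, seeded) and cut into 40 bins. Binning is
quantile-based (near-equal counts, sizes differing by at most one) because
equal-width bins put almost no cells in the extreme bins and the per-bin
fractions become noise-dominated; equal-width is available by flag. Per
state, the Pearson correlation between bin index and state fraction is
tested with the t statistic $r\sqrt{n-2}/\sqrt{1-r^2}$; enrichment "at the
start of the gradient" is a 2×2 Pearson chi-squared (no continuity
correction) of state membership against the top quarter of bins (the source
states no cutoff; `head_fraction` is configurable), BH-adjusted across
states. Cluster-signature testing is Kruskal-Wallis across clusters with BH
adjustment over signatures, followed (when FDR-significant at 0.05) by
one-vs-rest Wilcoxon rank-sum tests, BH-adjusted, star-coded at
0.05/0.01/0.001. Wherever the source says "FDR-corrected" without naming a
method, Benjamini-Hochberg is used.

## 5. The synthetic-data generator

Every stage is testable offline against generators with known ground truth.
What they emulate, and their defaults:

* **Reads** (`simulate_reads()`): 10x-style barcoded/UMI'd molecules;
  labeled fraction 0.25 (a realistic nascent/total ratio for a 2 h labeling
  window given typical mRNA half-lives), per-T conversion rate 0.02 (typical
  SLAM chemistry), sequencing error 1e-3 per covered base with uniform
  substitution — so an error at a T reads as C with probability 1/3, which is
  exactly what exercises the SNP/discordance logic; ~20 covered T per read;
  SNP density 1e-3 with heterozygous T>C alleles on half the molecules at
  SNP-T positions; each read covers a contiguous 80 % window of its
  molecule's T positions, creating partial overlap and the possibility of
  discordant evidence. Setting `read_coverage = 1` makes the closed-form
  sensitivity $f(1-(1-p_c)^m)$ exact. T positions are simulated in a
  gene-local 0-based frame; the SAM/VCF writers translate to global 1-based
  coordinates, isolating coordinate conversion in I/O.
* **Kinetic populations** (`simulate_kinetic_population()`): per-gene rates
  drawn from α ∈ [1, 5], β ∈ [0.5, 2], γ ∈ [0.2, 1], switch times in the
  middle 30–70 % of a t_max = 10 axis, true times uniform, Poisson (or
  negative binomial, variance μ + μ²/θ) capture noise; 20 % of genes are
  one-sided (switch pinned near 0 or t_max). These ranges give steady-state
  expectations of roughly 1–10 nascent and 2–25 old counts — the UMI regime
  where KNN moments still carry a usable kinetic signal. The simulator
  evaluates its own, independently written closed form of the ODE so fitter
  tests are not circular.
* **Clones** (`simulate_clone_expression()`): genomically ordered log-scale
  expression, zero-mean normals, clones with segmental shifts before
  gaussian noise (sd 0.15); a shift of 0 makes a clone indistinguishable
  from normal in expectation.
* **Conditions** (`simulate_condition_dataset()`): condition c is a unit
  isotropic gaussian at `separation · e_c`, so separation 0 is exchangeable
  and large separations fully isolate conditions.

What the generators do **not** emulate — and hence what a green test does not
establish: no sequence-level reads (no alignment errors, no multimapping,
no soft-clipping artifacts), no gene-length or capture-efficiency biases, no
doublets or empty droplets, no batch effects, no correlated gene programs
beyond the kinetic time axis, no subclonal tree structure, and no real
genome annotation. Green acceptance tests establish that the *computations*
are correct and calibrated on data matching their stated assumptions, not
that the biological conclusions of any particular study replicate.

## 6. Numerical and interface choices

* All genomic coordinates are 0-based half-open internally; VCF and SAM
  (1-based) are converted at the I/O boundary, BED passes through.
* TSV outputs are tab-separated with '.' decimals, Unix newlines and
  headers; MatrixMarket layers are written with a deterministic column-major
  entry order — the full pipeline is byte-identical across reruns with one
  seed (the run log, which carries wall-clock timestamps, is excluded from
  that contract).
* The MatrixMarket reader validates declared dimensions and entry counts and
  names the first out-of-range entry; unknown pipeline-config keys are
  rejected before any stage runs.
* Cell filters follow the organoid settings (2 000–5 000 detected genes,
  mitochondrial fraction 0.075–0.2, both read as closed intervals and the
  mitochondrial bound as a *fraction*, matching the printed decimals).
  HVG selection is the "Seurat-flavour" normalized dispersion (20
  equal-count mean bins, within-bin z-scores), ties broken by gene
  identifier.
* Ties in KNN are broken by cell index; ties in bin assignment by barcode;
  the lower weighted median is used — all choices deterministic.
* PCA for moments centers but does not scale genes (the common single-cell
  default).

## 7. Known limitations

* The ≥ 1-conversion rule underestimates nascent fractions for T-poor
  molecules; no mixture-model correction is provided by design.
* The kinetic fitter assumes one switch per gene and cannot represent
  re-induction; latent time is linear and cannot represent branching
  trajectories (cells on divergent end states get interleaved).
* The root-prior penalty is this package's operationalization of a
  one-sentence description; its config surface (`lambda`, `theta`) exists
  precisely because the original form is unrecoverable.
* Clone scoring presumes a usable normal reference; without genuinely
  diploid reference cells the centering absorbs clonal shifts.
* Moments are fitted per condition; whether the original analysis refitted
  kinetics jointly across conditions after per-condition moments is
  unstated, and this package fits per condition.
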