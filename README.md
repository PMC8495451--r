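# slamtraj

Nascent RNA quantification, kinetic trajectories and copy-number scoring for
single-cell SLAM-seq.

## What problem this solves, and for whom

Single-cell metabolic RNA labeling (scSLAM-seq) marks RNA transcribed during
a 4sU window with diagnostic T→C conversions, so each sequenced molecule can
be classified as **nascent** (labeled) or **old**. Layered nascent/old
counts are the ideal substrate for kinetic ("RNA velocity") models that
order cells along a developmental **latent time** — the approach used to
show that colorectal cancer organoid cells develop along a MAPK-activity
gradient. slamtraj packages the computational steps of that kind of study
for people who want to re-run, audit or extend them on their own data or on
fully synthetic data with known ground truth:

* **Molecule classification**: per-read T→C counting with common-SNP
  masking, per-molecule discordance exclusion across reads sharing a
  (barcode, UMI, gene) key, and the hard rule *nascent ⇔ ≥ 1 retained
  conversion*.
* **Kinetics**: per-gene fits of the two-layer model
  `du/dt = α − βu`, `ds/dt = βu − γs` (u = nascent, s = old, switch to
  α = 0 at t_s), on KNN-smoothed moments (30 PCs / 30 neighbors, per
  condition). The fit reports the identifiable ratios γ/β and α/β
  (gauge β = 1). One-sided genes (> 90 % of cells on one branch) are
  oriented by a **root prior**: candidate orientations are scored by
  `loss + λ · (fraction of root cells assigned late gene-local times)`.
  Latent time is a weighted median of per-gene times, rescaled to [0, 1];
  velocity is `βu − γs`.
* **SCNA scoring**: genomically smoothed, reference-centered expression
  (simplified inferCNV-style substrate), Ward dendrogram cut at k = 2,
  clone score = (mean per-cell SD across genomic positions) / (same for
  pooled normal cells), aberrant ⇔ score > max(normal scores).
* **Condition similarity**: mean fraction of a cell's k nearest neighbors
  in the other condition, symmetrized; average-linkage clustering on
  1 − similarity.
* **Gradient statistics**: 40 quantile bins along a signature score,
  Pearson r of state fraction vs bin index with t-based p, 2×2 chi-squared
  head-of-gradient enrichment with BH adjustment, and Kruskal-Wallis +
  post-hoc Wilcoxon cluster-signature tests.
* **Synthetic data** for all of the above, with truth tables, plus
  readers/writers for a SAM text dialect, minimal VCF, BED, and
  MatrixMarket layer directories, and an end-to-end pipeline driver with a
  JSON config.

## Worked example

```r
library(slamtraj)

## simulate a small scSLAM-seq experiment and classify molecules
sim  <- simulate_reads(read_sim_config(n_genes = 20, n_cells = 30,
                                       mean_molecules_per_cell = 80,
                                       seed = 42))
sim
#> scSLAM-seq simulation: 4679 reads, 2341 molecules, 20 genes, 30 cells, 1 SNPs

mask <- snp_mask(sim$snps$gene_id, sim$snps$pos)
res  <- classify_molecules(sim$reads, mask)
table(res$calls$label)
#> nascent     old
#>     252    2089
```

27.1 % of simulated molecules are truly labeled, but only 10.8 % are called
nascent: with ~25 usable T per molecule and a 2 % per-T conversion rate, a
labeled molecule carries at least one conversion with probability
1 − 0.98^25 ≈ 0.40, and 0.271 × 0.40 ≈ 0.108 — the hard ≥ 1-conversion rule
is deliberately conservative.

```r
## kinetic population -> moments -> per-gene fits -> latent time
kin  <- simulate_kinetic_population(kinetic_sim_config(n_genes = 100,
                                                       n_cells = 300,
                                                       seed = 7))
mom  <- compute_moments(kin$counts, n_pcs = 30, k = 30)[[1]]
fits <- fit_kinetics(mom$moments$nascent, mom$moments$old, min_shared = 20)
tau  <- compute_latent_time(fits)

fits$fits[[fits$genes$gene_id[1]]]
#> kinetic_fit: alpha/beta = 4.06, gamma/beta = 0.762, t_switch = 24.1, loss = 16.3
cor(as.numeric(tau), kin$truth_time, method = "spearman")
#> [1] 0.939
```

The first gene's true γ/β is 0.693 and the fit recovers 0.762 from Poisson
counts (within the 20 % band the acceptance suite requires of 80 % of
genes); the latent-time ordering correlates with the true simulation time at
Spearman ρ = 0.94.

The full pipeline (simulate → quantify → preprocess → velocity → scna →
similarity → gradient) runs from a JSON config:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "slamtraj"))
```

or from the command line via `slamtraj_cli()`:
`Rscript -e 'slamtraj::slamtraj_cli()' run --config demo_config.json --seed 1 --out out/`.
Reruns with the same seed are byte-identical (excluding the timestamped run
log).

## Documentation

`vignettes/slamtraj-methods.Rmd` describes the models, parameter defaults,
what the synthetic generators do and do not emulate, numerical choices and
known limitations.
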