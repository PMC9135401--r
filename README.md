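# blastemaST

Spot-level spatial transcriptomics of the regenerating digit-tip blastema.

After amputation of the distal third phalanx, a transient mass of
dedifferentiated cells — the blastema — regenerates the digit. On a spatial
gene-expression slide the blastema is a set of manually annotated spots, and
the questions become statistical: which genes mark the blastema against the
rest of the digit, what is the smallest gene signature that still labels it,
how active are metabolic / signalling / cell-cycle programs per spot, and
how do those programs change along the proximal–distal axis? `blastemaST`
implements that analysis chain as a tested, reusable R package for anyone
working with Visium-style spot data and manual region annotations:

* **Region markers** — two-sided Wilcoxon rank-sum DE of normalized
  expression (exact permutation p below combined n = 20, tie-corrected
  normal approximation above), with expressing fractions
  `pct_in`, `pct_out` and the *specificity ratio* `pct_in / pct_out`.
* **Signature selection** — three per-criterion top-*k* highlight lists
  (adjusted p, log fold change, specificity); genes in all three chosen
  first, then two-of-three weighted spec > lfc > padj, ordered by
  descending specificity, with a cluster-based exclusion list and nested
  reductive subsets (100 → 50 → 25 → 10 → 5 → 1).
* **Module scoring** — mean expression of a gene set minus
  expression-bin-matched random controls (24 equal-frequency bins, 100
  controls per gene, seeded), cell-cycle S/G2M scoring with S/G2M/G1 phase
  calls, and rank-sum score contrasts between regions.
* **SpatialTime** — minimum distance of each spot to a reference polyline
  drawn along the residual bone stump, min–max scaled per sample to [0, 1]
  (0 proximal, 1 distal), concatenated across samples, with binned gradient
  profiles.
* **Synthetic data** — a Visium-like generator (hex lattice digit layout,
  negative-binomial counts, planted signature / gradient / cell-cycle
  programs with ground truth) so the whole pipeline is testable offline.

## Worked example

```r
library(blastemaST)

gen  <- generate_dataset(synthetic_spec(seed = 1))
d    <- gen$dataset                  # 2000 genes x 1531 spots
                                     # blastema=296 boundary=133 bone=105 digit=997
norm <- normalize_log(d)             # ln(1 + 1e4 * c/T)

de <- region_de(norm, d, "blastema") # blastema vs all other regions
#> 250 genes tested; 222 significant (p_adj < 0.05, lfc > 0)

excl <- gen$gene_truth$gene[gen$gene_truth$set %in% c("s_phase", "g2m_phase")]
sig  <- select_signature(de, exclude = excl)   # proliferative genes excluded
head(as.data.frame(sig)[, c("rank", "gene", "tier", "specificity")], 5)
#>   rank  gene tier specificity
#> 1    1 g0039    3    5.242117
#> 2    2 g0083    3    5.152155
#> 3    3 g0002    3    5.099474
#> 4    4 g0053    3    5.092174
#> 5    5 g0034    3    5.087275
sum(sig$gene %in% gen$gene_truth$gene[gen$gene_truth$set == "signature"])
#> [1] 100        # all 100 planted blastema genes recovered

ms <- module_score(norm, sig$gene, seed = 1)
score_contrast(ms, d, "blastema", c("digit", "bone", "boundary"))
#> mean_diff 0.517, p = 1.43e-157   # signature labels the blastema

st   <- spatial_time(d, gen$polylines[[1]], "blastema")
grad <- gen$gene_truth$gene[gen$gene_truth$set == "gradient"]
binned_profile(st, module_score(norm, grad, seed = 2)$score, n_bins = 5)$mean
#> 0.613 0.446 0.280 0.132 0.042    # proximal-high gradient, decreasing distally

cc <- cell_cycle_score(norm,
                       gen$gene_truth$gene[gen$gene_truth$set == "s_phase"],
                       gen$gene_truth$gene[gen$gene_truth$set == "g2m_phase"],
                       seed = 3)
phase_distribution(cc, d)
#>     region      S    G2M    G1   n
#> 1 blastema 0.2872 0.1892 0.524 296   # blastema cycles; digit mostly G1
#> 4    digit 0.0512 0.0592 0.890 997
```

The numbers mean: the selected 100-gene signature scores ~0.52 normalized
log-units above expression-matched controls inside the blastema relative to
the rest of the digit; the planted proximal gradient module decays
monotonically across five SpatialTime bins; and phase calls recover the
planted cell-cycle mixtures (blastema ≈ 25/20/55% S/G2M/G1, digit ≈
5/5/90%).

On real data, `read_dataset()` ingests MatrixMarket counts with
`features.tsv` / `barcodes.tsv` sidecars, a 6-column Visium-dialect
positions CSV, and a `barcode,sample_id,region` annotations CSV;
`read_polylines()` reads the manually drawn stump line
(`sample_id,order,x,y`). Curated (placeholder — review before use) pathway
gene lists ship under `inst/extdata/gene_lists/`.

## Pipeline / CLI

`run_pipeline(config)` runs QC → DE → signature → scoring → SpatialTime from
a plain-text key-value config and writes deterministic CSV artifacts plus a
provenance log; reruns with the same config and seed are byte-identical. A
thin CLI wraps it:

```sh
Rscript inst/cli/blastemaST.R run --config analysis.cfg --seed 7 --out out/
```

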