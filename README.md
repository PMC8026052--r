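# consgrad

Two very different measures can quantify the evolutionary importance of a
protein site under purifying selection. The *intrinsic* measure is the
conservation of the site itself — its within-protein conservation rank, or
its absolute evolutionary rate (dN/dS). The *extrinsic* measure is the
**conservation gradient** the site induces in the rest of the tertiary
structure: how sharply the conservation of all other residues falls off
with distance from the site. `consgrad` implements both measures and the
statistics that relate them, for structural bioinformaticians and
molecular evolutionists studying how selective pressure on functional
sites (catalytic, ligand-binding, protein–protein interaction, allosteric)
percolates through residue–residue contacts.

## The statistics

For residue *i* of a protein with per-residue conservation scores
*c<sub>j</sub>* (oriented so higher = more conserved) and Cα distances
*d<sub>ij</sub>*, the conservation gradient is

> g<sub>i</sub> = cor( {d<sub>ij</sub>}, {c<sub>j</sub>} ) over all j ≠ i,

with Pearson or Spearman correlation, optionally restricted to windows
(0, 30] Å or (6, 30] Å. A site that radiates conservation gives
g<sub>i</sub> < 0; summaries also report the strength −g<sub>i</sub>. The
normalized conservation rank of residue *i* is its within-protein rank of
conservation divided by the number of scored residues (in (0, 1], higher =
more conserved; ties share average ranks). The per-protein
**conservation–percolation correlation** is the Pearson correlation across
residues between ranks and gradients. Around these sit the supporting
machinery: side-chain weighted contact number (SC-WCN, the
inverse-square-distance sum over side-chain centroids), distance to the
protein center (the max-SC-WCN residue), Shrake–Rupley relative solvent
accessibility with burial classes (buried RSA = 0, exposed RSA > 0.8,
middle otherwise), ΔRSA interface detection, OLS residualization of
gradients against packing covariates, equal-width binned trends,
functional-site subset resampling, within-protein concordance analysis
with exact binomial tests, and bootstrap standard errors.

A seeded synthetic-data generator plants distance-decaying conservation
fields in packed residue clouds so the full pipeline is exercisable — and
testable — without downloading any structure or database.

## Worked example

Generate a small two-site synthetic study (catalytic-like sites with decay
slope 0.3 per Å against shallow 0.1 per Å interaction sites) and run the
whole pipeline:

```r
library(consgrad)
cfg <- synthetic_config(
  n_proteins = 8, n_residues = 120,
  sites = list(list(site_type = "catalytic", k = 4, beta = 0.3, s0 = 0),
               list(site_type = "ppi",       k = 4, beta = 0.1, s0 = 0)),
  sigma = 1, seed = 42)
run <- run_pipeline(run_config(synthetic = cfg, n_subsets = 100,
                               subset_size = 30, seed = 42))

run$trend_rank_gradient
#> binned_trend: 20 bins, n = 960, slope = -1.225, r = -0.8255
mean(run$percolation$percolation_r)
#> [1] -0.83
run$concordance[c("n_concordant", "n_total", "p_value")]
#> $n_concordant [1] 109   $n_total [1] 128   $p_value [1] 1.56e-16
aggregate(mean_gradient_strength ~ site_type, run$subsets, mean)
#>   site_type mean_gradient_strength
#> 1 catalytic              0.8020408
#> 2       ppi              0.4991479
```

Reading the output: the binned trend's negative slope (−1.23, r = −0.83
over all 960 residues) says that higher-ranked (more conserved) residues
induce more negative gradients; the mean per-protein
conservation–percolation correlation of −0.83 says the same within
proteins. Concordance: in 109 of 128 cross-site residue pairs (85%) the
more conserved residue also induces the stronger gradient (exact binomial
p ≈ 2×10⁻¹⁶ against a fair coin). The subset resampling separates the two
planted classes: catalytic-like subsets average gradient strength 0.80
versus 0.50 for the shallow sites.

Real data enter through the same surface: `read_structure()` (PDB/mmCIF),
`read_consurf_scores()` (ConSurf-style grades, reoriented at ingest so
higher = conserved), `read_rate_table()`, `read_sites_tsv()` and
`read_pairwise_alignment()` + `transfer_profile()` for annotation
transfer, then `run_pipeline(run_config(manifest = ...))`.

A thin command-line wrapper over the same functions is at
`inst/scripts/consgrad.R` (`synth` and `run` subcommands).

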