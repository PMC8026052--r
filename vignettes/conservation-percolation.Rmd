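---
title: "Conservation gradients and the percolation of selective pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation gradients and the percolation of selective pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consgrad)
```

## The two measures and the model behind them

Purifying selection on a protein functional site leaves two distinct
footprints. The *intrinsic* footprint is the conservation of the site
itself, which `consgrad` expresses two ways: the **normalized conservation
rank** — a residue's within-protein rank of conservation divided by the
number of scored residues, in (0, 1] with higher = more conserved — and
the absolute evolutionary rate dN/dS, ingested per residue. The
*extrinsic* footprint is the **conservation gradient**: because selective
pressure propagates through residue–residue contacts, conservation decays
with distance from an important site, and the per-residue statistic

$$ g_i \;=\; \mathrm{cor}\big(\{d_{ij}\}_{j \ne i},\, \{c_j\}_{j \ne i}\big) $$

(correlation between the conservation scores of all *other* residues and
their Cα distance from residue $i$) captures how strongly residue $i$
radiates conservation. With scores oriented so higher = more conserved, a
radiating site gives $g_i < 0$; user-facing tables therefore also carry
the positive *strength* $-g_i$, and all package summaries state which
column they use. The per-protein **conservation–percolation correlation**
is the Pearson correlation across residues between ranks and gradients;
strongly negative values mean the protein's more conserved residues
induce its stronger gradients.

Assumptions worth keeping in mind: distances are Cα–Cα throughout (a
deliberate backbone-level abstraction; side-chain geometry enters only
through the packing covariates), conservation scores are comparable
within a protein but not across proteins (which is why ranks exist), and
the gradient is a correlation, not a fitted decay rate — it measures
monotone association, not slope.

## Gradient variants and their parameters

`gradient_variant()` fixes three choices:

* **method** — `pearson` (default) or `spearman` (Pearson on ranks;
  invariant to monotone transforms of the scores, useful when score
  scales are dubious).
* **window** — `full` (all other residues), `(0, 30]` Å, or `(6, 30]` Å.
  Windowed gradients focus on the neighbourhood a site can plausibly
  influence; the 6 Å lower cut additionally excludes immediate contacts
  whose conservation may be driven by direct physical interaction rather
  than percolation. Bounds are lower-exclusive, upper-inclusive: a pair
  at exactly 30.0 Å is included, one at exactly 6.0 Å is excluded.
* **min_points** — minimum residues in the window for a gradient to be
  defined; default 10. Below it (or when either variable is constant in
  the window) the gradient is missing rather than numerically fragile.
  Three points would be the mathematical minimum; 10 keeps single
  correlations from being dominated by one or two neighbours.

Degenerate inputs follow explicit contracts: constant conservation gives
missing gradients everywhere, the reference residue is always excluded,
and windowed point sets are by construction subsets of the full window.

## Geometry: packing, accessibility, interfaces

**SC-WCN.** The side-chain weighted contact number of residue $i$ is
$\sum_{j \ne i} r_{ij}^{-2}$ over side-chain geometric centers (heavy
atoms beyond backbone N, CA, C, O; glycine falls back to Cα), with no
distance cutoff. The inverse-square kernel without cutoff is the common
convention in the weighted-contact-number literature; since published
analyses rarely state every convention, exact numeric agreement with any
particular published SC-WCN table is not claimed — within this package
the definition is fixed and bit-reproducible. The **protein center** is
the residue with maximal SC-WCN (ties to the lowest residue order), and
`distance_to_center()` measures Cα distances from it.

**RSA.** Solvent-accessible surface area uses the Shrake–Rupley rolling
probe (probe 1.4 Å, 240 deterministic quasi-uniform sphere points per
atom — enough that the discretization error is far below the
classification thresholds), normalized by a packaged table of theoretical
maximum ASA per amino-acid type and clamped to [0, 1]. Burial classes
follow fixed thresholds: buried at RSA = 0 (compared with tolerance 1e-9,
so that a genuinely zero area computed through floating point still
classifies as buried), exposed above 0.8, middle between. Unknown residue
types normalize by the table mean with a warning. RSA is computed on the
monomer by default; `detect_interface()` recomputes it with a partner
chain deleted and flags residues whose RSA changes by more than 1e-4 (the
threshold is exposed as an argument; any nonzero change indicates
contact, and 1e-4 sits safely above point-sampling noise).

## Ingestion conventions

ConSurf-style grade files use the native convention that lower (more
negative) scores are more conserved; `read_consurf_scores()` negates at
ingest (flag-controlled) so that *every* downstream formula sees one
orientation: higher = more conserved. Rank ties share average ranks by
default (`min`/`max` selectable); missing scores are excluded from the
rank denominator. Annotation transfer across a pairwise alignment walks
the columns once: target positions aligned to source residues inherit
their values, gap-aligned positions become missing. dN/dS tables are
validated to be non-negative. All user-facing files are 1-based.

## Dataset-level statistics

**Binned trends** (`bin_trend`) use equal-width bins on the rank axis
(20 bins for rank–gradient, 100 for rank–dN/dS trends), right-closed with
the first bin including 0; the linear fit and Pearson r are computed over
all residues, never over bin means, so bin population imbalance cannot
distort the fit. **Subset resampling** (`sample_site_subsets`) draws 1000
subsets of 250 residues per site class by default, uniformly without
replacement within a subset and independently across subsets; pools
smaller than the subset size switch to replacement with a warning rather
than silently shrinking the subset. **Concordance analysis** enumerates
cross-site residue pairs within each multi-site protein (all pairs by
default; top-1 or top-3 most conserved residues per site as alternative
pairing modes, rank ties breaking to the lowest residue index) and asks
whether the more conserved residue also induces the stronger (more
negative) gradient; ties in rank or gradient drop the pair, and the
concordant count is tested against a fair coin with the exact binomial
test (two-sided by default, minlike rule). The definition is symmetric in
the two class filters. **Residualization** fits, over all pooled
residues, gradient ~ rank + covariate (SC-WCN or distance-to-center) by
OLS and subtracts the covariate's centered contribution, preserving the
pooled mean; pooling across proteins is the default because packing
covariates live on a comparable physical scale across proteins, with a
per-protein alternative available by applying the function per protein. A
constant covariate contributes nothing and leaves gradients unchanged;
constant ranks are a genuine design failure and error. **Bootstrap
standard errors** use 50 resampling rounds by default.

Buried non-functional pseudo-sites can be auto-generated from packing
thresholds (SC-WCN > 3.0, or distance to center < 5.0 Å) minus every
annotated functional residue, giving the packing-matched control class.

## The synthetic generator

`generate_dataset()` emulates exactly the statistical structure the
analysis assumes, with every random draw derived from one master seed by
documented stream-splitting (`split_seed`), so any component regenerates
in isolation and written datasets are byte-stable.

* **Structures** are residue clouds packed by rejection sampling,
  uniform in a sphere of radius $3.0\,n^{1/3}$ Å with a 3.8 Å minimum
  separation (the Cα virtual bond length): constant density and a radius
  of gyration matching compact globular domains. They are *not* chains —
  the analysis consumes only distances, so chain connectivity, secondary
  structure and side-chain packing realism are deliberately out of
  scope. Side-chain centroids are Cα plus sub-Å jitter.
* **Conservation** is an affine decay from each planted site,
  $c_i = s_0 - \beta\, d_i + \varepsilon_i$ with $d_i$ the minimum Cα
  distance to the site and $\varepsilon_i \sim N(0, \sigma^2)$. With
  several sites the per-site decays superpose *additively* — selective
  pressure from every site acts on every residue. Additivity was a
  genuinely open design choice (a pointwise maximum of per-site fields
  was the alternative); it was chosen because the maximum lets the
  shallowest decay dominate the field far from a steep site, which both
  inverts the slope–strength link for multi-site proteins and decouples
  a site's conservation from its own slope, whereas additive fields give
  each site a gradient reflecting its own decay and — as in real
  proteins — make residues of steep-decay sites emergently more
  conserved relative to distant sites. Site residues receive a score
  boost (default $2\sigma$) so planted sites are also top-ranked,
  mirroring the premise that functional residues are conserved.
* **Rates** follow $\mathrm{dN/dS}_i = \max(0.001,\; c_0 - c_1\,
  \mathrm{rank}_i + \eta_i)$ (defaults $c_0 = 1$, $c_1 = 0.9$, noise SD
  0.2), monotone-decreasing in rank in expectation with a floor keeping
  rates positive.
* **Sites** are spatially compact (a random seed residue plus nearest
  neighbours) and mutually disjoint.

Reference conditions used throughout the package's checks: proteins of
150 residues, score noise $\sigma = 1$, decay slopes $\beta$ between 0
and 0.3 per Å, 100 proteins for null calibration, 30 per slope level for
recovery, and 25 two-site proteins (catalytic-like $\beta = 0.3$ against
shallow $\beta = 0.1$) with 200 subsets of 50 residues for the
class-separation and concordance analyses. These sizes give stable means
(bootstrap/subset SEs in the third decimal) while keeping a full run in
the tens of seconds.

What passing on synthetic data does and does not show: it validates the
statistical machinery — sign conventions, window semantics, estimator
calibration, planted-effect recovery and class separation — under a
known ground truth. It does not validate structural realism (no chains,
no real contact topology), alignment-transfer noise, phylogenetic
correlation between residues, or database annotation quality; real-data
conclusions inherit those caveats from their inputs.

## Numerical behaviour of the null

One property uncovered by the package's own calibration checks deserves
emphasis: under the null (no planted decay, i.i.d. scores) the
per-residue gradients at site residues are unbiased around zero, but the
*per-protein correlation between ranks and gradients* is not exactly
centered on zero — it carries a small positive bias (a few hundredths at
150 residues). Every residue's score enters every other residue's
gradient, so ranks and gradients share noise, and the empirical
correlation across residues inherits a finite-sample coupling. The bias
shrinks with protein size and is negligible against the strongly
negative values real signal produces, but analyses that interpret
near-zero per-protein correlations should keep it in mind. The
acceptance script computes this null mean alongside the other headline
quantities.

## A small worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(
  n_proteins = 8, n_residues = 120,
  sites = list(list(site_type = "catalytic", k = 4, beta = 0.3, s0 = 0),
               list(site_type = "ppi",       k = 4, beta = 0.1, s0 = 0)),
  sigma = 1, seed = 42)
run <- run_pipeline(run_config(synthetic = cfg, n_subsets = 100,
                               subset_size = 30, seed = 42))
run$trend_rank_gradient
mean(run$percolation$percolation_r)
run$concordance$fraction
```

Real files go through the same surface; a tiny synthetic fixture ships
with the package for format reference:

```{r fixture, eval = FALSE}
s <- read_structure(system.file("extdata", "synthetic_toy.pdb",
                                package = "consgrad"))
prof <- read_consurf_scores(system.file("extdata",
                                        "synthetic_toy_grades.tsv",
                                        package = "consgrad"),
                            consurf_orientation = TRUE)
gradient_profile(s, prof)
```

## Known limitations

* Gradients are correlations, not mechanistic decay parameters; two
  sites with different spatial score profiles can share a gradient value.
* RSA is monomer-based by default; whether a deposited assembly is the
  right accessibility context is a per-study decision.
* SC-WCN conventions differ across the literature (kernel, centroid,
  cutoff); cross-package numeric comparisons need care.
* The concordance analysis conditions on annotated multi-site proteins;
  annotation incompleteness (e.g. unannotated catalytic residues inside
  ligand-binding sites) biases class comparisons in real data.
* The synthetic generator plants monotone, isotropic decay; anisotropic
  percolation along secondary-structure elements or allosteric paths is
  not modelled.
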