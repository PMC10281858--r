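---
title: "Neighborhood set tests with permutation nulls: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood set tests with permutation nulls: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppigwas)
```

## The model

`ppigwas` tests, for every gene $v$ in a protein–protein interaction (PPI)
network, whether the SNPs of its $k$-hop neighborhood are jointly
associated with a quantitative trait.  Sample $i$'s neighborhood feature
vector is the union of the dosage values of all SNPs overlapping the
member genes,
$$\ell_i(v) = \bigcup_{v' \in N_k(v)} a_i(v'),$$
and the set enters a linear mixed model as a random effect,
$$y = X_f\beta_f + g + \varepsilon,\qquad
  g \sim \mathcal N(0, \sigma_s^2 \tilde K_s),\qquad
  \varepsilon \sim \mathcal N(0, \sigma_e^2 I),$$
with $\tilde K_s$ a kernel over the neighborhood features: linear
($L L^\top$, i.e. an additive polygenic model on the set) or inhomogeneous
polynomial ($(1+\langle \ell_i,\ell_j\rangle)^2$, whose implicit feature
space adds all pairwise SNP products, so epistatic signal inside the set
becomes visible without ever materializing the interaction design).  The
kernel diagonal is normalized to 1 so the set variance component
$\sigma_s^2$ lives on a comparable scale across neighborhoods of very
different SNP counts.  Association is measured by the restricted-likelihood
ratio $t = \max\{0,\, 2(\ell_{\mathrm{alt}} - \ell_{\mathrm{null}})\}$
between the $\sigma_s^2 \ge 0$ and $\sigma_s^2 = 0$ fits.

Assumptions worth stating: the trait is continuous with approximately
Gaussian residuals; dosages are 0/1/2 minor-allele counts; the network is
an undirected simple graph and edge confidence filtering has happened
upstream; and the model contains **no background kinship component** — the
covariance is exactly $\sigma_s^2\tilde K_s + \sigma_e^2 I$.  Confounding
by relatedness is instead neutralized by the permutation scheme (below),
which leaves the arrangement of individuals untouched; optional fixed-effect
covariates (e.g. leading genotype principal components) can be supplied via
`covariates` when explicit adjustment is wanted.

## REML fitting

The alternative fit profiles the restricted likelihood over the variance
ratio $\delta = \sigma_e^2/\sigma_s^2$: the kernel is eigendecomposed once,
$y$ and $X_f$ are rotated into the eigenbasis, and for fixed $\delta$ both
$\hat\beta_f$ and $\hat\sigma_s^2$ have closed forms, leaving a 1-D search
on $\log_{10}\delta \in [-8, 8]$ (a 21-point bracketing grid, then Brent
refinement to tolerance $10^{-6}$ — the profile can be multimodal, so the
grid comes first).  For the linear kernel the eigen work runs on the
$n_s$-dimensional Gram factor, giving the $O(n\,n_s^2)$ per-set cost that
makes $n_g \times n_p$ refits affordable; the polynomial kernel falls back
to the dense $n \times n$ decomposition.  The $\sigma_s^2 = 0$ boundary is
evaluated explicitly (it is ordinary least squares with
$\hat\sigma_e^2 = \mathrm{RSS}/(n - n_f)$), and ties are resolved toward
the null with an absolute slack of $10^{-6}$ on the log-likelihood, which
absorbs spectral round-off when the kernel is (nearly) non-identified —
e.g. $\tilde K_s \propto I$, where alternative and null coincide by
construction and the statistic must be exactly 0.  Eigenvalues below
$10^{-12}$ of the largest are treated as zero.  Degenerate inputs are
signalled, not guessed at: a response explained exactly by the fixed
effects, an all-zero (monomorphic) kernel, or a non-finite likelihood mark
the neighborhood untestable and it is dropped from both the observed
statistics and the null pool, with a message.

The factor 2 and the clip in $t$ are conventions: the null distribution is
empirical and undergoes the identical transform, so only ordering matters.

## The permutation null

Under the per-neighborhood null hypothesis, LD among SNPs and the
population structure of the samples must be preserved.  Each permutation
index $m = 1,\dots,n_p$ therefore applies two randomizations jointly:

* **Circular SNP rotation.**  The gene-mapped SNP columns, in genomic
  order concatenated across chromosomes, are rotated by an offset
  $r \in \{1,\dots,p_{\mathrm{tot}}-1\}$ drawn without replacement across
  permutations (the identity is excluded; it would reproduce the observed
  statistics).  Coordinates — and hence the gene membership of every
  position — stay fixed, so each gene receives a different stretch of the
  genome while the relative order of SNPs, and with it the LD structure
  and any population stratification pattern, is conserved exactly.  Sample
  rows are never permuted.  SNPs mapping to no gene are excluded from the
  rotation domain: they never enter any neighborhood, and keeping them
  would let signal rotate into oblivion rather than into another
  neighborhood.  The rotation direction is fixed (columns shift forward);
  it is statistically irrelevant and determinism matters more.
* **Degree-preserving network permutation.**  Double-edge swaps — draw two
  edges $(v_a,v_b)$, $(v_c,v_d)$; reject the draw if any of $v_a,v_b$ is
  already connected to any of $v_c,v_d$; otherwise rewire to $(v_a,v_c)$,
  $(v_b,v_d)$ — repeated until at least `fraction` (default 0.5) of the
  original edges are absent from the current edge set.  An edge counts as
  rearranged only while absent, so a swap that later restores it un-counts
  it.  A cap of $100\,|E|$ candidate draws bounds the runtime on swap-poor
  graphs (a clique admits no valid swap at all); hitting the cap returns
  the best effort with a warning.

Neighborhoods are recomputed on the permuted network with the same $k$ as
the main analysis, every testable one is refit, and all statistics are
pooled: $T_0 = \{t^0_{l,m}\}$ with $|T_0| = n_g' \times n_p$.  Pooling
across neighborhoods is what lets `np` stay modest (default 100; the
calibration checks in this package use 20 at $n_g' = 100$).  A manifest
(permutation index, rotation offset, network seed) is kept so any single
null statistic can be regenerated.

The empirical p-value is
$$p_j = \frac{1 + \#\{t^0 \in T_0 : t^0 \ge t_j\}}{1 + |T_0|},$$
with ties counted for the null (conservative) and a +1/+1 pseudocount so
$p_j \in [1/(|T_0|+1),\, 1]$.

**What calibration does and does not mean here.**  Under a boundary test
roughly half of all null statistics are exactly 0 (the classical
$\tfrac12\delta_0 + \tfrac12\chi^2_1$ mixture), and every observed $t = 0$
then receives $p = 1$.  The p-value distribution under a pure-noise
phenotype is therefore uniform on its lower range but carries a large,
*conservative* atom at $p = 1$: tail probabilities obey
$P(p \le \alpha) \approx \alpha$ at any useful $\alpha$ (the acceptance
script measures the type-I error at $\alpha = 0.05$), while a global
uniformity statistic such as the Kolmogorov–Smirnov distance is dominated
by the atom and stays far from 0 no matter the sample size.  This is a
structural property of boundary likelihood-ratio statistics with
tie-conservative empirical p-values, not a finite-permutation artifact.

## Multiple testing

Within one trait, Benjamini–Hochberg across the $n_g'$ neighborhoods at
level $\alpha$.  Across $T$ traits, a two-level procedure: each trait's
p-values are combined by Simes' method, BH is applied across the $T$
trait-level p-values, and within each of the $R$ selected traits BH runs
at the reduced level $\alpha R/T$.  With $T = 1$ this reduces exactly to
plain BH.  The two-level construction is deliberately isolated behind
`hierarchical_fdr()` so an alternative hierarchical scheme can be swapped
in without touching anything else.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `k` | 1 | hop count; direct interactions are the biologically defensible unit, and cost grows only linearly in nodes for larger `k` |
| `kernel` | linear | `poly` adds pairwise-interaction sensitivity at $O(n^3)$ per fit |
| `np` | 100 | permutations; pooling makes the effective null size $n_g' n_p$ |
| `fraction` | 0.5 | share of edges rearranged per network permutation |
| `pseudocount` | 1 | +1/+1 empirical p-value; keeps $p > 0$ |
| `alpha` | 0.05 | FDR level |
| `standardize` | TRUE | center/scale SNP columns before the kernel, so each SNP contributes equal prior variance regardless of allele frequency |

Column standardization is exposed as a flag because an unstandardized
linear kernel (raw dosage inner products) is also a legitimate choice that
up-weights common variants.

## The synthetic study

The generator emulates the ingredients a real study would bring, at desk
scale and with a known ground truth:

* **Genotypes** — two independent haplotypes per sample; within an LD
  block the haplotype latents follow an AR(1) Gaussian (lag-one
  correlation `within_block_corr`, default 0.9, blocks of 10 SNPs) and are
  thresholded at a per-SNP MAF drawn from `maf_range` (default
  0.05–0.5), so dosages are Hardy–Weinberg with block LD, tiled over two
  chromosomes.
* **Network + annotation** — a preferential-attachment graph (heavy-tailed
  degrees, as in PPI networks; mean degree 4), with gene labels assigned
  to nodes at random and genes tiled as disjoint genomic intervals of
  about $p/n_g$ SNPs each.
* **Causal configuration** — `ncg` causal genes grown greedily as a
  connected subgraph whose realized mean ratio of causal neighbors (RCN)
  lands within $\pm 0.1$ of the target (at RCN $= 0$, a pairwise
  non-adjacent set instead); per causal gene, $\lceil r_c \cdot
  \text{slots}\rceil$ of its SNPs become causal.
* **Phenotype** — $y = c\,X\beta + (1-c)X^{(2)}\beta^{(2)} + \varepsilon$
  with standard-normal effects on the standardized causal columns;
  $X^{(2)}$ holds elementwise products of $\min(2\,\#\text{causal
  slots},\ \text{all pairs})$ random causal-slot pairs — the full
  $p(p-1)/2$ interaction design is neither desk-feasible nor needed, since
  the effect vector over all pairs is implicitly sparse; the noise
  variance is $\mathrm{var}(\text{signal})/\mathrm{SNR}$, and the realized
  SNR is recorded.

The anchor scenario (`scenario_config()` defaults) uses $n=300$, $p=1200$,
$n_g=120$, $n_{cg}=18$ (15% of genes), $r_c = 0.75$, RCN $= 0.8$, purely
linear signal, SNR $= 0.25$.  The SNR was fixed by a noncentrality
argument, not by experimentation on outcomes: the per-gene share of signal
variance, $\mathrm{SNR}/((1+\mathrm{SNR})\,n_{cg})$, should sit below the
single-gene detection knee at $n = 300$ while the neighborhood aggregation
multiple ($1 + \mathrm{RCN}\times\text{mean degree} \approx 4.2$) lifts
causal neighborhoods above it — that is the regime in which
network-guided set testing is the right tool, and the regime the
benchmark is meant to probe.  Ranking quality is summarized by the area
under the precision–recall step curve over genes (tied scores move as one
block, so a constant ranking scores exactly the prevalence), against the
simulated causal genes; the gene-only baseline is the identical mixed
model with $k = 0$ sets.

What the generator does **not** emulate: realistic long-range LD decay and
recombination maps, allele-frequency spectra, genuine population
stratification or cryptic relatedness, network modularity beyond what
preferential attachment induces, binary or non-Gaussian traits, and rare
variants.  Passing benchmarks here therefore demonstrate the machinery
(calibration of the permutation null, the benefit of aggregation when
causal genes cluster, its disappearance when they do not) — they do not
predict absolute power on any real dataset.  One consequence of the desk
prevalence (15% causal genes, against a few percent in a realistically
sized study) is that precision-based dominance of the neighborhood method
over the gene baseline is structurally compressed: the baseline's AUPRC
floor is already the prevalence, so ratio-type advantages are far smaller
than they would be at realistic prevalence.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the calibration study at
$n=300$, $p=1000$, $n_g=100$, $n_p=20$ over 5 seeds, and the power/trend
studies at the anchor size with $n_p = 10$ and 5 replicates per scenario
point — sizes chosen so the whole validation runs in minutes on one core
while keeping $|T_0| \ge 2000$ and stable AUPRC means.

## Known limitations

* Significant neighborhoods are not localized further: the test speaks for
  the set, not for individual genes or SNPs within it; post-hoc analysis
  (e.g. sparse regression inside the significant neighborhoods) is the
  intended follow-up.
* Genes with no mapped SNPs still shape the topology but are skipped as
  test centers; their signal is only visible through neighbors.
* The empirical null prices network randomness with degree-preserving
  swaps only; graph features beyond the degree sequence (clustering,
  communities) are not held fixed.
* Binary traits and dosage (imputed, non-integer) genotypes are out of
  scope; missing hard calls are imputed to the rounded per-SNP mean before
  any kernel work (R's round-half-even; the count is reported).
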