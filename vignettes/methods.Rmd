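---
title: "Models and methods behind micronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind micronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(micronet)
```

`micronet` packages the analysis chain of a comparative two-condition 16S
amplicon survey: abundance profiling, alpha/beta diversity with
nonparametric group tests, moderated-t differential abundance, and
compositional co-occurrence networks. This vignette explains the models, the
parameters that matter, and the design decisions taken where several
reasonable choices existed.

## Diversity indices

Per sample with counts $c_1, \dots, c_S$ and total $N$:

* **Richness** is the number of taxa with $c_i > 0$.
* **Chao1** uses the bias-corrected form
  $S + F_1 (F_1 - 1) / (2 (F_2 + 1))$ with $F_1, F_2$ the singleton and
  doubleton counts. The bias-corrected variant is defined even when
  $F_2 = 0$, which matters on shallow samples; it reduces to the richness
  whenever no singletons exist.
* **Shannon** is $-\sum p_i \log_2 p_i$ in **log base 2**. Published
  per-sample values in deep soil surveys (up to ~10.9 at fewer than 4,000
  ASVs) exceed the natural-log ceiling $\ln S$ but fit the $\log_2 S$
  ceiling, so bits are the only consistent reading of such tables; the
  package standardizes on it.
* **Faith PD** is the total branch length of the rooted subtree spanning the
  observed tips — the rooted convention, so a single observed tip scores its
  root-to-tip path length. Computation delegates to `picante::pd`.
* **Good's coverage** is $100 (1 - F_1 / N)$, a percentage.

Rarefaction subsamples each retained sample without replacement to exactly
the target depth (default 33,000 reads, the standardization depth typical of
this design); samples below the depth cannot be standardized and are dropped
with a warning. The iteration count for rarefaction curves defaults to 10 —
enough to stabilize the means without dominating run time; the seed is
exposed.

Group comparisons use the Mann-Whitney or Kruskal-Wallis test. For combined
$n \le 10$ the p-value comes from exhaustive enumeration of all label
assignments with mid-ranks for ties; beyond that, a tie-corrected normal
(respectively $\chi^2$) approximation without continuity correction, so the
squared Mann-Whitney z equals the two-group Kruskal-Wallis statistic and the
two tests decide identically.

## Beta diversity

Bray-Curtis $d(u, v) = \sum |u_i - v_i| / \sum (u_i + v_i)$ is a semi-metric
(no triangle inequality), which is why PCoA reports its negative eigenvalues
rather than hiding them. ANOSIM follows the standard rank form
$R = (\bar r_{between} - \bar r_{within}) / (M/2)$, $M = n(n-1)/2$, with the
permutation p-value $(1 + \#\{R^* \ge R\}) / (1 + n_{perm})$ — the $+1$
correction means a report of "p < 0.001" requires at least 999 permutations,
which is the default. NMDS minimizes Kruskal stress-1 through vegan's
`metaMDS`/`monoMDS` engine (primary tie treatment, 20 random restarts kept
at their best). We deliberately use the field's canonical optimizer rather
than re-deriving the isotonic-regression descent: the restart-initialization
scheme is an implementation detail, while stress definition, convergence
flags and restart counts are part of the contract and are surfaced in the
result object. UPGMA is average-linkage `hclust`; its tree is ultrametric by
construction.

## Moderated t differential abundance

Counts are transformed before testing; the default is the centered log-ratio
(clr), consistent with the network stage's compositional treatment (the
alternative `log_relative` uses pseudocounted log relative abundances). For
each taxon the pooled two-sample variance $s^2$ on $d_{res}$ df is shrunk
toward a prior $s_0^2$:

$$\tilde s^2 = \frac{d_0 s_0^2 + d_{res} s^2}{d_0 + d_{res}},$$

with $(d_0, s_0^2)$ estimated by method of moments on the scaled-F
distribution of the $s^2$ across taxa (`limma::fitFDist` does exactly this
fit and is used for it). The moderated statistic is referred to a
t distribution on $d_0 + d_{res}$ df and BH-adjusted. Setting the prior df
override to 0 recovers the ordinary two-sample t exactly — a useful
degeneracy check — and a failed or non-finite prior fit falls back to the
ordinary t with a warning. The full path is cross-checked against
`limma::eBayes` in the test suite.

## The network pipeline

Per condition (each condition's samples only — 9 and 8 in the emulated
design):

1. **Prevalence filter**: keep ASVs with nonzero counts in at least 5
   samples (inclusive).
2. **clr transform**: $x_{ij} = \ln(c_{ij} + 1) - \overline{\ln(c_{i\cdot} + 1)}$;
   the pseudocount of 1 handles zeros, and each transformed row sums to 0.
3. **Pearson correlation** across samples for every ASV pair; zero-variance
   ASVs are excluded (their correlation is undefined).
4. **RMT threshold** (below).
5. **Signed network**: edges where $|r| \ge \tau$, sign $= \mathrm{sign}(r)$,
   weight $w = (1 + r)/2$ — the affine map sending $r = 1$ to weight 1 and
   $r = -1$ to weight 0. Modularity and centrality run on these non-negative
   weights, which is what fast-greedy merging and power iteration require.
6. **Fast-greedy clusters** (Clauset-Newman-Moore via igraph) with
   canonicalized cluster ids (decreasing size, ties by smallest member), so
   partitions are invariant to node input order.
7. **Summaries**: positive/negative counts with the ratio
   $n_+ / \max(n_-, 1)$ — the $\max(\cdot, 1)$ denominator is forced by the
   convention that a node or network with zero negative edges reports its
   positive count as the ratio (e.g. 23 positive / 0 negative = 23.0);
   intra-/inter-cluster sign decomposition; per-ASV ratio shifts between the
   two condition networks sorted by fold-change; and keystone taxa.

### RMT threshold selection

The idea: a correlation matrix dominated by system-wide sampling noise has
delocalized eigenvectors and GOE (Wigner-Dyson) nearest-neighbor spacing
statistics, $p(s) = (\pi s / 2) e^{-\pi s^2/4}$; once thresholding has
stripped the noise and left modular structure, eigenvalues belong to
effectively independent blocks and spacings follow the Poisson law
$e^{-s}$. For each candidate threshold on a grid (default 0.10–0.98, step
0.01) the package zeroes sub-threshold entries, collapses near-degenerate
eigenvalues (tolerance $10^{-10}$), unfolds the spectrum with a smoothing
spline fitted to the cumulative spectral function (default 10 df), and
computes Kolmogorov-Smirnov distances of the unit-mean spacings to both
laws. Grid points with fewer than 30 usable spacings are skipped.

The selected $\tau$ is the smallest grid point opening a run of at least 5
consecutive usable points where the Poisson distance is below the GOE
distance. An earlier rule — requiring Poisson to stay closer for *all*
larger grid points — proved brittle: in the sparse tail of the grid only a
handful of spacings survive and their KS verdicts flip randomly, vetoing an
otherwise clean transition. The persistence window keeps the "earliest
stable transition" semantics while ignoring that tail noise; on clean traces
(pure-noise matrices, pipeline-scale data) both rules select the same
threshold. The full distance trace is returned and plotted by `autoplot()`
so the choice is auditable.

### Keystone taxa

Eigenvector centrality is computed per connected component by power
iteration on $W + I$ (the shift leaves eigenvectors unchanged while
preventing oscillation on bipartite components; tolerance $10^{-10}$, cap
10,000 iterations, non-convergence is an error), each component scaled to
maximum 1, then ranked across the network. A node is keystone when its
centrality is strictly above the 90th percentile and its mean relative
abundance strictly below the median — strict inequalities, so boundary ties
are excluded (the conservative reading of "top 10% … below the median").
A consequence worth knowing: in heavily fragmented networks many component
maxima tie at 1, the 90th percentile can itself be 1, and the keystone set
is then empty. That is the tie rule working as designed, not a failure.

## The synthetic community generator

`synthetic_spec()` describes a logistic-normal–multinomial model. Per sample
$i$ in group $g$, latent log-abundances are

$$\eta_{ij} = b_j \pm e_j/2 + m_{ij} + \log G_{ij}, \qquad
G_{ij} \sim \mathrm{Gamma}(a_g k w_{gj}),$$

with baseline log-weights $b_j \sim N(0, 1)$, sparse symmetric group effects
$e_j$ ($\pm e_j/2$ keeps both group baselines equally skewed, so the planted
evenness gap is governed by the concentration alone), module-structured
Gaussian noise $m_{ij}$ realized through per-module latent factors, and a
per-sample gamma layer whose group concentration $a_g$ plays the Dirichlet
role: with no modules and no effects the model reduces exactly to a
Dirichlet-multinomial, and with equal concentrations and zero effects the
group labels are fully exchangeable (so null simulations give uniform
p-values). Counts are multinomial at a depth drawn uniformly from the depth
range. One integer seed drives all randomness in a documented stream order
(baseline, effects, depths, module factors, per-sample draws, taxonomy,
tree), so partial regeneration is stable.

Defaults emulate the two-condition soil design the package targets: 9 "H"
vs 8 "NI" samples; depths uniform on [33,000, 69,000]; 3,000 ASVs (a
desk-scale stand-in for the tens of thousands in deep surveys);
concentrations 0.2 (H) vs 2 (NI) — a 10× gap planting lower evenness in H;
45% of ASVs carrying $N(0, 2)$ log-fold effects, echoing surveys where
roughly half of all families shift under land-use change; and three 25-ASV
positive modules at strength 0.85 whose members get a baseline boost of 1.5
log units so network-forming taxa sit above the detection and prevalence
filters, with module noise sd 1. Under these settings forward simulation
reproduces the qualitative structure of the motivating design: a ~2× richness
ratio, a Shannon gap near 1 bit with tight within-group spread, and strong
ANOSIM separation.

What the generator does **not** emulate: sequencing error, chimeras,
taxonomic misclassification, phylogenetic signal in abundances (the tree is
random, so Faith PD differences arise from richness alone), spatial or
temporal autocorrelation between replicates, and environmental covariates.
Passing recovery tests therefore demonstrates that the estimators recover
structure *of the kind planted*, not that real soil data satisfy the model.

## Numerical choices and degenerate inputs

* The 0.01% abundance filter applies to **dataset-wide** relative abundance
  with an inclusive boundary; the intent of the filter is to drop globally
  uninformative ASVs, and a per-sample variant would re-admit them through
  single noisy samples. The "Others" bucket likewise uses overall relative
  abundance (cutoff 1%), and taxa unclassified at the displayed rank join it.
* Empty samples get richness 0 and `NA` for the undefined indices, with a
  warning — never a silent 0.
* An edgeless network clusters into singletons with $Q = 0$; an all-zero
  sample is an error in distance computations (named in the message).
* Exact enumeration limits ($n \le 10$) keep the assignment count at most
  $\binom{10}{5} = 252$ (Mann-Whitney) / a few thousand (Kruskal-Wallis).
* Permutation p-values never return 0 (the $+1$ correction).
* Test-suite problem sizes are scaled to what the properties need: null
  uniformity uses 200 replicates of 80-ASV tables; directional recovery 50
  replicates at 400 ASVs; RMT transition checks use $p = 100$, $n = 200$
  matrices over 20 seeds; module recovery uses 50 samples at 150 ASVs. The
  defaults themselves stay at the emulated study scale.

## Known limitations

* With 8–9 samples per condition, Pearson correlations are extremely noisy
  and the RMT threshold lands high (≈0.85–0.95); the resulting networks are
  sparse and fragmented, and most surviving edges are individually at the
  noise edge. This mirrors the small-$n$ reality of the emulated design
  rather than a shortcoming of the threshold rule.
* The positive-to-negative edge ratios of simulated networks hover near 1
  because sampling-noise correlations are sign-symmetric; real communities
  shaped by shared environmental filtering show strong positive bias. The
  simulator plants positive modules but does not impose a global positive
  bias on the noise.
* Keystone sets can be empty on fragmented networks (see above).
* The moderated t is the single documented differential-abundance test; no
  multi-tool consensus calling is provided.
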