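---
title: "Methods: gridded allele-frequency mapping and geographic cline analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded allele-frequency mapping and geographic cline analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinemap)
```

# The problem

Many aposematic (warning-coloured) species are geographically variable in
colour pattern despite the expectation that predator learning should fix the
locally common form. For a highly dispersive butterfly such as the African
monarch, colour morphs are controlled by a small number of Mendelian loci
with full dominance, and the geographic structure of the polymorphism —
where each allele is fixed, where it is polymorphic, how wide the
transitions are — carries information about the balance of selection and
dispersal. `clinemap` implements the complete quantitative chain from raw
georeferenced occurrence records, scored only into dominant and recessive
phenotype classes, to fitted allele-frequency clines with credible
intervals and to tests of environmental association, plus a synthetic
record generator so every stage can be validated against known truth.

# From dominance-scored records to allele frequencies

Heterozygotes are not reliably distinguishable from dominant homozygotes at
these loci (variable penetrance), so each record carries, per locus, one of
two phenotype classes — the homozygous-recessive class or the pooled
dominant class — or a missing call. Records are grouped into
latitude/longitude grid cells (half-open squares anchored at (-180, -90);
4 degrees by default, 2 degrees for sensitivity checks). Within a cell the
counts are pooled and, under Hardy-Weinberg equilibrium, the recessive
allele frequency is estimated as

$$\hat q = \sqrt{\,n_{\mathrm{rec}} / n_{\mathrm{scored}}\,},$$

since the recessive class has frequency $q^2$ under HWE. The estimator is
applied per cell and locus, never averaged over records' individual
contributions. $\hat q$ is slightly biased for finite samples (the square
root is concave); at 500 genotypes the absolute bias is below 0.005 across
$q \in \{0.1, 0.5, 0.9\}$, which the test suite verifies against direct
binomial simulation. Records missing at all three loci still count toward
cell occupancy (they carry distributional information), but never enter
frequency denominators.

Per-cell frequencies are classified as *near-fixed* (> 0.95), *polymorphic*
(0.05–0.95) or *near-absent* (< 0.05); the thresholds are arguments, with
these conventional defaults.

# Transects and great-circle projection

Cline fitting is one-dimensional: grid cells are projected onto a
user-supplied transect, an ordered sequence of waypoints joined by
great-circle segments with a corridor half-width (450 km by default). For a
cell centre $P$ and a segment from $A$ to $B$, with $d_{13}$ the
great-circle distance $A \to P$, $\theta_{13}$, $\theta_{12}$ the initial
bearings $A \to P$ and $A \to B$, the signed cross-track distance is

$$d_{xt} = R \,\arcsin\!\big(\sin(d_{13}/R)\,\sin(\theta_{13} - \theta_{12})\big),$$

and the along-track distance of the perpendicular foot is

$$d_{at} = R \,\arccos\!\big(\cos(d_{13}/R) / \cos(d_{xt}/R)\big),$$

on a sphere of radius $R$ = 6371.0088 km (the IUGG mean radius; at a
4-degree cell size the departure from an ellipsoidal model is immaterial).
A cell joins the transect data set if its nearest path point lies within
the corridor; its position is the cumulative along-track distance. Feet
falling beyond a segment end resolve to the adjacent segment through the
shared waypoint (the nearest path point for cells in the corner wedge);
cells projecting beyond the terminal waypoints are excluded. All of this
is validated against a dense brute-force scan of 10^5 evenly spaced path
points: agreement is within 0.05 km over 1000 random cases, comfortably
inside the 1 km acceptance bound.

# The cline model family

The fitted curve is the standard hybrid-zone sigmoid with optional
exponential tails. The central shape in along-transect distance $x$ is

$$f(x) = \frac{1}{1 + e^{-4 (x - c)/w}},$$

with centre $c$ (km) and width $w$ (km; the inverse of the maximum slope
scaled by 4). With tails, beyond offsets $\delta_L$, $\delta_R$ from the
centre the curve follows exponential approaches to the asymptotes with
slope-ratio parameters $\tau_L, \tau_R \in [0, 1]$; the junction is
continuous in value always and in first derivative when $\tau = 1$ (checked
numerically by finite differences). The observed frequency is
$p(x) = p_{\min} + (p_{\max} - p_{\min}) f(x)$.

Six models are distinguished by *scaling* (none: asymptotes 0 and 1;
fixed: asymptotes pinned to the observed extreme frequencies within the
corridor; free: estimated) and *tails* (none / both), giving
$k = 2 + 2\,[\text{free}] + 4\,[\text{tails}]$ free parameters. Models are
named by their (scaling, tails) pair throughout; no index numbering is
used, because an index order is not meaningful.

The likelihood treats the per-cell estimate $\hat q_i$ as a binomial
proportion of $m_i$ alleles:

$$\log L = \sum_i m_i \big[\hat q_i \log p(x_i) + (1 - \hat q_i) \log(1 - p(x_i))\big],$$

with $m_i = 2 n_i$ under the default convention ($n_i$ scored
individuals = $2 n_i$ alleles; switchable to $m_i = n_i$ via
`allele_counts = "n"` for users who prefer the conservative choice, since
$\hat q$ from dominance data is noisier than a true allele count). Fitted
frequencies are clamped to $[10^{-6}, 1 - 10^{-6}]$ so observed 0/1
frequencies keep the likelihood finite. Clines that decrease along the
transect are fitted on the complement frequency with the orientation
recorded, so $w > 0$ always and reported curves are mapped back to the
data orientation.

## Maximum likelihood and model choice

`fit_cline_ml()` maximises the likelihood with bounded quasi-Newton
(L-BFGS-B) from ten dispersed deterministic starts (five centre positions
crossed with two widths); under free scaling the asymptotes are
parameterised as $(p_{\min}, p_{\max} = p_{\min} + \Delta(1 - p_{\min}))$
so the order constraint stays smooth. Effectively flat data drive the
width to its upper bound (4 times the data span); this is flagged with a
warning rather than hidden. Model comparison uses the small-sample
corrected AIC,

$$\mathrm{AICc} = -2\log L + 2k + \frac{2k(k+1)}{n - k - 1},$$

with $n$ the number of cells; ties resolve toward fewer parameters. On
data simulated without tails, the tails-free model is within 2 AICc of the
best model in ~98% of replicates.

## MCMC and credible regions

Posteriors come from random-walk Metropolis sampling: per-parameter
Gaussian proposals, uniform priors over a box (centre within one data-span
of the data range; width in $(0, 4\,\mathrm{span}]$; tail offsets in
$[0, 2\,\mathrm{span}]$; $\tau$ and asymptotes in $[0,1]$ with
$p_{\min} < p_{\max}$). Three independent chains (default) start from the
ML estimate jittered per chain, run $10^4$ burn-in generations during
which proposal scales adapt in windows of 100 generations toward a
0.15–0.45 acceptance rate, then $10^5$ sampling generations with scales
frozen (adaptation during burn-in only keeps the chain a valid Metropolis
sampler). Draws are thinned (default every 10th) and pooled; convergence
is monitored with the Gelman-Rubin statistic per parameter, and
$\hat R > 1.1$ attaches a warning rather than failing, so a long pipeline
reports rather than aborts. Seeds default to a hash of (transect name,
locus) so pipeline outputs are reproducible byte for byte; any seed can be
supplied.

The 95% credible intervals for centre and width are posterior 2.5–97.5%
quantiles; the "fuzzy cline" envelope is the pointwise quantile band of
the fitted curve over posterior draws (the envelope uses at most 5000
draws, which changes band edges by far less than MCMC noise). The offset
between two clines on the same transect is the absolute difference of
posterior median centres, with an interval from differences of paired
draws (the posteriors are independent, so pairing is arbitrary).

On the reference design — 31 cells every 100 km, truth $c = 1500$ km,
$w = 400$ km, 100 individuals per cell — the posterior median centre is
off by ~5 km on average, the 95% interval covers the truth in ~96–100% of
replicates, and the width is within 25% of truth in 100% of replicates
(50-replicate runs; the acceptance script recomputes these numbers).

# Environmental association

The per-cell morph frequency at the background-colour locus (dominant,
dark class by default; switchable) is regressed on four abiotic
covariates: annual mean temperature (bio01, deg C), solar radiation
(bio20), annual precipitation (bio12, mm) and a soil moisture index
(bio28), each averaged over record locations within the cell. Three
layers of evidence are computed:

* univariate screens — per-covariate linear regressions weighted by the
  number of records per cell, and both weighted and unweighted Pearson
  correlations (t-approximate p-values on $n - 2$ df);
* collinearity — variance inflation factors
  $\mathrm{VIF}_j = 1/(1 - R_j^2)$, with perfect collinearity reported as
  infinite rather than failing;
* generalized least squares over all $2^4 = 16$ covariate subsets
  (including the null), with residual covariance
  $$\Sigma_{ij} = \sigma^2 \sqrt{v_i v_j}\, e^{-d_{ij}/\rho}, \qquad
    \Sigma_{ii} = \sigma^2 v_i,$$
  where $v_i = 1/n_i$ (inverse records per cell) and $d_{ij}$ is the
  Euclidean distance between cell centres **in degrees** — the
  coordinate-space convention kept deliberately, with great-circle
  distance a trivial caller-side substitution if wanted. No nugget term
  is included (the structure is pure exponential).

Given $\rho$, the GLS coefficients and the ML variance scale have closed
forms, so fitting profiles a 1-D likelihood in $\log \rho$ (bounded golden
search). ML rather than REML is used so AIC ($-2\log L + 2k$, $k$ =
coefficients + 2 for $\sigma^2$ and $\rho$) is comparable across
fixed-effect structures. Wald standard errors use the $n - p$
residual-variance denominator and t-based p-values — the convention of
standard GLS software, which the tests verify reproduces `nlme::gls`
exactly. Coverage of the 95% Wald interval at the validation design is
~93% (300 replicates): the familiar slight undercoverage of plug-in Wald
intervals under strong spatial correlation, worth knowing when reading
the per-covariate verdicts.

A covariate is finally judged on three criteria: presence in all of the
top five models by AIC, a significant effect in the best model, and
significance in both the weighted univariate regression and the
unweighted Pearson correlation; the verdict is their conjunction.

# The synthetic world

`world_spec()` defines a generating process with the statistical structure
the analysis assumes — and its defaults are the package's reference study
conditions:

* three independent, fully dominant loci whose recessive-allele
  frequencies follow clines along a shared ~3900 km equatorial
  great-circle axis (centres 1000, 1800 and 2500 km; widths 400, 800 and
  400 km — the middle locus broadest, mirroring how background-colour
  variation is the most diffuse of the three traits);
* sampling effort drawn from a five-hotspot Gaussian mixture (spread 4
  degrees, unequal weights) to emulate geographically biased collecting;
  a uniform alternative is a one-line hotspot table away;
* 20 000 records, ~32% from the citizen source, and a 50% chance that a
  citizen record's B call is missing (background colour cannot be scored
  from underside photographs);
* covariate surfaces built parametrically: temperature linear in absolute
  latitude (30 - 0.45 |lat| ± 1 deg C noise), radiation linear in
  temperature, precipitation linear in absolute latitude, and soil
  moisture constructed from standardized precipitation to hit a 0.9
  correlation at the record level. Cell averaging necessarily raises
  such correlations, so the construction is checked at record level.

Genotype classes are drawn under HWE at the local true frequency
(recessive with probability $q^2$), and everything is reproducible from a
single seed. The generator does **not** model: land/ocean masks (ocean
"records" are harmless for statistical validation), temporal trends,
duplicate records across databases, heterozygote excess from male-killing
endosymbionts, or two-dimensional frequency surfaces — so passing tests
demonstrate correctness of the estimators under their assumptions, not
robustness to HWE violations or spatially biased mis-scoring in real
data.

The headline end-to-end check runs the entire chain — sample 20 000
records, grid at 4 degrees, project onto the axis with a 450 km corridor,
fit both loci by MCMC — and recovers the 1500 km centre offset between
the first and third locus to within ~20 km (tolerance ±200 km).

# Problem sizes and numerical choices

The validation suite uses the designs stated above: 1000 random
point/segment cases against a 10^5-point scan; 200 replicates of 500
genotypes for the HWE bias; 50 replicates of the 31-cell MCMC design with
3 × (10^4 + 10^5) generations per fit (the Metropolis core is compiled,
so a full fit takes ~1.5 s); 50 replicates of 25-cell model selection;
100 replicates of the 100-cell GLS coverage design; one 20 000-record
end-to-end run. These sizes give binomial standard errors of a few
percent on the reported rates.

Other numerical choices, collected: frequency clamp $10^{-6}$ in the
cline likelihood; width lower bound 0.01 km and flat-data flag at 98% of
the width prior bound; proposal-scale adaptation window 100 generations
with 0.7×/1.4× updates; $\rho$ profiled on a log grid bounded by
$10^{-3} \times$ the median and $10 \times$ the maximum inter-cell
distance; Cholesky factorisation throughout the GLS (the dense-oracle
test pins the likelihood to a determinant/solve evaluation within
$10^{-8}$); grid cells half-open so every record belongs to exactly one
cell, with latitude 90 folded into the top row.

# Limitations

The HWE assumption biases $\hat q$ where immigration or non-random mating
creates homozygote excess — for these data that means cline offsets can
be under- or overestimated in direction-specific ways, which is a feature
of the method, not of the implementation. One-dimensional projection
discards cross-corridor structure; transects crossing the antimeridian
are unsupported. The GLS distance is Euclidean in degrees, which distorts
at high latitude (the study region is tropical). p-values in the screens
are approximate and the Wald intervals mildly undercover under strong
spatial correlation, as quantified above.
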