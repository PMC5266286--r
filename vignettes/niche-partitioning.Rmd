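---
title: "Methods: quantifying trophic niche partitioning in a three-species lake fish community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying trophic niche partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichepart)
```

# The problem

Arctic charr, European whitefish and brown trout co-occur in deep
oligotrophic lakes, where coexistence is thought to rest on partitioning of
food, space and time. `nichepart` implements the complete quantitative
toolkit used to measure that partitioning from a standard multi-mesh
gill-net survey: habitat use from catch per unit effort (CPUE), short-term
diet from stomach contents, long-term diet from stable isotopes, and formal
tests of niche separation. The survey design the package assumes is a
3 species x 3 habitats (littoral, profundal, pelagic) x 3 months (June,
August, October) factorial sampled over two years.

# Models and statistics

## CPUE and habitat use

CPUE is the number of fish caught per 100 m^2 of net area per night.
Effort accumulates as `sum(net_area / 100 * nights)` per habitat/month
stratum over survey-gear deployments. Supplementary gear (large-mesh single
nets and trap nets deployed only to top up stomach and isotope samples)
carries `gear_class = "supplementary"` and is excluded from both the CPUE
numerator and denominator; its fish remain available to the diet and
isotope stages. This exclusion is our reading of gear used "as a
supplement": the survey series alone defines relative density. Strata with
effort but no catch are emitted with CPUE 0 — never dropped — so that
habitat-use profiles (CPUE shares across habitats, the `P_xi` fed to
Schoener's index) are always well defined. Years are pooled by default
after the between-year similarity check below; per-year cells are available
via `pool_years = FALSE`.

## Diet composition

Stomach fullness is scored 0–100% in total, split across six fixed prey
categories (copepod zooplankton; cladoceran zooplankton; benthic
cladocerans; benthic invertebrates; pleuston, i.e. surface-film insects and
emerging pupae; fish) such that the category values sum to the total. The
percent prey abundance of category *i* for a group is the pooled-sum ratio

$$\%A_i = 100 \times \frac{\sum F_i}{\sum F_t}$$

summed over fish — not the mean of per-fish percentages. The two differ on
unbalanced data; the pooled form is the printed formula and equals the
fullness-weighted mean of per-fish compositions (an identity the tests
check numerically). Empty stomachs contribute zero to both sums, so adding
them never changes a profile; all-empty groups are an explicit error
distinct from "no fish". Cells without usable stomachs are omitted from the
cell-mean matrix and listed, not zero-filled: the downstream overlap table
prints `-` for them, and the PERMANOVA residual degrees of freedom depend
on which cells exist.

## Schoener overlap

Diet and habitat overlap between species x and y is Schoener's
$\alpha = 1 - 0.5\sum_i |P_{xi} - P_{yi}|$, from 0 (none) to 1 (complete).
Internally $\alpha$ lives on [0, 1]; reports print whole percents. The
significance threshold is $\alpha \ge 0.60$: the source convention words
the pooling rule as "> 0.60" and the significance rule as ">= 0.60"; we use
`>=` for both and document the inconsistency rather than guess intent. The
same check drives the between-year merge decision: years are pooled only if
every group's between-year $\alpha$ clears the threshold.

## PERMANOVA on Bray–Curtis matrices

Cell-mean %A profiles are compared with Bray–Curtis dissimilarity
$d(x,y) = \sum|x_i - y_i| / \sum(x_i + y_i)$ and partitioned by species,
habitat and season with PERMANOVA. The implementation uses the
Gower-centered inner-product matrix $G = C(-\tfrac12 D^2)C$: for a design
hat matrix $H$, the explained sum of squares is $\mathrm{tr}(HGH)$, terms
enter sequentially (Type I) in a configurable order (default species,
habitat, season, then two-way interactions — the order is reported because
the design is generally unbalanced), and pseudo-F is the term/residual MS
ratio. Significance is by permutation of residuals under a reduced model
(Freedman–Lane): for each tested term the reduced model contains every
term *not containing* it, the reduced-model residuals are permuted, and the
full model is refit. The "not containing" qualification matters: with
interactions in the model, reducing by only the tested term leaves the
tested main effect inside the reduced fit through its interactions and
destroys the test (we verified this empirically: huge pseudo-F with p near
1). P-values use the $(1 + \#\{F^* \ge F\})/(1 + n_{perm})$ estimator so
p = 0 is impossible; when $n!$ is at most the requested permutation count
all permutations are enumerated and the p-value is exact (flagged in the
output). With one profile per cell of a full 3x3x3 design, the three-way
interaction is confounded with the residual; the module refuses to fit a
saturated design rather than report a zero-df residual. The total of 27
cell means as replicates (26 total df, residual df 8) matches the published
table layout this module mirrors.

## Bayesian stable-isotope mixing model

For diet proportions $p$ on the simplex, each consumer's expected isotope
value is the concentration-weighted mixture of TEF-corrected source means:

$$m_j(p) = \frac{\sum_k p_k q_{jk} (\mu_{jk} + \lambda_j)}
                {\sum_k p_k q_{jk}}, \qquad
  s_j(p)^2 = \frac{\sum_k (p_k q_{jk})^2 (\omega_{jk}^2 + \tau_j^2)}
                  {(\sum_k p_k q_{jk})^2}$$

with $j \in \{\delta^{13}C, \delta^{15}N\}$, source means/SDs
$\mu_{jk}, \omega_{jk}$ estimated from source samples and inserted as fixed
hyperparameters, elemental concentrations $q_{jk}$ (fractions of C and N by
weight; means only — concentration SDs are not modelled), and trophic
enrichment factors $\lambda_j \pm \tau_j$ defaulting to
$\Delta^{15}N = 3.23 \pm 0.79$ per mil and $\Delta^{13}C = 1.03 \pm 0.29$
per mil. Consumer data enter un-lipid-normalized; concentration dependence
is included precisely because of that choice. Equal concentrations reduce
$m_j$ to the plain linear mixture — checked as an algebraic limit. Source
sets are kept to the three most important prey per species: trout mix over
{fish, benthic invertebrates, zooplankton}, with the fish source pooling
small whitefish, charr and juvenile trout samples; charr and whitefish mix
over {profundal invertebrates, littoral invertebrates, zooplankton}.

The likelihood is
$X_{ij} \sim \mathcal N(m_j(p),\, s_j(p)^2 + \sigma_j^2)$ with a flat
Dirichlet(1, ..., 1) prior on $p$ and a half-Normal prior on each residual
SD $\sigma_j$ scaled to the consumer sample SD (weakly informative and
scale-aware). Sampling is random-walk Metropolis on softmax-transformed
proportions (K−1 free coordinates, log-Jacobian $\sum_k \log p_k$).
A single adaptive step, as first implemented, mixed poorly — the softmax
coordinates are strongly correlated and the posterior has heavy log-scale
tails near the simplex boundary, giving effective sample sizes below 30 per
6000 draws. The sampler therefore adapts in two phases: a coordinate-wise
warm-up tuned towards 44% acceptance, then a joint proposal whose
covariance is estimated from the warm-up, re-estimated once, and scaled
towards 30% acceptance before being frozen for the recorded draws.
Defaults (2 chains, 10 000 iterations, 2 000 burn-in) give split-chain
$\hat R < 1.08$ across seeds in about 1.5 s per fit; fits are exactly
reproducible for a fixed seed, and non-convergence is a flagged warning,
never silent. Posteriors are summarized both as mean with 5th–95th
percentiles and as density mode with a 95% interval, since the field
reports both and neither is privileged.

## Isotopic niche geometry

The standard ellipse of a group's $\delta^{13}C$–$\delta^{15}N$ scatter is
the 1-SD Mahalanobis contour of the sample covariance (about 40% coverage,
the convention under which SEA is defined — not a 95% ellipse), with area
$SEA = \pi\sqrt{\det\Sigma}$ and small-sample correction
$SEA_c = SEA \,(n-1)/(n-2)$. Total area (TA) is the convex-hull area of
all individuals (monotone-chain hull + shoelace). Pairwise ellipse overlap
is intersection-over-union: the source convention states only a [0, 1]
range and its printed values (0.61 and 0) cannot distinguish IoU from
proportion-of-smaller-ellipse, so we chose IoU — symmetric, 1 iff the
ellipses are identical, 0 iff disjoint — and document rather than infer.
The intersection is integrated on a midpoint grid over the overlap of the
two bounding boxes, with the grid doubled until two successive overlap
estimates agree within 0.002 (deterministic, seed-free); the unit-circle
lens fixture reproduces the closed form to well within the stated ±0.005.

# The synthetic-data generator

The raw field data behind the original survey are not deposited, so the
generator is a first-class module that emulates the *stated world*:

* catch counts per stratum are Poisson with mean intensity × effort, with
  intensities anchored to the printed CPUE values where the text prints
  them (trout littoral 12.3/7.8/7.5 across months; charr littoral peak 7.3
  in October and near-absence in August; charr pelagic June 0.3;
  off-habitat densities in the printed 0.1–1.0 band) and chosen once from
  the qualitative habitat-use description elsewhere (e.g. whitefish
  littoral peak in August); effort is one 8-panel survey series (~360 m^2)
  fished two nights per habitat/month/year;
* lengths are log-normal moment-matched to the printed per-species means
  and SDs (charr 20.4 ± 4.0 cm, whitefish 26.6 ± 7.6, trout 21.0 ± 6.6);
  weights follow W = 0.01 L^3 with 10% log-normal noise;
* stomachs are empty with the printed per-species probabilities (29.9%
  trout, 39.4% charr, 34.1% whitefish); non-empty totals are Uniform(5,100)
  — an arbitrary but harmless choice, since %A_i is invariant to fullness
  scale — and category splits are Dirichlet (precision 24) around
  species/habitat/month mean diets built from the qualitative diet
  descriptions (zooplanktivory for charr/whitefish, benthivory/piscivory
  plus surface insects for trout, a benthic June peak for profundal charr);
* isotope sources are bivariate normal with means/SDs placed to mimic the
  published biplot (zooplankton depleted in 13C, littoral invertebrates
  enriched and highly variable, prey fish high in 15N) and the consumer
  samples are drawn from the *exact forward model* the fitter inverts, at
  recorded true proportions — so parameter recovery is a meaningful test.

What a green test does **not** establish: the generator has no gear
selectivity, no ontogenetic diet shifts, no spatial autocorrelation, no
covariance between C and N within sources, and no seasonal isotope
turnover. Green acceptance means the estimators recover the stated
structure, not that they would be unbiased on real survey data with those
complications.

# Numerical and design choices

* All randomness flows from one user-visible seed; sub-seeds are derived
  deterministically and kept below 2^31.
* Profiles are validated to the simplex within 1e-6; fullness sums to the
  stated total within 1e-9; read–write round trips hold to 1e-12.
* Quantiles use R's default type-7 linear interpolation, stated in the
  summary documentation.
* Config files are JSON rather than YAML: the target runtime environment
  ships no YAML parser for R, and the config content is unchanged.
* The degenerate cases are deliberate: all-identical PERMANOVA rows report
  undefined tests rather than p = 0; collinear isotope samples give
  SEA = 0 with a degeneracy flag; an all-zero CPUE month is an error
  because a habitat-use profile cannot be normalized.

# Known limitations

* The PERMANOVA is Type I (sequential); with missing cells, term order
  matters and is therefore configurable and echoed in the output.
* Source means/SDs are fixed hyperparameters, not a hierarchical source
  model; their sampling uncertainty enters only through $s_j(p)$.
* Ellipse overlap is numerical (grid) rather than closed-form; tolerance
  is controlled but cost grows with the ellipse aspect ratio.
* No gear-selectivity correction, no null-model overlap resampling, no
  dispersion homogeneity test, and no Bayesian SEA posterior — all outside
  the package's scope.
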