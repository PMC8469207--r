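---
title: "Community bioassessment of littoral habitats with littora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community bioassessment of littoral habitats with littora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littora)
```

## The assessment problem

Littoral monitoring surveys ask whether the community of aquatic organisms
at an impacted shore differs from a background site and from historical
reference collections, and in which direction. `littora` implements the
quantitative core of that workflow for taxon × sample biomass tables (with
optional abundances): which taxa are faithful to which habitat, how diverse
and how organically loaded each habitat is, whether the size structure of the
community signals disturbance, and how the dominant taxa organise into
communities across habitats.

The universal input is a `community_table`: a taxon × sample matrix of
non-negative biomass (mg m⁻³ for plankton, mg m⁻² for benthos — units are
metadata only and never converted), an optional abundance matrix of the same
shape, and per-sample metadata (habitat, station, depth stratum, replicate).
Indicator information lives in a separate `taxon_registry`: higher group,
guild flags (eutrophic, oligotrophic, mesosaprobiont, endemic) and, for
saprobity indicators, the valence s_i on the 0–4.5 scale. Depth layers of a
station are combined into one integral sample by arithmetic mean
(`integrate_strata()`) before community analysis, the standard treatment of
a 0–15 m water column.

## Biotope confinement and key species

For taxon i and habitat j, with n_ij the taxon's pooled biomass in the
habitat, n_i its biomass over all collections, N_j the habitat total and N
the grand total,

$$F_{ij} = \frac{n_{ij} N - n_i N_j}{n_{ij} N + n_i N_j - 2\, n_{ij} N_j}.$$

The "volume of collections" entering the classical fidelity index is read
here as summed biomass, the only interpretation under which
$\sum_j n_{ij} = n_i$, $\sum_j N_j = N$ and the ±1 endpoints behave as
documented: F = −1 exactly when the taxon is absent from the habitat, +1
exactly when all of its biomass lies there, and 0 when its habitat share
equals its overall share. Because the rearranged denominator can differ from
the numerator by one ulp at the n_ij = n_i endpoint, the implementation
returns the analytically forced endpoints directly; elsewhere the printed
formula is evaluated as written. Under the preconditions (0 ≤ n_ij ≤ n_i ≤ N,
n_ij ≤ N_j < N) the denominator is strictly positive, so no genuine
degenerate case arises; a defensive guard reports one anyway if the
preconditions are bypassed.

`confinement_table()` computes F from habitat-pooled biomass (one n_ij per
habitat, matching the single-sample form of the formula; per-sample variants
are deliberately not offered). Key species (`select_key_species()`) are the
*dominant* taxa attaining the maximum positive F in a habitat; exact ties all
qualify — published tables bold two maxima in one habitat — and a habitat
whose dominants are all non-positively confined has no key species. F values
are conventionally reported to 3 decimals (`write_confinement_csv()`), but
full precision is kept internally.

## Trophic and saprobity indicators

`build_trophic_report()` assembles, per habitat: taxon richness; Shannon
diversity H = −Σ p log p on pooled-biomass proportions (biomass, not counts,
is the paper-standard input here; the log base is natural by default and
exposed as `shannon_base`, since published H values of 1–2.8 at richness
15–46 are consistent with either convention); the number of indicator
species; the saprobity index S = Σ s_i h_i / Σ h_i with its saprobic zone;
the E/O and M/E ratios; and total biomass ± SE (SE = sd/√n, missing for
single-sample habitats).

Choices that were genuinely open:

- **Occurrence weights h_i.** The source tradition says only "estimated
  frequency of occurrence in samples"; the default weight is the count of
  the habitat's samples containing the indicator, and `h_fun` accepts any
  alternative (e.g. Sládeček's 1–9 abundance classes). S is invariant to
  uniform rescaling of h, so only relative weighting matters.
- **Zone boundaries.** The printed intervals (0.50–1.50, 1.51–2.50, …) leave
  gaps such as (1.50, 1.51) uncovered; boundaries are implemented at the
  midpoints 1.505 / 2.505 / 3.505, preserving every printed two-decimal
  classification while classifying all of [0.50, 4.50]. Values outside the
  scale return `out_of_range`.
- **Ratio formatting.** Raw ratios are reported alongside a small-integer
  "x:y" rendering (r ≥ 1 → "round(r):1", else "1:round(1/r)", rounding half
  away from zero), the style of published indicator tables ("1:47", "7:1").
  Zero denominators yield an explicit sentinel ("M:0") rather than NaN.

The bundled `example_baikal_registry()` covers the dominant taxa named in
coastal-zone studies of Lake Baikal, with *synthetic placeholder* valences:
plausible per guild, but not the published saprobic-organism lists, which
are book-form sources users must supply for real assessments.

## k-dominance curves and ABC stress classification

`k_dominance_curve()` sorts a quantity vector in descending order (stable
under ties) and returns cumulative percentages. `classify_abc()` builds the
biomass and abundance curves independently — each ranked by its own variable,
as in standard abundance–biomass comparison — and compares them pointwise on
rank index (no interpolation; published figures plot plain ranked
sequences), over ranks 1..R−1: the terminal rank, where both curves are 100%
by construction, is vacuous and excluded. Biomass everywhere ≥ abundance
(with at least one strict rank) is `unstressed`; the reverse
`heavily_stressed`; anything else, including exactly coincident curves where
neither lies above the other, `moderately_stressed`. Pointwise comparisons
use a 10⁻⁹ tolerance on percentages so that rounding noise cannot manufacture
a crossing. Replicate samples within a habitat are summed before ranking
(`dominance_curves()`), giving one curve pair per habitat.

## Community structure of dominant taxa

`filter_dominants()` retains taxa whose habitat-mean biomass reaches the
group threshold in at least one habitat (plankton 10 mg m⁻³, benthic
macroalgae 10×10³ mg m⁻², microalgae 1 mg m⁻²). The retained taxon ×
habitat-mean matrix is log10(X+1)-transformed, then:

- `ward_communities()` clusters taxa with Ward's minimum-variance criterion
  on Euclidean distances (`hclust(method = "ward.D2")`, the implementation
  consistent with squared-Euclidean Ward updates) and cuts at k communities
  (default k = 3, the typical three-community outcome of the study design;
  no cut criterion is prescribed by the tradition, so k is explicit).
  Merge heights are non-decreasing by construction. All-identical rows are a
  degenerate geometry: k > 1 is refused with a zero-distance warning and one
  community returned.
- `pca_ordination()` performs covariance-matrix PCA (habitat columns are
  centred, not rescaled — with only a few habitat variables already
  commensurate after the log transform, correlation scaling would discard
  the dominance signal; `scale. = TRUE` switches to correlation). Scores
  carry a fixed sign convention (largest-magnitude loading of each component
  positive) so outputs are reproducible across platforms.

Multivariate analyses operate on habitat means (habitats as variables),
matching the design in which dominant-taxon biomass at reference, background
and impacted sites are the ordination variables. Zero rows of dominants are
retained: their zeros are informative for confinement.

## The synthetic generator

`synthetic_scenario()` + `generate_community()` emulate the statistical
structure the analysis assumes, not the mechanistic ecology: per taxon a
log-normal baseline biomass (log10 mean/sd), an enrichment multiplier e ≥ 1
in a preferred habitat (`Inf` plants a habitat-exclusive taxon),
multiplicative log-normal per-cell noise (keeping biomass non-negative and
right-skewed, as real abundance data are), deterministic guild-flag layouts,
clipped-normal saprobic valences on an indicator subset, and abundance
derived as biomass / body mass with log10(mass) linear in the standardised
log-baseline with slope (1 − κ)·σ_m: κ = 0 couples large bodies to high
biomass (unstressed ABC geometry), κ = 1 equalises masses (coincident
curves), κ > 1 inverts the coupling (numerically dominant tiny-bodied taxa,
the heavy-stress signature). All randomness flows through one seed, with the
caller's RNG state restored afterwards; identical (scenario, seed) pairs
reproduce identical bytes.

`scenario_baikal_like()` is the canned three-habitat design used throughout
the tests: habitats RD/Site1/Site2 × 3 samples, 45 taxa in three equal
confinement blocks (enrichment ×30), baseline log-normal(−0.7, 0.6) mg m⁻³
so that roughly 15–25 taxa pass the plankton dominance filter, noise
σ_log10 = 0.15, one Site2-exclusive dominant fixed at 10^1.5 mg m⁻³, guild
flags tied to blocks (reference block endemic, impacted block
mesosaprobiont) so M/E flips from below 1 to above 1 along the impact
gradient, an eutrophic:oligotrophic pool near 2:1, and 80% indicators with
valences from N(1.6, 0.3) clipped to [0, 4.5]. The enrichment and baseline
levels were set so that the planted blocks are recoverable by
Ward clustering at k = 3 across seeds (weaker enrichment lets Euclidean
distance split blocks by overall biomass magnitude rather than habitat
profile, which defeats planted-structure recovery without being a defect of
the clustering itself).

What passing the synthetic suite shows — and does not. The generator
reproduces habitat confinement, dominance filtering, guild contrasts,
valence mixtures and ABC geometry, so recovery tests validate the
*computations*. It does not emulate taxonomic covariance, zero inflation
from detection limits, temporal autocorrelation of reference collections, or
valence uncertainty; agreement on synthetic data therefore does not certify
field inference, only that the pipeline measures what it claims to measure.

## Numerical conventions and limitations

- Problem sizes in the test and validation runs: 45 taxa × 9 samples per
  survey; 20 seeds for clustering/key-species recovery and 200 seeds for
  valence recovery — small enough to run in seconds while leaving the
  Monte-Carlo margins (binomial at ≥ 95%) interpretable.
- Long-form input cells that are absent are zeros (absence), not missing
  data, the convention of quantitative count surveys; negative or non-finite
  cells are rejected naming the offending cell.
- Wide CSV output writes full double precision, so write→read round-trips
  are exact for decimal text of ≤ 15 significant digits.
- No statistical testing of F_ij, no Clarke's W statistic or
  partial-dominance curves, no chlorophyll/nutrient-based trophic
  classification, and no biomass-unit conversion: these are outside the
  assessment workflow the package implements.
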