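---
title: "Methods: quantitative diet analysis from faecal pellets"
author: "pelletdiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative diet analysis from faecal pellets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletdiet)
```

# The data and the questions

The unit of observation is the faecal pellet: a non-lethal record of what one
lizard (or other small insectivore) recently ate. Each pellet yields a count
of identifiable prey remains per taxonomic category, a visually estimated
fraction of plant matter, and covariates — year, month, and sampling area.
Alongside the pellets, availability samples census the invertebrates actually
present: a biocenometer (a bottomless 1 m mesh cube dropped over a plot)
traps the epigeal and flying fauna of 1 m^3, which is then counted by taxon.

Four families of questions drive the analysis:

1. **What is the diet made of?** Composition by numeric frequency, presence,
   volume and dry biomass.
2. **Is the diet a mirror of availability, or is there selection?**
   Electivity indices per taxon.
3. **How diverse is the diet, and do groups differ in diversity?**
   Hill-number profiles with bootstrap contrasts.
4. **Does composition differ across years, months, areas?** Permutational
   multivariate tests, plus classical frequency tests for single taxa.

# Composition metrics

For a group of pellets (any covariate combination), with `count[i]` the
pooled count of taxon *i*:

* `%n_i = 100 * count[i] / sum(count)` — numeric frequency;
* `%p_i = 100 * (pellets containing i) / (pellets)` — presence;
* `%vol_i = 100 * count[i] * V[i] / sum_j count[j] * V[j]` — volumetric
  contribution, with `V[i]` the taxon's **mean** volume;
* `%b_i` — the taxon's share of total estimated dry mass.

Volumes come from geometric models chosen per taxon: a prolate spheroid
`V = (4/3) pi (L/2) (W/2)^2` for compact-bodied prey, a cylinder
`V = pi (W/2)^2 L` for elongated prey such as millipedes, or a fixed
displacement volume measured in alcohol for rigid or shelled prey (woodlice,
crabs, snails). Lengths and widths are in mm, volumes in cm^3 (mm^3 / 1000),
masses in mg — fixed globally.

`%vol` deliberately applies taxon **mean** volumes to the count table rather
than per-item measurements: remains in pellets are usually too fragmented to
measure item by item, so the mean-volume estimator is the one actually
computable at scale, and the one the package mirrors. A consequence worth
keeping in mind: for shelled or partially eaten prey (snails, crabs) the
model volume overestimates the ingested volume. The package does **not**
correct this bias — it annotates it. Taxa can carry a `volume_overestimate`
flag in the trait table, and the flag is carried into every `%vol` output so
readers can discount those rows.

Dry mass uses a strict three-tier hierarchy per prey item:

1. a measured length and a taxon allometric regression `m = a L^b`;
2. otherwise, the taxon's mean recorded dry mass;
3. otherwise (unidentifiable remains), the overall mean across groups.

Exactly one rule fires for any item. The shipped default trait table
(`default_trait_table()`) carries **synthetic placeholder** coefficients in
the plausible range for arthropod length-mass allometry (`b` near 2.4-2.7);
they make the pipeline runnable end-to-end but must be replaced with
regressions fitted to the user's own system before biomass output is
interpreted.

# Electivity

With `r_i` the proportion of taxon *i* in the diet and `p_i` in the
environment, two indices are computed per taxon, both mapping to
[-1, +1] (total avoidance to maximal positive selection):

* Ivlev's index as modified by Jacobs, `D = (r - p) / (r + p - 2 r p)`;
* the Vanderploeg-Scavia index `E* = (W - 1/n) / (W + 1/n)` with
  `W_i = (r_i / p_i) / sum_j (r_j / p_j)` and `n` the number of available
  prey types — preferable at small sample sizes.

Two design choices deserve explanation:

* **The taxon universe.** Diets routinely contain taxa the availability
  census never sees (hypogeal prey, marine subsidies, vertebrate remains).
  `n` and the renormalised `r`, `p` depend on which taxon set is used, so
  the choice is explicit: the default universe is the union of diet and
  availability taxa; restriction to availability taxa is an option, and the
  chosen universe is recorded on the output.
* **Flags, not NaN.** `r = p = 0` is undefined (`absent_in_both`); `p = 0`
  with `r > 0` gives `D = E* = +1` by limit (`absent_in_availability`);
  `r = 0` gives -1 (`absent_in_diet`). Because a biocenometer only samples
  epigeal and flying prey reliably, these boundary values are expected and
  ecologically meaningful — but they are limits, not estimates, so every row
  carries its flag and downstream analyses can filter on it. The package's
  own recovery study (below) assesses sign recovery over `flag == "ok"`
  taxa only, since a flagged +1 for a taxon missing from the census carries
  no information about the true sign.

Availability replicates are pooled by default before computing `p`
(summed counts); averaging per-replicate proportions is available by option
for designs with very uneven replicate totals.

# Diversity: Hill numbers and bootstrap contrasts

All diversity indices are expressed in one family, the Hill numbers
`^qD = (sum_i p_i^q)^(1/(1-q))`, with `^1D = exp(Shannon entropy)` by
continuity. `q = 0` counts taxa (richness), `q = 2` is the inverse Simpson
concentration; larger `q` down-weights rare categories, negative `q`
up-weights them. The default profile uses the integral orders -1..3.
Zero-count categories are always excluded (mandatory for `q < 0`). The
Simpson concentration `lambda = sum p_i^2` is also reported with its
classical large-sample variance `(4/N) (sum p_i^3 - (sum p_i^2)^2)`; the
"Simpson diversity" the package prints is the Gini-Simpson `1 - lambda`.

Group comparisons use pellet-level bootstrap resampling: the pellet — not
the prey item — is the independent sampling unit of such studies, and
between-pellet heterogeneity would make an item-level bootstrap far too
optimistic. Within each group, pellets are resampled with replacement B
times (default 5000), counts pooled, and Hill numbers recomputed. For each
pair of groups and each order, the two-tailed p-value is the tail
probability of the centred bootstrap difference; across pairs, a
single-step max-modulus adjustment (the bootstrap analogue of a Tukey-type
all-pairs correction) uses the distribution of the maximum centred
difference, guaranteeing adjusted p >= raw p. Holm adjustment is available
as an alternative. Every stochastic routine takes a mandatory seed, which is
recorded in its output.

**Calibration and its limits.** The package's own null studies (run in the
test suite and the acceptance script) draw both groups from one multinomial
at the scale where such contrasts are typically applied — groups of ~200
pellets at ~3.4 items per pellet, i.e. pooled counts in the hundreds, the
scale of year-level comparisons. There the empirical type-I error at
alpha = 0.05 sits at the nominal level for q = 1 and q = 2 (500 runs,
B = 1000). Two caveats are deliberate:

* at `q = 0` the bootstrap difference distribution is nearly degenerate
  whenever richness saturates (most pooled samples contain every common
  taxon), so a calibration check against a two-sided band is not meaningful
  at that order and richness contrasts should be read qualitatively;
* with small groups (tens of pellets) the centred-difference percentile
  bootstrap is measurably anticonservative (empirical type-I around
  0.07-0.09 at 30 pellets per group in our experiments). Contrasts on small
  monthly cells should therefore be treated with caution.

# Multivariate tests

Composition differences across crossed factors (e.g. `year * month * area`)
are tested by permutational MANOVA on a distance matrix: the total sum of
squared interpoint distances is partitioned via the Gower-centred
inner-product matrix, with sequential (Type I, model-order) sums of squares,
and each term's pseudo-F is referred to its permutation distribution under
free relabelling of observations, `p = (#{F* >= F} + 1) / (n_perm + 1)`.
When the complete permutation group is smaller than `n_perm` the test
enumerates it and the p-value is exact. Ties at the observed statistic are
counted as exceedances with a small relative tolerance, so exact ties caused
by floating-point reordering cannot deflate p. With univariate responses and
Euclidean distance the pseudo-F reduces to the classical ANOVA F.

The distance is a user-visible choice; the default is Bray-Curtis on
per-pellet counts (with Jaccard and Euclidean as options), and pellets with
zero prey items must be excluded before the distance is computed — an empty
pellet has no composition. Sequential SS means term order matters and is
taken from the model formula as written.

The companion dispersion test (a multivariate Levene analogue) embeds the
distance matrix by principal coordinates, keeping negative eigenvalues with
their sign; squared distances to group centroids subtract the
imaginary-axis contribution and are floored at zero. A one-way F on the
distances is then referred to a permutation distribution of group labels.
Both routines are validated against independent implementations of the same
estimators (vegan's `adonis2` and `betadisper(type = "centroid")`) in the
test suite.

# Classical frequency tests

The G-test (log-likelihood ratio, `G = 2 sum O ln(O/E)`) serves one-way and
two-way count tables, with pairwise batteries over group pairs; no Williams
or Yates correction is applied by default (a Williams correction is
available by flag), and pairwise batteries report raw p-values by default —
matching how such tables are usually printed — with Holm as an option. The
Fisher exact test uses full hypergeometric enumeration for 2x2 tables (the
two-sided convention: sum of all outcome probabilities not exceeding the
observed one) and seeded Monte-Carlo with fixed margins for larger tables.
Kruskal-Wallis (tie-corrected, via `stats::kruskal.test`) compares the
visually estimated plant fractions between seasons or areas; the degenerate
all-tied case returns H = 0, p = 1.

# The synthetic-data generator

`scenario_config()` + `generate_scenario()` produce pellet, availability and
trait tables with known ground truth. The generative model per
(year, month, area) cell:

* cell diet composition = `selection * availability`, renormalised — so the
  true D and E* per taxon, and the true Hill numbers, are computable from
  the configuration alone before any sampling;
* per pellet, a composition is drawn from a Dirichlet around the cell
  composition with precision `dispersion` (the single overdispersion knob;
  `Inf` collapses to pure multinomial sampling), an item count from a
  Poisson, and counts from a multinomial;
* plant fraction is zero-inflated Beta, drawn independently of prey counts
  (they are separate measurements on a pellet); a pellet that drew zero prey
  items is forced to carry plant matter, honouring the data-model rule that
  every pellet carries some dietary information;
* availability samples are multinomial censuses of the cell's availability
  composition.

Defaults emulate the structure of a long-term island study scaled to desk
size: 3 years x 3 months (May-July) x 5 areas, 40 pellets per cell, 3.4
items per pellet (the items-to-pellets ratio of large published pellet
datasets), plant matter present in ~44% of pellets, five availability
replicates of ~20 individuals per cell, and an ant-dominated availability
vector. The dispersion default (15) is an assumption, not an estimate: real
between-pellet overdispersion is unknown, and the presets document their
value rather than claim realism. What the generator does **not** emulate:
spatial structure within areas, individual identity or repeated captures,
seasonal phenology within a month, and taxon-specific detectability in
pellets.

Passing tests on synthetic data therefore show that the estimators recover
the generative truth under the stated model — not that the model captures
every feature of field data.

Four presets drive the validation studies: `null_homogeneous` (no effects
anywhere; type-I error), `area_shift` (one area's composition permuted;
multivariate power), `strong_selection` (selection coefficients log-spaced
0.1-10; electivity recovery), `diversity_gap` (uniform over ten taxa vs 90%
single-taxon dominance, 50 pellets per group; diversity power).

# Numerical choices

* Hill numbers at `q = 0` return the category count exactly; near `q = 1`
  the general formula is evaluated in log space and is continuous to ~1e-10;
  the `q = 1` branch switches at |q - 1| < 1e-12.
* Percentage vectors are exact closures: each of %n, %vol, %b sums to 100
  (tolerance 1e-9) whenever the denominator is positive; zero-item groups
  yield NA with a warning rather than silent zeros.
* Permutation p-values are never zero ((b+1)/(B+1) with sampled
  permutations; b/n! with full enumeration), and permutation ties use a
  1e-10 relative tolerance.
* Degenerate inputs fail loudly and early: all-zero counts, groups of one
  pellet in resampling, aliased model terms (named in the error), zero
  total sum of squares, empty covariate grids.

# Problem sizes used in the shipped studies

The test suite and `scripts/acceptance.R` run every study at sizes chosen to
make the Monte-Carlo error small relative to the bands being checked while
staying desk-sized: 500 null runs at B = 1000 for bootstrap calibration
(99% binomial band around 0.05 is then +/- 0.025), 500 runs at
n_perm = 499 for PERMANOVA calibration, 200 and 100 runs for the power
studies, and 1000 random instances per formula oracle at 1e-12.

# Known limitations

* Electivity is only as good as the availability census; for hypogeal or
  crevice-dwelling prey the indices are flagged boundary values, not
  estimates.
* `%vol` inherits the shell/carapace overestimation of its volume models by
  design (annotated, not corrected).
* The default trait table's regression coefficients are placeholders.
* Small-group bootstrap contrasts are anticonservative (see above).
* Sequential SS makes PERMANOVA term tests order-dependent; with the
  heavily unbalanced designs typical of long-term field collections,
  different term orders answer different questions.
* No coverage-based rarefaction or extrapolation: diversity comparisons are
  at the observed sample sizes, which is why the bootstrap operates on
  pellets within groups of comparable effort.
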