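---
title: "Methods: prey importance and individual diet specialization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prey importance and individual diet specialization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatordiet)
```

This vignette is the package's own account of the statistics it implements:
the models, the parameters that matter, the numerical conventions, the
design choices that were genuinely open, and the limits of what the test
suite demonstrates.

## Data model and sample filters

The unit of observation is a stomach: a set of prey items, each assigned to
one of ten broad categories (`prey_categories()`), with per-category item
counts and total wet mass in grams. Two CSV tables — individuals and prey
rows — are read and validated strictly (`read_diet_tables()`): the category
vocabulary is closed, every prey row must resolve to an individual, and
numeric or date parse failures name their row. Aggregation into paired
individuals-by-categories count and mass matrices (`build_diet_matrix()`)
is the substrate for everything else.

Field datasets of this kind need four selection rules before analysis, all
captured in `filter_config()`:

* **Life stage.** Crocodilians shift diet ontogenetically, so analyses are
  usually restricted to juveniles. The cutoff is total length 180 cm and is
  a *strict* inequality: an animal at exactly 180.0 cm is an adult. A
  missing total length is fatal only when a life-stage filter is enabled;
  other morphometrics are optional.
* **Empty stomachs** carry no diet information and are removed (an empty
  stomach is defined as zero prey observations).
* **Recaptures.** The same animal must not appear twice. Records flagged as
  recaptures are dropped, and if an id still repeats, the earliest capture
  is kept — the first encounter is the least disturbed by prior handling.
* **Mono-category stomachs** bias the specialization index (a stomach with
  one or two items of a single category looks maximally specialized by
  accident). The default `"literal"` rule of `exclude_monocategory()` drops
  rows whose non-zero cells lie in one category *and* whose total count is
  at most two. Because one can also read the rule as excluding *every*
  single-category stomach, an `"any_single_category"` mode is selectable;
  the two differ only for mono-category stomachs with three or more items.
  Neither reading is asserted as uniquely correct; the mode and the dropped
  ids are always recorded.

The mono-category rule applies **only to the specialization branch**. The
IRI table is computed on the full post-filter analysis set, so the two
branches legitimately report different sample sizes; `run_comparison()`
enforces this branch structure and ledgers the counts at every stage.

Salinity at capture is classed as freshwater/intermediate (≤ 15 ppt,
inclusive) or marine (> 15 ppt). The class is metadata only — no statistic
in the package conditions on it.

## Prey importance (IRI)

For category $j$ over $n$ stomachs, with $FO_j$ the fraction of stomachs
containing the category, $N_j$ its share of all items and $W_j$ its share
of total wet mass:

$$IRI_j = FO_j\,(N_j + W_j), \qquad
  \%IRI_j = IRI_j \Big/ \sum_k IRI_k .$$

Computation is at full double precision; the writer rounds for display only
(default four decimals). The default output scale is proportion (0–1);
`scale = "percent"` multiplies the three ingredients and the normalized
index by 100. Both the ranking and the $\%IRI$ proportions are invariant to
the scale and to uniform mass rescaling, which the tests verify against a
literal transcription of the two equations. All ten categories are kept in
the table, including zero rows, and the $FO$ denominator is the post-filter
stomach count (empty stomachs having already been removed by the filter
stage, no other denominator is defensible).

## Niche decomposition and the specialization index

On the Shannon (natural-log) scale, with $q_j$ the pooled item proportions,
$p_{ij}$ individual $i$'s item proportions and $n_i$ its item count
($N = \sum_i n_i$):

$$TNW = -\sum_j q_j \ln q_j, \qquad
  WIC = \sum_i \frac{n_i}{N}\Big(-\sum_j p_{ij} \ln p_{ij}\Big), \qquad
  BIC = TNW - WIC .$$

The implementation computes $BIC$ *directly* as the item-weighted mean
Kullback–Leibler divergence $\sum_i (n_i/N)\, KL(p_i \,\|\, q)$ — the
mutual information between individual identity and prey category — so that
$TNW = WIC + BIC$ is a numerical check (it holds to $10^{-10}$ on random
matrices, and $BIC$ matches a brute-force cell-sum mutual-information
oracle exhaustively on all small matrices) rather than an identity imposed
by subtraction. The specialization index is $E_{obs} = BIC/TNW$: 0 when
every individual matches the pooled diet, 1 when individuals are disjoint.

Conventions:

* **Counts, not masses,** define $p_{ij}$ and $q_j$: the Shannon framework
  operates on resource-use frequencies, and weighting individuals by their
  item totals $n_i$ is exactly what makes the decomposition additive.
  Masses enter only the IRI.
* **Natural log.** Both $BIC/TNW$ and $E_{adj}$ are ratios, hence
  base-invariant; nats are the convention for this decomposition.
* $0 \ln 0 := 0$; $E_{obs} := 0$ when $TNW = 0$; tiny negative $BIC$ from
  floating-point cancellation is clamped at 0 and $E_{obs}$ to $[0, 1]$.

## The Monte Carlo null and adjusted E

The null hypothesis is that each individual samples its $n_i$ items
independently from the shared pool $q$. Each of $R$ replicates redraws
every row as $\mathrm{multinomial}(n_i, \hat q)$ (implemented as iid
category draws per item, which is the same distribution), recomputes
$BIC/TNW$, and

$$p = \frac{1 + \#\{\text{null} \ge E_{obs}\}}{R + 1},$$

a one-tailed test toward specialization that can never report zero. The
default is $R = 999$. A replicate whose resampled pool collapses to one
category has $TNW = 0$; its ratio is defined as 0 and counted
(`degenerate_count`), not redrawn — zero niche width carries zero
between-individual variance, and redrawing would bias $E_{null}$ upward.
The mono-category exclusion is applied once, to the observed data; null
replicates keep every retained individual and its $n_i$, i.e. the null
conditions on the observed design. Identical seeds give bit-identical
ensembles.

$E_{max} = 1 - 1/P$, with $P$ the number of categories with pooled count
above zero in the analyzed matrix, and

$$E_{adj} = \frac{E_{obs} - E_{null}}{E_{max} - E_{null}} .$$

$E_{adj}$ is **not clamped**. Because $BIC/TNW$ genuinely reaches 1 for
pure specialists while $E_{max} < 1$, values above 1 (and below 0, when a
population is more generalist than its null mean) are arithmetically
possible; the result carries an `e_adj_in_range` flag instead of silently
truncating, which would hide this tension in the definition of $E_{max}$.
$E_{max} = E_{null}$ raises an error rather than returning an infinity.

## The synthetic-data generator

`simulate_diet_dataset()` draws, per non-empty individual,
$p_i \sim \mathrm{Dirichlet}(\kappa q)$, an item total
$n_i = 1 + \mathrm{Poisson}(\lambda)$, category counts
$\mathrm{multinomial}(n_i, p_i)$, and per-item masses from a
category-specific lognormal rounded to 0.1 g (the recording resolution of a
field balance). The Dirichlet–multinomial was chosen because one knob spans
the whole phenomenon: $\kappa \to \infty$ gives $p_i = q$ exactly — the
Monte Carlo null *by construction* — while small $\kappa$ gives
near-mono-category individuals, so the generator can both calibrate the
test and probe its power.

Defaults, chosen once as field-plausible for a juvenile crocodilian in a
coastal wetland and not revisited: pooled diet dominated by
insects/arachnids (0.40) and crustaceans (0.30) with fishes (0.15) and
seven rare categories; $\lambda = 4$ (mean five items per stomach); mean
item masses from 0.2 g (seeds) and 0.3 g (insects) to 25 g (horseshoe
crabs) with lognormal $\sigma = 0.5$; juvenile total lengths uniform on
45–179 cm, adults 185–300 cm; capture dates across a 120-day season.
Metadata knobs (`adult_fraction`, `empty_fraction`, `recapture_fraction`)
exist purely to exercise the filters; recapture duplicates repeat an
existing id at a later date with no prey rows of their own.

The bundled fixtures (`make_paperlike_fixture()`, also shipped as CSVs
under `inst/extdata/`) are two synthetic populations built for a clear
qualitative contrast: "pondlike" (30 juveniles, insect-dominated pool,
$\kappa = 12$, relatively generalist) and "marshlike" (64 juveniles,
crustacean-dominated pool, $\kappa = 2$, strongly specialized), each with
three adults, two empty stomachs and two recaptures appended so the filter
ledger is non-trivial and the post-filter sizes are exactly 30 and 64.
These use $\lambda = 9$ (mean ten items per stomach) so that per-stomach
diets are informative at these sample sizes. They are qualitative
stand-ins, not calibrated replicas of any field dataset.

What the generator does **not** emulate: size–diet covariance (item masses
are independent of counts given category, and diet does not depend on body
length), seasonal or spatial structure, taxonomic resolution below the ten
categories, and detection/recovery error in stomach flushing. Tests passing
on simulated data therefore validate the statistical machinery, not the
ecology of any particular system.

## What the test suite establishes, and at what scale

The suite (under a minute on one CPU; sizes are the package's chosen desk
scale) verifies: the decomposition identity on 1,000 random matrices
($10^{-10}$); exhaustive agreement of $BIC$ with brute-force mutual
information on all count matrices with 2–4 individuals, 3 categories and up
to 5 items each (455,126 matrices, enumerated as row multisets since the
statistic is row-permutation invariant); the generalist/specialist
endpoints; Monte Carlo $E_{null}$ against the exactly enumerated 25-outcome
expectation for the 2×2, four-items-each design (within three standard
errors at $R = 10{,}000$); type-I calibration over 400 shared-pool datasets
($n = 50$, $R = 199$): rejection rate at $\alpha = 0.05$ inside the exact
binomial 95% interval and mean $E_{adj}$ within $\pm 0.05$ of zero; strict
monotone decrease of mean $E_{adj}$ along $\kappa \in \{0.2, 1, 5, 25,
1000\}$ (20 datasets per rung); the hand-derived IRI example to $10^{-12}$
plus normalization and rescaling invariance on 1,000 random matrices; and
the hand-enumerated filter ledger on the packaged five-individual fixture.

## Known limitations

* **Plug-in null and mid-range p-values.** The null replicates are drawn
  from the *estimated* pooled diet $\hat q$, not the truth. At realistic
  stomach sizes (~5 items) $\hat q$ has sampling zeros and biased entropy,
  and the observed statistic is computed on the same data that defines
  $\hat q$. The consequence, measured by the calibration study in the test
  suite, is that rejection rates at conventional $\alpha$ are well
  calibrated, but the *full* p-value distribution across datasets is not
  exactly uniform (a mid-range shift beyond the Kolmogorov–Smirnov 95%
  band; a control in which observed data and replicates share one fixed
  pool is uniform, isolating the cause to the plug-in step). The
  corresponding uniformity test is retained, failing, as documentation.
  Consumers should treat small p-values as trustworthy and mid-range
  p-values as approximate.
* **$E_{adj}$ can leave $[0, 1]$** (see above); comparisons across
  populations with very different $P$ or $E_{null}$ should quote all of
  $E_{obs}$, $E_{null}$, $E_{max}$, not the adjusted index alone.
* **No overlap indices, Bayesian variants, or bootstrap intervals** for the
  specialization index are provided, and populations are compared by their
  tables and indices, not by a formal diet-overlap test.
* The Welch body-size comparison is two-sided and uses the post-filter
  analysis sets; it is a comparability check, not part of the diet model.
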