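# gatordiet

Quantitative stomach-content analysis for crocodilian diet studies — and for
any predator diet dataset organized as "items of a prey category recovered
from one stomach". The package answers two questions ecologists routinely ask
of such data:

1. **Which prey categories matter to a population?** — via the Index of
   Relative Importance (IRI) per category.
2. **Is the population a set of generalists or of individual specialists?** —
   via the Shannon-scale decomposition of total niche width into within- and
   between-individual components, tested against a Monte Carlo null and
   rescaled to an adjusted specialization index.

It also ships the standard sample-selection rules for juvenile analysis sets
(a total-length cutoff, removal of empty stomachs, recaptures, and
mono-category stomachs), a Dirichlet–multinomial diet simulator spanning the
generalist–specialist continuum, and a two-population comparison report with
a complete filter ledger.

## The statistics

For prey category *j* over a set of *n* stomachs:

- *FO_j* — fraction of stomachs containing the category,
- *N_j* — the category's fraction of all prey items,
- *W_j* — the category's fraction of total wet mass,

and the composite index

```
IRI_j  = FO_j × (N_j + W_j)          %IRI_j = IRI_j / Σ_k IRI_k
```

`%IRI` combines how often, how numerous and how heavy a category is, and is
robust to the biases of any one of its three ingredients.

For specialization, with `q_j` the pooled item proportions and `p_ij`
individual *i*'s item proportions (*n_i* items):

```
TNW = −Σ_j q_j ln q_j                          (total niche width)
WIC = Σ_i (n_i/N) · (−Σ_j p_ij ln p_ij)        (within-individual component)
BIC = TNW − WIC                                (between-individual component)
E_obs = BIC / TNW ∈ [0, 1]
```

`BIC` is computed directly as the item-weighted mean Kullback–Leibler
divergence of each individual diet from the pooled diet — the Shannon mutual
information between individual identity and prey category — so the additive
identity `TNW = WIC + BIC` is verified numerically rather than imposed.
`E_obs = 0` means every individual eats the pooled diet (pure generalists);
`E_obs = 1` means individuals use disjoint resources (pure specialists).

The null hypothesis that diet variation arises from individuals sampling
randomly from a shared resource pool is simulated by redrawing each
individual's `n_i` items from a multinomial over the pooled `q`; the mean
null ratio `E_null`, the population maximum `E_max = 1 − 1/P` (*P* = number
of categories the population consumed) and the observed ratio combine into

```
E_adj = (E_obs − E_null) / (E_max − E_null)
```

with a one-tailed Monte Carlo p-value `(1 + #{null ≥ E_obs}) / (R + 1)`.

## Worked example

Using the bundled synthetic "pondlike" population (30 juveniles plus adults,
empty stomachs and recaptures that the filters must remove):

```r
library(gatordiet)
pond <- read_diet_tables(
  system.file("extdata", "pondlike_individuals.csv", package = "gatordiet"),
  system.file("extdata", "pondlike_prey.csv", package = "gatordiet"))

analysis <- filter_analysis_set(pond)   # <180 cm TL, non-empty, no recaptures
attr(analysis, "filter_ledger")
#>            stage n_in n_removed n_out
#> 1     recaptures   37         2    35
#> 2 juveniles_only   35         3    32
#> 3 empty_stomachs   32         2    30

m <- build_diet_matrix(analysis)
compute_iri_table(m)
#> IRI table: 30 stomachs, 338 items, 765.7 g total wet mass (scale: proportion)
#>           category     fo  pct_n  pct_w    iri pct_iri
#>  insects_arachnids 1.0000 0.6450 0.0906 0.7356  0.5251
#>             fishes 0.6333 0.1657 0.6134 0.4934  0.3522
#>        crustaceans 0.5333 0.0799 0.1019 0.0969  0.0692
#>  ...

specialization_test(exclude_monocategory(m), replicates = 999, seed = 42)
#> Niche decomposition (30 individuals, 8 categories used):
#>   TNW = 1.1317 nats  (WIC = 0.8051 + BIC = 0.3267)
#>   E_obs = BIC/TNW = 0.2886
#>   E_null = 0.1920 (R = 999), E_max = 1 - 1/8 = 0.8750
#>   E_adj = 0.1415; Monte Carlo p = 0.001
```

Reading: every stomach held insects/arachnids and they dominate the item
counts, so insects/arachnids top the `%IRI` ranking (0.53) even though
fishes carry most of the mass. The between-individual share of niche width
(`E_obs = 0.29`) exceeds what random sampling from the shared pool produces
(`E_null = 0.19`, p = 0.001): individuals are weakly but detectably
specialized, and `E_adj = 0.14` places the population near the generalist
end of the adjusted scale.

Two populations are compared with `run_comparison()`, which writes per-
population IRI CSVs, specialization JSONs, a filter ledger, and a Markdown
summary; `simulate_diet_dataset(simulation_config(...))` generates datasets
with known structure (the Dirichlet concentration `kappa` dials individuals
from specialists to exact shared-pool samplers at `kappa = Inf`).

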