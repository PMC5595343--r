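# dietmix

Dual diet analysis for marine top predators: stomach-content
reconstruction with dietary indices, and Bayesian stable-isotope mixing
models with mixing-polygon validation.

`dietmix` is written for trophic ecologists who hold the two classic data
streams on a predator population — hard parts recovered from stomachs of
stranded or bycaught animals, and δ¹³C/δ¹⁵N measurements of predator tissue
and candidate prey — and want both the *ingested* diet (stomach contents)
and the *assimilated* diet (isotope mixing model) from one coherent,
testable toolchain. The worked examples use the Gulf of Cadiz bottlenose
dolphin (*Tursiops truncatus*) system, whose published summary tables ship
with the package as example inputs.

## What it computes

**Stomach-content stream**

- `reconstruct()` turns identified hard-part records (otoliths, diagnostic
  fish bones, cephalopod beaks) into per-stomach prey counts and weights:
  each otolith counts as half a fish (bones: half if paired, whole
  otherwise, whichever structure implies more individuals), and length →
  weight follows allometric regressions `L = a + b·x` or `L = a·x^b`,
  `W = c·L^d`.
- `diet_table()` / `relative_importance()` compute the standard indices
  %N, %O, %W and the Index of Relative Importance
  `IRI = (%N + %W) × %O` (0–20 000), in full precision or in the
  two-decimal "reporting" convention of published diet tables.
- `prey_specific_abundance()` and `amundsen_points()` give the
  Costello–Amundsen feeding-strategy diagram coordinates
  `%Pᵢ = 100 · ΣWᵢ / ΣWₜᵢ` (weight share over only the stomachs containing
  prey *i*).
- `bootstrap_diet()` resamples whole stomachs with replacement and reports
  percentile medians and 95% confidence limits per index.

**Isotope stream**

- `summarize_species()`, `ward_cluster()` and `pool_groups()` summarise
  prey isotope values, cluster species into isotopically coherent source
  groups (Ward linkage on the δ¹³C/δ¹⁵N mean plane), and pool members into
  exact group-level summaries.
- `isomix()` fits the mass-balance mixing model: per isotope *j*,
  consumer values are `x_ij ~ N(Σₖ pₖ(μₖⱼ+λₖⱼ), √(Σₖ pₖ²(σₖⱼ²+τₖⱼ²)+ξⱼ²))`
  with a Dirichlet prior on the diet proportions `p`, diet-to-tissue
  discrimination factors `λ ± τ`, and an optional residual error `ξ`.
  Sampling is random-walk Metropolis on the additive-log-ratio transform,
  with split-chain Gelman–Rubin diagnostics; the fit is a classed object
  with `print`, `summary`, `coef`, `plot` and `simulate` methods.
- `mixing_polygon()` runs the Monte-Carlo mixing-polygon simulation: the
  convex hull of discrimination-corrected source draws is rebuilt per
  iteration, every consumer's inside probability is estimated, and the
  design passes only if all consumers sit inside the 95% mixing region
  (inside probability ≥ 0.05).

Synthetic-data generators (`simulate_stomach_dataset()`,
`simulate_isotope_dataset()`, `default_gulf_config()`) produce both kinds of
dataset with known ground truth, so the whole pipeline is testable end to
end.

## Worked example

Reporting-mode indices for three key prey of the Gulf of Cadiz dolphins,
recomputed from the bundled raw diet table (1001 prey items, 13 stomachs,
143 842.21 g reconstructed weight):

```r
library(dietmix)
t1  <- cadiz_table1()
fam <- t1[t1$taxon %in% c("Conger conger", "Merluccius merluccius",
                          "Cepola macrophthalma"), ]
cbind(fam["taxon"],
      relative_importance(fam$N, fam$O, fam$W, total_n = 1001,
                          n_stomachs = 13, total_w = 143842.21,
                          mode = "reporting"))
#>                    taxon  pctN  pctO  pctW     IRI
#> 5   Cepola macrophthalma 25.57 15.38  4.87  468.17
#> 8          Conger conger 21.48 61.54 35.18 3486.86
#> 17 Merluccius merluccius 13.69 38.46 16.52 1161.88
```

European conger is the dominant ingested prey: present in 61.54% of
stomachs and carrying 35.18% of the reconstructed weight, for an IRI of
3486.86 out of a possible 20 000.

Isotope side: simulate 51 consumers from a known four-group diet, validate
the design with the mixing polygon, then recover the diet:

```r
tdf <- data.frame(isotope = c("d13C", "d15N"), mean = c(1.0, 1.6),
                  sd = c(0.4, 0.5))          # study-specific; user-supplied
sim <- simulate_isotope_dataset(
  default_gulf_config(tdf, true_p = c(0.5, 0.3, 0.15, 0.05), seed = 7))

mixing_polygon(sim$consumers, cadiz_sources(), tdf, seed = 7)
#> Mixing-polygon simulation: 1500 iterations, 51 consumers
#> inside probability: min 0.285, median 0.765, max 0.845
#> 0 consumer(s) outside the 95% mixing region
#> overall: PASS

fit <- isomix(sim$consumers, cadiz_sources(), tdf, seed = 11)
fit
#> Bayesian stable-isotope mixing model (4 sources, 51 consumers)
#> 3 chains x 5000 draws after 5000 burn-in; residual error: yes
#> Posterior mean diet proportions:
#>   p_1   p_2   p_3   p_4
#> 0.496 0.247 0.208 0.050
#> Max split R-hat: 1.045
```

The posterior means land on the generating proportions (0.5, 0.3, 0.15,
0.05) to within a few percent — group 2 vs group 3 trade off slightly, as
expected with two isotopes and four sources — and every true value falls
inside its 95% credible interval (`summary(fit)`).

## Vignette

`vignettes/dietmix-methods.Rmd` documents the models, the numerical
choices (rounding convention, bootstrap percentiles, MCMC adaptation,
hull/point-in-polygon tolerances), what the synthetic-data generators do
and do not emulate, and known limitations.
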