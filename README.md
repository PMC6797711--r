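# trioscape

Burden-aware gene-list enrichment and belief-network landscape analysis for
congenital heart disease (CHD) trio cohorts.

Large exome-sequenced trio cohorts show that CHD has two largely distinct
genetic architectures: damaging **de novo** variants concentrated in
chromatin-modifying genes, and rare damaging **recessive** genotypes
(homozygous or compound heterozygous) concentrated in cilia-related genes.
Measuring this stratification requires controlling for the very different
background rare-variant burden of gene classes, and for confounders such as
ancestry and exome-capture platform. `trioscape` implements that analysis
stack for statistical geneticists:

- **Permutation enrichment test.** For a gene list of size *N*, the observed
  number of distinct damaged genes is compared against the counts in *P*
  random *N*-gene lists drawn from the whole universe. The empirical p-value
  is *p = (d + 1)/(P + 1)* with *d* the number of draws reaching the observed
  count (floor 1/(P+1), just under 1e-5 at the production *P* = 100,000).
  Counts are standardized to Z-scores against the null moments so lists of
  different size and burden can be ranked, and fold enrichments
  (observed/null mean) compared across inheritance modes.
- **Burden-matched and housekeeping controls.** Per-gene burden ratios
  (rare variants per base of the largest coding transcript) are matched
  decile by decile by stratified rejection sampling to build control lists
  that are disjoint from, equal in size to, and burden-equivalent with each
  test list.
- **Damaged-genotype filtering.** Burden-test p ≤ 0.005, carrier-fraction
  (PAR) ≥ 0.005 gene exclusion, mucin/olfactory-receptor exclusion, common
  polymorphism (maf ≥ 0.05) exclusion, plus expected population genotype
  frequencies (q² / 2q₁q₂, absent alleles floored at 1e-5).
- **Phenotype association** (Fisher's exact test of carrier status against
  heterotaxy/laterality, Benjamini–Hochberg control) and **trio-level QC**
  (kinship, syndrome, and variant-count filters).
- **Discrete belief networks**: exact AIC-optimal structure learning
  (dynamic programming over node subsets, ≤ 14 nodes), CPT fitting, exact
  inference by variable elimination, conditional risk-ratio queries with
  negated evidence, bootstrap edge support via hill climbing, nested
  likelihood-ratio tests, and moralized graphs with signed edge strengths.
- **A synthetic trio-cohort generator** (`sim_config()`, `simulate_study()`)
  that emulates the study conditions — an 18,876-gene universe with
  length- and class-dependent burden, the five candidate gene lists with
  their exact overlap structure, 2391 probands in four phenotype classes,
  ~3083 recessive and ~1351 de novo damaged calls with planted per-list
  enrichment multipliers, a heterotaxy phenotype conditionally dependent on
  recessive cilia genotypes, and ancestry-by-capture confounding — with
  recorded ground truth so every statistic can be validated by parameter
  recovery.

## Worked example

```r
library(trioscape)

study    <- simulate_study(sim_config(seed = 42))
retained <- classify_damaged(study$calls, n_probands = 2391)

enrich <- test_enrichment(retained, study$universe,
                          study$lists[c("SysCilia", "Cilia", "Chromatin",
                                        "Housekeeping")],
                          P = 2000, seed = 7)
```

```
          list      mode   N observed null_mean  empirical_p     z fold
1     SysCilia recessive 302      134     44.49 0.0004997501 14.66 3.01
2     SysCilia   de_novo 302       22     20.56 0.4092953523  0.34 1.07
3        Cilia recessive 669      228     99.07 0.0004997501 14.56 2.30
4        Cilia   de_novo 669       60     45.51 0.0219890055  2.24 1.32
5    Chromatin recessive 163       36     24.05 0.0084957521  2.65 1.50
6    Chromatin   de_novo 163       49     11.00 0.0004997501 11.70 4.46
7 Housekeeping recessive 669       36     99.08 1.0000000000 -6.92 0.36
8 Housekeeping   de_novo 669       33     45.21 0.9810094953 -1.88 0.73
```

Reading the table: the synthetic cilia lists are strongly enriched for
damaged recessive genotypes (SysCilia: 134 damaged genes observed vs a null
mean of 44.5, Z ≈ 14.7, empirical p at the floor of 1/(P+1)) but only weakly
for de novo variants, while the chromatin list shows the reciprocal pattern
(Z ≈ 11.7 for de novo vs 2.7 for recessive). The housekeeping control list
is *depleted* for recessive damage (Z ≈ −6.9) — the pattern the generator
plants and the analysis is designed to expose. A belief-net risk query on
the same cohort:

```r
x   <- encode_features(study$probands, retained, study$lists["Cilia"])
net <- fit_cpts(list(Phenotype = c("R_Cilia", "Gender")),
                x[, c("R_Cilia", "Gender", "Phenotype")])
risk_ratio(net, "Phenotype", "HTX", list(R_Cilia = "1"))
#> [1] 1.117
```

i.e. in this single simulated cohort, carrying a damaged recessive cilia
genotype raises the probability of a heterotaxy phenotype by ~12% over the
cohort marginal (the generator plants a 1.4-fold conditional risk; a single
cohort of 2391 probands measures it with visible Monte-Carlo error, which is
why the validation suite averages replicate cohorts).

`autoplot()` on a `build_null()` result draws the null histogram with the
observed count, `plot_enrichment()` the Z-score dot plot, and
`plot_moral_graph(moralize(net))` the undirected network with signed edge
strengths. `tidy()`/`glance()` methods summarize fitted belief networks.

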