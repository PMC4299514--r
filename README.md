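# warburgfba

Constraint-based modelling of the Warburg effect — aerobic glycolysis — in
cohorts of cell-line metabolic models.

Tumour cells secrete lactate even when oxygen is available. In a
flux-balance model (steady-state mass balance `S v = 0`, capacity bounds
`v_min <= v <= v_max`, maximised biomass flux) that phenotype has a sharp
structural signature: the **minimal feasible lactate secretion at maximal
growth is strictly positive** — the model is *forced* to ferment. This
package builds expression-tailored cell-line models from a generic
stoichiometric scaffold, quantifies their bioenergetic state by sampling
the maximal-biomass face of the flux polytope, and screens reaction
knockouts for targets that revert the glycolytic state without killing the
cell:

* **Metrics** — ECAR (mean lactate-secretion flux), OCR (mean oxygen
  uptake), their ratio EOR, and the **AFR**: the ratio of mean glycolytic
  ATP-producing flux to mean oxidative ATP-producing flux, weighted by ATP
  stoichiometry. A transcript-level proxy, the BEC index
  (GAPDH / ATP-synthase-beta expression ratio), is included.
* **Model tailoring** — per cell line, enzyme expression is aggregated over
  gene rules (isoenzymes sum, complex members take the minimum), min-max
  normalised across the cohort, and mapped onto maximal flux capacities of
  a growth-associated reaction subset.
* **Simulation** — oxygen calibration (largest uptake bound that still
  forces fermentation), hypoxia (50% of the normoxic bound), and inhibitor
  dose-response curves of ECAR and OCR.
* **Knockout screen** — three filters: abolish forced lactate in all lines;
  keep > 10% of wild-type growth; drop the sampled AFR below 60% of wild
  type. Survivors map to candidate target genes with
  knockdown-sufficiency annotations.
* **Statistics** — exact/Monte-Carlo permutation Spearman correlations,
  partial Spearman, Benjamini-Hochberg FDR, and a shuffle-based empirical
  cohort p-value for measure-drug-response association.
* **Synthetic data** — hand-solvable fixtures (`build_warburg_mini()` and
  friends), a 25-reaction core-carbon network (`build_toy_core()`) with
  verified forced-lactate structure, and cohort generators with planted
  glycolytic character, phenotypes and drug responses.

Models are plain R objects; I/O covers SBML Level 3 + FBC and a native
three-table TSV format.

## Worked example

The minimal fixture is solved completely by hand, so every number below is
checkable on paper:

```r
library(warburgfba)

m <- build_warburg_mini()
forced_lactate(m)
#> $max_biomass [1] 5      # glucose and oxygen caps bind
#> $min_lactate [1] 15     # growth at 5 is impossible without fermenting
#> $forced      [1] TRUE

# unlimited oxygen removes the forcing
forced_lactate(set_bounds(m, "EX_o2_in", upper = Inf))
#> $max_biomass [1] 15.71429   # 110/7
#> $min_lactate [1] 0

fs <- sample_optimal_face(m, n = 1000, seed = 1)
compute_metrics(fs, m)
#> <warburg_metrics> ECAR 15  OCR 2.5  EOR 6  AFR 2

scr <- run_screen(m, reactions = c("GLY", "RESP", "LDH", "TCA"),
                  n_samples = 1000, seed = 1)
scr
#> <warburg_screen> 4 reactions tested: 3 abolish lactate -> 1 spare growth -> 1 reduce AFR
#>   survivors: LDH
map_targets_to_genes(m, scr$survivors)
#>    gene reactions n_reactions knockdown_sufficient
#> 1 gLDH1       LDH           1                FALSE
#> 2 gLDH2       LDH           1                FALSE
```

The screen keeps exactly the lactate dehydrogenase knockout: it abolishes
lactate secretion, retains 55/130 ≈ 42% of wild-type growth, and drops the
AFR to 7/52 ≈ 13.5% of wild type. Both of its genes are isoenzymes, so no
single-gene knockdown closes the reaction — the kind of caveat the gene
table exists to surface.

Cohort-level analysis runs the same machinery across a synthetic panel:

```r
tc <- build_toy_core()
cohort <- generate_cohort(tc, n_lines = 20, seed = 7)
cw <- cohort_warburg(tc, cohort$expression, n_samples = 1000, seed = 7)
afr <- setNames(cw$afr, cw$line)
spearman_exact(afr, cohort$phenotypes$migration)   # positive, p < 0.05
spearman_exact(afr, cohort$phenotypes$growth)      # negative, p < 0.05
response_association(afr, cohort$responses, seed = 7)
#> ~30% of compounds significant, >90% positively correlated
```

A thin command-line wrapper with `synth`, `tailor`, `simulate`, `screen`
and `associate` subcommands lives at `inst/cli/warburgfba.R`.

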