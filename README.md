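# ptmdriver

Detects candidate disease-driver proteins whose post-translational
modification (PTM) motif regions carry a significantly elevated somatic
mutation rate relative to the rest of the protein. The intended users are
cancer-genomics and proteomics analysts who have cohort mutations already
mapped to protein coordinates (e.g. via ANNOVAR/VEP) and a catalog of
experimentally known modification sites (dbPTM-style TSV), and who want a
ranked list of proteins in which mutations preferentially hit the residues
around modification sites — a signature of selection acting on PTM-dependent
regulation.

## Model

For one protein of length *n* with known modification sites of one PTM type,
every residue within ±7 positions of a site belongs to the merged
**modification region** (*k* residues); the remaining *n − k* residues form
the **background**. Only missense mutations are counted (no stop gain/loss).
Per-position cohort-summed counts are modelled as

- *Y_i* ~ Poisson(λ₁), *i* = 1…*k* (modification region)
- *Y_i* ~ Poisson(λ₂), *i* = *k*+1…*n* (background)

with conjugate Gamma(α, β) priors (shape–rate; default α = β = 0.001) on
both rates, giving closed-form posteriors
Gamma(α + ΣY, β + #positions). The quantity of interest is the relative
rate **R = λ₁/λ₂**; each protein's p-value is the posterior probability of
the null **H₀: R ≤ 1**,

P(λ₁ ≤ λ₂ | Y) = I_x(a₁, a₂) with x = b₁/(b₁+b₂),

the regularized incomplete beta function of the two posterior parameters —
computed exactly by default, or by paired posterior sampling
(`method = "mc"`, with the conventional iterations/burn-in interface).
Benjamini–Hochberg correction across all tested proteins of a run yields
q-values; proteins with q below the threshold (default 0.05) are flagged as
candidate drivers.

## Worked example

Simulate a truth-labelled cohort at the package's reference conditions
(500 proteins × 400 residues, 3 phosphosites each, background rate 0.1
mutations/position, 10% drivers at five-fold enrichment), run the pipeline,
and score the calls:

```r
library(ptmdriver)
sim <- simulate_cohort(sim_config(seed = 43), out_dir = "cohort")
run <- run_pipeline(sim$paths$mutations, sim$paths$sites, sim$paths$proteins,
                    ptm_type = "Phosphorylation", out_dir = "run", quiet = TRUE)
head(run$results, 3)
#>   accession        ptm_type  k   n mod_mutations bg_mutations    r_mean
#> 1   SIM0196 Phosphorylation 31 400            24           22 13.603204
#> 2   SIM0320 Phosphorylation 45 400            32           31  8.414634
#> 3   SIM0121 Phosphorylation 45 400            35           43  6.573978
#>        p_value      q_value is_driver
#> 1 1.642805e-15 8.214024e-13      TRUE
#> 2 6.145147e-15 1.536287e-12      TRUE
#> 3 4.809524e-14 8.015873e-12      TRUE
unlist(evaluate_run(sim$truth, run$results))
#>     n_tested       n_null     n_driver type_i_error        power     n_called
#> 500.00000000 450.00000000  50.00000000   0.03333333   0.98000000  50.00000000
#> realized_fdr
#>   0.02000000
```

The top rows are true drivers: 24 mutations concentrated in a 31-residue
modification region against 22 spread over 369 background residues gives a
posterior relative rate near 14 and essentially zero posterior mass on
R ≤ 1. On this cohort 50 of 500 proteins are called at q < 0.05, recovering
49 of the 50 true drivers with one false call (realized FDR 0.02); 3.3% of
null proteins fall below p = 0.05. The run directory also receives `annotated_mutations.tsv` (region
membership, nearest site, optional 0–7 pathogenicity tally over the seven
functional predictors), `skipped_proteins.tsv` (e.g. proteins whose motif
regions swallow the whole sequence and leave no background), and
`manifest.json` with the config echo and per-stage mutation accounting.

A command-line front-end with `run`, `simulate` and `evaluate` subcommands
is installed at `inst/cli/ptmdriver.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ptmdriver.R", package="ptmdriver"))')" \
    run --mutations cohort/mutations.tsv --ptm-sites cohort/ptm_sites.tsv \
    --proteome cohort/protein_lengths.tsv --ptm-type Phosphorylation --out run
```

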