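---
title: "Testing for mutation enrichment in protein modification regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for mutation enrichment in protein modification regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmdriver)
```

## The question

Post-translational modifications — phosphorylation, ubiquitination,
acetylation and the rest — are read and written through short sequence
motifs around the modified residue. A missense mutation landing in such a
motif can abolish or rewire the modification even when it does not touch
the modified residue itself. If a disease cohort shows *more* missense
mutations per residue inside a protein's modification motifs than across
the rest of that same protein, that excess is a signature of selection and
the protein is a candidate driver. `ptmdriver` formalizes this comparison
protein by protein and controls the false discovery rate across the cohort.

Using the protein's own background as the reference sidesteps the largest
confounders of absolute-rate driver tests (gene-level mutability,
expression, replication timing): both regions share them, and only the
*within-protein contrast* is scored.

## Region construction

Every catalogued site of the chosen PTM type contributes a symmetric motif
window: the central residue plus `window` residues on either side
(default 7, i.e. up to 15 residues per site), truncated at the termini.
Same-type windows on one protein are merged into a single modification
region of size $k$; the other $n - k$ residues are the background. The
choice of a ±7 window including the center follows the motif half-width
conventions of kinase-substrate and modification-site predictors; it is a
tunable parameter, and the window is applied on 1-based, closed protein
coordinates. Different PTM types are never merged — each
(protein, PTM type) pair is an independent test unit, one type per run.

Two degenerate cases are excluded rather than forced through the test:
proteins with no catalogued site (nothing to compare) and proteins whose
merged region covers the whole sequence ($k = n$, no background to compare
against). Both are listed in the run's skipped-proteins report with a
reason, not assigned a pseudo-p-value.

## The model

Let $Y_1, \dots, Y_k$ be cohort-summed missense counts at the modification
region's positions and $Y_{k+1}, \dots, Y_n$ the background counts:

$$Y_i \sim \text{Poisson}(\lambda_1),\ i \le k; \qquad
  Y_i \sim \text{Poisson}(\lambda_2),\ i > k,$$

with independent conjugate priors
$\lambda_j \sim \text{Gamma}(\alpha_j, \beta_j)$ in the shape–rate
parametrization, so that the posteriors are available in closed form:

$$\lambda_1 \mid Y \sim \text{Gamma}\!\big(\alpha_1 + \textstyle\sum_{i\le k} Y_i,\ \beta_1 + k\big),
\qquad
\lambda_2 \mid Y \sim \text{Gamma}\!\big(\alpha_2 + \textstyle\sum_{i>k} Y_i,\ \beta_2 + (n-k)\big).$$

The target of inference is the relative rate $R = \lambda_1/\lambda_2$,
with the one-sided hypotheses $H_0: R \le 1$ versus $H_1: R > 1$. The
reported p-value is the posterior probability of the null,

$$p = P(\lambda_1 \le \lambda_2 \mid Y) = I_x(a_1, a_2), \quad
  x = \frac{b_1}{b_1 + b_2},$$

where $(a_j, b_j)$ are the posterior shape and rate and $I_x$ is the
regularized incomplete beta function (this follows from
$b_1\lambda_1/(b_1\lambda_1 + b_2\lambda_2) \sim \text{Beta}(a_1, a_2)$).
Benjamini–Hochberg correction is applied over all tested proteins of one
run — one cohort, one PTM type, which we take as the natural
multiple-testing family — and `q_value < q_threshold` (strict, default
0.05) flags a driver.

### Counting conventions

Counts are cohort totals per position, not per-sample indicators: a hotspot
mutated in 40 patients contributes 40, and distinct amino-acid changes at
one position all count. Recurrence is precisely the signal a driver test
should accumulate, and the per-position Poisson model takes a single count
per position. Only missense mutations are counted; synonymous changes do
not alter the protein and stop gain/loss act through truncation rather
than motif disruption, so both are filtered before counting (the filter
tallies what it drops, and the run manifest balances input = retained +
dropped-by-consequence + dropped-unmapped).

### Priors

No canonical hyperparameters exist for this problem, so both priors default
to the weakly-informative Gamma(0.001, 0.001) (prior mean 1, effectively
negligible pseudo-counts), user-configurable per region. With appreciable
counts in both regions the prior choice is immaterial — with ~30 counts in
the modification region and ~270 in the background, switching to Gamma(1,1)
moves the p-value by under $10^{-3}$ — but when the modification region
carries only a handful of counts a unit prior adds a visible pseudo-count,
which is why the weak default is the default.

### Exact versus Monte-Carlo evaluation

Because the posteriors are conjugate, the "MCMC" evaluation of
$P(R \le 1 \mid Y)$ reduces to exact iid sampling from two Gamma
distributions — no Markov kernel, no convergence question. The package
keeps the conventional `iterations`/`burn_in` interface (burn-in draws are
discarded) for compatibility with samplers of this family, and additionally
provides the incomplete-beta closed form as the default path: it is
deterministic, faster, and serves as the analytic oracle against which the
sampler is validated (agreement within three Monte-Carlo standard errors
across a randomized grid of posterior pairs is part of the test suite).
The point estimate of $R$ reported alongside is the posterior mean:
analytic, $a_1 b_2 / (b_1 (a_2 - 1))$, on the exact path (infinite when the
background posterior shape is ≤ 1, which the weak prior makes possible only
for an empty-count background); the draw-wise mean of $\lambda_1/\lambda_2$
on the sampling path.

### Numerical and determinism choices

Ties in the output ordering are broken by q-value, then p-value, then
accession string, so results tables are byte-identical across reruns of the
same configuration — on the sampling path a single seed set once before the
per-protein loop drives all draws. BH adjustment is the standard step-up
procedure (`stats::p.adjust`), validated in the tests against an
independently hand-coded implementation. Equidistant nearest-site ties in
the per-mutation annotation resolve to the lower position; predictor calls
for the 0–7 pathogenicity tally treat missing values as non-deleterious.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws from exactly the generative model above: site
positions uniform on the protein, per-position counts Poisson with
$\lambda_1 = R_{\text{true}} \lambda_2$ in the merged region, counts then
expanded into per-sample mutation rows (uniform sample attribution, uniform
ref/alt amino acids). Its defaults are fixed as the package's reference
study conditions: 500 proteins of 400 residues, three sites per protein,
window 7 (merged region ≤ 45 residues), cohort-summed background rate
$\lambda_2 = 0.1$ per position, 10% drivers at $R_{\text{true}} = 5$, and a
100-sample cohort (sample identity is ignored by the model, so this choice
only shapes the files; 100 is a typical cohort scale). Under those
conditions a driver expects $\approx 45 \times 0.5 > 20$ region mutations.

Passing calibration and power tests on these cohorts shows the inference is
correct *for its own model*. Real cohorts violate that model in known ways
the simulator deliberately omits: mutation rates vary along real proteins
with sequence context and domain structure (the Gamma prior absorbs
overdispersion between regions, not systematic within-region structure);
hypermutated samples concentrate counts; mutational signatures prefer some
codons; and PTM catalogs are incomplete, which dilutes true regions into
the background and biases the test conservative. Results on real data
should be read with those caveats.

## Problem sizes used in validation

The test suite and the acceptance script run the reference conditions
(500 proteins, one null and one 10%-driver cohort), a 60-pair randomized
posterior grid at $10^5$ draws for the sampler-versus-oracle check, 1,000
random partitions for the region algebra, and 100 random vectors for the
BH cross-check. Observed behaviour at these sizes (seeds 1, 7, 123, 2026):
type-I error 0.028–0.046 at nominal 0.05 — slightly conservative, as
expected from a discrete-count posterior probability used as a p-value —
power 0.96–1.00, realized FDR 0.00–0.09 at q < 0.05, and pooled background
rate recovered within 1% of the configured $\lambda_2$.

## Known limitations

- Protein-coordinate input only: genomic mutations must be pre-annotated
  (ANNOVAR/VEP) upstream; no liftover or transcript selection is done.
- No covariate modelling (expression, replication timing, trinucleotide
  context) beyond the within-protein contrast itself.
- The per-run BH family is one cohort × one PTM type; analyses across many
  PTM types should correct accordingly.
- The posterior-probability p-value is one-sided by construction; regional
  *depletion* ($R < 1$) is visible as $p \to 1$ but is not separately
  tested.
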