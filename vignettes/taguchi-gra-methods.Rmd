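---
title: "Methods: Taguchi S/N analysis and grey relational multi-response optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Taguchi S/N analysis and grey relational multi-response optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taguchigra)
```

## The problem and the data

A bacterial biocontrol agent is harvested from its cultivation broth by
flocculation with chitosan. Five process factors — chitosan type, pH,
chitosan dosage (45/55/65 mg/L), rapid mixing (250/350/450 rpm) and slow
mixing (50/100/150 rpm), each at three levels — are screened in an
L18(3^5) orthogonal array: 18 runs instead of the 3^5 = 243 of a full
factorial. Each run yields five larger-the-better responses: the
flocculation efficiency (the percentage drop in optical density at 600 nm,
`flocculation_efficiency()`) and four inhibition-zone diameters (mm)
measuring the antimicrobial activity of the chitosan–biomass precipitate
against bacterial and fungal phytopathogens.

The design is stored explicitly (`l18_design()`), not generated from a
generic L18 catalogue, because the study fixes one particular column
selection. Its defining property — each level six times per factor, each of
the nine level pairs exactly twice per factor pair — is verified by
exhaustive counting in `check_balance()`.

## Single-response analysis

Every response is converted to a decibel signal-to-noise ratio with the
larger-the-better convention

$$\mathrm{S/N} = -10\log_{10}\Big(\tfrac1n\sum_i y_i^{-2}\Big),$$

which for the single measurement per run used here reduces to
$20\log_{10} y$. The study never prints the formula; this standard form
reproduces all 18 published S/N values to the fourth decimal, which fixes it
as the definition. Smaller-the-better and nominal-is-best variants are out
of scope.

Factor influence is quantified by a balanced fixed-effects ANOVA of the S/N
vector (`doe_anova()`): with six runs per level,
$SS_f = 6\sum_l (\bar y_{f,l} - \bar y)^2$, each factor carries 2 degrees of
freedom, the error takes the remaining $17 - 10 = 7$, and p-values come from
the exact upper tail of $F(2,7)$ (`stats::pf`). The implementation uses
these closed-form identities rather than a generic linear-model fit so that
the degenerate cases required of it (zero error mean square reported as
$F=\infty$, $p=0$; constant input reported as all-zero SS) are well defined;
the test suite cross-checks it against `stats::aov` on random inputs. The
optimal combination is the per-factor argmax of the per-level mean S/N
(`select_optimal()`). Exact ties are reported as ties rather than silently
broken — real data never tie here, synthetic data can.

## Grey relational analysis

With several responses, each column is first normalized larger-the-better to
$[0,1]$ over the design runs, $X_{ij} = (Y_{ij} - \min_j)/(\max_j - \min_j)$,
so every column attains both 0 and 1. Deviations $\Delta_{ij} = 1 - X_{ij}$
are converted to grey relational coefficients

$$GRC_{ij} = \frac{\Delta_{\min} + \psi\,\Delta_{\max}}
                 {\Delta_{ij} + \psi\,\Delta_{\max}},$$

and averaged with weights $w_j$ into the grade
$GRG_i = \sum_j w_j\,GRC_{ij}$, the single objective that is then pushed
through the same S/N → ANOVA → main-effects machinery.

Numerical conventions, chosen where the published procedure is silent:

* **$\Delta_{\min}, \Delta_{\max}$ are global** over the deviation matrix.
  After larger-the-better normalization every column attains 0 and 1, so the
  global and per-column conventions coincide on any valid in-design matrix;
  the global one is what `grey_relational_coefficient()` implements and what
  out-of-design scoring fixes at 0 and 1 explicitly.
* **$\psi = 0.5$** by convention, configurable in $(0,1]$. Smaller $\psi$
  sharpens the discrimination between deviations; the grade ordering of the
  best runs is insensitive to it in these data.
* **Equal weights** by default (the study treats flocculation and biocontrol
  as equally important); any non-negative weight vector summing to 1 is
  accepted.
* **Ranking** is competition style: equal grades share a rank and the next
  rank is skipped.

### Scoring validation runs

A confirmation experiment is performed outside the design, so its responses
are normalized against the *stored* per-response min/max of the design runs
(`score_external()`); the context is deliberately not refreshed. A
validation response may exceed the design maximum (here the *Aspergillus*
zone, 44.85 mm vs a design maximum of 44.33 mm); with `clamp = TRUE`
(default) its normalized value is clipped to 1 (deviation 0), keeping every
coefficient in $[\psi/(1+\psi), 1]$. This clipped convention is the one that
reproduces the study's validation grade; `clamp = FALSE` is available and
flags coefficients above 1 instead.

### The thirds convention

Zone diameters are means of triplicate integer-valued plate reads and print
as `x.33` / `x.67`. `load_fixture(..., thirds = TRUE)` (default) restores
the exact repeating thirds ($x + 1/3$, $x + 2/3$) before analysis, which
reproduces the published normalized/coefficient tables to 4 decimals;
feeding the literal 2-decimal values instead degrades agreement to roughly
$5\times10^{-4}$. This motivates the package-wide comparison tolerance for
published 4-decimal values of $\pm 10^{-3}$: the published tables were
rounded from unrounded intermediates, so recomputation from printed inputs
can differ in the fourth decimal. The same applies to the S/N column — one
published efficiency S/N (run 14) differs from the value recomputed from
the 2-decimal efficiency by $5\times10^{-4}$, which is exactly this rounding
effect.

### Additive prediction

`predict_additive()` predicts the response at an arbitrary combination under
the no-interaction model: grand mean plus the chosen levels' deviations from
it, on either the raw-value or the decibel scale (with $10^{\mathrm{pred}/20}$
back-transform), over any subset of factors. The study's printed predicted
validation grade is **not** recoverable by any of these variants (the
all-term value-scale prediction from the published grades gives 0.8712
where 0.8673 is printed, and the S/N-scale and significant-terms-only
variants do not match either); the publication does not state its prediction
formula, so the package documents the divergence rather than imitating an
unknown computation. The default is the value scale with all terms.

## The synthetic generator

`synthetic_config()` / `simulate_doe()` emulate the statistical structure the
analysis assumes — and only that structure:

* an **additive main-effects surface** $y_{ij} = \mu_j + \sum_f e_{f,l_f(i),j}$
  with zero-sum level effects per factor (identifiability), deliberately
  without interactions so that "the planted optimum" is well defined;
* **Gaussian noise**, a single draw for the efficiency and the mean of three
  replicate draws, rounded to 2 decimals, for each zone (mimicking how
  triplicate plate reads are recorded — this exercises the thirds-tolerance
  path);
* **physical bounds**: efficiency clipped to $(0.01, 100]$ and zones floored
  at 0.01 mm, with clipping flagged via the `clipped` attribute (the small
  floor keeps the decibel transform finite and is a generator artifact, not
  a model claim).

Defaults were chosen once for realism: planted optimum A3 B1 C2 D3 E1,
efficiency baseline 82 % with factor amplitudes 4/6/1/0.5/2.5 (pH strongest,
rapid mixing weakest, mirroring the observed importance ordering), zone
baselines 34 mm with amplitudes 3/2.5/1/0.5/2, $\sigma = 2\,\%$ for the
efficiency and 1 mm per zone replicate. The noise-free surface at the
optimum is then about 96 % efficiency and 41 mm zones, resembling the best
observed runs; the defaults are not fitted to the study's residuals.

`recovery_experiment()` repeats generate → GRA → S/N → main effects →
select, and reports per-factor and joint recovery rates of the planted
optimum (a tie counts as a miss). Without noise recovery is certain; under
the null (all effects zero) each factor is recovered at chance level 1/3.

What passing these checks does *not* show: real flocculation data have
interactions, non-Gaussian measurement error and responses whose scales the
normalization reweights, so synthetic recovery rates are an internal
consistency check of the pipeline, not a power analysis for the laboratory
assay.

## Problem sizes and determinism

All published-table reproductions run on the 18-run fixtures in well under a
second. Property-style checks use 10–20 random 18×5 matrices; recovery
experiments use 1000 repetitions for the chance-level null (binomial
standard error ≈ 0.015) and 60 per effect size for the monotonicity check —
sizes chosen so the whole suite completes in a few seconds while keeping
Monte-Carlo error far below the margins being asserted. Everything
downstream of `set.seed()` is reproducible; the analysis pipeline itself is
fully deterministic.

## Known limitations

* No interaction terms, factor pooling, or confidence intervals on
  predictions; the ANOVA is the balanced, equal-replication special case and
  refuses unbalanced designs rather than switching to adjusted sums of
  squares.
* All responses must be larger-the-better; smaller-the-better or
  nominal-is-best normalizations are not provided.
* GRA variants (entropy weighting, grey target theory) and alternative
  multi-criteria methods (TOPSIS, desirability functions) are out of scope.
* The generator's clipping can, at extreme noise, truncate the efficiency
  distribution; clipped cells are flagged so such runs can be excluded.
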