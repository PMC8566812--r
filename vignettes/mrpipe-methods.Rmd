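---
title: "Methods and design of mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization treats K genetic variants as
instrumental variables. For variant $k$, the exposure GWAS reports
$X_k \sim N(\gamma_k, \sigma_{X_k}^2)$ and the outcome GWAS — from a
*different* sample, so the noise terms are independent — reports
$Y_k \sim N(\beta\gamma_k + \alpha_k, \sigma_{Y_k}^2)$, where $\beta$ is
the causal log-odds effect of one SD of exposure and $\alpha_k$ is the
variant's direct (pleiotropic) effect on the outcome. Instrument validity
means $\alpha_k = 0$.

The three estimators make progressively weaker assumptions:

* **IVW** (the primary method): all instruments valid. Fixed-effect
  combination of the Wald ratios $Y_k/X_k$ with weights
  $w_k = (X_k/\sigma_{Y_k})^2$, algebraically
  $\hat\beta = \sum X_k Y_k \sigma_{Y_k}^{-2} / \sum X_k^2 \sigma_{Y_k}^{-2}$
  with $\hat\sigma^2 = 1/\sum X_k^2\sigma_{Y_k}^{-2}$. We deliberately use
  these *first-order* weights — $\sigma_{X_k}$ does not appear — and no
  over-dispersion scaling, because that is the estimator whose closed form
  the downstream reports quote; a multiplicative random-effects variant is
  available behind `random_effects = TRUE` and can only widen intervals.
* **Weighted median**: valid instruments carry more than half of the total
  weight. The estimate inverts the weighted empirical CDF of the sorted
  Wald ratios at 1/2, with midpoint-style cumulative weights
  $s_k = \sum_{j\le k} w_j - w_k/2$ and linear interpolation, so it varies
  continuously with the data. Its sampling SE has no closed form; we use a
  parametric bootstrap redrawing $X_k$ and $Y_k$ from their reported
  normal distributions (default 1000 replicates, explicit seed required).
* **MR-Egger**: InSIDE — instrument strength independent of direct
  effects. Weighted regression with a free intercept after orienting all
  $X_k \ge 0$ (the fit is not invariant to allele coding, so a canonical
  orientation is part of the estimator). The intercept estimates the mean
  direct effect; the slope is the adjusted causal estimate.

## Reference distributions and numerical choices

* IVW and weighted-median p-values and CIs use the standard normal
  ($z_{0.975} = 1.959964$); Egger slope *and* intercept use $t_{K-2}$.
  The sources this workflow mirrors are silent on the choice; $t$ is the
  convention of the regression-based estimator and is conservative at the
  small K typical of protein exposures.
* Egger SEs are the unit-dispersion WLS covariance scaled by
  $\max(1, \sqrt{RSE})$, $RSE$ = weighted residual sum of squares over
  $K-2$: under-dispersion is never allowed to shrink an interval.
* Wald ratios error out at $X_k = 0$ rather than returning infinities;
  instrument selection at $p < 5\times10^{-8}$ makes this unreachable in
  practice.
* All estimators are permutation invariant; the weighted median sorts SNPs
  by id before resampling so a fixed seed gives one answer regardless of
  input order.
* Report display rounds OR/CI to 2 decimals and switches p-values to
  scientific notation below 0.001; stored and serialized values keep full
  precision (15 significant digits in TSV, unrounded in JSON).

## Harmonization policies

Records are aligned to the exposure's effect allele: identical alleles
pass through; swapped alleles negate the outcome beta and reflect the
frequency; a strand-complement match is complemented first. Palindromic
variants (A/T, C/G) are ambiguous because complementing equals swapping.
The default policy is `keep` — trust the stated alleles — which is correct
exactly when both datasets are already harmonized to the forward strand,
as repository downloads typically are; `drop` and `frequency` (keep only
when both frequencies are outside [0.42, 0.58] and on the same side of
0.5, the community-conventional ambiguity window) are provided for data of
unknown strand.

Thresholds are deliberately strict on the printed side of each inequality:
instruments at $p <$ threshold, clumping removes $r^2 >$ 0.01 (a pair at
exactly 0.01 survives) within a 1 Mb window, proxies require
$r^2 \ge 0.8$. Greedy clumping seeds by ascending p-value with
(chromosome, position, id) tie-breaks for determinism. LD and proxy
information are consumed as user-supplied tables; the package never
computes LD from genotypes nor queries remote services. Unphased proxies
whose alleles cannot be reconciled fall back to frequency alignment (both
EAFs informative, i.e. at least 0.08 from 0.5) and are logged; otherwise
they are dropped with a reason. Every decision lands in the audit table —
which instruments were proxied or dropped is surfaced, never guessed.

## The synthetic-data generator

`simulate_study()` emulates the post-clumping state of a two-sample
analysis at the summary level: K independent instruments (no LD — matching
the state after clumping), $\gamma_k \sim U(0.05, 0.3)$, independent
exposure/outcome noise (the two-sample, no-overlap assumption), forward-
strand allele pairs with a configurable palindromic fraction, and exposure
p-values computed from $X_k/\sigma_{X_k}$ so selection is exercisable.
Direct effects $\alpha_k$ implement balanced or directional pleiotropy on
a configurable fraction of instruments (`frac_pleiotropic`), and
`inside_violation = TRUE` makes $\alpha_k$ proportional to $\gamma_k$ plus
noise — the canonical InSIDE failure.

Default SE magnitudes were fixed a priori from the study design the
scenarios echo: `se_Y_level = 0.02` is the per-SNP log-OR SE implied by a
case-control outcome GWAS of roughly 15k cases and 27k controls at common
allele frequencies, and `se_X_level = 0.005` places instruments firmly in
the strong-instrument (NOME) regime that the first-order Wald/IVW theory
assumes — genome-wide-significant instruments require
$|\gamma_k|/\sigma_{X_k} > 5.45$ even at the weakest, and the estimators'
unbiasedness claims are statements about this regime. Raising
`se_X_level` toward 0.015 (a 17k-sample exposure GWAS) reintroduces
regression-dilution bias of order $\beta\,\sigma_X^2/\mathrm{E}\gamma^2$;
the generator permits this, but the pinned validation scenarios do not use
it, so a green recovery test establishes correctness of the estimator
under its own assumptions, not robustness to weak instruments.

What the generator does *not* emulate: LD between instruments, sample
overlap, liability-scale subtleties of binary traits (outcome effects are
taken as exact log-ORs), allele-frequency-dependent SEs, and selection of
instruments *after* noise (winner's curse). Green simulation tests
therefore do not establish robustness to any of these.

## Pipeline and multiple testing

`run_study()` executes select → clump → proxy → harmonize → estimate →
sensitivity per exposure. The Bonferroni threshold divides $\alpha$ by the
number of exposures (not exposures × methods): IVW is the designated
primary test and the other estimators are sensitivity analyses, so the
family is the set of exposures. A failing exposure (e.g. empty harmonized
set) is recorded and rendered as an explicit failed row — partial studies
never abort, and the CLI signals partial failure with exit status 2.
Rendering serializes stored estimates only; nothing is recomputed at
report time, so identical inputs give byte-identical outputs.

The study configuration is a single JSON file (schema = the arguments of
`study_config()`). JSON was chosen over YAML/TOML because jsonlite is the
only structured-data parser guaranteed everywhere this package must run;
the schema, not the surface syntax, is the contract.

A reproducible outlier flag is attached to the leave-one-out table — a SNP
is flagged when its omission moves the IVW beta by more than one full-set
SE or its Q contribution exceeds the $\chi^2_1$ critical value at
$0.05/K$. This rule is this package's own (visual plot inspection is the
field's habit and is not reproducible); it only ever annotates, never
removes.

## Known limitations

* First-order weights ignore exposure-side uncertainty; with weak
  instruments the IVW estimate dilutes toward the null. Use the generator
  with larger `se_X_level` to quantify this for a given design.
* No MR-PRESSO, mode-based or multivariable estimators, and no funnel
  plots — the scope is the three-estimator workflow with its standard
  sensitivity analyses.
* Plots are not rendered; the tables that would underlie them are the
  canonical outputs.
* Sex-specific and non-linear MR are out of scope.
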