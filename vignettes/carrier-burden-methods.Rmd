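---
title: "Weighted carrier burden: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted carrier burden: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierburden)
```

## The problem

Panel sequencing of cancer cases unselected for family history yields, per
case, a handful of rare germline variants. Some are clearly pathogenic;
many are variants of uncertain significance (VUS). Counting only the
clearly pathogenic ones understates the fraction of cases whose result
would change the medical management of their relatives; counting every VUS
wildly overstates it. The approach implemented here weights each surviving
variant by a probability that it is pathogenic, and estimates the *weighted*
carrier proportion — per cohort, pooled across cohorts, and relative to a
reference population.

## Triage model

Three exclusion filters run first, each logged with a reason code so that
every input variant is accounted for either in a carrier record or in the
exclusion ledger:

* **Allele frequency** — excluded if the minor allele frequency is at or
  above 0.1 % (`maf_threshold = 0.001`, a frequency) in *any* reference
  population present in the annotation. The boundary is inclusive: a
  dominant cancer-predisposition allele at 0.1 % population frequency is
  already implausibly common. Population labels are free-form; the filter
  applies over whichever populations the annotation carries, and a variant
  absent from the reference passes.
* **Benign consensus** — excluded if at least two sources assert benign or
  likely benign *and* no source asserts pathogenic, likely pathogenic or
  uncertain. One benign source, or any conflict, is not enough.
* **Silent/splice** — synonymous and intronic variants survive only with a
  predicted splice effect. Splice predictions are consumed as annotations;
  the package does not recompute them.

Survivors are classified in a fixed precedence order; the weight constants
are package-level defaults:

| rule | category | weight |
|---|---|---|
| frameshift/nonsense, `exon_index < exon_count` | pathogenic | 1 |
| canonical splice, effect demonstrated | pathogenic | 1 |
| canonical splice, effect predicted only | HiP-VUS | 0.97 |
| missense, damaging in a functional assay | HiP-VUS | 0.99 |
| missense, calibrated prior > 0.8 | HiP-VUS | the prior |
| missense, ≥ 3 of 4 predictors severe | HiP-VUS | 0.81 |
| otherwise | excluded | 0 |

Notes on the choices that were genuinely open:

* **Final-exon rule, literally.** A truncating variant in the final exon is
  excluded, full stop. We deliberately do not add the 50-nt
  penultimate-exon refinement of nonsense-mediated-decay escape: the
  weighting scheme being reproduced defines truncation pathogenicity at
  exon granularity, and the fixture encodes the final-exon status directly
  (transcript choice for exon numbering is upstream of this package).
  A truncating variant without exon fields is an error, not a guess.
* **Missing predictor calls count as not severe.** Conservative, and no
  imputation rule is defensible from four heterogeneous predictors.
* **Calibrated prior only above 0.8.** A calibrated gene whose prior is
  ≤ 0.8 falls through to the consensus rule (and possibly exclusion); the
  prior is a gate as well as a weight.
* **Precedence** (pathogenic > functional assay > prior > consensus)
  matches which weight each variant in the packaged fixture actually
  received; e.g. a missense that is both assay-damaging and
  consensus-severe takes 0.99, not 0.81.
* **Overrides.** Real curated tables occasionally carry weights no rule
  reproduces (the packaged fixture has two: a CHEK2 missense at 0.95 and a
  CDKN2A missense at 1). These are carried as explicit `weight_override`
  values; the engine applies them and flags the record
  `rule_unattributed = TRUE` rather than silently absorbing them into a
  rule.

**Per-individual combination is noisy-OR:** an individual with variants of
weight $w_1,\dots,w_k$ is one carrier of weight $1-\prod_i(1-w_i)$. It is
order-invariant, monotone, never below the largest single weight, and
reproduces both same-individual combinations in the fixture
($0.97 \oplus 1 = 1$; $0.99 \oplus 0 = 0.99$). The interpretation is the
probability that at least one of the individual's variants is truly
pathogenic, under independence.

## Burden and intervals

The cohort burden is $100\,x/n$ with $x$ the sum of combined per-individual
weights and $n$ the number of cases *tested* (non-carriers count). Because
$x$ is fractional, the 95 % interval is a generalized Clopper–Pearson:
lower limit the $\alpha/2$ quantile of $\mathrm{Beta}(x,\,n-x+1)$, upper
the $1-\alpha/2$ quantile of $\mathrm{Beta}(x+1,\,n-x)$. At integer $x$
this is exactly the classic interval (tests cross-check against
`binom.test` and direct CDF inversion); at $x=0$ and $x=n$ the endpoints
are exactly 0 and 100. The interval method used for the originally
published per-cohort CIs is not recoverable (computed in a commercial
package), so those printed intervals are treated as non-binding; ours is
chosen for exactness and for reduction to the standard method.

## Meta-analysis

Per gene group, cohort counts $(x_i, n_i)$ are pooled as proportions:

* **Freeman–Tukey double arcsine**,
  $y=\arcsin\sqrt{x/(n+1)}+\arcsin\sqrt{(x+1)/(n+1)}$, $v=1/(n+\tfrac12)$ —
  defined at $x=0$ without continuity corrections, which is why
  zero-carrier cohorts enter as-is. Weighted, non-integer $x$ is accepted
  throughout because the carrier counts being pooled are weighted sums.
* **DerSimonian–Laird** between-study variance (the default of the
  proportion-meta-analysis tooling this mirrors), with
  $I^2=\max(0,100(Q-\mathrm{df})/Q)$.
* **Miller's harmonic-mean back-transform** to the proportion scale,
  documented as a closed formula so any implementation is auditable:
  with $t$ the pooled transformed value and $\tilde n$ the harmonic mean
  of the $n_i$,
  $p=\tfrac12\!\left(1-\mathrm{sgn}(\cos t)\sqrt{1-\left(\sin t+\frac{\sin t-1/\sin t}{\tilde n}\right)^2}\right)$,
  with out-of-domain $t$ clamped to the boundary proportions. CI limits are
  back-transformed from $t \pm z_{1-\alpha/2}\,\mathrm{se}$.
* **The test against zero.** The null hypothesis behind published pooled
  p-values of this kind is rarely stated. We test the pooled transformed
  value against the transform of a zero proportion at $\tilde n$ with a
  two-sided normal test — a zero proportion does not transform to zero
  under Freeman–Tukey, so testing against 0 on the transformed scale would
  be wrong. Published pooled p-values are therefore reproduced in spirit
  (order of magnitude), not digit-for-digit.

Tests verify the transform and the pooling against `metafor`
(`escalc(measure = "PFT")`, `rma(method = "DL")`,
`transf.ipft.hm`) at integer counts, a hand-computed three-study
DerSimonian–Laird instance, exact single-study and homogeneous-study
identities, a transform/back-transform round trip (error < 1e-3 for
$p\in[0.05,0.95]$, $n\ge 50$), and 95 % CI coverage over 200 simulated
five-cohort meta-analyses at the study's cohort sizes.

## Standardized incidence ratios

The expected count is $E=p_{\mathrm{ref}}\,n_{\mathrm{cases}}$, with
$p_{\mathrm{ref}}$ a *weighted* carrier proportion from a reference
population graded with the same triage scheme — the module takes this as a
precomputed summary rather than re-triaging tens of thousands of exomes.
$\mathrm{SIR}=O/E$ with the exact Garwood interval on $O$
($\mathrm{qgamma}(\alpha/2;O)$ to $\mathrm{qgamma}(1-\alpha/2;O+1)$)
divided by $E$, and the exact two-sided p-value
$2\min(P(X\le O),P(X\ge O))$ under $X\sim\mathrm{Poisson}(E)$, capped at 1.
Because $O$ is a weighted sum, fractional counts are handled by the gamma
continuous analogue of the Poisson tails rather than by rounding — at these
small counts rounding visibly moves the SIR. Whether the original p-values
were one- or two-sided is unstated; two-sided is the conservative reading.

## Synthetic data

`simulation_config()` defines the generator; one integer seed drives
deterministic substreams for the cohort and reference draws, so the two are
independent but jointly reproducible. Defaults mirror the study conditions:
three cohorts of 66, 147 and 61 cases; per-group carrier proportions of
2.7 % (high-risk HBOC), 1.3 % (Lynch MMR), 1.2 % (other high-risk) and
3.5 % (moderate HRR); a 60:40 pathogenic:HiP-VUS mix (the fixture has 16
clearly pathogenic of 27 variants); HiP-VUS missense predictor calls severe
with probability 0.9 per predictor (so an intended HiP-VUS can still fail
the 3-of-4 consensus, as real ones do); a 30 % contamination rate of
filter-fodder variants whose allele frequencies are drawn from the common
arm of a rare/common mixture (uniform 0.001–0.05) precisely to exercise the
inclusive frequency boundary; and a reference population of 49,451.

What the generator does *not* emulate: sequence-level realism, linkage or
relatedness, per-gene allele spectra, annotation noise (mis-called
consequences, disagreeing transcripts), or ascertainment bias. Passing
recovery tests on this generator therefore demonstrates that the pipeline's
statistics are consistent — configured carrier proportions and risk ratios
are recovered within Monte-Carlo error — not that the triage rules are
robust to annotation error in real data.

## Numerical choices and degenerate inputs

Single-study meta-analyses return the study itself with $\tau^2=0$; empty
study lists, $n=0$ cohorts, and $E\le0$ are errors, not NaNs. Back-transform
values outside the achievable range for $\tilde n$ clamp to 0 or 100 %. The
exclusion ledger plus carrier records always partition the input rows
(tested as an invariant). Cohort sizes smaller than the number of distinct
carriers are a consistency error. Problem sizes in the test suite are kept
deliberately modest — 200-replicate coverage runs, 2000-case SIR recovery,
5000-case proportion recovery — which is ample for 3-standard-error
Monte-Carlo bounds on quantities of this magnitude.

## Known limitations

* The weighting constants (0.81, 0.97, 0.99) are calibrated to one
  published evaluation scheme; they are arguments and package constants,
  not re-estimated from data.
* The noisy-OR independence assumption across variants within an individual
  is untestable at these counts and slightly anti-conservative for variants
  in linkage.
* Tier analyses assume the high/moderate gene partition is total for the
  genes analyzed; overlapping *group* membership is supported, conflicting
  *tier* membership is a configuration error.
* No age or sex standardization in the SIR: the reference summary is a
  single overall proportion per gene group.
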