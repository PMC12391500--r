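---
title: "Drug-target cis-MR with a CRP-weighted IL-6R instrument: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target cis-MR with a CRP-weighted IL-6R instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The causal question and the instrument

IL-6 signals through its receptor IL-6R: membrane-bound on hepatocytes and
immune cells (classical signalling), or soluble in plasma (trans
signalling). Variants near *IL6R* that increase the soluble receptor act as a
buffer for circulating IL-6 and reduce classical signalling; carriers show
lower CRP, the canonical downstream acute-phase readout. Such variants
therefore proxy pharmacological IL-6 inhibition, and two-sample Mendelian
randomisation with them estimates the effect of lifelong, genetically
conferred IL-6 downregulation on a binary outcome (here pleural infection,
ICD-10 J86, from a case-control GWAS on the log-odds scale).

The instrument is built by composition, in this order:

1. **cis window** — SNPs on the target gene's chromosome with position in the
   closed interval `[gene start − w, gene end + w]`, default `w = 300` kb.
   Both interpretations left open by the source design — anchoring at a
   point versus the gene boundaries — are defensible; we anchor at both
   boundaries because a cis window is conventionally gene-relative, and the
   gene coordinates plus build are config inputs, never hardcoded.
2. **relevance** — protein-GWAS `p < 5e-8`, strict inequality.
3. **concordance** — after allele alignment, keep SNPs whose protein-raising
   allele *lowers* CRP; re-orient so that allele is the effect allele. This
   encodes the biology above: a variant raising soluble IL-6R without
   lowering CRP is not proxying reduced signalling.
4. **independence** — greedy clumping: repeatedly take the most significant
   remaining SNP as an index and discard remaining SNPs with `r² ≥ 0.1`
   against it. Ties on p-value break by position then identifier, making the
   output deterministic.
5. **strength** — single-SNP `F = (β/se)² > 10`, strict, computed from the
   protein (selection) GWAS: the F screen belongs to the relevance
   assumption, which the selection GWAS defines; the CRP GWAS only supplies
   the weights afterwards.

Whether clumping should precede or follow the concordance filter is genuinely
open; we follow the order above (concordance before clumping) so that index
SNPs are chosen among variants that are valid proxies, and we do not reorder
silently — the composition is fixed in `build_instrument()` and its per-stage
counts are logged.

**Orientation contract.** After the build, `beta_exposure` is the negated CRP
effect: one exposure unit is one unit *decrease* in natural-log CRP, all
`beta_exposure > 0`, and downstream odds ratios below one mean protection
under IL-6 inhibition. Estimators never re-flip signs; a property test
asserts invariance of the pooled estimate under joint per-SNP negation. The
exposure scale is worth a flag: the source GWAS is on natural-log CRP, so
"per SD decrease" phrasing elsewhere is approximate; output headers state
"per unit decrease in natural-log CRP".

## Harmonisation policy

For each instrument SNP found in the outcome table we compare allele pairs:
identical pairs are kept (`aligned`), reversed pairs negate the outcome beta
and reflect its frequency (`swapped`), complementary pairs are re-compared
after strand flipping (`strand_flipped`). Palindromic SNPs (A/T, C/G) cannot
be resolved from alleles; we resolve them by frequency only when both sides'
frequencies are outside `[0.42, 0.58]` — the conventional band in MR
practice — and drop them otherwise, including when either frequency is
missing. Instrument SNPs missing from the outcome are dropped and logged; we
do not search LD proxies or impute. The audit trail (one status per input
SNP, counts summing to the input size) is a mandatory output because drop
counts are part of reproducibility.

## Estimators

With harmonised pairs `(bx_j, by_j)` and outcome SEs `se_j`:

* **Wald ratio** `θ_j = by_j / bx_j`, SE `se_j / |bx_j|` (first-order delta
  method). Ignoring exposure noise is deliberate: with every `F ≫ 10` the
  second-order term is negligible, and the first-order form makes IVW
  algebraically identical to origin-constrained WLS with weights
  `1/se_j²`. A `second_order = TRUE` switch adds the exposure-variance term
  for sensitivity.
* **Fixed-effects IVW** `β̂ = Σ w_j θ_j / Σ w_j`, `w_j = bx_j²/se_j²`,
  `se(β̂) = (Σ w_j)^{-1/2}`; 95% CI `β̂ ± 1.959964·se`; two-sided normal p.
  A single-SNP pool returns the Wald ratio bit-for-bit.
* **MR-Egger** — orient all `bx ≥ 0` (negating pairs jointly), then weighted
  regression of `by` on `bx` with intercept, weights `1/se_j²`; coefficient
  SEs from the weighted fit and t inference with `n − 2` df, appropriate at
  instrument sizes of a few dozen. The intercept estimates average
  directional pleiotropy.
* **Cochran's Q / radial exclusion** — `q_j = w_j (θ_j − β̂)²`; SNPs with
  `q_j` above the upper `α/n` χ²₁ quantile (Bonferroni, default α = 0.05)
  are removed and the pool re-estimated, iterating to convergence. The
  radial method's α is not fixed by convention; 0.05 with Bonferroni is the
  common default and is logged.
* **Leave-one-out** — the IVW pool excluding each SNP in turn; the report
  keeps the two extreme rows (min/max β) as the forest-plot summary.
* **Steiger** — exposure r² per SNP from `t²/(t² + n − 2)`, `t = bx/bx_se`;
  outcome r² from a linear-probability approximation to the log-OR with case
  fraction `v`: `r²_j = by_j²·v(1−v)·2p_j(1−p_j)`. Variants of the binary-r²
  transform differ across software and none is canonical; ours is the
  simplest frequency-aware choice and is stated in the run log. Direction is
  declared exposure→outcome when `Σr²_exposure > Σr²_outcome`, with a
  Fisher-z two-sample p-value.

## What the simulator emulates — and what it does not

`simulate_two_sample()` draws summary statistics directly, never
individual-level genotypes:

* per-SNP true exposure effects `d_j` (unit: decrease in log CRP per effect
  allele) as `1 + |N(0,1)|` scaled so `Σ 2p_j(1−p_j) d_j² = r²` — the floor
  encodes that the simulated panel emulates variants that *already passed*
  pQTL selection in their discovery GWAS, so near-zero effects are absent by
  design and the selection filters pass with realistic margins;
* protein effects `protein_scale × d_j` (SD units), outcome effects
  `true_effect × d_j + α_j` with pleiotropy `α_j ~ N(mean, sd)`;
* standard errors from the standard GWAS approximations — quantitative:
  `1/√(2np(1−p))` per unit trait SD; case-control log-OR:
  `√((1/n_case + 1/n_control)/(2p(1−p)))` — and estimates as truth plus
  independent normal noise times those SEs (a `correlated_noise` switch
  draws noise with the LD structure instead; by default LD enters only
  through clumping);
* Wald p-values clamped at the smallest positive double so extreme signals
  never produce an out-of-range exact zero.

Defaults are the study's geometry: 44 SNPs, protein GWAS n = 54,219, outcome
1601 cases / 830,709 controls, true log-OR −1.47 (OR 0.23). Two quantities
the study does not state were fixed once as field-realistic: the CRP
weighting GWAS size (575,000, the scale of current UKB/CHARGE
meta-analyses) and the instrument's CRP r² (0.01, typical for a clumped cis
region at this locus; it reproduces a pooled SE near 0.25, the order of the
published interval). MAF is uniform on [0.1, 0.5] (instrument SNPs are
common variants), LD is block AR(1) with ρ = 0.25 in blocks of four — below
the 0.1 r² clumping threshold but above the strict 0.01 one, so the two
clumping analyses genuinely differ (44 vs 22 SNPs).

Passing tests on this generator therefore show that the *procedures* are
correct under a clean two-sample model. They do not show robustness to
features of real data the generator omits: winner's curse in the selection
GWAS, the ~6.5% UKB sample overlap between exposure and outcome, imputation
noise, allele-frequency drift between cohorts, population stratification, or
LD reference mismatch. Reproducing the published ORs requires the external
UKB-PPP / UKB-CHARGE / FinnGen+UKB summary files.

## Numerical and degenerate-input choices

Strict inequalities throughout (`p < 5e-8`, `F > 10`, remove when
`r² ≥ threshold`). Records failing invariants (se ≤ 0, p ∉ (0,1], indels,
identical alleles, frequency outside [0,1]) are dropped at parse time and
counted; duplicate identifiers keep the smallest p-value. LD matrices must
be symmetric to 1e-8 on file (averaged) and 1e-12 in memory. `bx = 0` is a
fatal undefined-ratio error naming the SNP; an empty instrument is fatal
naming the stage; Cochran's p is missing at df = 0; Egger requires ≥ 3
variants; radial aborts if every SNP is flagged. Every random draw in the
simulator flows from one mandatory seed, and the generator restores the
caller's RNG state.

## Validation problem sizes

The test suite validates IVW against an origin-constrained WLS oracle on 100
random instances (1e-10), greedy clumping against a brute-force transcription
of the procedure over 150 random 10-SNP LD instances, parameter recovery and
CI coverage over 1000 study-geometry replicates (mean bias below 0.05,
coverage in [93%, 97%]), the Egger intercept's false-positive rate over 1000
no-pleiotropy replicates ([3.5%, 6.5%]), and Steiger direction over 500
causal replicates at n = 50,000 (≥ 99% correct). These sizes keep the full
suite near half a minute while holding Monte-Carlo error well inside each
acceptance band.

## Known limitations

Estimates are interpretable as effects of *lifelong* IL-6R-mediated CRP
lowering on infection *incidence*, not of acute inhibition during an
episode. The fixed-effects pool assumes one shared causal effect; no
weighted-median/mode or multivariable estimators are provided because the
analysis battery does not use them. No VCF parsing, no on-the-fly LD from
genotypes, no liftover, no proxy-SNP search: inputs are delimited
summary-statistics exports plus a precomputed LD correlation matrix.
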