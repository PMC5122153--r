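---
title: "Threshold liability models and CNV-region association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold liability models and CNV-region association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabscan)
```

## The problem

Embryonic mortality in cattle artificial-insemination (AI) programs is
observed only indirectly: a cow that returns to estrus and receives a
second AI some days after the first has lost the conceptus. The trait is
therefore a repeated binary record — per AI opportunity, did the cow
return within a given post-AI window (18–29, 30–60, 61–90, 91–140 or
141 days–parturition)? liabscan implements the quantitative-genetic
machinery to (i) estimate liability-scale variance components and
breeding values for such traits, (ii) scan deleted-type copy-number
variant regions (CNVRs) for association with those breeding values,
(iii) characterize a candidate deletion at sequence level, and (iv)
replicate and size its effect. Every stage runs on synthetic cohorts, so
the full pipeline is testable without external data.

## The threshold liability animal model

The observed outcome is a thresholded latent liability:

$$U_{ijkl} = \mu + PARITY_i + FARM_j + YM_k + b\,AGE_{ijkl} + a_l +
pe_l + e_{ijkl}, \qquad Y = \mathbf{1}(U > t),$$

with parity, farm and year–month of AI as fixed factors, a linear age
regression, breeding values $a \sim N(0, A\sigma^2_a)$ structured by the
pedigree numerator relationship matrix $A$, permanent environmental
effects $pe \sim N(0, I\sigma^2_{pe})$ per cow, and residual
$e \sim N(0,1)$.

**Identifiability.** A probit scale is only identified up to location and
scale, so the threshold is fixed at $t = 0$ and the residual variance at
$\sigma^2_e = 1$; $\mu$ is estimated. Derived parameters are
$\sigma^2_p = \sigma^2_a + \sigma^2_{pe} + 1$,
$h^2 = \sigma^2_a/\sigma^2_p$, $c^2 = \sigma^2_{pe}/\sigma^2_p$ and the
repeatability $R = (\sigma^2_a + \sigma^2_{pe})/\sigma^2_p$.

**Gibbs sampler.** `threshold_gibbs()` augments the data with latent
liabilities and cycles through full conditionals: truncated-normal
liability draws per record (inverse-CDF in the relevant tail, stable to
about 8 SD from the threshold); a block Gaussian update of the fixed
effects under a flat prior (Cholesky of $X'X$, computed once);
single-site (Gauss–Seidel) updates of breeding values against
$A^{-1}/\sigma^2_a$; independent scalar updates of the permanent
environmental effects; and scaled-inverse-chi-square draws for
$\sigma^2_a$ and $\sigma^2_{pe}$. The computational core is C++; all
random numbers come from R's stream, so a seed reproduces a chain
exactly.

**Priors and chain defaults.** The default variance prior is the flat
scaled inverse chi-square ($\nu = -2$, $S = 0$), the convention of the
national-evaluation threshold-model software this re-implements. Two
caveats are documented rather than hidden. First, with very small or
weakly informative cohorts (a few dozen cows, or outcomes constant
within every cow) the flat prior leaves the variances so poorly
identified that the chain can drift to large values; the `priors`
argument accepts mildly proper settings (e.g. $\nu = 4$, $S = 0.05$) for
such toys, and variances are floored at $10^{-8}$ to keep conditionals
proper. Second, the intercept and the mean breeding value form a
slowly-mixing ridge in small, fully related families; the
Gaussian-response check against Henderson's mixed-model equations uses a
long chain for that reason. The default chain is a desk-scale 11,000
cycles with 1,000 burn-in and thinning 10; the published national-scale
protocol (110,000 / 10,000 / 100) is available by argument. Stored
samples number exactly (chain − burn-in)/thinning. Posterior ratios
($h^2$, $c^2$, $R$) are computed per stored sample and then averaged.

## Relationship matrices

`a_matrix()` builds $A$ by the tabular method (unknown parents =
unrelated founders; no unknown-parent groups). `grm()` builds the
VanRaden method-1 genomic matrix $G = ZZ'/(2\sum_k p_k(1-p_k))$ with
sample allele frequencies, per-marker mean imputation, and monomorphic
markers dropped with a reported count. Centered (not standardized) $G$
was chosen because it is the common default of mixed-model association
software; the scan's Wald test is insensitive to this choice on the
synthetic cohorts we generate.

## CNV regions and the association scan

A CNV region is the union of overlapping same-type per-animal calls on a
chromosome (`merge_cnvrs()`, built on IRanges). Two filters follow the
field's practice for deleted-type scans: at least two distinct carriers,
and carrier frequency strictly above 1%. Coordinates are 1-based
inclusive; only truly overlapping calls merge (abutting calls do not).
Region *lengths* are reported as end − start, matching how CNVR spans
are usually quoted, while homology arms below are inclusive counts —
`deletion_length()` exposes both conventions explicitly instead of
reconciling them.

`lmm_assoc()` is the per-region test: $y = W\alpha + x\beta + u +
\varepsilon$ with $u \sim N(0, G\sigma^2_g)$, the variance ratio
profiled by REML through a one-dimensional optimisation on the
eigendecomposed model, and a Wald $\chi^2_1$ test on $\beta$ — the
standard mixed-model scan. Carrier coding is 0/1 by default (a deletion
with no live homozygotes has no dosage-2 class); 0/1/2 dosages are
accepted wherever a numeric vector is. With the variance ratio at 0 or
an identity kinship, the test collapses exactly to ordinary least
squares, which the tests exploit as an oracle. `lambda_gc()` computes the
genomic inflation factor as the median Wald statistic over the null
$\chi^2_1$ median, and `bonferroni_threshold()` the family-wise
threshold ($\alpha/m$; for 116 regions at $\alpha = 0.05$ this is
$4.31\times10^{-4}$, i.e. $-\log_{10} P = 3.365$).

## Breakpoints, transcripts, copy number

**NAHR arms.** A deletion created by non-allelic homologous
recombination leaves one copy of the homology arm at the junction, so
the breakpoint is ambiguous within the arm. `find_homology_arms()`
anchors the junction read's prefix and suffix on the reference, extends
both exactly, and reports the overlap as the arm; the ambiguity interval
has exactly arm length, and single-coordinate breakpoints use the
arm-adjacent bounds (end of left copy, end of right copy) with the
difference length convention. Matching is exact by construction: an
edit-tolerant mode was considered and rejected — with a mismatch inside
one arm copy the exact rule returns the longest exactly shared segment,
which is the defensible statement about the data, and no in-scope
consumer needs approximate arms.

**Transcript consequence.** `predict_transcript_consequence()` removes
exons fully inside the deletion, splices the remainder in genomic order,
optionally inserts retained introns at their anatomical position, and
evaluates the reading frame on the fused CDS (in-frame / frameshift /
null). Protein length is CDS/3 − 1 (the stop is not a residue) and mass
is approximated at 0.111 kDa per residue — a prediction, not a
measurement. Only plus-strand models are supported; flip coordinates
for minus-strand genes. Without sequence, a frameshift's premature stop
position is unknowable, so the length is `NA` rather than a guess.

**qPCR.** `ddct_copy_number()` implements
$CN = 2 \times 2^{-\Delta\Delta C_T}$ against a two-copy calibrator,
with the SEM delta-method-propagated from replicate scatter
($SEM_{CN} = CN\,\ln 2\,SEM_{\Delta\Delta C_T}$). The estimate is
invariant to shifting a sample's target and reference $C_T$ together.

## Replication statistics

`lsmeans_contrast()` fits a Gaussian identity-link linear model
(response = breeding value; fixed effects genotype + covariate factors)
and reports least-squares means — predictions averaged over a balanced
covariate grid — with a two-sided t contrast. "Generalized linear
model" in the source protocol is interpreted as this Gaussian model: the
response is continuous. `variance_explained()` uses the additive
$2p(1-p)a^2$ form over the total genetic variance; with no homozygotes
observed, the carrier-coded effect stands in for the allele-substitution
effect and the output says so. `allele_freq()` keeps count arithmetic
integer-exact. `mendelian_chisq()` is the Pearson goodness-of-fit test
(the published F2 p-value of 0.38 for 37:76:29 against 1:2:1 is not
reproducible from the Pearson statistic, which gives 0.448; the original
test construction is unstated, so no code targets the printed value).
`group_comparisons()` offers Tukey–Kramer (studentized range with
unequal-n correction, pooled variance) and Welch t tests.

## The synthetic world

`sim_config()` states the world once; generators only consume it:

- Five post-AI windows with at-risk incidences 23.00, 21.97, 16.91,
  8.47, 3.30% — the national return rates the pipeline targets. The
  focal binary trait defaults to the 30–60 D window.
- Liability variance components default to that window's national
  estimates ($\sigma^2_a = 0.01$, $\sigma^2_{pe} = 0.03$,
  $\sigma^2_e = 1$); recovery tests override to $h^2 = 0.30$.
- A deleted-type CNV at risk-allele frequency 0.02, Hardy–Weinberg
  carriers with homozygotes redrawn (none are observed alive), adding
  0.3 liability units to carriers. No published liability-scale carrier
  effect exists to copy; 0.3 (≈ a quarter of a phenotypic SD) was chosen
  once as a realistic single-locus fertility effect and is not tuned.
- Fixed-effect level effects are drawn with SD 0.1 per factor and age
  enters at 0.002 liability/month — small against the residual, as
  management and age effects on return rates are.
- The intercept is calibrated numerically (`uniroot` on the realized
  predictor distribution) so the simulated incidence matches the target
  exactly in expectation.
- Array signals: one-copy log-R-ratio shift −0.45 (SD 0.2), hemizygous
  B-allele frequencies with no heterozygous band inside the deletion.
- Junction fixtures: two identical same-orientation arms around the
  deletion interior; the deleted allele carries a single arm copy.
  63-bp arms and a 33,934-bp deletion reproduce the motivating locus.
- The period generator draws returns sequentially per window among cows
  still at risk. A cow returning in an earlier window leaves the risk
  set of all later windows — the published per-window record counts
  decrease monotonically, which is what sequential exclusion produces;
  a return before the first window (day < 18) is excluded from every
  window. This risk-set rule is an inference, stated here because the
  source protocol does not spell it out.

What the generator does **not** emulate: genotyping error, pedigree
errors, selection (parents are sampled at random), non-random mating,
environment-by-genetics interaction, linkage between the SNP panel and
the CNV (SNP genotypes are drawn independently, so the observed absence
of LD with the CNVR is built in rather than discovered), or raw array
intensities beyond the marker-level LRR/BAF summaries. A green test
therefore establishes internal statistical correctness of the
estimators on their assumed model, not robustness to those
real-data pathologies.

## Numerical choices

- Truncated-normal draws by inverse CDF in the relevant tail; the
  uniform deviate is floored at the smallest positive double so draws
  never land exactly on ±Inf.
- Variance draws floored at $10^{-8}$; REML residual variance floored at
  $10^{-300}$ to survive perfect fits; p-values floored at the smallest
  positive double (the invariant is $p \in (0,1]$).
- REML's variance ratio is optimised on $\log\lambda \in [-12, 12]$ and
  compared against the $\lambda = 0$ boundary, which may beat the
  interior optimum.
- `a_matrix` processes animals in topological order (Kahn), so cycles
  are detected and named before any arithmetic.
- Chains store exactly (chain − burn-in)/thinning samples; Monte-Carlo
  SEs reported by `summarize_posterior()` are naive (no autocorrelation
  correction) and say so.

## Limitations

Single-trait, single-chain, dense-matrix throughout: the package is
sized for cohorts of a few thousand animals, not national evaluations
(no sparse $A^{-1}$, no REML for the threshold model, no multi-trait or
sire models). The association scan tests one predictor at a time with a
REML ratio re-profiled per region, as the standard tools do. Minus-strand
gene models and edit-tolerant arm matching are intentionally out of
scope, as are PennCNV's HMM internals — CNV calls are inputs here.
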