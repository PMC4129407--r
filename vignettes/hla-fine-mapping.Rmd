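---
title: "Fine-mapping HLA association signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping HLA association signals: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical machinery of `hlafinemap`: what each
model assumes, which tunable parameters matter, what the synthetic-data
generator does and does not emulate, and where genuinely open design
questions were settled by a package-level decision.

## The data model

Classical HLA genes are unusual among association-study targets: each 4-digit
classical allele (`B*27:05`) names a unique protein sequence, so a panel of
imputed classical-allele dosages can be re-expressed, through an
allele-to-protein dictionary, as dosages of individual amino-acid residues at
aligned positions of the mature protein. `hlafinemap` works with four marker
kinds: biallelic SNPs, 2- and 4-digit classical alleles, biallelic residue
markers (carrying residue r at position p of gene g), and multiallelic
amino-acid positions, represented as groups of residue markers.

Dosages are additive expected allele counts in [0, 2]; they may be fractional
(imputed) or hard calls. Two conservation laws are enforced and tested:
per-individual classical dosages of one gene sum to 2 when the allele set is
complete, and so do residue dosages at any one position. Expansion from
alleles to residues is linear, so it commutes with dosage averaging — the
property that makes fractional imputed dosages safe to expand.

Position numbering follows the mature-protein convention (position 1 is the
first residue of the mature protein; positions 5' of it are negative, with no
position 0). Alignment gaps are one extra residue level, written `"-"`: this
keeps indel polymorphism testable instead of silently dropping it. How
intra-position insertions should be numbered is not standardised; the `"-"`
convention is this package's choice.

## The association model

All association tests are likelihood-ratio tests in one pooled logistic
regression:

log odds = b0 + sum_j b1j x_j + sum_k ( sum_l b2kl y_kl + b3k z_k )

where x_j are the m − 1 non-reference allele dosages of the tested variant
(the most frequent allele is always the reference), z_k are indicator
variables giving each data-set collection its own intercept, and y_kl are
collection-specific principal-component covariates: PC l enters with its own
slope inside each collection k (K × L columns), matching the double-indexed
covariate structure. A pooled-PC mode (`pcs = "pooled"`) is available as a
switch. Collections are fixed effects; no meta-analysis or mixed model is
used.

The omnibus p-value of a variant compares the full model against the null
model that keeps every covariate and conditioning column but omits the m − 1
variant columns; the deviance 2(LL1 − LL0) is referred to chi-square with
m − 1 degrees of freedom. For biallelic variants this is the ordinary 1-df
LRT; for a multiallelic amino-acid position it tests all residues jointly.

Numerical choices, all of which are exercised by tests:

* Fitting is IRLS (`glm.fit`) with relative deviance convergence 1e-8 and at
  most 100 iterations. Neither criterion is standardised in the field; these
  are package choices.
* Collinear columns are pruned by QR rank (tolerance 1e-7, i.e. columns whose
  R² against the retained span exceeds ~1 − 1e-8 are dropped) with a warning;
  variant columns that add no rank beyond the null design reduce the test's
  degrees of freedom, and a variant fully contained in the conditioning span
  is reported with df = 0 and p = 1 rather than an error.
* Separation (fitted probabilities within 1e-8 of 0/1, or the IRLS warning)
  flags the fit unreliable; Wald SEs from such fits should not be used, but
  likelihood-ratio quantities remain meaningful. Exact logistic regression is
  out of scope.
* A constant dosage column is a degenerate variant and raises a classed
  error; batch scans catch it and emit a flagged row instead of aborting.
* Markers enter only if their pooled minor-allele frequency strictly exceeds
  0.1% (the post-imputation QC convention); multiallelic groups are rebuilt
  after filtering.
* 95% intervals use the fixed multiplier 1.959964.

## Conditional analysis and stepwise selection

Conditioning follows the field's two conventions, selected by item type:
conditioning on an amino-acid position adds its m − 1 non-reference residue
dosages; conditioning on a gene adds all its 2- and 4-digit classical allele
columns after excluding the most frequent allele as reference and greedily
pruning columns with pairwise R² > 0.97 (descending frequency order, so the
more frequent of a correlated pair survives). The reference is always chosen
by pooled (cases + controls) frequency with lexicographic tie-break; the
stratum for "most frequent" is not standardised, and pooled frequency is the
package's choice.

Forward stepwise selection scans all in-scope variants conditioned on
everything selected so far, takes the smallest omnibus p-value if it beats
the genome-wide threshold 5e-8 (configurable), and stops otherwise. Ties are
broken by larger deviance, then lexicographic ID. One consequence of
lexicographic tie-breaking worth knowing: when a 2-digit group contains a
single 4-digit allele the two columns are identical, their tests tie exactly,
and the 2-digit ID (sorting earlier) is selected — the same signal under
another name. The `scope` argument restricts candidates to chosen genes; a
whole-region scope reproduces per-gene analysis in the order signals
naturally emerge, because the strongest remaining gene always wins the next
step.

The multivariate full model refits all selected variants jointly in a single
regression and lays the result out per locus: each amino-acid position shows
its m − 1 non-reference residues plus a marked reference row, and each
classical-allele locus shows the named alleles plus an "other alleles"
reference row whose frequency is the complement of the named rows.

## Liability-scale variance explained

Case-control ORs say nothing directly about how much phenotypic variance a
variant explains; for that the package uses a liability threshold model.
Disease occurs when a latent standard-normal liability exceeds
T = qnorm(1 − K) at prevalence K. For a variant with population frequency p
and per-allele odds ratio OR, genotype relative risks are taken as
multiplicative (1, OR, OR²) under Hardy–Weinberg proportions, penetrances are
scaled so the population prevalence equals K, each genotype class is assigned
the mean liability that reproduces its penetrance, and the variance of those
genotype means (the residual within-genotype variance being 1) is the
variant's liability-scale contribution.

Two sub-choices here were genuinely open, and both are exposed as arguments:

* OR versus relative risk: at K = 2% the OR approximates the genotype
  relative risk closely, and the default uses it directly
  (`rr_correction = FALSE`); `rr_correction = TRUE` applies
  RR = OR / (1 − K + K·OR) first. At the package's default prevalence the
  difference is a few tenths of a percentage point.
* Scale: the default reports the between-genotype variance V on the
  unit-residual liability scale; `scale = "proportion"` reports V / (V + 1).
  For the effect sizes involved the two differ by about 4% relative.

The combined estimate for a multivariate model sums per-variant
contributions computed from multivariate ORs and control-sample frequencies
(control frequency stands in for population frequency, a mild approximation
at 2% prevalence), assuming independence across loci — the joint formula is
not standardised, so a Monte-Carlo joint estimator
(`method = "simulation"`) is provided as a sensitivity check; on the shipped
model table the two agree to within Monte-Carlo error.

## Subphenotype heterogeneity

To ask whether a gene's classical alleles act differently on two clinical
subtypes (psoriatic arthritis, PsA, versus purely cutaneous psoriasis, PsC),
the package fits the gene's m − 1 non-reference 4-digit alleles jointly in
each of the two case-control contrasts (PsA vs controls, PsC vs controls;
common allele set and common reference, fixed from pooled frequencies) and
forms

sum_i (beta_PsA,i − beta_PsC,i)² / (v_PsA,i + v_PsC,i)

which is chi-square with m − 1 df under concordant effects. Because both
contrasts share the control sample the two estimates are positively
correlated and the test is conservative; no covariance correction is
applied, and the conservatism is verified by a null simulation in the test
suite. Alleles inestimable in either contrast are dropped from both, with the
df reduced and the result flagged.

Allele predictors default to additive dosage for consistency with the main
analysis; a `carriage` mode (carrier indicator, dosage ≥ 1) is provided
because gene-level allele effects are sometimes modelled on carriers. On
hard calls without homozygous carriers the codings coincide (a tested
identity).

With eight class I/II genes examined, the per-gene Bonferroni threshold is
0.05/8 = 0.00625. The package reports the exact quotient; a figure of
"0.0073" sometimes quoted for this quotient is a misrounding, and the print
method says so.

## The synthetic cohort generator

No usable genotype deposit accompanies published MHC fine-mapping summary
tables, so the generator exists to create cohorts with the same statistical
structure as a multi-collection European case-control study, making every
pipeline stage testable end to end.

What it emulates, and the defaults it fixes as study conditions:

* Four genes (HLA-C, HLA-B, HLA-A, HLA-DQA1) with realistic classical allele
  sets whose frequencies are chosen so that residue frequencies at the
  fine-mapped positions (HLA-B 9/45/67, HLA-A 95, HLA-DQalpha1 53) match the
  published control frequencies. The dictionary is synthetic: residue
  assignments reproduce the published marginal frequencies, not IMGT
  alignments, and HLA-C intentionally has no dictionary entries because its
  published risk is allele-level (a residue private to one allele would just
  duplicate that allele's column).
* Haplotypes are drawn gene by gene along a coupling chain; the default
  couples HLA-B to HLA-C by mixing the marginal HLA-B frequencies with a
  preferred partner per HLA-C allele (e.g. C*06:02 with B*57:01, the classic
  psoriasis haplotype), creating the inter-gene LD that makes conditioning
  necessary. Real inter-gene LD magnitudes are not published; the default
  coupling weight (0.2) is illustrative and labelled as such.
* Disease effects are the published multivariate model's log-ORs
  (`psv_published_model()`), placed on classical alleles for HLA-C and on
  residues elsewhere; residue effects act through the dictionary, so
  allele-level and residue-level signals are mechanically confounded exactly
  as in real data. The disease intercept is calibrated by root finding to a
  2% population prevalence.
* Among cases, subtype (PsA vs PsC) follows a second logistic model whose
  only default effect is Glu at HLA-B position 45 with OR 1.46, the
  subtype-differentiating signal; a third of cases are left with unknown
  subtype. Default sample sizes are 9,000 cases and 13,000 controls across
  K = 3 collections with log-scale allele-frequency perturbations
  (SD 0.15) and L = 2 collection-mean-shifted Gaussian PCs.
* Ascertainment is retrospective: a large population pool is simulated at
  the target prevalence and the requested numbers of cases and controls are
  sampled from it, which keeps logistic ORs directly interpretable.

What it does not emulate: genotype imputation error and uncertainty
(dosages are hard calls), SNP-level LD with flanking variation, phasing
error, real IMGT protein alignments, relatedness, or PCs computed from
genotypes (simulated PCs exist to exercise the covariate machinery, and the
collection frequency shifts are what create genuine confounding pressure).
Passing tests therefore demonstrate the statistical machinery — calibration,
conditioning logic, parameter recovery, heterogeneity localisation — not
robustness to imputation artefacts.

## Problem sizes used by the test suite

The test suite chooses sizes that keep each property decisively testable on a
single CPU: null calibration of the omnibus test uses 2,000 replicates of
n = 2,000 cohorts (rejection within 3 binomial SDs of 5%); oracle agreement
compares deviances against direct BFGS maximisation of both likelihoods at
n = 500 to 1e-6; parameter recovery runs 60 replicates at 2,500 cases /
3,750 controls (mean log-OR bias and pooled CI coverage) and 20 stepwise
replicates for selection order; heterogeneity localisation runs once at the
generator's default 9,000 / 13,000 scale, where the planted OR-1.46 subtype
effect yields decisive power. Published real-data p-values (e.g. 10^-201)
require consortium-scale genotypes and are not reproduction targets.

## Known limitations

* Wald CIs and p-values in the multivariate table are unreliable under
  separation (flagged); no Firth or exact correction is implemented.
* The joint variance-explained estimate assumes independent loci; with
  strong inter-gene LD it can overstate the total (the simulation estimator
  quantifies this).
* The heterogeneity test's conservatism under shared controls means its
  rejection rate is below nominal; power statements should account for that.
* Stepwise selection inherits the usual caveats of forward selection in LD:
  the selected label is a tag for a signal region, not proof of causality.
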