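# hlafinemap

Amino-acid-resolution fine-mapping of MHC association signals in case-control
cohorts.

The MHC is the strongest risk region for many immune-mediated diseases, but
its dense linkage disequilibrium makes it hard to tell which of the classical
HLA alleles and which of the amino-acid positions they encode carry the
independent signals. Because every 4-digit classical HLA allele corresponds
to a unique protein sequence, allele dosages can be re-expressed as residue
dosages at aligned positions of the mature protein, and association can be
dissected at both resolutions. `hlafinemap` implements that workflow for
statistical geneticists working with imputed HLA panels (SNP2HLA-style dosage
data): it is built around psoriasis and its clinical subtypes (psoriatic
arthritis, PsA, versus cutaneous psoriasis, PsC), but the machinery is
generic for any HLA or HLA-like gene, including MICA.

## What it computes

Everything is a view on one additive-dosage logistic model. For a variant
with m alleles, the m − 1 non-reference allele dosages x_j enter

log odds = β0 + Σ_j β1j·x_j + Σ_k ( Σ_l β2kl·y_kl + β3k·z_k )

with an indicator z_k per data-set collection and collection-specific
principal-component covariates y_kl. On top of this fit the package provides:

* **Omnibus tests** (`omnibus_test`, `scan_region`): the deviance
  2(LL_full − LL_null) against chi-square with m − 1 df, for biallelic
  markers and multiallelic amino-acid positions alike.
* **Conditional fine-mapping** (`conditioning_spec`,
  `build_conditioning_covariates`, `stepwise_forward`): forward stepwise
  selection at the genome-wide threshold 5×10⁻⁸, conditioning on amino-acid
  positions (m − 1 residue dosages) or whole genes (all 2-/4-digit alleles,
  reference excluded, R² > 0.97 pruned).
* **The multivariate full model** (`fit_full_multivariate`): all selected
  risk variants refit jointly, laid out per locus with reference rows —
  the classic summary table of an MHC fine-mapping study.
* **Liability-scale variance explained**
  (`variance_explained_liability`, `variance_explained_joint`): a liability
  threshold model converting allele frequency, OR and disease prevalence
  into the proportion of latent liability variance a variant explains.
* **Subphenotype heterogeneity** (`gene_heterogeneity_test`): the
  discordance statistic Σ(β_PsA,i − β_PsC,i)²/(v_PsA,i + v_PsC,i), chi-square
  with m − 1 df under concordant effects, with the exact Bonferroni
  threshold 0.05/8 for the eight class I/II genes.
* **A cohort simulator** (`psv_sim_config`, `simulate_cohort`): haplotypes
  with inter-gene LD, collection frequency shifts, planted allele/residue
  effects and a subtype-differentiating residue, so the whole pipeline is
  testable without consortium genotypes.
* **I/O** (`read_dosages`, `write_results`, `concordance`): SNP2HLA-style
  dosage TSV/VCF (DS field), allele dictionaries, result tables with run
  manifests, and best-guess imputation concordance.

## Worked example

Simulate a cohort with the package's default generative model (published
psoriasis effect sizes, 3 collections, HLA-C→HLA-B LD), then fine-map it:

```r
library(hlafinemap)

cfg <- psv_sim_config(n_case = 2500, n_control = 3750)
sim <- simulate_cohort(cfg, seed = 1)
cls <- sim$classical
resid <- expand_to_residue_dosages(
  cls[, which(variant_info(cls)$gene %in% unique(cfg$dictionary$gene))],
  cfg$dictionary)
panel <- cbind(cls, collapse_to_two_digit(cls), resid)

stepwise_forward(panel, sim$cohort, scope = c("HLA-C", "HLA-B"))
#> Forward stepwise selection (PsV_vs_control, threshold 5e-08): 2 step(s)
#>  step       id  gene                    kind             p  deviance
#>     1 HLA_C_06 HLA-C classical_allele_2digit 9.969008e-111 499.90495
#>     2  AA_B_67 HLA-B       aa_position_group  6.749778e-14  67.75711
#> Stopped: no_variant_below_threshold
```

The strongest signal is the planted HLA-C*06:02 allele (selected under its
2-digit label, which holds an identical dosage column), and conditional on
it the HLA-B amino-acid position 67 group carries the next independent
signal. Refitting selected variants jointly gives the familiar per-locus
table:

```r
mv <- fit_full_multivariate(
  c("marker:C*06:02", "marker:C*12:03", "aa:HLA-B:67", "aa:HLA-B:9"),
  cls, resid, sim$cohort)
mv
#> Multivariate full model (PsV_vs_control): 8 variants, n = 6250
#>              locus             variant freq_case freq_control      OR (95% CI)         p
#>              HLA-C             C*06:02     0.245        0.094 3.14 (2.81-3.50)   8.2e-92
#>              HLA-C             C*12:03     0.064        0.058 1.38 (1.18-1.61)   4.2e-05
#>              HLA-C other HLA-C alleles     0.691        0.848        reference reference
#>  HLA-B position 67                   C     0.202        0.174 1.49 (1.30-1.72)   1.2e-08
#>  ...

variance_explained(mv, prevalence = 0.02)   # liability scale
#> 0.058  — these variants explain ~5.8% of liability variance
```

The estimated ORs recover the planted values (3.14 vs 3.26 for C*06:02,
1.49 vs 1.56 for Cys67, ...). The subtype comparison localises the planted
PsA-vs-PsC signal to HLA-B:

```r
gene_heterogeneity_test("HLA-B", sim$cohort, cls)
#> Effect-size heterogeneity, HLA-B (PsA vs control / PsC vs control)
#>   9 allele(s), reference B*07:02, mode dosage, conditioning: none
#>   statistic = 24.990 on 9 df, p_heterogeneity = 0.00298
#>   Bonferroni threshold 0.05/8 = 0.00625 (exact quotient): significant
```

Conditioning on `aa:HLA-B:45` (the planted subtype residue) abolishes the
heterogeneity, while conditioning on the HLA-C risk allele does not — the
pattern that pins the subtype difference on HLA-B position 45.

Single published quantities can be checked directly:

```r
variance_explained_liability(freq = 0.093, or = 3.26, prevalence = 0.02)
#> 0.046  — a frequency-9.3% allele with OR 3.26 explains ~4.6% of
#>          liability variance at 2% prevalence
```

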