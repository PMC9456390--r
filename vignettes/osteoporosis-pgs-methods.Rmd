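---
title: "Polygenic scoring for osteoporosis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scoring for osteoporosis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Primary osteoporosis in postmenopausal women expresses itself through two
partially independent endophenotypes: fragility fractures and low bone
mineral density (BMD, measured by DXA and expressed as a T-score in SD units
against a young-adult reference). A polygenic score (PGS) built from a
curated panel of BMD- and fracture-associated SNPs can stratify women by
genetic risk before either endophenotype manifests. `osteopgs` implements
the full analysis a targeted-panel PGS study needs: locus quality control,
a population-structure check, per-individual scoring, normalization, and
case-control evaluation of three prognostic models — fracture vs no
fracture, low BMD (osteopenia or osteoporosis, T ≤ −1.0) vs normal BMD, and
the comorbid model (fracture *and* low BMD vs neither).

## The score

For individual $j$ genotyped at a panel of $N$ variants with per-allele
effect sizes expressed as odds ratios $S_i$:

$$
\mathrm{PRS}_j \;=\; \frac{\sum_{i} s_i \, G_{ij}}{P \, M_j},
$$

where $G_{ij} \in \{0,1,2\}$ counts risk (effect) alleles, $P = 2$ is the
ploidy, $M_j$ is the number of variants with an observed (non-missing)
genotype for individual $j$, and the sum runs over those variants. Scores
are then z-normalized across the cohort.

Two decisions here were genuinely open:

* **Denominator.** We interpret $M_j$ as the count of *non-missing*
  variants — the average-score convention of standard scoring tools. The
  alternative reading ("number of missing genotypes") yields a zero
  denominator for completely genotyped individuals and is unusable. With
  the average convention, individuals with different genotyping success
  remain comparable, and $M_j = N$ when nothing is missing.
* **Weight transform.** The default is $s_i = \ln S_i$: odds ratios
  multiply, so their logarithms add on the liability scale, and a
  protective allele ($S_i < 1$) correctly subtracts. `transform =
  "identity"` ($s_i = S_i$) is retained as a first-class option because
  panel weights are sometimes summed as raw odds ratios in practice; with
  no missingness the two transforms are monotonically related *per locus*
  but not jointly, so AUCs can differ slightly and the transform used is
  recorded in the score set.

Normalization uses the whole cohort's mean and sample SD by default;
control-only moments are available (`normalize = "controls"`) for settings
where the case fraction is by design far from the population's.

## Quality control

Filters run in a fixed order, so each removed locus carries exactly one
primary reason and reports are reproducible:

1. **Sample call rate** ≥ 0.97, then **variant call rate** ≥ 0.97
   (computed on retained samples). These match the conventional 97%
   genotyping-success inclusion rule for targeted panels.
2. **MAF window** 0.01–0.49. The upper bound excludes loci whose minor
   allele is ambiguous at sampling precision.
3. **Hardy-Weinberg exact test** at α = 0.05. We use the conditional exact
   test (Levene–Haldane distribution over heterozygote counts, standard
   non-mid p), not the χ² approximation: panel MAFs run down to 1%, where
   the χ² test misbehaves. By default the test runs on fracture *controls*
   when phenotypes are available, because case ascertainment itself
   distorts genotype frequencies at truly associated loci.
4. **LD pruning** at dosage-$r^2$ > 0.8, greedy per chromosome in map
   order. Genotype-correlation $r^2$ (composite LD) stands in for haplotype
   $r^2$ since phase is unavailable; for pruning redundant panel loci the
   difference is immaterial. Within a conflicting pair, the variant with
   the higher call rate survives (ties: higher MAF, then map order).

Note that an exact test with nominal size 5% applied to ~140 clean loci
*will* remove a handful of true-null loci per run; that is the operating
characteristic of the published threshold, not a defect, and the QC report
records every removal with its reason so the account can be audited.
Cochran's Q and $I^2$ (inverse-variance, log-OR scale, significance at
p < 0.1) are provided for curating externally sourced weights but are not
part of the default filter chain, since heterogeneity screening acts on
summary statistics, not on cohort genotypes.

QC is idempotent: running it on its own output removes nothing.

## Population structure

Genotypes are standardized per variant to $(d - 2\hat p)/\sqrt{2\hat p(1-\hat
p)}$ with missing entries mean-imputed to exactly 0, and the top components
are taken from the SVD. Component signs are fixed (largest-magnitude loading
positive) so results are machine-independent. Because a visual "no
clustering" judgement is not assertable, `stratification_test()` turns it
into a number: the mean distance between group centroids in the PC1–PC2
plane, referred to its label-permutation null (default 999 permutations,
seeded). A large p-value supports analysing the cohort as a single
population; differentiation of the magnitude produced by two
subpopulations at $F_{st} = 0.05$ across 140 SNPs at $n = 700$ is detected
essentially always.

## Evaluation battery

Per contrast, the report contains:

* **AUC** as the Mann-Whitney concordance (ties half-weighted), with a
  DeLong variance CI. The stepwise ROC curve's trapezoidal area equals the
  Mann-Whitney statistic to machine precision — this identity is enforced
  in the tests. A seeded percentile bootstrap CI is available behind
  `ci_method = "bootstrap"`.
* **Operating point** by Youden's J (ties toward sensitivity). The
  selection rule for published sensitivity/specificity pairs is often
  unstated; Youden is the conventional default.
* **Odds ratios**, two constructions, because both are common and reported
  ORs are frequently ambiguous between them: the primary per-SD logistic
  OR (ML fit; Firth's penalized likelihood as a flagged fallback under
  separation), and a secondary top-vs-bottom-decile 2×2 OR
  (Haldane–Anscombe correction, Woolf CI).
* **Decile table** (remainders to lower deciles, ties stable by sample id)
  with a Cochran–Armitage trend test across deciles scored 1..10.
* **Group summaries** (medians, means, raw score vectors) for density
  plots.

The three contrasts are reported unadjusted, with a Bonferroni column in
the cross-contrast ranking for transparency; the ranking flags overlapping
AUC confidence intervals, in which case no superiority claim is made.

## The synthetic cohort

No individual-level genotypes ship with the package, so a seeded generator
produces cohorts with the statistical structure the analysis assumes.
Defaults emulate the targeted study design end to end: 701 postmenopausal
women; 150 biallelic SNPs with effect-allele frequencies uniform on
[0.01, 0.49]; all loci causal with ORs log-uniform on [1.05, 1.5]
(conventional effect sizes for BMD-associated common variants);
liability-scale heritability $h^2 = 0.35$, which yields study-scale
discrimination (fracture AUC ≈ 0.75); fracture prevalence 294/701; BMD
measured in a random 496/701 subset with low-BMD prevalence 324/496;
liability correlation 0.6 between the fracture and BMD traits, which makes
the comorbid contrast the best-discriminating model, as observed in
practice; MCAR missingness 0.5% (the level at which a 97% call-rate filter
retains essentially everyone); and 5 engineered Hardy-Weinberg violators
(inbreeding-style heterozygote depletion, F = 0.5) plus 5 LD
near-duplicates (1% of entries re-drawn), emulating a 150-locus panel that
loses about 10 loci at QC. The split between HWE and LD exclusions is a
package choice; both are recorded per locus in the QC report.

Phenotypes follow a liability-threshold model: liability = genetic value +
Gaussian environment scaled to the target $h^2$; cases lie above the
empirical quantile implied by the trait's prevalence; BMD liabilities map
affinely to T-scores anchored so the low-BMD prevalence sits at T = −1.0,
then classify as normal (T > −1.0), osteopenia (−2.5 ≤ T ≤ −1.0, both
boundaries included in the band), or osteoporosis (T < −2.5). Comorbid
cases are, by construction, exactly the fracture-case ∩ low-BMD samples.
Optional two-subpopulation structure uses the Balding–Nichols model.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: realistic LD beyond engineered duplicates,
informative (non-MCAR) missingness, covariate effects of age and BMI on
risk, genotyping batch effects, and weight misspecification (scoring
weights equal the generative effects). Results on real cohorts depend on
the quality of the externally supplied weight table in ways no simulation
can certify.

## Numerical conventions

* Exact HWE p-values are computed from log-factorials with a relative
  tie tolerance of 1e-9 when summing tables "at most as probable as
  observed"; verified against direct enumeration to 1e-12 for totals ≤ 50.
* Degenerate LD ($r^2$ undefined on monomorphic or <2 pairwise-complete
  entries) is flagged `NA` and treated as 0 by the pruner.
* DeLong degenerate variance returns the widest informative interval
  [0, 1] with a warning rather than failing.
* Every stochastic step (simulation, permutation, bootstrap) takes an
  explicit seed; sub-streams are derived deterministically from it, and a
  pipeline manifest carries the seed plus a configuration fingerprint so
  identical configurations give byte-identical outputs.
* Problem sizes used in the packaged checks: oracle-recovery simulations
  at n = 20,000 × 140 SNPs; calibration loops at 200 replicates; the QC
  truth-recovery experiment at the study's own 701 × 150 across 20 seeds.

## Worked example

```{r, eval = FALSE}
library(osteopgs)

cfg <- pipeline_config(sim = sim_config(seed = 1), seed = 1)
res <- run_pipeline(cfg)

res$qc_report           # removal accounting
res$stratification$p    # permutation p for clustering by ethnicity label
res$reports$comorbid    # AUC/CI, sens/spec, ORs, deciles, trend
res$ranking             # contrasts ranked by AUC with CI-overlap flags
```

For real data, replace `sim` with `ped_path`/`map_path` (or `vcf_path`),
`weights_path`, and `phenotype_path`. The weight table is tab-delimited
with columns `variant_id`, `chr`, `pos`, `effect_allele`, `other_allele`,
`OR`; genotype sites join to it by chromosome + position + unordered allele
pair, with automatic dosage flips when REF/ALT are swapped relative to the
weight table (strand-ambiguous A/T and C/G pairs resolve by allele match
only, with a warning).

## Known limitations

* Evaluation is PGS-only by design; covariate-adjusted and survival models
  are out of scope.
* Multi-allelic VCF sites are skipped, not decomposed.
* The pruner is O(m²) per chromosome — appropriate for targeted panels
  (10²–10³ loci), not genome-wide data.
* The per-SD and group-based OR constructions answer different questions;
  both are emitted precisely because published ORs often do not say which
  was used.
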