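---
title: "Family-based exome variant prioritization: models and methods"
author: "pedexome maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based exome variant prioritization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedexome)
```

# The problem

Small pedigrees with a strongly heritable, early-onset phenotype (the
motivating application is early-onset atopic dermatitis in Korean
families) offer a cheap route to candidate genes: any causal variant
inherited dominantly must be carried by every affected member and by no
unaffected member, which removes the vast majority of the tens of
thousands of coding variants an exome carries. `pedexome` implements
this discovery design end to end: dominant-model segregation filtering,
a seven-stage annotation cascade, gene-level intersection across
families, linkage-locus proximity annotation, and a case-control
validation module for candidate SNPs.

The package consumes *annotated* variant callsets (VCF with
snpEff-style effect/impact terms plus dbNSFP-style scores in INFO
fields). Alignment, variant calling and score computation are upstream
concerns and out of scope.

# The segregation model

For a family with affected set $A$ and unaffected set $U$, a variant
with genotype $g_s \in \{\mathrm{HOM\_REF}, \mathrm{HET},
\mathrm{HOM\_ALT}, \mathrm{MISSING}\}$ per sample $s$ co-segregates
under the dominant model iff

$$\forall s \in A: g_s = \mathrm{HET} \quad\text{and}\quad
  \forall s \in U: g_s = \mathrm{HOM\_REF}.$$

Two deliberate strictness choices:

* **Affected members must be exactly heterozygous.** In an outbred
  pedigree a dominant causal allele is realistically present in a
  single copy; demanding HET (rather than "carries the alternate
  allele") matches every published candidate genotype in this design
  and sharpens specificity. `allowHomAlt = TRUE` relaxes this for
  reuse on consanguineous or late-generation pedigrees.
* **A missing genotype fails the test.** Prioritization favours
  specificity over sensitivity: a variant that cannot be verified in
  every family member is not a clean candidate. This too is a switch
  away for users who prefer imputation-style leniency.

A recessive mode (affected HOM\_ALT, unaffected at most carriers)
exists for model exploration but is not part of the discovery cascade.
Segregation is applied *before* the annotation filters: the survivor
trace's `raw` row therefore counts segregating variants per family, a
number that can vary widely between families because it is driven by
per-family genotype configurations rather than by cohort-wide
annotation properties.

# The seven-stage cascade

Stages run in a fixed order; each removes variants and the
`FilterTrace` records survivors after every stage per family.

| stage | keeps a variant when | default |
|---|---|---|
| 1 `effect` | effect is a protein-altering consequence | `defaultEffectKeep()` |
| 2 `impact` | predicted impact HIGH or MODERATE | `{HIGH, MODERATE}` |
| 3 `deleteriousness` | not (both scores present and both benign) | SIFT < 0.05, PolyPhen2 ≥ 0.453 |
| 4 `phylop` | PhyloP > 0 or missing | 0, exclusive |
| 5 `phastcons` | PhastCons ≥ 0.2 or missing | 0.2, inclusive |
| 6 `af_global` | global AF < 0.01 or unknown | 0.01, exclusive |
| 7 `af_korean` | Korean reference MAF < 0.02 or unknown | 0.02, exclusive |

Boundary semantics follow the only wording the thresholds come with:
SIFT "lower than 0.05" and the frequency "less than" bounds are
exclusive; the PolyPhen2 possibly-damaging range starts *at* 0.453 and
the PhastCons evidence level *at* 0.2, so those are inclusive. These
endpoints are unit-tested explicitly.

**Missing scores pass.** Stage 3 removes a variant only when *both*
SIFT and PolyPhen2 are present and both benign — one damaging call, or
an absent score, retains it. This is the only rule consistent with
published candidate tables in which variants with an absent PolyPhen2
and a tolerated SIFT survive the cascade. Stages 4–7 likewise let
missing values through ("or unknown frequencies"). Every
missing-passes decision is a per-stage flag in `FilterConfig`, because
reasonable users disagree here; the default is the permissive reading.

**Two output tiers.** Survivors of stages 1–5 are functionally
credible variants; the two frequency stages then split them into a
*rare* tier (passes both) and a *common* tier (fails at least one).
The tiers are disjoint and jointly equal the stage-5 survivor set — a
property the test suite asserts against an independently coded
one-pass reference filter.

**Reported averages** use the floor of the per-family mean
(`summarizeTrace()`), matching the convention in which e.g. per-family
counts (33, 60, 53) are reported as "an average of 48".

# Cross-family candidate discovery

Overlap is *gene-level*: a gene counts as shared when at least
`minFamilies` families carry any cascade-surviving variant in it, not
necessarily the same one. With three families the meaningful default
is `minFamilies = 2`; on the published three-family candidate lists
this yields exactly 14 genes, with one gene (*COL6A6*) present in all
three, and the identities of the rs-labels are deliberately ignored
(the same variant can be printed with inconsistent rsIDs across family
tables, so identity is keyed on `chrom:pos_ref/alt`).

A candidate gene is flagged `hasRareVariant` when any member variant
sits in the rare tier in at least one family. Requiring rare-tier
sharing in two or more families would be stricter, but contradicts the
published count of four rare overlap genes; the at-least-one-family
reading is therefore implemented.

**Locus proximity.** Candidate positions are compared against linkage
loci (1-based inclusive intervals; megabase-dialect tables are
converted with the exact factor $10^6$). A gene is `WITHIN` a
same-chromosome locus containing one of its positions, `PROXIMAL` when
within `marginBp` bases of a locus end, else `NONE`; `WITHIN` beats
`PROXIMAL`, ties go to the smallest distance. The default margin of
1 Mb is the scale at which linkage peaks are customarily considered to
"contain" a flanking gene — a gene 0.7 Mb beyond a reported interval
end is well inside the resolution of a genome-wide linkage scan — and
it is exposed as a parameter because nothing principled pins it down
more precisely.

# Case-control validation

For each SNP, genotype counts for cases and controls collapse to 2×2
tables under three models: allelic (alt vs ref allele counts, $2n$
alleles per group), dominant (carrier vs non-carrier samples) and
recessive (HOM\_ALT vs rest). The association measure is the
cross-product odds ratio with the Woolf log-interval

$$\mathrm{CI}_{95} = \exp\!\left(\ln\widehat{OR} \pm z_{0.975}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right),$$

with the Haldane–Anscombe correction (add 0.5 to all four cells) when
any cell is zero; the correction is flagged in the result and can be
disabled, in which case a zero cell is a hard error rather than a
silent `NaN`. This estimator was chosen because it is the standard for
small candidate-SNP tables; logistic regression with covariates is a
non-goal. No multiple-testing adjustment is applied — the analysis
reports a handful of pre-specified candidate SNPs — but the table
carries its own test count so users can adjust.

Frequency tables print percentages rounded *half-up* to one decimal
(`22.95 → 23.0`), because that is the convention of the published
tables the module reproduces; base R's round-half-even would print
`22.9`.

`hweExactCheck()` is the exact conditional test of Hardy–Weinberg
proportions (Levene–Haldane distribution of the heterozygote count
given allele counts, point-mass two-sided ordering), computed by the
standard stable recurrence. It exists to validate the synthetic
generator and is cross-checked in the tests against an independent
log-factorial enumeration.

# The synthetic cohort generator

No sequence data accompanies the motivating study, so the package
ships a generator that emulates the *statistical structure* the
pipeline assumes:

* **Families**: 3 families of 2 affected + 2 unaffected members, the
  study's design.
* **Background variants** (default 20,000 per cohort, an exome-scale
  coding callset; drawn from a pool of 5,000 gene symbols so that
  gene-level overlap between families arises by chance): population
  allele frequency $p \sim \mathrm{Beta}(0.4, 2.5)$ (rare-skewed),
  genotypes per sample i.i.d. Hardy–Weinberg draws *independent of
  affection status*, so background variants survive segregation only
  by chance — at rate $(2p(1-p))^2((1-p)^2)^2$ per family, a closed
  form the tests compare against observed rates.
* **Annotations**: effects follow a categorical distribution
  resembling a coding callset (≈30% non-synonymous, ≈28% synonymous,
  rare truncating classes); impact equals the canonical snpEff impact
  of the effect with probability 0.7 and is otherwise jittered, so the
  impact stage does nontrivial work; scores are two-component mixtures
  (benign bulk + damaging/conserved tail: e.g. SIFT
  $0.75\,\mathrm{Beta}(5,1.5) + 0.25\,\mathrm{Beta}(0.6,8)$) with 10%
  missingness, so every stage removes a configurable, nontrivial
  fraction and traces take the expected staircase shape.
* **Planted causal variants**: one per family in a single configured
  gene (per-family positions on chr3 by default), heterozygous in
  every affected and homozygous-reference in every unaffected member,
  with annotations that are *validated against the active
  `FilterConfig` before any data is drawn* — a planted value violating
  a threshold aborts generation naming the threshold. Recovery of the
  planted gene in the `minFamilies = 3` overlap is therefore
  guaranteed by construction and asserted end-to-end.
* **Case-control block**: defaults of 112 cases and 61 controls typed
  at three SNPs whose group-specific alt-allele frequencies match the
  published validation table; genotypes are Hardy–Weinberg draws at
  the group frequency.

One global seed drives every draw, and a fixed config + seed
reproduces output files byte for byte.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: linkage disequilibrium between
variants (each variant is drawn independently), Mendelian transmission
within families (genotypes are population draws, not parental
gametes), realistic human site-frequency spectra or gene lengths,
indels and multi-allelic sites (the parser handles them; the generator
emits biallelic SNVs), batch effects, and genotyping error beyond
simple missingness.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (VCF convention);
  megabase locus tables are converted with exactly $10^6$ and rounded
  to integer base pairs.
* A missing annotation is `NA`, never 0 — `0.0` is a legal and highly
  damaging SIFT score, and a legal PolyPhen2 value.
* Multi-allelic VCF records are split into one row per ALT allele
  before anything else; a genotype is classified relative to *that*
  allele (`1/2` is HET for each of the two alternates), and any `.`
  allele makes the call MISSING.
* Only the first transcript annotation per record is consumed (one
  effect per variant).
* An empty callset flows through every stage as an empty result with a
  zero trace, not an error; an empty pedigree file, by contrast, is an
  error, as is any phenotype code other than 1/2.
* `minFamilies` larger than the number of families yields an empty
  overlap, not an error; a margin of 0 makes `PROXIMAL` impossible.

# Test problem sizes

The shipped suite exercises the cascade-vs-reference equivalence on
10,000 generated variants, planted-gene recovery on 20 seeded
three-family cohorts of 300 background variants, null case-control
odds ratios over 15–20 replicates of 800–1,000 samples per arm, and
Hardy–Weinberg calibration on 300 SNPs; these sizes give the
stochastic assertions comfortable Monte-Carlo margins (stated inline
in each test) while keeping the default `R CMD check` run fast.

# Known limitations

* The dominant segregation test assumes a fully genotyped nuclear
  family; it has no concept of phase, de novo events,
  compound heterozygosity or X-linked inheritance.
* Gene-level overlap treats gene symbols as opaque labels; symbol
  drift between annotation versions will silently break overlap.
* The odds-ratio module is estimation-only by design; it reports no
  p-values and applies no multiplicity control.
* The cascade trusts its input annotations. Internally inconsistent
  published tables (e.g. a variant printed with a conservation score
  below the threshold it supposedly survived) are reproduced as data
  but cannot be reconciled by the package; the tests document one such
  case rather than asserting it.
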