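---
title: "Methods: cfDNA somatic mutation post-processing and clinical association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA somatic mutation post-processing and clinical association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfsomatic)
library(dplyr)
```

## The problem

Liquid biopsy calls somatic mutations from plasma cell-free DNA (cfDNA)
against a matched germline (blood) sample. At the depths typical of
whole-exome cfDNA sequencing (~90x) every variant caller produces large
numbers of artifact calls, and no single caller is sensitive across the
allele-frequency spectrum, so a common design runs several callers
(here: MuSE, Mutect2, Strelka2, SomaticSniper, VarDict), merges their
output, and then aggressively filters the union. The surviving calls feed
a per-patient burden statistic — the plasma mutation burden, PMB, defined
as the number of somatic mutations with variant allele frequency (VAF)
of at least 5% per megabase of the capture target — and gene-level
association analyses against clinical endpoints (metastasis, stage,
overall survival).

`cfsomatic` implements that post-processing end to end: caller-dialect
VCF ingestion, allele normalization, union consensus, a six-rule somatic
filter cascade plus a recurrent false-positive gene blacklist, an
automated read-level stand-in for manual IGV inspection, codon-level
consequence annotation against minimal gene models, burden and
association statistics, and a seeded synthetic-cohort generator that
makes every stage testable without controlled-access sequencing data.

## Consensus merging

Each caller's VCF is normalized to a common per-allele schema. Depth and
alt-read counts come from the caller's own FORMAT dialect (Mutect2
`AD`/`SB`/`F1R2`/`F2R1`; Strelka2 tier-1 `AU/CU/GU/TU` or `TAR/TIR`;
VarDict `AD`/`RD`/`ALD`; MuSE and SomaticSniper `AD`/`DP` only). Callers
that do not report strand or read-pair orientation yield records flagged
`strand_unknown`; such records are *exempted* from strand-dependent
filters rather than auto-failed, so the filter outcome does not depend on
which caller happened to contribute the consolidated evidence.

Indels are trimmed of shared prefix/suffix bases and left-aligned against
the reference before merging, so all five callers produce byte-identical
keys for the same allele. The merge key is
`sample-chrom-pos-ref-alt`: position alone would conflate distinct
alternate alleles at one site, for which allele-level statistics (VAF)
are undefined. Union semantics (any caller suffices) is the default; a
`min_callers` argument exposes stricter intersections. When several
callers support one variant, the consolidated read evidence is taken from
the highest-priority caller — Mutect2 > Strelka2 > VarDict > MuSE >
SomaticSniper, ordered by decreasing completeness of count, strand and
orientation fields.

## The filter cascade

Seven vectorized predicates, all evaluated on every variant (no
short-circuiting), with a full per-variant trace:

| filter | rule | default |
|---|---|---|
| population AF | population MAF strictly above threshold | 1% |
| panel of normals | allele-level locus key in the PoN list | — |
| oxoG | C>A/G>T with alt read-pair orientation fraction ≥ threshold (≥3 informative pairs) | 0.9 |
| multiallelic | caller flag, or >1 alt allele at the site | — |
| clustered | ≥ k same-sample variants in some w-bp window | k=3, w=100 |
| strand bias | one-sided exact test on the ref/alt × fwd/rev table | p < 0.005 |
| allele support | tumor alt reads < a or normal alt reads ≥ b | a=4, b=4 |
| VAF | cfDNA VAF strictly below threshold | 0.05 |
| gene blacklist | gene in the recurrent false-positive list | MUC16, MUC19 |

Notes on the genuinely open choices:

* **VAF threshold.** The source rules state both "VAF < 0.05 is removed"
  and a 2% detection limit. The default is 0.05, consistent with the PMB
  definition (which is explicitly ≥5%); `filter_config(min_vaf = 0.02)`
  is the supported profile for assays read down to the ~2% limit.
* **Clustered events and strand bias** are named after GATK tooling
  without parameters in the source; the reconstruction here is ≥3
  same-sample events inside any 100 bp window, and a one-sided exact
  (hypergeometric-tail) test at p < 0.005 taken in the direction of the
  observed imbalance. When a caller reports no ref-strand counts the ref
  reads are assumed balanced — the conservative choice, since it can only
  make the test less significant for a fixed alt imbalance.
* **oxoG** uses an orientation-fraction rule (≥90% of alt-supporting
  pairs in one of F1R2/F2R1, with at least 3 informative pairs) rather
  than a full damage model: fully oriented artifacts fire, balanced true
  variants essentially never do. Records without orientation counts are
  logged untestable, not fired.
* **Expected-count routing.** Categorical tests use Pearson chi-square
  without continuity correction, switching to Fisher's exact test when
  any expected cell is ≤ 5. The boundary is included so the marginal case
  gets the exact test.

A variant is kept iff zero filters fire; because the predicates are
independent, the kept set is invariant to evaluation order, and
`|kept| + |dropped| = |input|` always. Raising `min_vaf` or
`min_tumor_alt` can only shrink the kept set; both properties are
enforced by tests.

## Automated read-level validation

Manual IGV inspection of candidate calls is automated as four
deterministic criteria on 20 bp pileup windows (center ± 10 bp) around
the variant:

1. **allele configuration** — a clean biallelic column: no third allele
   supported by ≥2 reads (one stray sequencing-error read is tolerated).
   The source text for this criterion literally asks that true positives
   *be* multiallelic, which contradicts the cascade's multiallelic
   removal; the biallelic-cleanliness reading is the only one consistent
   with the rest of the pipeline, and is the one implemented.
2. **strand support** — ≥1 alt read on each strand (strand-unknown
   pileups are exempt, matching the ingestion policy).
3. **clean window** — a read whose total mismatch count in the window
   reaches 2 *including* the candidate base (i.e. ≥1 extra mismatch) is
   discounted; the site passes when at least one alt read is clean and
   the clean fraction is ≥ 0.5. Whether the historical rule was applied
   per read or per pileup column is not recorded; both are implemented
   (`window_rule = "per_read"` default, `"per_column"` passes when the
   mean extra-mismatch count per alt read is < 1).
4. **alt counts** — ≥3 alt reads in the tumor window and <3 in the
   normal window.

The verdict is `pass` iff all four hold; a missing window makes the
variant `untestable` and removes it from pass-rate denominators.
Tightening any criterion can only convert passes to non-passes. Per-gene
pass/non-pass tables use one-decimal percentages, and the association
between a gene's total mutation count and its non-pass count is
quantified with the tie-corrected Spearman correlation on **counts** (on
the published 25-gene validation table this reproduces rho = 0.763;
percentages would not).

## Consequence annotation

A deliberately minimal stand-in for a full annotation engine: one
transcript per gene, exons whose concatenation is the CDS (ATG start, no
internal stops), splice sites fixed at ±2 bp outside exon boundaries.
SNVs are classified by translating the reference and mutated codons on
the coding strand into the nine categories used throughout (synonymous,
missense, splicing site, frameshift, in-frame, start lost, stop gained,
stop lost, stop retained); indels are frameshift/in-frame by length mod
3. "Nonsynonymous" excludes synonymous and stop-retained calls, the two
classes that leave the protein unchanged. A pre-annotated `consequence`
column bypasses the classifier, so output from a full annotator can be
substituted. Strand symmetry (a minus-strand gene classifies identically
to its plus-strand mirror) is property-tested against a
translate-both-haplotypes oracle.

## Statistics

PMB divides the count of kept, in-target mutations with VAF ≥ 5% by the
target size in Mb (91.08 Mb, the whole-exome + UTR capture design, when
no BED is supplied). Group comparisons use the Mann-Whitney U test —
exact enumeration when the combined n is ≤12 without ties, otherwise the
tie-corrected normal approximation appropriate at cohort scale. The
age-adjusted burden model is OLS on standardized variables, reporting
the standardized coefficient of the binary clinical predictor.
Family-wise corrections follow the reporting convention of the clinical
tables: Bonferroni thresholds per family (0.05/9 for the nine clinical
dichotomies, displayed as 0.006; 0.05/2 for the two survival gene sets,
0.025; per-gene testing corrects over the number of genes actually
tested). Survival uses Kaplan-Meier product-limit curves with the
two-group 1-df log-rank test. The power calculation is a two-sided
normal-approximation two-sample power at the pooled standardized
difference; no record of the original method exists, so this routine is
property-tested (against Monte-Carlo rejection rates and its own
inverse) rather than compared to printed values.

## The synthetic cohort generator

The generator draws a complete study from one seed, and its defaults
*are* the study conditions: 50 patients, 9 metastatic, per-patient
qualifying somatic counts Poisson with planted rates of 14 (non-
metastatic) and 38 (metastatic) mutations per Mb — the reported group
means — against the 91.08 Mb burden denominator. The planted rates refer
to PMB-qualifying mutations (observed VAF ≥ 5%, enforced by
construction), which is what makes "group mean PMB recovers the planted
rate" a well-defined check; sub-threshold somatics (VAF 2–5%) are drawn
at a separate rate (3/Mb) to exercise the VAF filter. VAFs follow a
Beta(2, 8) truncated at 0.05 (mean ≈ 0.2, the clonal-fraction scale seen
in cfDNA), depths are Poisson with mean 90 (the reported mean coverage),
and binomial read sampling ties alt counts, strand splits and
orientation splits to the depths.

The synthetic exome is ~4.5 Mb of coding sequence (250 genes × 6,000
codons, three exons each, alternating strands, no internal stops) spread
over ten chromosomes; `target_mb` stays at 91.08 purely as the burden
denominator. The gene space is large enough that random placement makes
accidental 3-in-100-bp clusters rare (<1% of true somatics), so cascade
sensitivity is not confounded by the clustered-site filter.

Planted classes and the mechanism designed to remove each:

* germline SNPs (200/patient, population MAF drawn in 2–50%) → population
  AF filter;
* recurrent panel-of-normals loci shared across patients → PoN filter;
* oxoG artifacts at reference C/G positions with near-total orientation
  skew (stray-orientation rate 0.5%, the sequencing-error scale) → oxoG
  filter, via Mutect2's orientation fields (systematic artifacts are
  emitted by callers at a high shared rate, 0.98 — unlike stochastic
  sensitivity to true variants, damage artifacts recur across callers);
* positional clusters (triplets inside <100 bp) → clustered filter;
* blacklist-gene false positives in MUC16/MUC19 → blacklist;
* low-support artifacts (tumor alt < 3 or normal alt ≥ 4) → allele
  support filter and validation criterion (iv);
* strand-biased and clustered-mismatch artifacts → the read-level
  validation criteria (ii) and (iii); strand-biased calls with many alt
  reads are additionally caught upstream by the strand-bias site filter,
  while weakly supported ones deliberately survive to validation — as
  in real data, where the site-level test is underpowered at low depth;
* caller-private false positives (per-caller counts echoing the relative
  yields of the five callers) with 1–3 alt reads → allele support/VAF
  filters.

Gene-set coupling is designed rather than emergent: because a ~250-gene
exome inflates per-gene hit rates relative to a real 20,000-gene exome,
the five BCAA-catabolism and five hypoxia-related genes (plus the planted
metastasis-associated gene and the two blacklist genes) are excluded from
uniform placement, and member-gene mutations are planted in a designated
24% / 30% of patients — the published gene-set fractions — with the
planted variants drawn from each patient's Poisson budget so burden
recovery stays unbiased. Planted hits sit at middle codon positions,
which are always nonsynonymous under the standard code. Survival is
exponential (baseline median 3 years, administrative censoring uniform
on 500–2,500 days) with a hazard ratio of 3 for patients carrying a
mutated survival gene set.

Determinism: every stage draws from a stream seeded by a fixed offset
from the master seed, so a rebuilt genome plus replicated cohort is
byte-identical to an inline run, and replicate studies can share one
genome while varying only the cohort stream.

### What the generator does not emulate

Clonal structure and subclonal VAF mixtures; patient-level
overdispersion of mutation rates (the reported group SDs are far above
Poisson, so real burden distributions are heavier-tailed than simulated
ones — group *means* are matched, not variances); sequencing base
qualities and mapping artifacts beyond the planted classes;
caller-specific count noise (all callers see the same read evidence);
and real population LD/AF structure. Passing the pipeline's tests on
synthetic cohorts therefore demonstrates that each mechanism removes the
class it was designed for and that the statistics are calibrated — not
that the specific thresholds are optimal for any particular real assay.

## Problem sizes used by the test suite and acceptance script

Scaled runs preserve the study's per-Mb composition
(`sim_config_scaled()` shrinks the target and every count that scales
with it by the same factor), so sensitivity and FDR expectations carry
over: end-to-end checks use 10 patients at a 4 Mb target (~1,300 merged
variants); classifier checks use a 6-patient cohort with inflated
artifact counts (per-class accuracy is class-conditional, so abundance
does not distort it); parameter-recovery checks run 100 full-size
replicates (n = 50, 91.08 Mb rates) over a shared genome; null
calibrations use 5,000 replicates per test.

## Known limitations

The dialect mappings are a reconstruction — the original field
extraction per caller is not recorded anywhere; the mapping is config-
visible and every count survives a write/read round trip by
construction. Whether the original merge conflated distinct alt alleles
at one position is unknowable from the text; this implementation keys on
alleles. Contamination estimation is reduced to the normal-alt-count
rule; GATK is not re-run. The consequence classifier covers one
transcript per gene and the nine categories only.
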