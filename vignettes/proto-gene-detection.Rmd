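---
title: "Detecting proto-genes from mutation-aware window transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting proto-genes from mutation-aware window transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A proto-gene is a genomic region that was transcriptionally silent in an
ancestor and acquired stable transcription (possibly translation) after a
new mutation, without yet having a demonstrated beneficial function. In a
long-running bacterial evolution experiment, clones are archived together
with complete lists of the mutations separating them from their ancestor,
and RNA-seq/Ribo-seq data exist for the ancestor, the evolved clones, and
the ancestral genotype grown in a large panel of environmental conditions.
That combination makes proto-gene birth directly observable: find regions
immediately downstream of new mutations whose transcription rose
significantly relative to the ancestor, was absent in the ancestor, and is
not simply a condition-dependent programme that the ancestor can already
express elsewhere.

`protoscan` implements this detection cascade as reusable, tested
components, together with a synthetic-data generator that emulates the
structure of such an experiment and plants proto-gene events with known
ground truth, so every stage can be validated without external downloads.

## Pipeline overview

1. **Genome engineering** (`apply_mutations`, `lift_interval`): mutations
   in the breseq GenomeDiff dialect (SNP, small indel, large deletion,
   mobile-element insertion) are applied exactly to the ancestral
   sequence, producing the evolved clone's genome and an exact
   ancestral-to-evolved coordinate map. This replaces aligner-based
   remapping: liftover status (`clean`, `contains-indel`, `partial`,
   `deleted`) is arithmetic, not heuristic.
2. **Window transcriptome** (`partition_windows`, `filter_windows`,
   `categorize_windows`): the ancestral genome is tiled into fixed-width
   (default 400 bp) windows on both strands; windows deleted in any
   clone, carrying a net indel > 10 bp, or overlapping an annotated
   IS/repeat are removed; the rest are `annotated` (same-strand coding
   overlap strictly > 10 bp), `antisense` (opposite-strand coding overlap
   >= 1 bp) or `intergenic`, with non-genic windows flagged
   `gene_adjacent` when they touch the 300 bp upstream or 100 bp
   downstream flank of a same-strand gene.
3. **Quantification** (`count_reads`, `compute_nrc`, `compute_tpm`): a
   strand-aware read interval increments *every* same-strand feature it
   overlaps by at least 1 bp (htseq-count "nonunique-all"); NRC is count
   divided by feature length, TPM is NRC normalised to one million per
   sample. The normalisation universe is always the feature set of the
   analysis at hand — windows for the genome-wide survey, candidate
   regions plus annotated genes for detection — never a mixture.
4. **Differential expression** (`nb_wald_test`,
   `differential_translation`): an NB GLM with log link, median-of-ratios
   size factors, and a fixed per-feature dispersion estimated by method
   of moments with trend shrinkage; the Wald statistic on the group
   coefficient gives a two-sided normal p-value, BH-adjusted over all
   tested features. Differential translation is the assay-by-group
   interaction in a joint GLM over stacked RNA-seq and Ribo-seq counts,
   with size factors estimated per assay and q < 0.01 as the
   conventional threshold.
5. **Detection cascade** (`run_detection`): 100- and 200-bp regions
   immediately downstream of each mutation (both strands, except MOB
   insertions, which transcribe outward from the element's promoter on
   one strand) are filtered for > 10-bp same-strand overlap with any
   annotated gene, RNA gene, pseudogene or repeat, tested for
   differential transcription (significant = adjusted p < 0.05 *and*
   positive fold change; a candidate is carried when either length is
   significant), deduplicated, screened for ancestral silence and for
   visibility in the condition library, classified by mutational cause,
   and scanned for ORFs.

## The synthetic scenario

`simulate_scenario(sim_config())` generates the default study conditions:

* a 50-kb linear genome fragment carrying 40 disjoint genes of
  400–1,200 bp with 50–400-bp intergenic gaps (roughly two thirds of positions genic,
  echoing dense bacterial annotation) and an annotated repeat;
* 100 mutations with class weights 0.957 on SNP+small-indel, 0.03 on
  IS-element insertion (a 1,443-bp element with 3-bp target-site
  duplication) and 0.013 on large deletions (1–8 kb), mirroring the
  observed spectrum in which SNPs and small indels carry over 95% of the
  mass;
* an expression model with log-normal gene levels around 20 TPM and a
  low stochastic non-genic background, plus five planted proto-gene
  events: 200-bp downstream regions of eligible mutations whose
  evolved-group mean is 50-fold the near-zero ancestral mean (MOB events
  are planted on the element's promoter strand only);
* 2 ancestor + 2 evolved RNA-seq samples of 300,000 30-bp reads with NB2
  noise (`var = mu + 0.1 mu^2`), evolved reads lifted exactly onto the
  evolved genome; optionally matched Ribo-seq samples scaled by a
  per-feature translation-efficiency factor;
* a 34-condition expression library of the ancestor genotype (20,000
  reads per condition) in which one planted region is also expressed at
  30 reads per condition, to exercise the cross-condition exclusion
  filter.

Every stage draws from its own stream derived from the master seed, so
identical configurations reproduce byte-identical outputs and changing
one stage's parameters does not perturb the others.

### What the generator emulates, and what it does not

The generator reproduces the *structure* that the detection method
depends on: dense annotation with small gaps, a realistic mutation
spectrum, NB-distributed replicated counts, high genic and near-zero
non-genic expression, strand-aware read evidence, and planted
transcription gains tied to specific mutations. It does not simulate raw
sequencing reads, base qualities, mapping bias, rRNA contamination,
aligner multi-mapping artifacts, or operon structure, and the genome is
linear (no window or region wraps the origin). Passing tests therefore
demonstrate correctness of the pipeline's logic and calibration of its
statistics under the stated noise model — not robustness to artifacts
that only raw-read processing introduces.

## Numerical choices worth knowing

**Non-genic background level.** No quantitative noise model for
stochastic non-genic transcription is available from data; the default
baseline of 0.02 TPM is chosen so that, as in the real ancestor, silent
regions remain silent under the quantitative screen below (per-base
background coverage ~0.3 reads against a genic level several hundred
times higher). The planted region's ancestral mean *is* this baseline;
the background tile beneath a planted region is zeroed so the level is
not double-counted.

**Dispersion estimation.** Per-feature method-of-moments estimates from
the within-group variance of normalised counts are floored at 1e-8 and
shrunk toward a parametric mean-dispersion trend `a0 + a1/mean`, fitted
over features with mean >= 1 (floored estimates included, so the trend
is not selection-biased upward on near-Poisson data; extreme estimates
are clipped at 10 for the fit). The per-feature estimate retains weight
0.3 and the trend 0.7. With 2 replicates per group the per-feature
estimate has one residual degree of freedom per group; weaker shrinkage
visibly inflates the Wald test's size (about 0.085 at nominal 0.05 with
0.3 on the trend, against ~0.05 with 0.7), so strong shrinkage is the
calibrated default for 2-replicate designs.

**Wald stabilisation.** The GLM is fitted on counts plus a 0.25
pseudocount. This is negligible at moderate counts but essential when
one group is all zero: complete separation otherwise drives the
coefficient to the optimiser's bound, the standard error diverges and
the p-value goes to 1 — the test would silently lose all power exactly
on the strongest true gains (silent ancestor, strong evolved signal).
Raw counts still drive `baseMean` and the low-count skip (total < 2).
IRLS stops when the relative deviance change falls below 1e-8 (analytic
NB2 deviance, continuous in the counts) or after 100 iterations;
non-converged fits are flagged and excluded from the BH family.

**Ancestral silence.** Manual workflows inspect coverage plots
visually for this decision; here the verdict is quantitative and configurable. A region is
`silent` when its mean per-base ancestral coverage is below `t_silent`
(default 0.1x the genome-wide per-base median, floored at 1 read) in
every replicate *and* no 25-bp run of coverage >= 3 reads appears in
every replicate; `expressed` when any replicate's mean reaches `t_expr`
(1.0x the median); `ambiguous` otherwise. The run condition is
replicate-consistent by design: at ~1.5 expected background reads per
region, a 3-read pileup in a single replicate is sampling noise that
visual inspection would never call transcription, whereas genuine
low-level transcription reproduces across replicates.

**Condition screen.** A candidate is `seen` when it gathers >= 3 reads
in at least one condition (a per-condition rule — no pooling across
conditions), `unseen` otherwise. The floor of 3 reads corresponds to the
display floor used when inspecting condition-library coverage.

**Dedup and attribution.** Exact duplicate regions keep the first in
genome order. Distinct candidates overlapping on the same strand — two
adjacent mutations counted against one gained transcript — collapse to
the candidate with the smallest raw p-value (BH-adjusted values tie),
then the largest fold change, then genome order. Causal attribution
between adjacent upstream mutations is not identifiable from read
evidence alone, so planted-truth evaluation (`evaluate_detection`)
scores recovery and false discoveries by same-strand region overlap, not
by mutation identity.

**Cause classification.** MOB insertions are "promoter in insertion
sequence". Deletions >= 1,000 bp with an annotated same-strand gene
within 500 bp upstream of the new junction are "translocation to
existing promoter". SNPs and small indels remain
"point mutation or small indel (promoter status unknown)" — promoter
prediction is out of scope.

**ORF scan.** The window from 200 bp upstream of the gained region's
start to 500 bp downstream, oriented to the transcribed strand, is
scanned in all three frames for ORFs from an ATG/GTG/TTG start to the
next in-frame stop (stop included in the length), reporting maximal ORFs
strictly longer than 30 bp — a 117-aa ORF reports 354 bp.

**Boundary conventions.** All thresholds are strict where the procedure
says "more than": a 10-bp annotation overlap is retained and 11 bp
excluded; a 10-bp net indel keeps a window and 11 bp drops it; a window
at exactly a TPM cutoff is not counted as expressed. "Immediately
downstream" means the first base after the mutation's footprint in the
evolved genome — after the deletion junction for DEL, after the element
plus target-site duplication for MOB, after the variant for SNP/INS —
extending in each strand's reading direction. "Sliding windows" are
tiled at step = width: the window counts this mirrors are only
consistent with tiling, though the step is configurable. The historical
"mapped more than once" filter has no analogue under exact liftover
without duplication events and is logged as a no-op.

## Design decisions that were genuinely open

* The 100-bp and 200-bp variants of a candidate are combined with
  "either significant" (a `strict_both_lengths` switch requires both);
  reported counts elsewhere hint that some gains are visible only in the
  shorter region.
* Whether the genome-wide survey's TPM denominator includes annotated
  genes as well as windows is not fully settled; windows-only is the
  default for the survey, and detection always uses candidates + genes.
* Gene adjacency uses inclusive (>= 1 bp) overlap with the 300/100-bp
  flanks.
* Each evolved time point would be tested against the ancestor
  independently; no time-course trend test is provided.
* Amplifications and inversions are rejected loudly rather than
  supported: none of the documented proto-gene events involves them, and
  forbidding overlap/nesting keeps the coordinate map exact.

## Problem sizes

The shipped analyses and tests run on a 50-kb genome with 100 mutations,
2+2 replicates of 3x10^5 reads and a 34 x 2x10^4-read condition library;
statistical calibration uses 10^4 null features and 10^3 signal features
(type-I error within [0.03, 0.07] at alpha = 0.05; power >= 0.9 at an
8-fold change), and planted-truth recovery is averaged over 5 scenario
seeds (sensitivity >= 0.9, false-discovery proportion <= 0.1). These
sizes keep a full run in minutes on one core while leaving every rate
estimable with useful precision.

## Known limitations

* The Wald test relies on the normal approximation; at 2 replicates per
  group its size depends on the dispersion shrinkage being strong, and
  effect sizes are not posterior-shrunk, so extreme fold changes at low
  counts should be read qualitatively.
* The silence and condition screens are read-count rules on synthetic
  coverage; on real data their thresholds interact with library depth
  and rRNA depletion efficiency and would need dataset-specific review.
* Candidate regions inherit reads from anything they overlap
  (nonunique-all), so a candidate abutting a highly expressed gene can
  carry readthrough signal; the overlap filter removes the worst cases
  but transcriptional spillover is not modelled away.
* The homology screen against an external transcript catalogue is a
  placeholder column in the report, to be filled by the user.
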