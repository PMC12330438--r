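---
title: "Sieving rare structural variants from family cohorts: models and design"
author: "svsieve"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`svsieve` implements a pangenome-filtered rare structural-variant (SV)
analysis for family cohorts sequenced with long reads. This vignette is the
package's own account of the models and procedures it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the design was genuinely open.

## The matching model

Everything downstream rests on one predicate: when do two SV calls describe
the same allele? `sv_match()` declares a match when all of

* same SV type (DEL or INS — the only classes analysed here; inversions and
  translocations are rejected at parse time with a warning rather than
  silently dropped);
* breakpoint distance $|pos_a - pos_b| \le$ `refdist` (default 500 bp);
* reciprocal size similarity $\min(L_a, L_b)/\max(L_a, L_b) \ge$ `pctsize`
  (default 0.90);
* when both calls carry an allele sequence, sequence similarity
  $1 - d_{\mathrm{edit}}(s_a, s_b)/\max(|s_a|, |s_b|) \ge$ `pctseq`
  (default 0.90).

The defaults mirror the truvari-style flags (`pctseq`, `pctsize`,
`refdist`, `sizemin`, `sizemax`, keep rule) under their usual names. The
sequence metric is global Levenshtein distance normalised by the longer
sequence; merging tools do not pin down one canonical similarity, so the
choice is documented here and the threshold test is centralised in one
function. Deletions frequently omit the deleted sequence, in which case the
sequence test is skipped and matching rests on position and size — the
conservative reading, since requiring sequences would silently disable
matching for most DEL records. The edit distance is computed exactly
(`utils::adist`); a cheap length-difference lower bound and, for
equal-length sequences, a Hamming upper bound decide most comparisons
without running the full dynamic program.

## Collapse: greedy, order-dependent, on purpose

`collapse()` clusters calls greedily in (chrom, pos) order: each call joins
the first existing cluster whose *founding* call it matches, else founds a
new cluster. This reproduces the order-dependent behaviour of the
single-pass merging tools practitioners actually run, rather than an
idealised transitive closure. The test suite constructs instances where the
two coincide (well-separated loci with tightly jittered copies) and asserts
equality against an independent union–find oracle there; on adversarial
chains the greedy result is the intended one. The output representative is
chosen per `keep_rule`: highest quality for within-sample collapse, the
representation carried by most samples for the cohort-level collapse.
Ties break deterministically (quality, then leftmost position, then
lexicographic id), so the pipeline is reproducible call-for-call.

Genotypes transfer to the representative locus per sample; a sample
contributing two distinct member calls to one cluster becomes homozygous
alt. Non-carriers get sex-aware reference genotypes: `0` on hemizygous male
sex-chromosome loci, `.` for chrY in females.

## Coordinates, sex chromosomes, missing data

Internally every interval is 0-based half-open; VCF's 1-based convention is
converted exactly once at the I/O boundary, and a round-trip property test
pins that conversion. Males are haploid on non-PAR chrX and chrY: diploid
genotypes emitted there by callers are coerced to hemizygous (any alt
allele wins) with a warning, a rule the package documents because upstream
tools do not define one.

Missing parental genotypes are handled asymmetrically, and deliberately so:
for frequency-style rules (control filtering, the "observed once" private
rule) a missing genotype counts as *not a carrier*; for Mendelian checks it
yields *unknown*, which routes the call into the transmission-curation
chain instead of declaring a violation. This mirrors the two-tier
high/low-confidence structure of the analysis: absence of evidence filters
nothing, but it is not allowed to manufacture de novo candidates directly.

## The transmission-curation chain

Rare SVs that deviate from clean Mendelian inheritance walk an ordered
chain, stopping at the first resolving step:

1. **Relaxed rematch** against the parents' pre-validation raw callsets at
   pctseq/pctsize 0.9 — recovers inheritance lost to callerset validation.
2. **Callable-region score**: a fixed logistic rule
   $\sigma(w_0 + w_1\log(1+n_\mathrm{reads}) + w_2\,\mathrm{mapq}/60 -
   w_3\,\mathrm{clip})$ with $w = (-2, 1.5, 1, 2)$ and threshold 0.5.
   The published analyses use a trained model for this step whose features
   and weights are not public; the package substitutes this documented,
   monotone rule with the same inputs and the same 0.5 decision threshold,
   and exposes the weights as configuration. With the default weights a
   single read at a perfectly mappable locus (mapq 60, no clipping) scores
   just above 0.5 — the rule trusts one clean read in a clean region; the
   read-support tier (step 5) only governs loci the score cannot clear.
3. **Genotyper support**: a parental re-genotyped alt call resolves the SV
   as transmitted.
4. **Tandem-repeat allele lengths** (TR-flagged loci only): inherited when
   a parental allele length is within $\max(10\,\mathrm{bp},
   0.1 \times AL_\mathrm{child})$ of the child's; the tolerances are this
   package's defaults, configurable, since none are published. A child
   allele exceeding all parental alleles by more than the tolerance is an
   expansion candidate and falls through to read support.
5. **Read support**: $\ge 3$ parental reads = moderate-confidence
   transmission, 1–2 reads = low confidence (the boundary case of exactly 2
   reads is unspecified upstream; assigning it low confidence is the
   conservative choice), 0 reads in both parents = de novo. The per-parent
   maximum is used, since transmission requires only one carrier parent.

Steps 1–4 resolve to "moderate" confidence: the named confidence tiers
upstream attach only to Mendelian consistency (high) and the read-support
step (moderate/low), so intermediate rescues are not promoted to high.
Manual inspection (a step 6 in the original workflow) is out of scope;
after step 5, zero support anywhere means de novo. The chain is strictly
ordered 1→5 also for TR-overlapping SVs, where the relative order of the
genotyper and TR steps is otherwise ambiguous.

## Rare classes

On the rare pool (post control-filtering), per (SV, child):

* **six genotype categories** partition every carried genotype: AUTO_HET,
  AUTO_HOM, X_HET, X_HOM (females), MALE_HEMI_X, MALE_HEMI_Y. PAR calls
  are diploid and classified autosomal-style; the default genome masks the
  PARs anyway.
* **private inherited**: exactly one carrier parent across all cohort
  parents, and that parent is the child's own. Presence/absence only — no
  allele-frequency thresholds, matching a filter defined on carrier counts.
* **biparental homozygous**: child hom-alt, both parents het, never
  homozygous in any control, configuration unique to one family,
  autosomes only.
* **de novo**: the chain above found no parental support.

Control filtering itself is presence-based ("carried by ≥ 1 control"), with
sex-matched comparisons on chrX/chrY, and a control locus whose genotypes
are all missing does not count as carried (conservative retention).

## Burden statistics

`chisq_rate_test(k1, n1, k2, n2)` reports the **per-individual rate ratio**
$(k_1/n_1)/(k_2/n_2)$ as its headline ratio. The choice is deliberate: on
per-child de novo counts of 26/51 versus 20/36 this statistic equals 0.918
and prints as 0.92, whereas the classical 2×2 odds ratio equals 0.83 — the
rate ratio is the quantity this style of analysis reports as "OR". The
classical odds ratio is also returned. The chi-square uses the 2×2 layout
$(k, n-k)$ with Yates continuity correction, which constrains it to
at-most-one-event-per-individual counts ($k \le n$); per-child counts that
exceed group sizes are compared with `mwu_counts()` instead.

`mwu_counts()` uses the normal approximation with tie-corrected variance
and *no* continuity correction (two-sided $p = 2\Phi(-|Z|)$), with the sign
convention probands-minus-siblings. Bonferroni adjustment spans all strata
tested in one run; the family size is recorded alongside the result.

`discovery_curve()` reduces both pangenome scaling curves to per-locus
first-carrier indices: the cumulative nonredundant count at panel size $k$
and each child's rare-pool size after filtering against the first $k$
controls. Monotonicity (non-decreasing discovery, non-increasing rare
pools) is structural in this formulation, and the test suite verifies the
curves against brute-force union recomputation at every prefix.

## Sex-chromosome statistics

`window_coverage()` partitions a chromosome into 1 Mbp windows and
qualifies a window when the union of contig alignment blocks covers ≥ 95 %
of its unmasked length with ≤ 3 distinct overlapping contigs. Two readings
of the contig condition are possible (disqualify the window, or drop
contigs); the package disqualifies the window, since the statistic is a
property of windows. Coverage uses the union of aligned blocks, not contig
spans with internal gaps. Windows fully inside the exclusion mask (PARs,
centromere, Yq12-like heterochromatin) leave the denominator.

`methylation_skew()` averages per-CpG methylated fractions per haplotype
over each CpG island ± 5 kbp flank; islands with no covered CpGs on either
haplotype are flagged and excluded from chromosome summaries. `xci_call()`
declares skewed X inactivation when the mean haplotype difference reaches
0.25 with ≥ 80 % of islands agreeing in direction — the source analyses are
qualitative here, so both numbers are explicit, configurable package
defaults rather than published constants.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; everything derives from one
seed, and identical configurations produce byte-identical outputs.

* **Allele-frequency spectrum**: Beta(0.15, 3). No spectrum is published
  for this setting; these values were chosen analytically so that, at the
  default scale (100 controls, 5,000 loci), roughly 99 % of a child's
  *common* SVs match the panel and ~96–97 % of the child's total pool is
  filtered once planted rare events are included — the filtering fraction
  the analysis design anticipates. It is a calibration of realism, not a
  test target.
* **Sizes**: 0.5·Normal(300, 50) + 0.1·Normal(6000, 800) +
  0.4·LogNormal(log 500, 1), clamped to [50, 50000] bp — the two
  retrotransposon modes with a log-normal background; the mode positions
  are fixed by biology, the weights are free choices.
* **Families**: four quads and two trios with mixed child sexes; probands
  affected, siblings not; family-level superpopulation with an AFR allele
  frequency boost (×1.5) so AFR genomes carry more SVs.
* **Planted events** (defaults): 2 de novo and 5 private-inherited SVs per
  child, 3 biparental-homozygous SVs cohort-wide, all on autosomes, placed
  on grid positions no panel locus occupies. In quads, the carrier parent's
  other child is forced to the reference allele at private loci (and to het
  at biparental loci), so planted per-child counts are exactly recoverable.
* **Realized ledger**: the ground truth records *realized* classes — a
  panel locus that happens to end up with exactly one carrier parent
  cohort-wide and no control carrier genuinely is private-inherited in the
  realized cohort and is labelled so. Recovery tests therefore compare the
  pipeline to what is true, not merely to what was planted.
* **Jitter and divergence**: per-caller breakpoint jitter is
  Normal(0, 30 bp) truncated at ±⌊(refdist−1)/2⌋ = ±249 bp. The truncation
  is half the single-call bound one might naively use, because matches are
  *pairwise*: two independently jittered representations must stay within
  `refdist` of each other. The same argument halves the per-representation
  substitution budget to (1−pctseq)/2; configurations violating either
  bound are rejected at construction. Distinct loci sit ≥ 2 kbp apart on
  the placement grid, so jitter can never alias two different alleles.
* **Error channels**: per-caller detection sensitivity (defaults: assembly
  1.0, each aligner 0.8 — making ~96 % of assembly calls validate, the
  $1-(1-0.8)^2$ closed form); an optional genotype-error channel that swaps
  carried diploid genotypes het↔hom-alt with the configured probability.
  The swap channel was chosen because its effect on trio concordance is
  computable by exact enumeration over Hardy–Weinberg trio configurations,
  giving the test suite an independent closed form.
* **Read support**: Poisson(λ_carrier = 10) for carrier parents,
  Poisson(λ_noise = 0) otherwise — so true de novo events have exactly zero
  parental support unless noise is configured.

What the generator does **not** emulate: sequencing reads, assembly,
repeat-aware sequence context (TR loci are a ledger flag, with uniform
random nucleotide sequences), breakpoint microhomology, caller-specific
error signatures, population structure beyond the two-way AFR/non-AFR
split, and de novo events on sex chromosomes. Passing tests demonstrate
that the *logic* of filtering, classification, curation and statistics is
correct under the stated stochastic model — they do not measure caller
accuracy or breakpoint precision on real genomes.

## Scale and numerical choices

Desk-scale defaults (5,000 panel loci, 100 controls, six families) run the
full pipeline in well under a minute and make exhaustive oracles feasible:
quadratic interval scans, transitive-closure clustering on ≤ 200 calls,
per-base window-coverage recomputation, exact Mann–Whitney enumeration at
n ≤ 8. The published cohort-scale figures (tens of thousands of SVs per
genome, hundreds of thousands of nonredundant loci) derive from
restricted-access data and are emulated in structure, not magnitude; the
generator's scale is a configuration choice.

Degenerate inputs are defined behaviour: an empty control panel filters
nothing and warns prominently; an empty assembly callset validates to an
empty set; a chromosome with no assessable windows is an error; ties in
representative selection break deterministically. The methylation
simulator clips fractions to [0, 1], which biases extreme-skew means
toward zero when per-CpG noise is large relative to the clipping headroom;
recovery tests keep noise small enough that the unclipped standard error
is the correct yardstick.

## Known limitations

* Only DEL and INS are modelled end to end; other SV classes are rejected
  at parse time.
* The callable-region score is a fixed logistic stand-in with documented
  weights, not a trained model; its threshold semantics (0.5) are
  preserved but its discrimination on real alignments is untested.
* Greedy collapse is order-dependent by design; no optimal clustering is
  attempted.
* The rate-ratio chi-square requires at-most-one-event-per-individual
  counts; large-count strata must use the Mann–Whitney path.
* X-inactivation direction assumes the more-methylated CpG-island
  haplotype is the inactive one and that haplotype-to-parent assignment is
  provided by the caller.
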