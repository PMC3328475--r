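---
title: "Bulk segregant analysis of reduced-representation libraries: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk segregant analysis of reduced-representation libraries: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rrlbsa` turns a classical QTL-mapping shortcut — bulk segregant analysis
(BSA) of a reduced-representation library (RRL) — into a tested pipeline.
This vignette records the models behind each stage, the parameters that
matter, the numerical conventions, and the choices made where the design
was genuinely open. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## The experimental model

An F2 population from a biparental cross segregates 1:2:1 at every locus.
If one major locus controls the trait, individuals in the extreme
phenotypic tails are nearly all homozygous for the corresponding allele, so
a pool ("bulk") of tail individuals is close to monomorphic at the locus
and at everything tightly linked to it, while remaining a 50/50 allele
mixture everywhere unlinked. Sequencing both bulks over the same genomic
subset and testing, site by site, whether the two pools' allele counts
differ is therefore a genome-wide linkage scan with two libraries.

The RRL provides the "same genomic subset": a complete restriction digest
followed by a 450–550 bp size selection yields a reproducible ~10% of the
genome, sequenced as 90 bp single-end tags that start at fragment ends and
hence begin with the enzyme's residual tag (`CT` for AluI `AG^CT`).

## Phenotype index and bulk construction

The shattering-resistance index of an individual is
`SSRI = 1 − Σxᵢ/(N·P)` over `N = 10` replicates of `P = 20` pods, `xᵢ`
broken pods per replicate; repeated assays of one individual are averaged.
The printed form of the source assay is an unrendered expression in the
literature this package follows; this is the unique simple form consistent
with the reported parental values (0.94 resistant, 0.06 susceptible), and
it is the package's definition.

Segregation at one major locus is checked by classifying the index at
caller-supplied boundaries (default 0.30/0.70, suited to class modes near
0.06/0.50/0.94 — in practice the antimodes of the observed distribution)
and testing the three class counts against 1:2:1 (Pearson chi-square,
2 df, via `chisq.test`).

Bulks take the `bulk_size` (default 10) *most extreme* individuals whose
index strictly clears the cut (default < 0.10 susceptible, > 0.90
resistant), not all qualifying individuals; ties break on individual id so
the assignment is order-independent. Requiring both the cut and the count
fails loudly (`insufficient extremes`) when a tail is too thin, rather
than silently relaxing the design.

## Digestion and enzyme survey

Digestion is complete: every site occurrence (including overlapping ones)
is cut at `match_start + cut_offset`. Sites are matched on the forward
strand; all four shipped enzymes have palindromic sites, making this
equivalent to double-strand recognition (non-palindromic sites warn).
Recognition sites may carry IUPAC ambiguity codes because one of the four
screened blunt cutters (RseI, `CAYNN^NNRTG`) requires them; ambiguity
codes act as wildcards, while `N` in the *genome* never matches, so
unsequenced regions produce no spurious cuts. Coordinates are 0-based
half-open everywhere internally; only the TSV/VCF exports are 1-based.

The survey statistic is the representation fraction — selected-fragment
bases over genome bases — plus a 50 bp-binned size histogram and, when a
repeat mask (BED) is supplied, the masked share of selected bases. The
mask is caller-supplied because no masking procedure is prescribed by the
design itself.

## The synthetic study

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| population | 276 F2 | the motivating study's population size |
| phenotype class means | 0.06 / 0.50 / 0.94 | parental indices, midparent heterozygote |
| phenotype sd | 0.08 | keeps the three modes separated but overlapping at the boundaries, giving realistic (>90%) but imperfect bulk purity |
| bulks | 10 + 10, cuts 0.10/0.90 | the published bulk design |
| enzyme, window | AluI, 450–550 bp | the selected library design |
| site spacing | 256 bp | the expected spacing of a 4-base cutter in random sequence; puts ~10% of genome bases into the selection window, matching the published representation |
| genome | 3 × 900 kb | desk-scale stand-in for a 790 Mb genome; large enough for ~600 selectable fragments |
| markers | 600 | desk-scale compression of tens of thousands of genome-wide simple SNPs: enough informative sites per chromosome that the cluster scan has material to work with |
| reads | 90 bp, Phred+33, Q30 constant | single-end tag sequencing; only the QC threshold, not the error profile, is prescribed, so constant quality with an optional per-position profile |
| base error | 0.002 | Q27-ish effective accuracy, era-appropriate |
| depth | 20× per bulk (default); 30× in the acceptance studies | 20-fold mirrors the published coverage; the acceptance studies pair 30× with the −log10 p > 16 threshold because a fully differentiated 2×2 table cannot exceed that bar below ~60 combined reads (see below) |
| map scale | 250 kb/cM | configurable; at 900 kb per chromosome this makes each chromosome a tightly linked block, which is what concentrates associated SNPs on the QTL chromosome |

Chromosomes are built as random sequence with recognition sites planted at
approximately exponential spacing and accidental occurrences scrubbed, so
the digest of the reference is exactly the planted fragmentation. Markers
(biallelic, parent-1 allele = reference base) are planted only in the
*read-accessible* footprint of size-selected fragments — the first and
last `read_length` bases, since reads start flush at fragment ends — and
away from recognition sites, so no substitution can create or destroy a
cut site. One marker coincides with the QTL. Because of this placement
rule every haplotype digests identically to the reference, and bulk reads
are fragment-end windows with the member haplotype's alleles substituted,
then uniformly errored. Reads are drawn from either fragment end with
equal probability and reverse-end reads are emitted reverse-complemented,
so all reads begin with the residual tag. `target_depth` is defined over
the read-accessible footprint.

Meiosis follows the Haldane map (no interference): recombination
probability `(1 − e^(−2d/100))/2` between markers `d` cM apart, one
Markov pass per gamete. The no-QTL null (`qtl_effect = FALSE`) draws the
phenotype from an *independent* 1:2:1 class indicator, preserving the
three-peak phenotype distribution and the bulk-construction mechanics
while making bulks uninformative about every locus.

What the generator deliberately does not emulate: allopolyploidy and
homeologous cross-mapping (the real crop is an AACC allotetraploid; here a
single diploid genome, with homeology handled only by the multi-hit
discard rule), indels, PCR duplicates, GC or fragment-length sequencing
bias, and positionally varying error rates. Passing tests therefore show
the method's behavior under clean diploid conditions, not robustness to
those real-data complications.

## Read QC

Filters run tag-then-quality, with counts reported at each stage in the
style of a library-accounting table. "Average base quality ≥ 25" is the
arithmetic mean of integer Phred scores (the simplest reading), inclusive
at the boundary; Phred+64 input is accepted behind an explicit flag. The
quality filter runs pre-placement; the alternative order is not
distinguishable from the published accounting, and pre-placement is the
cheaper and more conservative choice.

## Placement

The engine is exact full-length matching (via Biostrings `PDict`) on both
strands, reverse hits normalized to forward coordinates; `hit_count` is
the number of distinct genomic positions (a palindromic read matching one
position on both strands counts it once). Unique hits are kept; multi-hit
reads are discarded; reads with more than `repeat_threshold = 100` hits
are additionally flagged as repetitive contaminants. A read carrying any
base-call error matches nowhere and is simply unmapped — the expected loss
is `1 − (1 − e)^L` (≈ 16% at e = 0.002, L = 90), and the read-accounting
report makes it visible.

Exact matching alone, however, would also reject every read that shows a
*true* non-reference allele, which would make between-bulk SNP discovery
structurally impossible — the aligner it stands in for tolerated
mismatches. The index therefore accepts an optional panel of parental
haplotypes (the reference plus a copy with known second-parent alleles
substituted); a read matches a genomic position if it matches either
haplotype sequence there, and hits are deduplicated by position. This
keeps placement conservative for errors while making planted variation
mappable. For real data with an arbitrary aligner, `read_sam_placements()`
imports SAM with documented keep rules (mapped, primary, MAPQ > 0) and
restores as-sequenced orientation so pileups behave identically.

## SNP calling and the Fisher exact test

Pileups tally reference-oriented read bases per bulk at every covered
position. A position is a *simple SNP* candidate when (i) both bulks have
depth ≥ 4; (ii) the two most frequent alleles jointly carry ≥ 90% of all
reads (the remainder is treated as sequencing noise and dropped from the
2×2 table); and (iii) the two bulks' allele frequencies differ. The
(depth 4, purity 90%) operationalization is this package's: it is chosen
so that error-free simulated data recovers every planted inter-parent SNP
covered at depth ≥ 4 in both bulks, and both knobs are exposed.

The association score is the two-sided Fisher exact p-value by the
minimum-likelihood rule: sum the hypergeometric probabilities of all
tables with the observed margins whose probability does not exceed the
observed table's, with relative tolerance 1e-7 on the comparison so exact
ties survive floating-point rounding. Probabilities are accumulated in
log space (`dhyper(log = TRUE)` + log-sum-exp), so −log10 p is accurate
far below double underflow of naive summation. Degenerate tables (a zero
row or column margin) return p = 1 by convention. The unit tests verify
the implementation against `stats::fisher.test`, and the acceptance suite
against an exhaustive exact-rational enumeration over all 2×2 tables with
margins ≤ 30.

Association uses raw p-values with a *strict* −log10 p > 16 cut, plus a
reported 2/5/10/16 threshold ladder; no multiple-testing correction is
applied, matching the thresholding practice the pipeline reproduces. The
exact test makes the depth–significance tradeoff sharp: a fully
differentiated site needs roughly 60 combined reads before −log10 p can
exceed 16 (29 + 30 passes; 28 + 28 does not). This is why the acceptance
studies pair bulks-of-10 with 30× per-bulk raw depth: after the ~16%
exact-match error loss, informative sites sit near the boundary and a
few dozen markers per chromosome clear it.

## Cluster scan

The tight-cluster judgement is formalized as an anchored sliding window:
a window of `window_bp = 400000` starting at each associated SNP; windows
holding ≥ `min_count = 5` SNPs qualify; overlapping qualifying windows on
a chromosome merge; each merged cluster reports the minimal span of its
member SNPs (the span convention of "14 SNPs within 396 kb"), its SNP
count and its share of all associated SNPs, ranked by count. The defaults
are calibrated so a 14-SNP/396-kb configuration is detected.

One subtlety: with window merging, "raising `min_count` never increases
the cluster count" is *false* in general — removing a middle qualifying
window can split one merged cluster into two. The guaranteed monotone
quantity is the number of qualifying anchor windows, and that is what the
property tests assert; the scan itself is verified against a brute-force
O(n²) enumeration.

## Statistical limitations

The Fisher test treats the two bulks' reads as independent draws from the
bulk allele frequencies. They are not: each bulk contains only
`2 × bulk_size = 20` haplotypes, so at any locus unlinked to the trait the
bulk's true allele frequency already drifts around 1/2 with standard
deviation `sqrt(0.25/20) ≈ 0.11` before a single read is sequenced, and
this drift is shared across all linked markers on a chromosome. The
pooled-count test is therefore overdispersed and anti-conservative at
moderate nominal levels: under the package's own no-QTL simulation, several
percent of candidate sites reach p < 0.01, well above the nominal rate,
and the excess varies strongly between seeds because chromosome-level
drift is correlated. The extreme −log10 p > 16 threshold is what keeps
the *associated-SNP* list clean despite this: drift alone cannot fix a
20-haplotype bulk (probability ~2·10⁻⁶ per site), and the null arm of the
acceptance study reports no clusters. Users lowering the threshold toward
conventional significance levels should expect drift-driven false
positives, or model the bulk size explicitly (beyond this package's
scope).

Other limitations: no genotype-likelihood model, no indel calling, no
base-quality recalibration; the internal mapper does no gapped or
mismatch alignment (use SAM import for that); the variance explained by a
detected QTL is not estimated.

## Problem sizes

The shipped tests and the acceptance script run the full design at a
3 × 900 kb genome, 276 individuals, ~46,800 raw reads per study arm
(30× per-bulk over a ~105 kb accessible footprint), 20 seeds per study
arm, plus an exhaustive 164,176-table Fisher cross-validation — sizes
chosen so the whole battery runs in minutes on one CPU while every stage
operates far from trivial regimes.
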