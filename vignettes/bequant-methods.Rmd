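---
title: "Quantifying base-editor outcomes from amplicon sequencing: methods and design"
author: "bequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying base-editor outcomes from amplicon sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bequant)
```

# The measurement problem

Cytidine base editors (CBEs) convert C•G to T•A and adenine base editors
(ABEs) convert A•T to G•C within a window of the 20-nt protospacer matched
by the sgRNA. Positions are numbered 1–20 from the PAM-distal end, with the
PAM trinucleotide counted as positions 21–23. Canonical CBEs edit
efficiently at positions 4–8 and ABE7.10-class editors at positions 4–7;
conversions elsewhere in the protospacer are out-of-window (bystander)
edits, and they are what separates an allele that is *perfectly* corrected
from one that is merely *edited*.

Amplicon deep sequencing is the standard readout: a locus is PCR-amplified,
sequenced as overlapping paired-end reads, and each read pair is reduced to
a per-position observation of the protospacer. The quantities this package
computes from such data are:

* the **editing frequency** $f(p)$ — the fraction of quality-passing base
  calls at protospacer position $p$ that carry the intended product base
  (T for CBE, G for ABE), computed only at positions whose reference base
  is editable;
* the **indel frequency** — reads containing at least one inserted or
  deleted nucleotide whose footprint intersects protospacer positions 1–20,
  divided by total accepted reads;
* the **inhibition rate** at position $p$ between a control and an
  inhibitor-treated condition,
  $$\mathrm{IR}(p) = 1 - \frac{f_{\text{treated}}(p)}{f_{\text{control}}(p)},$$
  clamped to $[0,1]$ for reporting (raw values retained);
* the **selectivity fold** — the ratio of mean IR over out-of-window
  positions to mean IR over on-target positions, with a two-tailed
  equal-variance Student's *t* test between the two groups of per-position
  IR values;
* **allele-level classes** — every fully observed protospacer sequence is
  classified as `unedited`, `perfect` (the intended conversion at every
  intended position and nothing else), `imperfect_edit`, or `indel_allele`,
  and summarized as perfect-of-total, edited-of-total and
  perfect-of-edited fractions.

The motivating use case is the evaluation of editing-window modulators such
as the phage-derived SpCas9 inhibitor peptide G8P_PD, whose hallmark is a
much stronger attenuation of out-of-window than on-target editing: a
selectivity fold well above 1 and a rise in the perfectly edited fraction.

# Pipeline stages and their assumptions

## Consensus merging

Read pairs are merged into a single consensus when the best-scoring
ungapped overlap (score = matches − mismatches) is at least
`min_overlap = 11` bp with a mismatch fraction at most
`max_mismatch_frac = 0.1`. At agreeing overlap columns the consensus Phred
is the maximum of the two calls capped at 41; at disagreeing columns the
higher-quality base wins and the consensus Phred is the difference of the
two. The 11-bp floor is the conventional minimum for trusting an overlap;
the mismatch tolerance and the quality arithmetic are the standard consensus
rules used by common mergers, made explicit here because they decide which
bases survive the downstream Phred-30 mask. Pairs with no qualifying
overlap are flagged and excluded downstream rather than guessed at.

Adapter trimming is deliberately out of scope: the package expects
insert-only (pre-trimmed) FASTQ, as produced by any standard trimmer, and
its simulator emits insert-only reads. A length-sanity guard (reads shorter
than `min_overlap` never merge) protects against degenerate input.

## Targeted alignment

Each consensus read is aligned to its amplicon reference with affine-gap
scoring — match +2, mismatch −4, gap open −6, gap extend −1, so a length-$k$
gap costs $6 + k$ — global in the read and local in the amplicon. Both
orientations are tried and the better kept. The alignment engine is
`Biostrings::pairwiseAlignment()`; the test suite holds its scores equal to
an independently written exhaustive dynamic-programming oracle over
hundreds of randomized pairs, so the engine is verified rather than trusted.

Single-amplicon data have no meaningful mapping quality (every read maps to
the one reference), so the usual mapping-quality filter is replaced by an
**alignment identity gate**: reads whose matching columns divided by total
alignment columns fall below `min_identity = 0.7` are rejected and counted.
This plays the role of a minimum mapping/alignment-quality threshold in a
multi-reference setting.

## Per-position counting

For every protospacer position 1–20 (always expressed on the protospacer
strand, whichever amplicon strand was sequenced), accepted reads contribute
one of: a base call (A/C/G/T), a deletion, or a masked observation. Calls
with Phred below `min_base_qual = 30` and all N calls are masked — the
analog of a base-quality floor of 30 in standard per-position counters.
Reads whose alignment does not cover a position count as masked there, so
the per-position counts always sum to the number of accepted reads (a
conservation invariant asserted throughout the test suite). Insertions are
attributed to the gap immediately 3′ of the preceding position on the
protospacer strand — a deterministic bookkeeping convention, since an
insertion lives between positions.

Frequencies use **position-specific denominators** (total − masked −
deletions at that position) rather than one global denominator, because
masking varies by position. An editable position with a zero denominator is
reported as undefined, never as 0. Positions whose reference base is not
editable are not applicable and carry `NA`.

## Inhibition rates and the window contrast

IR is computed per matched control/treated pair of profiles, only where the
control frequency is at least `min_control_freq = 0.005`: below half a
percent the ratio estimator is dominated by sampling noise and a masked
cell is more honest than a wild number. Raw (possibly negative) IR values
are kept for diagnostics; reported values are clamped to $[0,1]$, matching
the semantics of an inhibition heat map. IR is a ratio of frequencies, so
it is invariant to uniform coverage rescaling, and it is strictly
decreasing in the treated frequency at fixed control — both held as
property tests.

The selectivity fold is defined as the **ratio of group means** of IR
(out-of-window over on-target), pooled across replicate pairs and sites
when several are supplied. A means-of-ratios alternative is computable from
the long-format heat-map table, but ratio-of-pooled-means is the simplest
statistic consistent with reporting a single "X-fold selectivity". The
group comparison uses the pooled-variance Student's *t* test (two-sided),
with Welch's form available behind `var_equal = FALSE`; identical constant
groups return $t = 0$, $p = 1$ rather than an error.

## Allele classification

Allele identity requires full, confident observation: reads that do not
cover the whole quantification region (default positions 1–20; PAM and
flanks excluded, configurable) or that carry any masked base inside it are
dropped from allele calling — though they still contribute to the
per-position matrices, which have per-position denominators. "Perfect"
demands the intended conversion at every intended position, zero other
substitutions and zero indels in the region; a non-intended product at an
intended position (e.g. C→G) is imperfect, not perfect. Indel alleles
outrank substitution patterns. These four classes partition the called
reads exactly, and the classifier is held equal to a brute-force
rule-evaluation oracle over all ~32,000 alleles with up to three
substitutions of the built-in fixture protospacer.

## Sample-level QC

Samples can be dropped by an accepted-read floor (`min_reads`). There is no
meaningful universal default — required depth depends on the frequencies of
interest — so the filter defaults to disabled (0) and is fully
configurable; a floor of a few hundred to a few thousand reads is typical
for amplicon experiments.

# The synthetic-data generator

Every stage above is testable without downloads because the package ships a
generator whose truth is known exactly:

* **Editing model.** Each editable position converts independently with a
  window-shaped probability vector (presets peak at 0.30–0.45 inside
  positions 4–8 and stay at or below 0.1–0.15 outside, an A3A-like shape).
  An optional Gaussian-copula correlation couples edits within a read
  (shared editing propensity) while preserving marginals exactly;
  independence is the default because no co-editing model is implied by
  per-position frequencies alone, and the knob exists to probe the
  robustness of allele-level summaries.
* **Inhibitor model.** The treated condition multiplies each position's
  probability by $1 - \text{inhibition}(p)$. The `focused_inhibitor`
  preset sets inhibition 0.1 on-target and 0.9 out-of-window, so the truth
  selectivity fold is exactly 9 by construction.
* **Indels.** One indel per affected read at rate `indel_rate`, uniform
  over protospacer positions, insertion or deletion with equal probability,
  lengths 1–3 (0.6/0.3/0.1).
* **Reads.** Each pair covers the full amplicon (R2 reverse-complemented),
  guaranteeing the configured overlap; per-base miscalls at
  `seq_error_rate` (default 0.2%, Illumina-like); Phred scores from a
  truncated normal with mean 35 and SD 3, deliberately leaving a tail below
  the Phred-30 mask so the masking path is exercised. Output is
  byte-identical under a fixed seed.

What the generator does **not** emulate: PCR and sequencing-cycle error
profiles (errors are i.i.d. uniform over substitutions, with quality
independent of error status), adapter read-through, chimeric reads, large
structural events, strand-specific damage, and coverage heterogeneity.
Passing tests therefore demonstrate that the pipeline's estimators are
correct and calibrated under a clean generative model — not that real
libraries are free of artifacts upstream of it.

# Numerical choices and problem sizes

Validation runs at fixed sizes chosen to make the checks sharp:

* zero-noise identity at coverage 2,000 with error, indels and quality
  dispersion all zero (a degenerate quality distribution is part of "zero
  noise": random sub-Phred-30 masking would otherwise subset reads and
  break exact equality);
* frequency recovery over truth grids {0.05, 0.2, 0.5, 0.8} at coverage
  5,000 with 0.5% error, 20 seeded runs, requiring ≥95% of editable
  positions within 3 binomial SDs;
* selectivity recovery on the `focused_inhibitor` preset at 25,000 reads
  per condition. The coverage is a power choice: the fold's relative
  sampling error is dominated by the small on-target IRs in the
  denominator and decays as $1/\sqrt{n}$, sitting near 5% at 25,000 reads —
  comfortably inside the 20% recovery band while staying realistic for
  amplicon sequencing depth;
* exhaustive classifier agreement over all 32,551 alleles with ≤3
  substitutions; aligner-oracle score equality over 500 randomized pairs
  up to 150 nt; closed-form perfect-allele expectation
  ($0.4 \times 0.8 = 0.32$) at $n = 10{,}000$.

Seeds: a simulation config's single seed fixes everything; the control and
treated conditions and the read-generation stage use distinct sub-seeds
derived from it (offsets, kept below $2^{31}$), so pools and reads are
independently reproducible.

# Known limitations

* The aligner is targeted, not a general mapper: reads from other loci are
  only rejected by the identity gate, not recognized.
* Insertions adjacent to the region boundary are attributed by the 3′
  convention and can be invisible to allele calling when they fall wholly
  outside positions 1–20.
* The selectivity fold is undefined (reported `NA`) when on-target
  inhibition is exactly zero while out-of-window inhibition is not; when
  neither group shows any inhibition the fold is reported as 1.
* No multiple-testing correction across sites is applied; reported
  *p*-values are per-comparison, matching the single-contrast use case.
* Embryo-style analyses (per-blastocyst allele fractions) are served by the
  per-sample allele tables; no mosaicism model or allele-frequency cutoff
  for calling a sample "perfectly edited" is imposed — the fractions are
  exposed and the cutoff left to the analyst.

# Reproducing the validation numbers

`scripts/acceptance.R --seed <int> --out <path>` re-runs the full
validation from scratch — simulating, running the pipeline, and measuring
recovery — and writes the quantities above as JSON. The test suite
(`testthat`) holds the same properties as assertions, at the same sizes.
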