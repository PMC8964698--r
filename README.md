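# bequant — base-editing outcome quantification from amplicon sequencing

`bequant` quantifies CRISPR base-editor outcomes from paired-end amplicon
deep sequencing. It is written for experiments that ask not only *how much*
a cytidine or adenine base editor (CBE/ABE) edits, but *where in the
protospacer* it edits and *how cleanly*: per-position conversion
frequencies across the 20-nt protospacer (PAM counted as positions 21–23),
indel frequencies, the position-indexed inhibition rate between a control
and an inhibitor-treated condition, the on-target versus out-of-window
selectivity contrast, and allele-level classification of perfectly edited
outcomes. Its motivating application is the evaluation of editing-window
modulators — e.g. the phage-derived SpCas9 inhibitor peptide G8P_PD, which
preferentially suppresses out-of-window editing and thereby raises the
fraction of perfectly corrected alleles.

## The statistics at the core

For protospacer position `p` with editable reference base (C for CBE, A
for ABE), the editing frequency is

    f(p) = (intended product base calls at p) / (quality-passing calls at p)

with per-position denominators (total accepted reads minus masked minus
deletion-spanning calls; Phred < 30 and N calls are masked). Between
conditions the inhibition rate is

    IR(p) = 1 − f_treated(p) / f_control(p),   defined where f_control(p) ≥ 0.005,

clamped to [0, 1] for reporting. With the canonical editing window (4–8 for
CBE, 4–7 for ABE) partitioning positions 1–20, the selectivity fold is

    fold = mean IR(out-of-window) / mean IR(on-target)

compared by a two-tailed equal-variance Student's t test. At the allele
level, every fully observed protospacer sequence is classified as
`unedited`, `perfect` (intended conversion at every intended position and
nothing else), `imperfect_edit`, or `indel_allele`; indel frequency counts
reads with ≥ 1 inserted/deleted nucleotide intersecting positions 1–20 over
total accepted reads.

Upstream, read pairs are merged into quality-aware consensus reads
(ungapped overlap ≥ 11 bp, higher-quality base wins at disagreements) and
aligned to the amplicon with affine-gap scoring (match +2, mismatch −4, gap
open −6, extend −1), global in the read and local in the amplicon.

A synthetic-data module (`sim_config`, `simulate_allele_pool`,
`pool_to_fastq`, `scenario_presets`) generates truth-known allele pools and
paired FASTQ with window-shaped editing probabilities, an inhibitor
attenuation vector, low-rate indels and Illumina-like base-call errors, so
every pipeline stage can be validated against exact truth.

## Worked example

Simulate a control/treated pair for the built-in target under a focused
inhibitor (truth: inhibition 0.1 on-target, 0.9 out-of-window, i.e. a
construction selectivity fold of 9), then run the full pipeline:

```r
library(bequant)

tg <- example_target()
tg
#> <amplicon_target> example_CBE (CBE, strand +)
#>   amplicon: 120 nt; protospacer window at offset 30; PAM CGG
#>   protospacer: CAGCTCACGACTGATCGATA
#>   intended positions: 6

cfg <- scenario_presets(seed = 1)$focused_inhibitor$config
cfg$coverage <- 4000L
sim <- run_simulate(cfg, out_dir = tempdir())

ctl <- quantify_sample(path_r1 = sim$control$r1, path_r2 = sim$control$r2,
                       target = tg, label = "control")
trt <- quantify_sample(path_r1 = sim$treated$r1, path_r2 = sim$treated$r2,
                       target = tg, label = "treated")
ctl
#> <sample_quant> control: parsed 4000 -> merged 4000 -> aligned 4000 -> accepted 4000
#>   protospacer indel frequency: 0.0055
ctl$profile
#> <editing_profile> target example_CBE (CBE), sample control
#>   6 editable positions; frequencies: p1=0.157 p4=0.353 p6=0.451 p8=0.299 p11=0.118 p16=0.094

ir <- inhibition_rate(ctl$profile, trt$profile)
comp <- window_comparison(ir, window_partition("CBE"))
comp
#> <window_comparison>
#>   mean IR on-target    : 0.0879 (n = 3)
#>   mean IR out-of-window: 0.8943 (n = 3)
#>   selectivity fold (out/on): 10.18
#>   Student's t = 38.228, two-sided p = 2.8e-06
```

The recovered fold (10.2 here, at 4,000 reads per condition) estimates the
constructed truth of 9: the inhibitor suppresses out-of-window editing ten
times more strongly than on-target editing, and the contrast between the
two groups of per-position inhibition rates is highly significant. Allele
tables make the precision gain explicit:

```r
s <- perfect_edit_summary(call_alleles(ctl$alignments, tg),
                          call_alleles(trt$alignments, tg))
#> perfect-of-total: control 0.136 -> treated 0.180 (fold 1.3)
```

For real data, describe targets and samples in one YAML (see
`?read_run_config`) and use `run_quantify()`, `run_compare()` and
`run_alleles()`, which write per-sample conversion TSVs, inhibition
heat-map tables and window-comparison/allele-summary JSONs. A thin
command-line wrapper lives at `inst/scripts/bequant.R`
(`simulate | quantify | compare | alleles`). A 60-pair demo FASTQ pair and
a target config ship under `inst/extdata/`.

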