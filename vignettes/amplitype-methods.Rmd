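---
title: "Methods: mismatch-minimising HLA-B typing from noisy long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mismatch-minimising HLA-B typing from noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

HLA-B is the most polymorphic gene in the human genome; clinically relevant
alleles (B\*57:01 for abacavir hypersensitivity, B\*58:01 for
allopurinol-induced severe cutaneous reactions, B\*15:02 for
carbamazepine-induced SJS/TEN) differ from their neighbours by a handful of
nucleotides in exons 2 and 3, the exons encoding the peptide-binding groove.
A single long amplicon spanning both exons, sequenced on a nanopore device,
covers every informative position in one molecule and so phases the two
haplotypes directly — at the price of a per-base error rate around 7%,
dominated by deletions. This package implements the complete desk-scale
pipeline around that trade-off: reference handling, read simulation,
demultiplexing, quality filtering, genotyping, and cohort statistics.

## The typing model

For a sample's read set $R$ and a candidate allele pair $(a, b)$ the engine
computes:

1. **Read assignment.** Each read is assigned to the pair member with the
   smaller semi-global edit distance; equidistant reads are *unassignable*
   (they count toward depth but not consensus — assigning them to both would
   double-count shared-haplotype reads). For a self-pair $(a,a)$ every read
   belongs to the single member.
2. **Per-member consensus.** Each read's alignment projects onto allele
   columns; per column the majority among $\{A, C, G, T, \text{gap}\}$ wins,
   exact ties resolve to the reference base, a gap majority deletes the
   column, and an insertion is kept only when more than half of the reads
   carry it at that junction.
3. **Mismatch count.** The pair's score is the number of
   consensus-vs-reference edits restricted to exon 2+3 columns, summed over
   both members. Intron differences are reported but never scored, because
   alleles sharing exon 2+3 sequence (a G-group) are not distinguishable at
   the resolution this assay claims.
4. **Ranking.** All unordered pairs over a vote-based shortlist (self-pairs
   included) are ranked by total mismatches ascending, then balanced read
   support (the smaller member's read count; all reads for a self-pair)
   descending, then pair name. The top pair is the call; co-ranked distinct
   pairs raise the ambiguity flag; a nonzero best total marks the call for
   manual review and ships the full ranked list.

```{r}
library(amplitype)
alleles <- synthetic_allele_set(n = 8, seed = 42)
barcodes <- synthetic_barcodes(8, seed = 7)
cohort <- make_cohort(alleles, 8, barcodes, seed = 1)
run <- simulate_run(cohort, alleles, barcodes, depth = 80, seed = 2)
reads_s1 <- run$reads[run$truth$sample_id == "S01", ]
call <- call_genotype(reads_s1, alleles, build_ggroups(alleles),
                      sample_id = "S01")
tidy(call)   # ranked pair list
glance(call) # one-row summary
```

### Two guards that make the score identifiable

Pure majority-vote consensus cannot distinguish a heterozygote from either
homozygote: under the self-pair hypothesis $(a,a)$ on truly heterozygous
data, every informative column splits close to 50/50 and the majority is a
coin flip shared across all columns (votes are read-level correlated). Two
explicit guards close this gap:

* **Heterozygosity guard.** A consensus column that matches the reference
  but carries a strong minority vote is an *unexplained polymorphism* under
  the pair hypothesis and counts as one mismatch. Two clauses: minority
  fraction ≥ 0.3 with ≥ 5 minority reads (well-covered members), or
  minority fraction ≥ 0.4 with ≥ 2 reads (so a 50/50 split is caught even at
  minimal depth). The thresholds sit well above the per-column noise floor
  (≈ 3.5% gap votes, ≈ 1% per alternative base at the default error model)
  and well below the ≈ 50% signal of a genuine second haplotype; the count
  floors keep one or two coincident errors at low depth from firing the
  guard.
* **Dropout guard.** A pair whose minor member attracts fewer than 20% of
  the assignable reads (`minor_fraction`) is demoted to the homozygous pair
  of the majority member: low-input samples can lose one allele during
  amplification, and a spurious low-support heterozygous pair must not
  outrank the homozygote it mimics.

### Alignment

All distances are unit-cost semi-global edit distances computed in C++ with
the *allele anchored*: the allele amplicon aligns end to end while the
read's flanks (adapter and barcode remnants) overhang free. Amplicon reads
span the full allele by construction, so anchoring the allele is exact for
this design and avoids the degeneracy of a both-ends-free minimal edit
distance (which is zero on an empty overlap). Traceback ties prefer match >
substitution > deletion > insertion, so indel placement inside repeats is
deterministic (gaps pile on one canonical column — which is also what makes
repeat artifacts visible to the consensus rather than smeared). Reads are
auto-oriented by aligning each read and its reverse complement to a probe
allele.

### Repeat artifacts and masked rescoring

Nanopore deletion errors concentrate in short tandem repeats. In the
(GA)₃ tract at exon 2 nucleotides ~128–137, a G at the heterozygous site at
nucleotide 133 extends a G-run and roughly triples the local deletion rate;
deterministic gap placement then accumulates those deletions on one column,
and the carrier member's consensus either deletes the column or trips the
heterozygosity guard. The call is still correct but arrives flagged with a
nonzero total. `find_hotspots()` reports mismatch positions recurring in at
least half of the top five pairs (1-based, exon-local), labelling positions
inside the repeat mask as repeat-associated; `rescore_masked()` recomputes
pair scores with masked exon columns excluded, and `adjudicate_call()`
re-ranks the top pairs on masked totals — the automated counterpart of
manually accepting the least-mismatch pair after discounting the known
artifact tract.

```{r}
alleles <- synthetic_allele_set(n = 6, seed = 42, ga_carrier = 2)
mask <- str_mask(alleles)
run <- simulate_run(cohort, alleles, barcodes, depth = 100, seed = 3,
                    use_str_mask = TRUE)
call <- call_genotype(run$reads, alleles, repeat_mask = mask)
call$hotspots
adjudicate_call(call, run$reads, alleles, mask)
```

## The read simulator

The simulator emulates the study conditions this pipeline targets:
49-sample multiplexed runs of a 943 bp exon 2+3 amplicon, barcoded to
1,063 bp (24 bp barcodes inside 36 bp adapters per side), diploid samples,
per-sample depth skew, and an R9-era 2D error profile.

* **Error model.** Per template base one multinomial draw: deletion with
  `p_del` = 3.5%, substitution with `p_sub` = 2.8% (uniform over the three
  alternatives), else the correct base; an independent uniform-base
  insertion follows each position with `p_ins` = 1.0%. The published
  profile pins the total (7.3%) and the deletion component (3.5%); the
  substitution/insertion split is this package's choice, weighted toward
  substitutions as the larger residual component. The multinomial
  formulation makes the configured rates exactly the per-template-base
  event rates, which is what the calibration tests measure.
* **Repeat boost.** Inside annotated STR intervals `p_del` is multiplied by
  `repeat_del_multiplier` (default 3). The source observations are
  qualitative (deletions concentrate in the tract); 3× is the package's
  default and reliably reproduces the flag-and-rescue behaviour above at
  depth ~100.
* **Qualities.** Per-read mean quality ~ Normal(12, 3) truncated to
  [2, 30], emitted as a flat quality string. This is phenomenological —
  only mean-Q filtering consumes qualities; no per-base signal model is
  implied.
* **Depth.** Fixed depth, explicit per-sample depths, or
  `depth_lognormal()` (floored log-normal) to emulate the order-of-magnitude
  per-sample skew seen in multiplexed runs.
* **Reproducibility.** One RNG stream seeded once per run; identical seeds
  give byte-identical FASTQ output.

What the simulator does *not* model: signal-level behaviour, chimeric PCR
products, sample cross-contamination, strand-asymmetric error profiles, or
basecaller-specific quality/error correlations. Passing the recovery tests
therefore demonstrates the engine's correctness under a calibrated,
deletion-dominant, repeat-aware error process — not performance on any
particular real flow cell.

## Measuring error rates

`measure_error_rates()` re-aligns each simulated read globally to its
template and counts events per template base — the same protocol used to
estimate platform error rates from amplicon data, and what
`scripts/acceptance.R` recomputes. Minimal-edit re-alignment merges an
occasional adjacent insertion+deletion into one substitution, so measured
totals sit a few percent (relative) below the generating rates; the
calibration tests therefore check the simulator's event counts against the
configured rates with binomial tolerances, while the reported measurement
uses the alignment protocol.

## Demultiplexing

Each barcode and its reverse complement is aligned semi-globally into the
first and last 150 bases of the read (window default: total tails are
≤ 120 bp, plus slack for leading insertions). A read is classified when its
best barcode scores at most `max_edits` (default 25% of barcode length) and
leads the runner-up by `min_margin` (default 2); both-end matches to
different barcodes are unclassified. With the symmetric double-end layout
(forward barcode left, reverse-complement right) both strands present
identical barcode evidence, so strand inference belongs to the asymmetric
adapters (`trim_tails()`), not the demultiplexer.

## Quality filtering

Mean read quality averages error *probabilities* (the nanopore pass/fail
convention), not Phred scores: a read of half Q10 / half Q20 bases scores
12.60, not 15. The default length window is 80%–125% of the expected
amplicon. The simulator's quality stand-in means Q-threshold pass fractions
are not calibrated to any real run; the filter is exposed both before and
after demultiplexing and the typing tests run on unfiltered reads.

## Cohort statistics

Allele frequencies are reported under two denominators: per chromosome
(2 × samples; sums to 1; the default) and per distinct allele — the
denominator under which the source cohort's percentages were published
(top allele 11/38 = 28.95%), retained for comparability and labelled as
such. Risk screening matches at the risk entry's own field resolution,
ignoring suffixes and G flags (B\*57:01:01G carries B\*57:01). The
Māori/Pacific subset of the shipped fixture is defined by the `PI_`
sample-id prefix; ancestry-fraction strings are informational.

## Problem sizes and numerical choices

The test suite and acceptance checks run at desk scale, chosen as the
smallest sizes at which each property is statistically meaningful:
calibration over ≥ 10⁵ simulated bases (3 binomial SEs), genotype recovery
over 50 samples at depth 80 (the minimum viable depth demonstrated by the
source study) with 8 fixture alleles at pairwise exon distance ≥ 6,
demultiplexing fidelity over ~1,000 reads and 12 barcodes, and oracle
equivalence of the aligner on 1,000 random pairs against an independent
quadratic DP. Fixture alleles are deterministic given a seed; the (GA)₃
tract, exon layout (270 bp exon 2, 276 bp exon 3 inside 943 bp), primer
footprints and barcode geometry are fixed by construction.

Open choices resolved here (and why): exon coordinates ride in a sidecar
TSV rather than an annotated flat-file parser (format-light; real IMGT
import is a conversion step, not a core dependency); G-group names are
derived as numerically-smallest-member, three fields, plus `G`, with
registry names accepted from input metadata when present; all internal
coordinates are 0-based half-open with 1-based exon-local reporting;
`in_silico_pcr` returns the shortest product when degenerate primers admit
several (spurious distal sites); `min_depth` defaults to 20 as a floor with
an explicit override.

## Known limitations

* Genotyping resolution is bounded by exons 2+3: alleles within one G-group
  are inherently interchangeable in a call (reported under the group name).
* The engine assumes a two-haplotype mixture; contamination or chimeras are
  out of model.
* Hotspot coordinates are exon-local and assume locus-wide exon alignment
  (true for the fixture set and for HLA-B's near-constant exon lengths);
  indel-divergent references would need a liftover.
* `score_pair` on a pair whose members differ at a single masked or
  repeat-degraded site may be unresolvable by design; the ambiguity flag,
  not a forced call, is the intended output.
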