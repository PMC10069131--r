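---
title: "Calling transposable element insertions and their allele frequencies from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transposable element insertions and their allele frequencies from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telltale)
library(dplyr)
```

## The problem

Transposable elements (TEs) are mobile DNA sequences whose new insertions
segregate in populations at every frequency, from fixed to private. In a
pooled long-read sequencing experiment (say, 100 flies sequenced together),
a single genome assembly can only represent the **major haplotype**: a TE
insertion carried by most of the pool ends up in the assembly, while an
insertion carried by a few haplotypes does not. `telltale` therefore splits
detection into two complementary tracks:

* **insider** calls — insertions (and deletions) present in the sample
  assembly but absent from the reference, recovered by parsing a
  whole-genome pairwise alignment of the two assemblies;
* **outsider** calls — low-frequency insertions absent from the assembly,
  recovered from reads that map back to that assembly with large insertion
  operations or long soft-clipped ends.

Both tracks share one annotation engine, and every call can then be
decorated with a target-site duplication (TSD) and an allele-frequency
estimate.

## Detection model

**Insider track.** The contig-to-reference alignment is scanned for two
signal classes: `I`/`D` CIGAR operations of at least `min_te_len` (200 bp)
inside one alignment, and length discrepancies between consecutive anchor
alignments of the same contig (anchors are alignments with >= 10 kb aligned
or the contig's primary alignment; events whose anchors overlap on the
other genome are classed as tandem expansions/contractions). Insertion
sequences are retrieved from the assembly, deletion sequences from the
reference, and each candidate between 200 bp and 15 kb is annotated against
the TE library.

**Outsider track.** Primary read alignments contribute raw signals:
insertion operations >= 30 bp (with their inserted sequence) and terminal
soft clips >= 200 bp (anchored at the clip boundary). Signals within a
30 bp window of a growing cluster's median position merge into one
candidate insertion; the cluster's position is the member median, and its
support is the set of distinct reads. One informative read is enough — a
single long read carrying a full TE plus flanks identifies an insertion
unambiguously — though `min_support` can raise the floor.

**Annotation and the 80/80 rule.** Candidates are compared to the TE
consensus library with BLASTN (the standard nucleotide local-alignment
tool for this task; `blastn`/`makeblastdb` must be on the PATH). A
candidate is annotated as family *F* when its percent identity is at least
80 and at least 80% of the *consensus length* is covered — coverage is
deliberately measured on the consensus, not the candidate, so that a
candidate embedded in extra sequence still annotates cleanly. Collinear
fragment hits are grouped (gap tolerance 100 bp on candidate and consensus,
small relative to the 200 bp minimum TE length) and their coverages
unioned. Both thresholds are configurable; dropping coverage to 10% recovers
5'-truncated or internally deleted copies at a specificity cost.

One deliberate design choice: for outsider clusters the 80/80 filter is
applied to the **pooled evidence of the whole cluster** (union of consensus
coverage across the member reads of one family), not to each read alone. At
low carrier depth, a long TE is often sampled only by a 5'-clipped read and
a 3'-clipped read, neither of which alone covers 80% of the consensus
although together they plainly do. The reported representative read is
still the single member with the highest alignment score, and the highest
scoring family labels the call (ties: higher coverage, then family name, so
output is deterministic). When several families pass, the alternatives are
counted in `n_alt_families`.

## Target site duplications

TE integration through staggered double-strand breaks duplicates a short
target motif on both sides of the new insertion. `find_tsd()` compares the
30 bp flanks of the two junctions: the 5' flank should *end* with the motif
and the 3' flank should *start* with it. Exact search uses Boyer-Moore
(bad-character plus strong good-suffix rules, implemented in the package);
read-derived (outsider) junctions tolerate one mismatch, via a
Hamming-distance scan on top — mismatches only, no indels, since an indel
inside a 4-6 bp motif is indistinguishable from a different motif.
Assembly-derived (insider) junctions are compared exactly.

Numerical choices: motifs shorter than 2 bp are noise and never reported;
occurrences more than 2 bp from a junction (inclusive tolerance — exactly
2 bp passes) are rejected as pre-existing duplications, and the search is
restricted to that neighbourhood so an unrelated longer repeat elsewhere in
the flanks cannot shadow a genuine at-junction duplication; ties between
equal-length motifs resolve to the smallest summed junction offset, then
leftmost. For outsider calls the motif must additionally occur exactly once
in the +/- 30 bp empty-site window of the assembly. A retained TSD moves
the call's junctions onto the motif boundaries — never by more than the
flank width, in practice by at most the 2 bp tolerance.

## Allele frequency

The estimate is `supporting / spanning_total`, clamped to [0, 1]. The
denominator is the rounded mean per-base depth of the two 30 bp windows
flanking the junctions (secondary/supplementary records excluded), the
long-read analogue of counting reads that span the site either with or
without the TE.

The numerator differs by track:

* **Insider.** Reads overlapping the call +/- 100 bp are fetched. A read
  supports the insertion when it *cleanly* covers a junction +/- 5 bp — no
  clip boundary and no structural-size (>= 30 bp) indel inside that window;
  1 bp sequencing-error indels do not disqualify. Non-carrier reads either
  clip at the junction or jump the TE with a TE-sized deletion, so they are
  excluded automatically. The count is the rounded mean over the two
  junctions. Counting per junction rather than requiring a read to span the
  entire TE interval keeps the estimator unbiased for TEs long relative to
  the read length; with interval spanning, a 10 kb TE under 20 kb reads
  would lose most of its genuine carriers and the estimate would shrink
  with TE length.
* **Outsider.** Reads near the call are fetched and terminal clips abutting
  the insertion point are rewritten as insertion operations of the TE
  length plus 10 bp (sequence padded with `N` at quality 8), so that
  clipped carriers and full-insertion carriers look alike; signals are then
  re-collected and re-clustered, and the cluster at the call position is
  counted — a read contributing both a clip and an insertion op counts
  once. Carriers are tallied per flank side (a read must cover that side's
  depth window) and averaged, mirroring the denominator; without this, a
  read that merely grazes the TE would count against both windows and
  inflate the estimate by roughly (1 + TE length / read length).

Deletion calls receive no frequency: reads cannot "support" an absence the
same way, and no defensible procedure presents itself. A zero denominator
reports an absent (`NA`) frequency with a warning rather than a number.

## The synthetic benchmark

`simulate_te_benchmark()` reproduces the three-pool simulation design this
class of caller is usually validated on:

1. a random base genome (GC 0.42 by default, uniform composition);
2. an "assembly" haplotype carrying the **insider** insertions — by default
   100 of them (5 each for ZAM and gtwin, 10 each for nine further
   families);
3. a third haplotype carrying 1000 additional **outsider** insertions
   (200/200 for ZAM and gtwin, 50 for eight families, 100 for gypsy and
   Idefix) on top of the insider ones.

Reads are drawn from the three haplotypes at a 10x/45x/5x depth mix (60x
total), so each insertion's population frequency is set purely by depth
ratios: insiders ride in pools 2+3 (50/60 ~ 0.83), outsiders only in pool 3
(5/60 ~ 0.083). Molecules start uniformly along the contig (overhanging
molecules are truncated at the contig bounds, so nominal depth holds
uniformly rather than piling up mid-contig). Read lengths are lognormal
with mean 20 kb and sdlog 0.6 —
long-read libraries are strongly right-skewed, and the heavy tail is what
lets single reads span multi-kilobase TEs. Errors follow a parametric
model: per-base rate (default 5%, 0 for oracle tests) split 40/30/30 into
substitutions, insertions and deletions. Planted insertions get a 4-6 bp
TSD (typical of LTR retroelements), random strand, and uniform positions at
least 2 kb from contig ends and 1 kb apart.

The generator emits ground-truth alignments instead of running an external
aligner: every read is aligned to the assembly haplotype with an exact
CIGAR, in which outsider insertions appear as `I` operations or terminal
clips exactly as a mapper would report them, and assembly-private
insertions appear as `D` operations in base-pool reads. Reads falling
wholly inside a non-assembly insertion are emitted as unmapped. This is
what lets the detection and frequency modules be tested deterministically
and offline.

What the simulation does **not** emulate — and hence what passing tests do
not show about real data: realistic nanopore error structure (homopolymer
compression, basecaller quality strings), chimeric reads, genuine genomic
repeat landscapes (the base genome is random sequence, so there are no
pre-existing TE copies or segmental duplications to confuse annotation),
diverged TE copies (planted copies match their consensus exactly up to read
error), and real aligner behaviour at junctions. Results on real genomes
will be less clean, particularly the false-positive rate in repeat-rich
regions.

## Scoring

`benchmark_calls()` matches truth events to calls greedily, nearest first,
within a 30 bp tolerance (the same anchor window used for clustering; the
tolerance is a knob since no canonical value exists), requiring family
agreement for a true positive by default (`strict`); position-only matches
are tallied as `mislabeled`. Sensitivity is TP/(TP+FN), the false-positive
fraction FP/(TP+FP). Matching is 1-to-1 and deterministic under input
reordering.

## Problem sizes and run times

The package's own checks run the full design at desk scale, chosen so a
laptop reproduces them in minutes: the benchmark proper on a 2 Mb genome
with 10 insider + 100 outsider insertions at the 10x/45x/5x mix and 2%
read error; frequency recovery additionally at outsider fractions 0.2 and
0.33 on a 1 Mb genome with 50 outsider events; the full 100/1000 planting
recipe is exercised on a 20 Mb genome without read simulation. Event counts
scale with `scale_recipe()` by largest-remainder apportionment so totals
stay exact.

## Known limitations

* Fully unmapped reads are searched against the library and logged, but
  produce no positioned call — nothing anchors them to a locus.
* Clip-only outsider clusters see only one junction in the best read, so
  they get no TSD and their size is estimated from the matched consensus
  span.
* Tandem/repeat SV subclasses are detected and labelled but not treated
  differently downstream.
* The insider denominator uses flank depth; a retained-read-count
  denominator is a plausible alternative the interface could grow.
* Frequencies at very low depth are systematically underestimated (a read
  pool that thin simply misses carriers), and estimates below ~10% carrier
  fraction carry large relative error.

## A worked run

```{r run, eval = FALSE}
run <- run_te_pipeline(
  scale_recipe(simulation_recipe(seed = 1, error_rate = 0.02), 0.1))
print(run)
glance(run)
autoplot(run$scores$combined)
plot_frequency_recovery(run$outsider,
                        filter(run$sim$truth, class_label == "OUTSIDER"))
```
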