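---
title: "End-guided transcript assembly: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-guided transcript assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endguide)
```

## The model

`endguide` treats transcript assembly as a path problem whose boundary
conditions come from the reads themselves. Template-switching protocols
attach a known oligo to cDNA 5′ ends and prime cDNA synthesis from the
poly(A) tail, so after trimming (`label_reads()`) every read is annotated
as carrying a 5′ label, a 3′ label, or none. After alignment, a label is
*confirmed* only if the soft-clipped terminal sequence is consistent with
untemplated adapter leftovers; a confirmed 5′ label whose clip ends in at
least one untemplated G adjacent to the aligned start is promoted to a Cap
Tag, because template switching adds extra guanosines specifically at
7-methylguanosine caps. Start/Cap Tags, End Tags, splice junctions, mate
gaps and the sample of origin are all that assembly needs; reads are
stored in that reduced form (the ELR text format).

Assembly then runs per locus:

* **Tag Clustering.** Tag positions are scored as
  `signal = w · (w / c)` where `w` is the (Cap-bonused) tag weight at the
  position and `c` the read coverage there. Positions with `w < f·c` are
  discarded (`f` = `min_proportion`, default 0.02), survivors within
  `cluster_distance` merge into clusters with a summit at the maximal
  signal (ties leftmost). The normalization by *local read coverage*
  rather than by the locus tag pool is a deliberate reading of
  "proportion of total coverage": it keeps minor TSSs inside
  well-expressed genes detectable, where pool-relative scoring
  quadratically favors the dominant site and erases every other one.
* **Frags and Membership.** Cluster summits and coverage-filtered splice
  sites partition the locus; each read's membership over the frags
  records what it supports (+1), what it is incompatible with (−1: a
  spanned intron, anything upstream of its Start-Tag cluster or
  downstream of its End-Tag cluster, the wrong strand's virtual frags)
  and what it does not speak to (0). Terminal partial overlaps below
  `min_overhang` count as 0, and the bases counted for element weight
  are exactly the bases inside member frags, which makes
  `sum(weight × length)` an invariant of all later reductions.
* **Overlap graph.** Support-set logic defines the pair codes; identical
  supports merge, non-branching corridors collapse (a pure optimization
  — see below), and contained elements pass their bases to their
  containers proportionally to container weight, *unless* all containers
  jointly exclude evidence the contained element is compatible with — in
  that case the element stays, because it may be the only witness of an
  isoform combination the containers rule out.
* **Greedy paths.** Seeds are the heaviest unassigned elements;
  extensions must preserve source/sink reachability and maximize the
  equal combination of (a) candidate weight relative to the best
  candidate, (b) cosine similarity of per-sample coverage between path
  and candidate, and (c) `1/(1+CV)` of the per-frag coverage after the
  extension. Term (b) is the mechanism that pairs the right TSS with the
  right PAS when several isoforms share internal structure: isoform
  usage varies across samples, and elements of the same isoform co-vary.
  A finished path takes its bottleneck (minimum per-frag) coverage,
  which is subtracted from its constituents so shared exons can support
  several isoforms.

Three bookkeeping rules around the greedy loop deserve explanation
because the design space was genuinely open:

* **Absorption.** After a path is emitted, every element whose support
  lies inside the path's (hole-filled) support and does not contradict
  it is marked *explained*. Explained elements no longer count as
  unassigned signal and cannot seed new paths — otherwise leftover
  fragments of already-explained isoforms recombine into chimeric
  TSS-of-A/PAS-of-B models — but they remain usable as constituents of
  later paths, since their residual coverage is real.
* **Anchored seeding.** Iteration normally stops when unassigned weight
  falls below `min_proportion` of the locus, but elements that carry end
  evidence (a Start or End virtual frag) may seed even below that
  threshold: every boundary cluster that survived tag filtering deserves
  an explanation attempt. Unanchored residue below the threshold is
  noise by definition and is left unassigned.
* **Parsimony pruning.** A finished path all of whose elements are fully
  explained by other emitted paths is dropped: it carries no unique
  evidence and merely recombines theirs. End-labeled elements always
  conflict with any path crossing their excluded flanks, so a genuine
  alternative-end isoform can never be pruned this way.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `max_gap` | 50 | nt | locus chunking gap; also default tag cluster distance |
| `min_cov` | 2 | × | minimum assigned coverage of an emitted model |
| `min_len` | 60 | nt | minimum emitted model length |
| `min_proportion` | 0.02 | — | signal floor: tag positions, junctions, path share, greedy stop |
| `min_overhang` | 3 | nt | minimum aligned overlap for frag membership / junction flanks |
| `cap_bonus` | 5 | × | Cap Tag weight multiplier in tag clustering |
| `cap_filter` | 0.02 | — | minimum capped fraction for a capped TSS |
| `require_cap` | off | — | complete models must start at a capped TSS |
| `discard_incomplete` | on | — | drop paths lacking either end anchor (off in `condense()`) |

Label detection defaults follow the short-read protocol settings:
adapters `AAGCAGTGGTATCAACGCAGAGTAC GGG` (TSO) and
`AAGCAGTGGTATCAACGCAGAGTAC T×20+` (oligo-dT), `min_start` 7,
`min_end` 9, `mismatch_rate` 0.06, `minlen` 18, `minqual` 25 (mean),
`qualmask` 16 (bases below it match anything). The `+` suffix marks the
homopolymer as greedily extendable. The A-rich mispriming filter uses a
20 nt window and 12 sense-strand A's by default; the thresholds are
exposed because the phenomenon, not the cutoff, is the established fact.

## What the simulator emulates — and what it does not

`simulate_locus()` builds genes of 4–7 exons with canonical `GT..AG`
splice motifs and isoform variations (exon skipping, alternative TSS at
an exon start or mid-exon, alternative PAS), assigns each isoform
10–60× coverage with log-normal (sd 0.4) variation across 3 samples by
default, and keeps 20 nt downstream of every true PAS A-poor so genuine
ends never look misprimed. `simulate_reads()` fragments transcripts
uniformly (clipped-normal length, mean 220, sd 50, range 90–400 nt),
attaches labels at configurable rates, jitters uncapped label positions
by 0–3 nt downstream (mode at the true site; capped/uuG reads are exact,
which is the biological reason Cap Tags are the most precise TSS
evidence), and injects read-through and oligo-dT mispriming artifacts on
request. Genomic motifs that a read-level detector cannot distinguish
from real adapters (the TSO 3′ end, ≥8 nt A/T homopolymers) are masked
out of the simulated genome, so the truth table stays well defined: a
simulated read is labeled iff an adapter was attached.

The simulator does not model indel sequencing errors for short reads,
quality-score distributions, PCR duplication, multimapping, or
expression-level biological covariance beyond the per-sample log-normal
factor. Passing tests therefore demonstrate the correctness of the
*algorithmic* pipeline under realistic geometry and signal levels, not
robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

Ties are broken deterministically everywhere: cluster summits leftmost,
greedy candidates by leftmost support column then element index, seeds by
`which.max` (first index). Coordinates are 0-based half-open internally
and 1-based inclusive in GTF. ELR weights are written in the shortest
decimal form that parses back to the identical double, so round trips
are bit-exact. Empty inputs (no reads, no tags, no junctions) yield
empty—but well-formed—results at every stage. Unstranded elements can
join stranded paths but can never touch source or sink, and a path that
never acquires a strand is not reported.

## Known limitations

* Fragment-scale phasing limits: when an exon is longer than the
  fragment length, no read pairs the features on its two sides, so
  nested combinations of alternative ends and skipping events are not
  always identifiable. The assembler resolves such forks with the
  coverage-similarity and smoothness terms and refuses to emit
  evidence-free recombinations (parsimony pruning), at the cost of
  occasionally omitting a true "combination" isoform whose every read is
  also consistent with other isoforms. On the simulator's study
  conditions (50 loci, 2–6 isoforms, 10–60×, ≥5% label rates) this
  leaves end-to-end exact recovery around 88–92% depending on the random
  draw, with zero-to-one structurally false models; the misses
  concentrate in minor isoforms whose label signal sits at the
  2% detection floor and in non-identifiable full-length variants.
* Assigned coverages are bottleneck estimates after proportional
  containment redistribution; they rank isoforms correctly but are not
  an EM-grade quantification (deliberately out of scope).
* Containment redistribution is single-pass in increasing information
  content; a fixpoint iteration would differ only when containers are
  themselves contained, which the identical-support merge largely
  removes.
* The ELR dialect is this package's own loss-free text serialization of
  the end-labeled read abstraction; it is not a compatibility target for
  any external tool.

## Problem sizes used in the shipped checks

The test-suite and `scripts/acceptance.R` use 50-locus recovery panels,
100-fixture conservation/invariance sweeps, 200 (tests; 100 in the
script) small-graph oracle comparisons, 10-locus mispriming panels,
600-read label sets and 10,000-read serialization round trips; one
complete run of the acceptance script takes under two minutes on a
single CPU.
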