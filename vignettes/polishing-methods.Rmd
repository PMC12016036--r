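---
title: "Polishing HiFi assemblies without overcorrection: methods and design"
author: "hifipolish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polishing HiFi assemblies without overcorrection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A genome assembled from PacBio HiFi reads is accurate to roughly one
error in 10^4–10^6 bases, with the residue concentrated where the reads
themselves err: homopolymers and low-complexity tracts. Two properties
make these final errors hard to remove safely. First, a diploid sample
leaves heterozygous columns in the pileup wherever the assembly collapsed
both haplotypes into one sequence; a naive consensus happily "corrects"
the assembly's allele to the slightly better-covered allele of the other
haplotype, producing haplotype switch errors without changing — indeed
while *improving* — the K-mer-based QV. Second, near-identical repeat
copies attract each other's reads, and a consensus over mixed pileups
homogenises the copies. `hifipolish` addresses both: it detects exactly
the columns where the evidence is mixed, separates the reads responsible,
keeps one consistent group, and refuses to write any sequence the
sample's short reads cannot vouch for.

## The consensus model

The pileup stores, per read and reference column, one *allele*: a base,
`-` for a deleted column, or the anchor base concatenated with inserted
bases (insertions are attached to the left anchor, which keeps columns
indexable by reference position). The K-mer score chain (KSC) consensus
is a dynamic program over (position, allele) nodes:

* `score(P, a) = max_b [ score(P−1, b) + count(chain(b→a)) ] − depth(P)`,
  where the chain is the tuple of the last `chainK` alleles along `b`'s
  best path ending in `a`, and its count is the number of reads whose
  alleles match the whole tuple;
* a node at the first column scores its supporter count minus depth.

Each node remembers only the suffix of its own best path
(Viterbi-style); the exact DP over all `chainK`-tuples would multiply the
state space without changing behaviour on the depths this tool targets.
With `chainK = 3` the transition inspects 3-mers such as `CCC`, `-CC`,
`--C`. Chains reward reads that agree over consecutive columns, so
locally linked evidence (e.g. an indel plus its shifted neighbours)
outvotes columns considered independently; when errors are unlinked the
result reduces to the column-wise majority vote, a property the test
suite checks against a brute-force majority oracle on 50 random pileups.

Ties — between predecessors, and at the final column — prefer the allele
equal to the reference base, then the lexicographically smaller allele:
deterministic, and conservative toward the input assembly. Zero-coverage
columns emit the reference base, carry support 0, and are always flagged
low quality.

## Low-quality regions and K-mer validation

A traceback position whose chosen allele accounts for ≤ 95% of the
column's valid depth (inclusive boundary) is a low-quality position;
consecutive LQPs closer than the validation K (21) merge into a region.
Regions are *not* additionally padded: K-mer extraction pads by K − 1 on
each side, which already guarantees that every extracted K-mer overlaps a
low-quality column. Padding twice would dilute the region's K-mer set
with flanking K-mers common to both haplotypes and hide the very
disagreement the region marks — this single-padding rule is load-bearing
for conflict detection.

Reads spanning the padded window contribute their K-mers; K-mers absent
from the short-read database (canonical 21-mers counted from the sample's
accurate short reads, count ≥ 2 so that singleton sequencing errors drop
out) are discarded. A read whose window K-mers all validate contributes a
*version* of the region; a region with ≥ 2 distinct validated versions is
heterozygous — two haplotypes or repeat copies meet there. Counting
versions rather than raw valid K-mers matters: any window longer than K
holds ≥ 2 valid K-mers, so the raw count would mark every region
heterozygous.

## Phasing

For each heterozygous region and pair of spanning reads, the pair's
weight gains +1 per distinct shared valid K-mer and loses 1 per
rank-paired (i-th valid K-mer of each read within the window) K-mer on
which the reads differ; weights accumulate over regions. The exact
weight formula from K-mer counts is a design choice — unit contributions
keep the graph depth-robust; database counts are reserved for
residual-region resolution.

Louvain modularity optimisation (resolution 1, seeded) runs on the
positive-weight subgraph, since modularity is undefined with negative
weights; the negative weights then define *conflicts*: community pairs
whose total inter-community weight is negative, i.e. read groups
occupying the same loci with incompatible validated K-mers. Conflicts
are resolved most-negative-first. The default keeps the community whose
reads share the most K-mers with the reference sequence (each shared
K-mer counted once per read, so deeper communities are not penalised),
which preserves the haplotype the assembly already represents; `largest`
mode keeps the bigger community instead. Exact ties keep the community
containing the lexicographically smallest read id. All reads of losing
communities are dropped and the whole procedure — consensus, regions,
graph, Louvain — repeats, by default up to 5 iterations; in practice the
haplotype conflict resolves in the first round and later rounds retire
singleton error reads.

## Residual regions

Regions still low-quality after the final consensus pass are spliced
from the spanning-read window subsequences, validated K-mer by K-mer:

* no fully validated candidate → the input assembly's window is kept
  verbatim (`reference_kmer`): nothing unverifiable is written;
* one candidate → it is adopted (`majority`);
* several → ranked by supporting reads, then by the database count of the
  weakest constituent K-mer, then reference match, then lexicographic
  order (`best_count_kmer`).

Read support ranks first for a structural reason: a sequencing error in
a homopolymer run touching the window edge produces a candidate that is
a genuine genome substring — every one of its K-mers validates, and its
K-mer set is a subset of the correct candidate's, so no K-mer statistic
can reject it. Among equally supported candidates (the genuinely
ambiguous case) the database count decides. Overlapping residual windows
are merged before splicing, and a window replacement identical to the
reference is a no-op, not an edit.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 21 | validation K-mer length (bases); the conventional assembly-validation K |
| `minCount` | 2 | short-read count for a K-mer to be valid; drops singleton errors |
| `chainK` | 3 | chain-mer length (alleles) in the consensus DP |
| `lqpThreshold` | 0.95 | support fraction at or below which a position is low-quality |
| `mergeGap` | `k` | LQPs closer than this merge into one region (bases) |
| `pad` | 0 | extra region padding; extraction itself pads by `k − 1` |
| `minMapq` | 1 | drops MAPQ-0 multimappers at the parser |
| `mode` | `reference` | conflict resolution: reference-sharing or largest community |
| `maxIters` | 5 | phasing iteration budget |

## The simulator: what it emulates, and what it does not

`simulateDiploid()`/`simulateReads()` generate the study conditions the
tests run under: a random 100-kb diploid genome at 1% heterozygosity
(90% substitutions, 10% indels of 1–3 bp, ≥ 4 bp apart, away from repeat
copies and contig ends), optionally with near-identical repeat copies
carrying recorded diagnostic substitutions; 30× HiFi-like 10-kb reads
whose errors are substitutions at 0.1% outside homopolymers and 1-bp
indels at 10× that rate inside runs of ≥ 3 bases; and 50× accurate
150-bp short reads (0.1% substitutions). A random base sequence holds
about 16% of its bases in runs of ≥ 3, so the homopolymer regime is well
represented. Read starts are uniform on `[-(readLen−1), L−1]` and clipped
to the contig (minimum 100 bp emitted), which keeps coverage near-uniform
to the contig ends; `perturbAssembly()` injects ledgered substitutions
and 1–2 bp indels, 70% into homopolymer tracts, to create the draft the
polisher must fix.

The simulator emits the truth SAM itself, with CIGARs composed from the
haplotype variants, the inverse of the injected draft errors, and the
sequencing errors — against the *draft*, because after indel
perturbations the draft's coordinates differ from the truth's, and the
alignments must target the sequence being polished. No external aligner
is involved; any real SAM can be substituted. When repeat copies are
planted, a configurable fraction (default 20%) of reads lying fully
inside one copy is relocated to the homologous position of another copy,
emulating the one mapper failure mode that matters here; only contained
reads are relocated, because partially overlapping reads cannot be
reassigned without fabricating impossible alignments — the repeat test
scenario therefore uses 3-kb reads (the short end of a HiFi library)
against 5-kb copies so containment occurs.

What passing tests on these data do **not** show: robustness to real
mapper behaviour (soft-clipping around SVs, MAPQ miscalibration),
PCR/GC coverage bias, instrument-specific error spectra beyond the
homopolymer bias, heterozygous structural variation, and genomes whose
repeat families are much longer than the reads. The simulator is a
designed stand-in at desk scale, not a reproduction of any published
benchmark's construction.

## Numerical and degenerate-input choices

* QV ceilings: 99 for zero-error inputs of both QV estimators (finite
  reporting of a log of zero).
* PAF filtering removes records with coverage ≤ 0.90 **or** identity
  ≤ 0.98, both boundaries inclusive; coverage is block length over query
  length.
* Switch-error sites whose two haplotype K-mers are both present or both
  absent in the polished assembly are unassignable and excluded from
  adjacent pairs; one or zero assignable sites yields rate 0 with a
  `defined = FALSE` flag.
* A contig with zero coverage, or whose reads are all discarded, is
  returned unchanged with a warning.
* An empty K-mer database, a K-mer of the wrong length, or a pileup with
  no reads raise errors rather than guessing.
* All exported R interfaces use 1-based closed coordinates (GRanges
  convention); 0-based half-open appears only in BED output and inside
  the compiled code.

## Problem sizes

The unit tests run on 0.2–60 kb constructions; the whole-pipeline
acceptance checks and `scripts/acceptance.R` use 100-kb genomes at 30×
long-read and 50× short-read coverage — large enough that every pipeline
stage (hundreds of LQRs, hundreds of phased reads, ~10^3 heterozygous
sites) is exercised, small enough to run in minutes on one CPU. Sizes
are the package's chosen study conditions, fixed before the checks were
run, and the same seeds drive every source of randomness.

## Known limitations

* Phasing is local: read communities chain only across shared LQRs, so
  haplotype consistency is maintained per conflict neighbourhood, not
  chromosome-scale (no Hi-C or trio integration).
* The consensus DP's chain state is the predecessor's best path, not the
  full tuple space; adversarial pileups could exploit this, though HiFi
  depths do not.
* Residual windows longer than the read span fall back to the reference.
* The K-mer database is held in memory; for genomes beyond tens of
  megabases a disk-backed counter would be needed.
* `largest` mode can, by construction, switch the assembly toward the
  better-covered haplotype; it is provided for haplotype-resolved
  assemblies where the reference side is not privileged.
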