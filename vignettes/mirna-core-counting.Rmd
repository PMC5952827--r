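---
title: "Counting miRNA functional groups by exact core matching"
author: "miRcore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting miRNA functional groups by exact core matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRcore)
```

## The quantification model

miRcore assigns adapter-clipped small RNA-seq reads to *functional groups*
of miRNAs rather than to individual annotated miRNAs, and it does so by
exact substring matching against an end-trimmed *core region* of each
mature sequence.

The reasoning behind each half:

* **Core matching.** Mature miRNAs are short and the repertoire has low
  sequence complexity, so permissive (mismatch-tolerant) alignment lets
  non-miRNA reads and sequencing noise accrete onto miRNA counts. Exact
  matching of the miRNA *interior* is stringent where stringency helps —
  in the body of the molecule — while the trimmed ends leave room for the
  end variation that dominates real read populations: 5′/3′ isomiRs,
  imprecise Drosha/Dicer processing, and untemplated 3′ additions. The
  net behaviour is that end-shift isomiRs (within the trim widths) are
  merged with their parent miRNA, while polymorphic isomiRs — internal
  substitutions, which can have distinct targeting behaviour — fail the
  exact match and are discarded.
* **Group collapsing.** Identical or near-identical matures are
  transcribed from multiple loci. Counting each locus separately double
  counts every read from such a family, and because miRNA abundances are
  strongly right-skewed, a duplicated high-expression family can move the
  whole library total. Collapsing to a functional group and counting each
  read at most once per group removes this bias and returns counts at the
  unit most analyses actually care about (the family arm).

A read \(r\) matches group \(g\) iff \(\min \le |r| \le \max\) (read-length
gates) and some substring of \(r\) equals the core of some member of
\(g\). Matching is as-sequenced only — small RNA-seq protocols are
stranded, so no reverse-complement search is performed.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `trim5`, `trim3` | 2, 2 | nt | end trims defining the core; also the maximal absorbed end shift |
| `minCoreLen` | 16 | nt | shortest admissible core; shorter matures are excluded (warned) |
| `minReadLen`, `maxReadLen` | 16, 30 | nt | read-length gates; stop long fragments that happen to contain a core |
| `policy` | `all_groups` | — | cross-group handling of ambiguous reads |

The trim widths are a declared design choice: symmetric 2 nt trims absorb
the dominant ±1–2 nt end-variation classes while keeping ≥ 16 nt of exact
anchor for typical 19–23 nt matures (a 19 nt mature falls below the core
floor under 2+2 trims and is excluded — the conservative outcome for a
sequence that short). All values are exposed both in `coreParams()` and as
CLI flags.

**Ambiguity policy.** A read can match two distinct groups (e.g. identical
matures placed in different groups under the `none` scheme). The counting
rule "at most once per functional group" fixes within-group behaviour but
not cross-group behaviour, so the latter is an explicit option:
`all_groups` (default; add 1 to every matched group — the literal
once-per-group reading), `discard_ambiguous`, or `fractional` (1/k each).
The ambiguous-read tally is always reported, so users can see how much
the choice matters for their data.

## Grouping schemes

`buildGroups()` implements `none` (singletons), `mimat` (accession before
the first underscore — underscore suffixes mark duplicated-locus or
individualized variants of one accession), and `name` (family class +
core number + letter + 5p/3p arm, case-folding `mir`/`miR` and dropping
locus indices). Two decisions were genuinely open:

* the species prefix is dropped from name-based group ids, since grouping
  is meaningful within a single-species reference;
* names lacking an arm token group by (class, number, letter) alone, and
  unparseable names fall back to singleton groups with a warning rather
  than aborting — public databases contain irregular names and
  quantification must not die on them.

`N` bases are retained in sequences, but a core containing `N` can never
be matched (`N` equals no base) — conservative under ambiguity.

## The accuracy metric

The per-library estimate of miRNA input reads is the number of
adapter-clipped reads 19–23 nt long (inclusive); the canonical mature
length band. A method's accuracy over a cohort is the mean squared error
between these estimates and the method's total counts, reported ± 1 SEM.
Two choices are declared here for reproducibility: squared errors are
computed on **raw** counts (the comparison is absolute totals vs absolute
input estimates, so normalized counts would change the question), and the
SEM uses the sample (n−1) standard deviation of the squared errors, with
SEM undefined for a single library.

## What the simulator emulates — and what it does not

`simulateReference()` / `simulateReads()` generate:

* families named with the miRBase-like grammar and accessions with
  underscore suffixes, so the `name` and `mimat` schemes reconstruct the
  simulated families exactly;
* duplicated loci (probability `pDuplicateLocus`) with identical mature
  sequences;
* mature lengths uniform on 19–23 nt, matching the canonical band;
* right-skewed per-family abundances, log-normal with `meanlog = 3`,
  `sdlog = 1.5` on the natural-log scale (declared, not fitted — chosen to
  give a few dominant families and a long tail, the shape seen in real
  count distributions);
* per-read isomiR classes with defaults `frac3p = 0.25 > frac5p = 0.10 >
  fracPolymorphic = 0.05`, reflecting that 3′ isomiRs are the most common
  class; end shifts are deletions or untemplated extensions of up to
  `maxEndShift` nt, equally likely;
* background fragments with lengths drawn from a 16–30 nt mixture that
  puts most mass *outside* the 19–23 nt band (weights 3 : 1 : 3 for
  16–18 / 19–23 / 24–30 nt), so both the length filter and the matcher are
  exercised; `backgroundReadsForFraction()` solves for the background
  count that lands the in-band read fraction on a requested target;
* a flat per-base substitution error.

Three constructions make ground truth exact rather than probabilistic:
reference sequences are rejection-sampled so no family's core occurs
inside another family's mature sequence; random end extensions are
resampled if they would create a foreign core; and background reads (and
polymorphic substitutions) are resampled until they contain no reference
core at all. A read is labelled *countable* when its source miRNA has an
admissible core, its end deletions fit within the declared trims, its
length passes the read gates, and no sequencing error fell inside the
core — exactly the set an exact core matcher should count.

The simulator does **not** emulate adapter sequences or trimming
artefacts, realistic quality strings, platform-specific error profiles,
genomic cross-mapping (e.g. reads from other small RNA species that share
sequence with miRNAs), or expression correlation between family members.
Passing the exact-recovery tests therefore demonstrates that the
implementation counts what the method *defines* as countable — it does
not demonstrate that the method's totals are unbiased on real libraries,
where the definition itself (e.g. discarding polymorphic isomiRs) is part
of the modelling choice.

## Numerical and degenerate-input choices

* Output rows and group ids are sorted with C-locale (radix) ordering, so
  files are byte-deterministic across platforms and locales.
* Identical reads are deduplicated internally and matched once;
  observationally equivalent to per-read matching, and order-invariant.
* Fractional counts are printed to 6 decimal places; integer policies
  print integers.
* An empty library is a warning plus an all-zero dense table, not an
  error; an empty reference, a duplicate miRNA id, a malformed group-table
  row, and a group table that conflicts with itself are errors.
* Zero raw reads makes a library's ratio `NA`, not an exception.
* Seeded runs are byte-reproducible; the read generator offsets the seed
  so reference and reads use distinct streams.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations use cohorts of 20 libraries ×
50 families × 2,000 reads, and 10,000 randomized matcher-vs-oracle
instances across trim settings 0–3 — sizes chosen so the full suite
completes in about a minute while every code path (duplicated loci, all
three schemes, all isomiR classes, ambiguous reads, excluded short cores)
is exercised with comfortable margins.

## Known limitations

* The tool produces counts only: no normalization, differential
  expression, or novel-miRNA discovery.
* High stringency trades sensitivity for specificity: sequencing errors or
  genuine individual variation inside the core cause false-negative
  mappings.
* Matures shorter than `trim5 + trim3 + minCoreLen` are excluded from the
  index entirely; with the defaults this affects 19 nt matures.
* Group definitions are identifier-based (names/accessions) or
  user-supplied; no sequence-similarity clustering is performed.
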