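---
title: "Discriminative k-mer classification of long error-prone reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative k-mer classification of long error-prone reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dktax)
```

## Why approximate k-mer matching

Exact-k-mer classifiers assign reads by intersecting a read's k-mer set
with a reference index. That works when reads are accurate; it degrades
sharply on third-generation (Nanopore/PacBio) reads with 10–20% error.
Under independent per-base errors at rate $e$, a k-mer survives
error-free with probability $(1-e)^k$, so a read of length $L$ carries

$$\mathbb{E}[\text{exact }k\text{-mers}] = (L - k + 1)\,(1-e)^k$$

in expectation. At $L = 1000$, $k = 16$, $e = 0.15$:

```{r}
expected_exact_kmer_matches(1000, 16, 0.15)
```

Only ~7% of positions yield usable evidence. dktax's answer is to use
*long* k-mers ($k = 32$) for specificity, but to match them with an
explicit, bounded error tolerance so that most windows still produce
evidence at high error rates.

## The k-mer anatomy and the error budget

A 32-base k-mer is split into fields with different matching roles:

| field  | bases            | stored?            | comparison                      | tolerance |
|--------|------------------|--------------------|---------------------------------|-----------|
| PREFIX | 1 … n (n = 14)   | as the group index | exact (group lookup)            | 0         |
| middle | n+1 … 16         | no                 | none                            | free      |
| QM     | 17 … 16+m (m = 6)| in SUFFIX          | masked equality (seed masks)    | ≤ 1 sub   |
| DP     | 17+m … 32        | in SUFFIX          | banded edit distance            | ≤ 2 edits |

Only the group id (implicitly, by position in the index) and the 16-base
SUFFIX are stored per k-mer, alongside a taxid: 8 bytes per k-mer.

**QM matching.** The $m$ QM bases are packed 2 bits/base. For each of
the $m$ positions there is a *seed mask* that wildcards exactly that
position; two QM fields match when they compare equal under at least one
mask. This is an O(m) test that accepts exactly the pairs with Hamming
distance ≤ 1 — no indels, by design: an indel this early would shift the
whole SUFFIX frame and is better paid for in the DP field.

**DP matching.** The remaining $16-m$ bases are compared by edit-distance
dynamic programming restricted to a band of width 4 around the main
diagonal, with a cost cap of 2. We interpret "band width 4" as the
maximal frame shift of ±2, i.e. cells with $|i-j| \le 2$: any alignment
of cost ≤ 2 moves at most 2 cells off the diagonal, so this band is
exactly the region a within-budget alignment can visit, and the banded
decision provably equals the unbanded one at this cap. (A literal
4-diagonal band $\{-2,-1,0,+1\}$ would be asymmetric and could reject
alignments with two insertions that are within budget.) The query side
is aligned *prefix-free*: the alignment may consume up to 2 bases of the
read beyond the 32-base window, so deletions in the read do not push the
k-mer's tail out of reach.

**Middle bases.** The $16-n$ bases between PREFIX and SUFFIX are neither
stored nor compared. This is deliberate: they provide free error
tolerance (any corruption there is invisible) and halve storage. The
identity of a k-mer is therefore the pair (first $n$ bases, last 16
bases).

A window thus matches a stored k-mer under at most 1 + 2 = 3 errors in
the compared fields, plus anything in the middle. Worked example — one
QM substitution, one DP substitution and one DP deletion, accepted:

```{r}
match_kmer_detail("GCTTAACAACGTCGTTAAGCTCAATGTCATA",
                  "GCTTAACAACGTCGTTAAACTCAAATGTAATA",
                  codec_params(n = 14, m = 6))
```

## Building the discriminative database

`build_kmer_db()` runs four stages:

1. **Species collection.** Each species' genomes (and, by default, their
   reverse complements) are scanned with stride 1; windows containing
   ambiguous bases are skipped; the per-species k-mer set is
   deduplicated. K-merizing both strands at build time lets the
   classifier scan reads forward-only.
2. **Genus promotion.** A k-mer present in ≥ 2 species of one genus is
   reassigned to the genus taxid. These genus-level k-mers are treated as
   high priority: they always survive selection.
3. **Positional selection.** Species-unique k-mers are thinned to X%
   (default 15) by keeping window positions on a uniform stride of
   `round(100 / X)` (X = 15 → every 7th position, ≈ 14.3%). Positional
   (rather than hashed) selection keeps retained k-mers evenly spaced
   along genomes, so every read of reasonable length overlaps several.
   A k-mer is kept if *any* of its occurrences falls on the stride.
   Selection runs *after* genus resolution so thinning can never
   demote/destroy the evidence that two species share a k-mer.
4. **Cross-taxon removal.** Any k-mer still claimed by more than one
   taxid (i.e. across genera, or genus-vs-foreign-species) is removed
   outright rather than promoted to a higher LCA — k-mers that do not
   discriminate at genus level or below carry little ranking value and
   would bloat the index.

The database is serialized as a text JSON header plus three little-endian
`uint32` arrays: per-group sizes (4^n entries), suffixes, and taxids.
The group table costs $4 \cdot 4^n$ bytes, which is the reason the
*index* prefix length n trades memory for group occupancy: n = 14 (the
default, matching genome-scale use) needs 1 GiB; the examples and tests
here use n = 8–10.

## Classification and tie-breaking

Every valid 32-base window of a read (stride 1) is looked up in its
PREFIX group and the group's entries are probed linearly; the first
entry that matches under the error budget scores one hit for its taxid
(at most one hit per window). The read goes to the taxid with the most
hits, if that count reaches `min_hits` (default 1 — on long reads even a
single 32-base discriminative match is strong evidence, and the
evaluation layer exposes the precision cost of that choice). Ties are
broken toward the *deepest* tied taxon (prefer specific claims);
residual ties report the lowest common ancestor of the tied taxa, which
asserts only what the evidence supports.

## The simulator and what it does (not) model

`simulate_community()` builds a four-level taxonomy (root, family,
genera, species) over i.i.d.-uniform random genomes, planting within
each genus a shared block of `shared_fraction × genome_length` bases at
a random offset per species — this is what makes genus promotion and VP
(vague positive) behavior reachable in synthetic data. Strains are
copies with sparse substitutions.

`simulate_reads()` draws uniform start positions and applies independent
per-base errors at the model rate, split among substitution, insertion
and deletion by the `mix` knob (default (0.5, 0.25, 0.25), loosely
nanopore-like; matcher properties hold for any mix). Truth coordinates
are recorded 1-based on the forward strand. The simulator reproduces
error *rates* and length drift, not realistic error *structure*: no
homopolymer bias, no quality correlation along the read, no chimeras,
and genomes have no repeat structure or GC skew. Conclusions about
absolute accuracy on real data should not be drawn from it; it is built
for controlled, seeded experiments where the truth is known exactly.

## Evaluation

At a chosen rank (genus or species), each read is one of: **TP**
(assignment projects to the truth's taxon at that rank), **VP** (species
rank only: correct at genus but carrying no species information),
**FP** (conflicts with the truth's clade), **FN** (unclassified, or
assigned above the rank on the truth's own lineage), **TN**
(unclassified while the truth is absent from the database). Metrics:

$$\text{D-rate} = \frac{TP+FP+VP}{total},\quad
  SEN = \frac{TP}{TP+FP+VP+FN},\quad
  PRE = \frac{TP}{TP+FP},\quad
  F1 = \frac{2 \cdot SEN \cdot PRE}{SEN+PRE}.$$

Counting VP against sensitivity but not precision separates "wrong" from
"vague": a classifier that retreats to genus level loses SEN, not PRE.

## Numerical and implementation choices

- 2-bit base codes in the order A=0, C=1, G=2, T=3; group ids and
  suffixes are unsigned 32-bit values, carried in R as doubles (R has no
  native u32) and written little-endian.
- All randomness flows through R's RNG, including inside the compiled
  simulator loops, so `set.seed()` makes every pipeline stage
  reproducible end to end.
- Banded DP uses a cost cap with early row-abort; the classifier's inner
  loops are compiled, the orchestration is plain R.
- Lowercase input is upcased; IUPAC ambiguity codes make a window
  skipped, never an error, except that a sequence with *no* valid window
  is reported as empty input.

## Limitations

Beyond the simulator's realism limits above: the whole database lives in
memory; the linear probe within a group is O(group size) and relies on
discriminative thinning to keep groups small; reads shorter than 32
bases are rejected; and classification quality at species level depends
strongly on how much sequence genuinely distinguishes sibling species —
with heavily shared genomes the method by design retreats to genus-level
(VP) calls rather than guessing.
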