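---
title: "Fold-back artifact prediction and filtering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold-back artifact prediction and filtering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldback)
```

## The problem

Hybridization-capture deep sequencing panels report recurrent
low-allele-fraction SNVs and indels that are not present in the input
DNA. A large share of these calls sits inside naturally occurring
fold-back structures of the reference: imperfect **inverted repeat
sequences** (IVS) — two same-strand segments in which the downstream
*arm* is the reverse complement of the upstream arm, separated by a
*spacer* — and imperfect **palindromic sequences** (PS), whose two
halves are reverse complements around a central base. During library
preparation, fragmentation exposes partial single strands; a strand
whose end falls inside one arm can anneal to the partner arm of a
similar molecule (the PDSM mechanism: pairing of partial single strands
derived from a similar molecule). Exonuclease trimming and polymerase
fill-in then copy one arm onto the other. Wherever the two arms are not
perfectly complementary, the fill-in writes the *complement of the
partner arm's base* — a reproducible, sequence-programmed substitution
(or, at gapped positions, a small indel). The chimeric molecule also
carries a segment that aligns only as the reverse complement of nearby
reference, which an aligner soft-clips: artifact calls therefore
co-occur with soft-clipped reads.

The two fragmentation chemistries differ in when the error becomes
double-stranded. After sonication, the filled strand carries the induced
base while the template strand keeps the original: the repaired molecule
is a **heteroduplex**, and unbiased PCR propagates each strand into half
of the final molecules — so 50% of the chimeric reads from such a
template carry the mutation. Enzymatic fragmentation nicks inside the
palindrome and end repair fixes the induced base into both strands
before amplification (**homoduplex**): all chimeric reads from the
template are mutated.

Because the artifact alleles are determined entirely by the reference
sequence, they can be predicted in advance. The package scans the padded
target regions, extracts every interruption (mismatched pair or gap) of
every qualifying structure, derives the artifact allele each would
induce, and assembles a *potential mutation blacklist* against which
variant calls are filtered.

## Structure detection

### Inverted repeats

A reported IVS is *nearly perfect*: its arms pair exactly except for at
most one contiguous interrupted region containing at most
`max_interrupt` discrepant bases on each arm (the region decomposes into
`min(g1, g2)` mismatched pairs plus a `|g1 - g2|`-base gap on the longer
arm). Detection works in pairing space: a column pairs arm position
`x` with arm position `y > x` when `base(y) == complement(base(x))`;
an exact structure lies on one anti-diagonal (`x + y` constant). The
scanner finds maximal exact pairing runs of at least the effective seed
length and joins run pairs whose geometry admits a single bridgeable
region; arms always extend to their natural, non-extendable limits —
structures are never trimmed inward to satisfy a constraint. The
criteria (below) are then applied, and a structure is dropped only when
*both* of its arms are covered by another criterion-satisfying
structure; overlapping structures are all reported. The hot loop is
implemented in C++ (`src/ivs_candidates.cpp`); an independent
brute-force oracle in the test suite checks exact equivalence on random
windows.

The conceptual description of the assembly — enumerate all k-mers of
every length `K = 2..L/2` and join adjacent reverse-complementary ones —
is exposed as `kmer_census()` for verification, but the scanner uses
fixed-length seeds: the all-`K` enumeration is quadratic in window
length and entirely redundant with seeds plus extension. The effective
seed length is capped at run time to `min(seed_len, min_edge + 1)`
(floor 2) so that every structure whose interruption keeps `min_edge`
columns clear of the arm ends still contains a findable exact block.

### Palindromes

Every nucleotide (and, optionally, every between-base position) is
treated as the center of a candidate palindrome. Expansion compares
`seq[center - k]` with the complement of `seq[center + k]` outward,
records the first non-pairing column, and halts immediately before the
second (`stop_mismatches = 2`); an `N` counts as a mismatch for stopping
but never yields a predicted allele. A structure whose only non-pairing
column is terminal is trimmed to its perfect core. With the full span
(both arms plus the unpaired center) written `L`, a reported palindrome
with an internal mismatch has a longest continuously matched stretch of
exactly `L - 2` — the unpaired center and the mismatch column are the
only interior breaks — an identity the test suite asserts on random
windows.

## Blacklist criteria and allele prediction

Defaults follow the criteria used to build the panel blacklists:

| parameter | default | meaning |
|---|---|---|
| `pad` | 50 bp | flank added to each BED region before scanning |
| `min_spacer` | 5 bp | minimum arm-to-arm spacer N of an IVS |
| `min_arm` | 8 bp | minimum per-arm aligned length |
| `min_edge` | 2 bp | minimum distance from an interruption to both arm ends |
| `max_interrupt` | 3 bp | per-arm size bound of the single interrupted region |
| `max_spacer` | 300 bp | arm search horizon (intra-fragment distances) |
| `min_helix` | 17 bp | minimum palindrome span L |
| `stop_mismatches` | 2 | expansion halts at the second non-pairing column |

Two readings of the published spacer criterion are possible — the
nucleotides between the two arms, or the gap between exact blocks within
the alignment; the package binds `min_spacer` to the first (the
fold-back loop) and bounds the second by `max_interrupt`, and both are
configurable. "Total length of the inverted repeat" is likewise read as
per-arm aligned length; the sum-of-arms alternative is strictly looser
at the same number.

For a mismatched pair, *both* genomic sites are blacklisted, because the
chimera's copy direction is not fixed — either arm can be written onto
the other. At the arm1 site the predicted allele is the complement of
the arm2 base, and symmetrically. A gap of g bases on one arm predicts a
g-base deletion at its own site and a g-base insertion (the reverse
complement of the gap bases) at the partner junction; indel entries are
left-normalized against the reference, and calls must be normalized the
same way (`normalize_variants()`) before filtering. Entries are
restricted to the original unpadded regions: the pad exists so that
structures straddling a region boundary are seen, but the blacklist is
declared for the target itself.

`filter_variants()` defaults to *position* mode (any overlap between the
normalized reference span of a call and an entry span removes the call),
matching a site-based blacklist; *allele* mode additionally requires the
exact predicted alternate and is offered as a stricter opt-in, since a
site blacklist cannot distinguish a genuine variant that happens to sit
on a predicted site. Removed records are tagged in FILTER
(`ivps_blacklist`) rather than deleted unless dropping is requested.

Note that random (and real) sequence is dense in structures meeting
these published thresholds: on uniform random 1 kb backgrounds the
default blacklist covers most positions. This matches the method's
observed behaviour on real panels — the filter removes the large
majority of raw low-frequency calls — and it is why position-mode
filtering should be followed by review of any clinically relevant site.

## The simulator

`make_synthetic_reference()` builds the study conditions: a random
background at a chosen GC (default 0.5, 1 kb — an exon-scale target),
planted IVS (default arm 12 bp, spacer 6 bp, one internal mismatch 4 bp
from the arm end), planted PS (default helix 21 bp, mismatch 5 columns
from the center), and planted true variants (defaults 30% and 20%
allele fraction, the range of unambiguous somatic calls in tissue
panels). Base pairing is deliberately broken in the plant flanks and
spacer so each planted structure's natural extent is exactly what was
planted. True-variant positions are drawn by rejection against the
blacklist of the finished sequence — chance background structures are
real structures, and a variant placed on one of their predicted sites
would be indistinguishable from an artifact by construction (the same
constraint any in-silico validation of a site blacklist must respect).
Everything is deterministic given the spec seed.

`simulate_sonication_chimeras()` draws uniform double-strand breaks;
breaks inside an arm fold onto the partner arm (either direction,
depending on which arm is hit), producing heteroduplex templates whose
filled strand carries every induced allele the copy covers, plus a
reverse-complement tail that a real aligner would soft-clip.
`simulate_enzymatic_chimeras()` nicks uniformly inside palindrome arms
and writes the induced allele into both strands. `pcr_and_sample()`
amplifies with exact, unbiased, error-free doubling — polymerase-error
and oxidation artifact channels are deliberately excluded so the PDSM
mechanism is isolated — and samples reads uniformly from the final
molecules, windowed around the clip boundary so chimeric reads keep
5–40 soft-clipped bases. `naive_pileup()` places reads by their truth
coordinates with the chimeric copy already mapped to its *apparent*
position (the mirror position in the partner arm), which is precisely
the misalignment that turns a chimera into a variant call; it then
counts alleles and applies depth and allele-fraction thresholds. No
sequencing-error model, quality model, read pairing, or UMI handling is
simulated, so passing the in-silico loop demonstrates the blacklist
logic, not robustness to noisy real data.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere internally; BED is native
  and VCF positions are converted at the boundary. Multi-allelic VCF
  records are split per alternate on read.
- Ambiguity codes other than `N` are rejected (pairing is defined over
  `{A,C,G,T}`); `N` never pairs, terminates extension, and never
  produces a blacklist entry.
- Maximality is decided at the natural extent; the containment rule is
  applied among criterion-satisfying structures ("not contained in
  another *reported* structure"), so a reportable structure is never
  suppressed by an unreportable super-structure. Ties are broken by
  leftmost arm1, then leftmost arm2.
- PCR is modeled as exact doubling with founder strands sampled at
  probability 1/2 each — the binomial that produces the stochastic 50%
  heteroduplex read fraction.
- Sonication break points are uniform over the molecule and enzymatic
  nicks uniform within palindrome arms; no fragmentation-bias model is
  published for either.
- Desk-scale problem sizes: oracle equivalence is asserted on 100 random
  300 bp windows per scanner; the end-to-end loop on 20 random 1 kb
  references with ~4,000 reads each; the heteroduplex fraction on
  10,000 chimeric reads from 1,000 templates (binomial 3·SE band,
  ±1.5 percentage points).

## Known limitations

- The scanner reports single-region nearly perfect structures; chains
  with two or more widely separated interruption regions are reported as
  their maximal single-region parts instead.
- Structures with interruptions closer than `min_edge` to an arm end are
  detected but contribute no blacklist sites, so artifacts they induce
  (rare, edge-adjacent) are not filterable — a property of the published
  criteria, reproduced faithfully.
- The simulator's apparent-position bookkeeping replaces a real aligner;
  soft-clip geometry is exact but mapping-quality effects, multi-mapping
  and fusion-like distant chimeras are out of scope.
- Position-mode filtering of a dense blacklist is aggressive by design;
  allele mode and the FILTER-tag (rather than drop) default exist to
  keep the decision auditable.
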