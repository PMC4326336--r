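---
title: "Exhaustive guide RNA off-target enumeration: model, index, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive guide RNA off-target enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offtargetr)
```

## The problem and its contract

A CRISPR/Cas nuclease loaded with a 20-nt guide RNA cleaves a genomic site
when the site's 20-mer (the protospacer) is sufficiently complementary to
the guide and is flanked 3′ by a protospacer adjacent motif (PAM). Sites
other than the intended one that satisfy these conditions are potential
off-targets, and missing one can invalidate an experiment. The contract
this package implements is therefore *exhaustive*: for genome $G$, query
$Q$ (|Q| = 20), PAM pattern $P$, mismatch budget $M \le 5$ and seed mask
$S \subseteq \{0..19\}$, report **all** positions on **both** strands where
the underlying 20-mer $q$ satisfies

$$d_H(q, Q) \le M, \qquad q_i = Q_i \ \forall i \in S, \qquad
\text{PAM matches immediately 3′ of } q .$$

Mismatches are Hamming only — equal-length comparison, no bulges or
indels — and no activity scoring (MIT/CFD-style) is applied; ranking
heuristics belong downstream of an exhaustive list, not inside it. The
seed is deliberately *not* hard-wired: its location and extent are query
parameters, because what constitutes a functional seed is still debated
and users need to explore alternatives cheaply.

## Encoding and the prefix-hash index

Each k-mer over {A,C,G,T} is identified with its base-4 value
($A{=}0, C{=}1, G{=}2, T{=}3$, leftmost base most significant):
$\mathrm{code}(s) = \sum_j \mathrm{digit}(s_j)\,4^{k-1-j}$. The map is a
bijection between k-mers and $0..4^k{-}1$, monotone in lexicographic
order, and trivially invertible — it is simultaneously the hash and the
2-bit packing of the sequence.

The off-line stage scans both strands for every 20-mer followed by one of
the registered PAM patterns and stores one record per (site, pattern)
pair:

| field | bits | meaning |
|---|---|---|
| position | 0–27 | 0-based, forward-strand leftmost base of the 20-mer |
| strand | 28 | 0 forward, 1 reverse |
| chromosome | 29–33 | 0-based FASTA ordinal (≤ 32 sequences) |
| PAM id | 34–36 | ≤ 8 patterns per index |
| captured PAM bases | 37–44 | 2 bits per unspecified (N/R) pattern position |
| tail code | 45–52 | guide bases 17–20 as a 4-mer code |

The 16-mer *prefix* is not stored: records are grouped by its code, and an
offset table maps prefix → group, so the prefix is recovered by inverting
the hash and the offset differences are exactly the per-prefix site counts
(an identity the tests verify against an independent, string-based
counter). Positions always refer to the forward strand regardless of the
record's strand — one coordinate convention, disambiguated by the strand
bit.

Records span bits 0–52, so every packed word is below $2^{53}$ and is held
*exactly* in an R double; all packing arithmetic is plain
multiply/divide/modulo on doubles. Serialization writes each word as two
little-endian 32-bit halves (low first) behind a magic string and format
version, making index files portable and refusing foreign or truncated
input.

Construction is organized as the classic two-pass counting sort: pass 1
counts sites per prefix and initializes the offsets from the cumulative
counts; pass 2 places the packed records into their groups. The genome
scan itself is a single vectorized sweep that feeds both passes — the
counts and offsets are identical to scanning twice, and the group-size
identity test pins that down. Within a group, records are ordered by
(chromosome, position, strand, PAM id) so builds are bit-deterministic.

The full table over all $4^{16}$ prefixes is genome-scale equipment (tens
of GB of offsets; appropriate when indexing a human genome on a large
server). This package stores the occupied prefixes only, as a sorted code
vector plus offsets — semantics are identical, and the serialized format
carries an encoding tag so a dense payload variant can be added without a
format break.

## The on-line query

Mismatches can hit the prefix (positions 0–15) or the tail (16–19). The
query enumerates every 16-mer within Hamming distance $M$ of the guide
prefix — substituting only outside the seed — looks each variant up among
the occupied prefixes, and walks its record group; tail mismatches are
read off the stored tail codes. Enumerating prefixes rather than whole
20-mers is an exact refactoring of the $\sum_{i\le M} \binom{20}{i}3^i$
candidate bound (4,192,468 at $M{=}5$): the tail's $3^j\binom{4}{j}$
alternatives are resolved by comparison instead of generation. The
neighborhood itself is generated arithmetically (per-position code deltas,
outer-summed), so no string allocation happens on the hot path.

**Seed semantics.** Seed positions must match exactly. Since a seed
position can never mismatch, "seed positions don't consume the budget" and
"mismatches are counted over all 20 positions" coincide; substitutions are
simply never generated there, and tail records mismatching in the seed are
dropped. Position 0 is the 5′ guide base; because bench convention counts
seeds from the PAM-proximal 3′ end, the mask parser also accepts
`"3prime:k"` for $\{20{-}k..19\}$.

**Hit reporting.** Each hit carries the reconstituted 20-mer, the exact
mismatch position set, the *dereferenced* PAM (the concrete genomic bases
at the pattern's N/R positions, recovered from the stored capture bits),
and GC content. Hits are sorted by (chromosome, position, strand). The
guide's own perfect site, when present, is reported like any other hit —
it satisfies the contract, and dropping it is a one-line post-filter.

## PAM patterns

Patterns are strings over {A,C,G,T,N,R}; N matches any base, R a purine.
These two symbols cover the built-ins (NGG, NAG, NNNNACA, NNGRRT —
registered with stable ids 0–3; user patterns take ids 4–7); other IUPAC
codes are rejected loudly rather than half-supported, and extending the
parser later costs nothing because every unspecified position is captured
in a uniform 2 bits regardless of its allowed set. Genomic windows
containing N never match any pattern. 5′-side PAMs (Cpf1-style) are out of
scope.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_mm` | — (required) | mismatch budget, validated to 0..5; the cap mirrors the biology (sites beyond 5 mismatches are not credible off-targets) and bounds the neighborhood |
| `seed` | `NULL` (none) | exact-match mask, 0-based 5′ positions or `"3prime:k"` |
| `pams` (build) | — | patterns indexed together; a site matching several patterns yields one record each, filtered by id at query time |
| `gc_bias` (fixtures) | 0.5 | i.i.d. base model for synthetic genomes |

## What the synthetic data emulates — and what it does not

`synth_genome()` draws i.i.d. bases with a chosen GC fraction: the right
null model for verifying *search correctness*, because hit/no-hit is a
pure string predicate. It does not emulate repeats, segmental
duplications, or soft-masked regions, so test genomes under-represent the
clustered near-duplicate hits real genomes produce; nothing in the
algorithm depends on that structure (the index stores every site
regardless), but measured hit *counts* on synthetic genomes say nothing
about real-genome counts. `plant_offtargets()` overwrites windows with
guide copies mutated at exactly the requested positions followed by a
concrete PAM instance, refusing overlapping or out-of-bounds plantings;
because a random background can contain chance look-alikes, ground truth
is subset-semantics unless the background is verified hit-free first
(`verify_background = TRUE`), in which case it is the exact hit set.

## Numerical and degenerate-input choices

- All k-mer codes and packed words are doubles; every value is below
  $2^{53}$, so arithmetic is exact. 16-mer codes exceed R's 32-bit
  integers, which is why codes carry their `k` and are never coerced.
- FASTA ingestion uppercases (soft-masked regions are indexed —
  exhaustiveness is the contract) and folds IUPAC ambiguity codes and gaps
  to N; any window containing N is excluded from indexing, matching, and
  querying, so the fold is conservative.
- Chromosomes are capped at 32 (5-bit field) and $2^{28}$ nt (28-bit
  positions); exceeding either fails with a capacity error rather than
  silently widening the record.
- Degenerate inputs resolve by the contract: an all-frozen prefix
  enumerates exactly one variant; a genome with no PAM occurrence builds
  an empty (but valid, serializable) index; an annotation covering only
  some chromosomes treats the rest as intergenic.
- Annotation overlap requires ≥ 1 bp of the 20-nt window and ignores
  feature strand; GTF (1-based inclusive) and BED (0-based half-open) are
  normalized to 0-based half-open internally.

## Verification strategy and problem sizes

The primary correctness surface is *oracle equivalence*: the indexed
search must return exactly the same hit set as an independent brute-force
sliding-window scanner that shares only the base-encoding and PAM
primitives. The shipped suite runs 200+ randomized trials (genomes 1–50 kb
with 1–3 chromosomes, GC 0.35–0.65, random and genome-sampled guides,
budgets 0–5, all four built-in PAMs, random seed masks) plus planted-site
recovery, the Table A offset identity against a string-based counter,
exhaustive small-k properties (hash bijection to k = 8, Hamming-ball
counts at k = 5), and serialization round-trips. Genome sizes were chosen
so the whole suite exercises every code path in a few minutes on one core;
correctness is size-independent (no heuristic thresholds scale with the
genome), which is what the randomized size sweep demonstrates.

## Known limitations

- Guide length is fixed at 20 nt and the prefix/tail split at 16 + 4.
- Hamming distance only: DNA/RNA bulges are invisible to this model.
- At most 8 PAM patterns, 32 chromosomes, and 2^28 nt per chromosome per
  index.
- The in-memory index targets desk-scale genomes (up to tens of Mb);
  indexing a mammalian genome needs the dense-table, large-RAM variant
  this package intentionally does not ship.
- Reported sites are sequence-level candidates; chromatin state,
  methylation, and cleavage-activity scoring are out of scope by design.
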