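---
title: "Synteny-restricted orthologue search: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-restricted orthologue search: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`synorth` treats orthologue discovery for a weakly conserved query element
as a two-part inference. First, *where could the orthologue be?* Whole-genome
alignment chains answer this independently of the element's own sequence:
the query locus is lifted through the chain into the subject genome, and the
lifted coordinates — possibly several per locus, when duplications exist —
are merged and flanked into syntenic regions. Second, *is the local
similarity there more than chance?* A loose local aligner will produce
high-scoring segment pairs (HSPs) even between unrelated sequences, so every
foreground HSP score is referred to an explicitly constructed null: the
distribution of scores the same query achieves against shuffled genomic
ranges of the subject annotation. The assumption underlying the test is
exchangeability — absent true homology, an HSP score inside the syntenic
region is distributed like an HSP score against random subject sequence of
comparable composition. Significant HSPs are then linked into collinear
chains, which is where the method tolerates insertions, deletions and
diverged stretches: the aligner itself is deliberately ungapped, and gaps
are bridged at the chaining stage at zero cost.

The per-query test is a permutation-style empirical p-value with a
pseudo-count,

$$p = \frac{1 + \#\{b \in B : b \ge s\}}{1 + |B|},$$

right-sided in the raw score $s$ over the pooled background multiset $B$,
followed by Benjamini–Hochberg adjustment within the query's own HSP family
and a strict cutoff $q < \alpha$. This controls the false-discovery rate
among one query's HSPs at $\alpha \cdot 100\%$; it is not a genome-wide FDR
across queries, matching the per-query atomicity of the algorithm.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_match` | 0.05 | fraction | minimum share of a locus's bases that must map through gapless chain blocks for a lift to be accepted |
| `merge_dist` | 2 × `flank_len` | bp | lifted duplicates closer than this merge into one synteny (strict `<`) |
| `flank_len` | 50000 | bp | flank added to merged syntenies and to the query sequence |
| `word_size` | 6 | bp | exact-match seed length of the aligner |
| `match_reward` / `mismatch_penalty` | +1 / −2 | score | ungapped scoring scheme |
| `xdrop` | 20 | score | extension stops when the running score falls this far below its best |
| `min_score` | 20 | score | reporting threshold for HSPs |
| `bg_size` | 200 | ranges | shuffled background ranges per query |
| `alpha` | 0.05 | fraction | FDR level, strict `q < alpha` |
| `seed` | 1 | — | master seed; per-query sub-seeds are derived from it and the query name |

`word_size`, `min_match` and `alpha` defaults are the method's canonical
loose-search settings. The scoring scheme, X-drop and reporting threshold
are package choices tuned for the loose-seed regime: +1/−2 keeps random
ungapped extensions short (expected drift −1.25 per base on random
sequence), and `min_score = 20` means an isolated random HSP needs roughly
20 near-contiguous matching bases, which is rare enough that unrelated
sequence pairs usually yield no HSP at all. `flank_len` is a genome-scale
quantity: 50 kb suits mammalian-scale synteny, while the package's own
tests and acceptance runs use `flank_len = 500` / `merge_dist = 1000` on
toy genomes of 30–150 kb per chromosome — the flank should be large
relative to chain-gap sizes and expected annotation error, not to the
genome.

`bg_size` bounds the resolution of the empirical p-value: with an empty
background pool the p-value cannot be smaller than `1/(1 + bg_size)`
(see below), and with the default 200 a single-HSP family reaches
`q ≈ 0.005`.

# Numerical and boundary decisions

* **Coordinates.** 0-based half-open everywhere internally (BED
  convention); GFF3 input is converted at the boundary (start − 1). A
  single convention eliminates off-by-one drift between modules.
* **Merging.** "Closer than the specified distance" is read strictly:
  ranges merge when `gap < merge_dist`; overlapping or abutting ranges
  always merge, even at `merge_dist = 0`. Merging is transitive and
  idempotent.
* **Lift semantics.** `min_match` counts in-block (mapped) bases over
  source length, the documented liftOver meaning. All chains passing the
  cutoff are kept (duplications allowed); deduplication happens only via
  merging. The subject interval is the minimal span of all mapped bases,
  converted from strand-relative to forward coordinates for minus-strand
  chains. Syntenies are built per (chromosome, strand composed with chain
  orientation) group; groups never merge across chromosomes or strands.
* **Query sequence.** The flanked query (lncRNA ± `flank_len`,
  strand-extracted) is what gets aligned, to syntenies and to background
  ranges alike, and foreground HSPs are then *filtered* — kept whole, never
  clipped — by ≥ 1 bp overlap with the unflanked locus. Clipping would
  change scores and break comparability with the background. Background
  HSPs are not pruned: the pool keeps flank-driven scores, which can only
  enlarge the upper tail of the null and thus raise p-values — a
  conservative direction for FDR control.
* **Empty background.** If `bg_size` ranges yield no HSP at all, the
  p-value is defined as `1/(1 + bg_size)` rather than `1/(1 + 0) = 1`:
  the query aligned nowhere random in `bg_size` attempts, which is
  evidence of specificity, and `bg_size` is precisely the resolution of
  that evidence. The rule is pinned by a unit test.
* **N and case.** `N` never seeds and never matches (an all-N query
  produces nothing); soft-masked lowercase is uppercased and treated as
  ordinary sequence. Inputs with more than 10% non-ACGTN characters are
  rejected.
* **Chaining.** Within one synteny and one orientation class, dynamic
  programming maximizes the sum of raw HSP scores under strict
  collinearity (query intervals increasing and non-overlapping; subject
  intervals increasing for same-orientation, decreasing for
  opposite-orientation chains) with zero gap cost. Overlapping HSPs
  compete rather than coexist: ungapped segments overlapping on the query
  are alternative, not additive, evidence. Ties prefer fewer HSPs, then
  the smallest subject start; orientation classes never mix, and only the
  better class survives as the region's single chain.
* **Selection.** Among a query's chains, the best orthologue maximizes
  total HSP length (not score); ties fall back to higher total score, then
  the lexicographically smallest span locus. Length is the criterion
  because the one-to-one call should be the most completely aligned locus,
  not the least diverged fragment.
* **Determinism.** One master seed drives everything; each query's
  background sampling uses a sub-seed derived from the seed and a stable
  hash of the query name, so worker count and scheduling order cannot
  change any result. Serial and 8-worker runs are asserted byte-identical.
* **Degenerate inputs.** Empty lift → `unlifted`; zero HSPs → `unaligned`
  with lifted coordinates reported; no significant HSPs → `insignificant`
  with all HSPs reported; empty inputs to merging/chaining return empty
  results rather than errors. A background built with one engine
  configuration refuses to be combined with foreground scores from
  another (engine tags are compared at the filtering stage).

# Open design points, resolved

The Benjamini–Hochberg family is all HSPs of one query across its
syntenic regions — per-query, not genome-wide — because the algorithm is
atomic per query and a genome-wide family would make one query's calls
depend on which other queries happen to be in the input. Background ranges
are not length-matched to the query; they inherit the subject annotation's
record lengths, matching common shuffle semantics and keeping the null's
length distribution realistic (the alternative is flagged, not silently
mixed in). A prediction for an orthologous query that intersects a
*different* query's true orthologue counts toward neither TP nor FP in the
benchmark module; it surfaces only as FN mass.

# What the simulator emulates — and what it does not

`simulate_pair()` builds both genomes as i.i.d. uniform ACGT, places
non-overlapping query elements, emits a three-block chain per chromosome
whose gap cuts avoid the elements (so every element lifts fully,
optionally onto permuted chromosomes and minus-strand chains), plants a
substitution/indel-mutated copy of each conserved element's transcript at
the chain-mapped subject location, and writes the planted copies plus
decoy genes as the subject annotation. `simulate_null()` is the same
construction with no planted copies.

This exercises every pipeline stage under the statistical test's own null
assumption (uniform composition). Real genomes violate that assumption in
ways the simulator deliberately omits: repeat families and low-complexity
tracts (which inflate both foreground and background scores and are the
reason the background is drawn from the annotation rather than from
uniform sequence), GC and isochore structure, transcript splicing, and
realistic indel/rearrangement patterns. Passing tests therefore
demonstrate correctness of the machinery and calibration under uniform
nulls; they do not certify calibration on repeat-rich genomes, where the
background annotation must carry the same repeat content as the syntenies
for exchangeability to hold.

Problem sizes used by the test suite and acceptance script, chosen as
desk-scale analogues: null calibration on 200 queries of 300–800 bp over
4 × 150 kb chromosomes; sensitivity on 60 planted copies at 20%
substitution divergence (recovery floor 90%); oracle equivalence suites of
500–1000 randomized cases against brute-force enumeration, per-base block
walking and step-up recomputation.

# Known limitations

* The built-in aligner is ungapped; a single HSP never spans an indel, so
  heavily indel-diverged orthologues depend entirely on chaining, and the
  per-HSP scores understate total similarity.
* Paralogue resolution is by total aligned length only; when the
  benchmark's truth contains one-to-many families, the selected call may
  legitimately disagree with the annotated one-to-one pair.
* The empirical p-value's resolution is `1/(1 + |B|)`; small `bg_size`
  with multi-HSP families can leave true hits above the strict `q < alpha`
  line.
* No two-step lifting through an intermediate assembly, no chain
  generation, no e-values, and no protein-coding-potential or reciprocal
  best-hit post-processing — these compose downstream of the package's
  outputs.
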