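# synorth

Synteny-restricted search for orthologues of long noncoding RNAs, with an
empirical statistical test of sequence conservation.

## The problem

Long noncoding RNAs are weakly conserved at the sequence level, and novel
lncRNAs discovered in a single experiment have no annotation and no
matching expression data in other species, so transcriptome-comparison
orthology tools cannot be applied to them. A naive sensitive alignment of
each lncRNA against a whole subject genome is both slow and swamped by
spurious hits. `synorth` addresses this for researchers who have nothing
but coordinates: it restricts a sensitive local alignment search to the
syntenic neighbourhood of each query locus and filters the resulting hits
with an explicit null model, so unannotated orthologues can be called in a
distant genome at a controlled false-discovery rate.

## The method

For each query lncRNA:

1. **Synteny.** The locus is lifted through a UCSC chain file with
   duplications allowed and a `minMatch` cutoff (default 0.05, the fraction
   of bases that must map through gapless chain blocks). Lifted duplicates
   closer than `merge_dist` are merged, and the merged regions are extended
   by `flank_len` to form flanked syntenic regions.
2. **Alignment.** The flanked query sequence is aligned to each syntenic
   region with a loose, ungapped seed-and-extend local aligner
   (`word_size = 6` by default, X-drop termination, both orientations),
   yielding high-scoring segment pairs (HSPs), which are then pruned to
   those overlapping the unflanked lncRNA interval.
3. **Null model.** The same query is aligned, with the same engine and
   parameters, to `bg_size` shuffled genomic ranges drawn from the subject
   annotation (ranges intersecting any lifted query locus are excluded).
   The pooled background scores give each foreground HSP an empirical
   right-sided p-value `p = (1 + #{b >= s}) / (1 + |B|)`.
4. **FDR filter.** P-values are Benjamini–Hochberg-adjusted within the
   lncRNA's own HSP family; HSPs with `q < alpha` (default 0.05) survive,
   controlling the false-discovery rate at `alpha * 100%`.
5. **Chaining and selection.** Surviving HSPs in each syntenic region are
   linked by dynamic programming into the maximum-score collinear chain;
   among a lncRNA's chains the one with the largest total HSP length is the
   one-to-one call (*bestSignificant*).

Every lncRNA receives exactly one conservation status: `significant` (with
the best chain marked), `insignificant` (HSPs exist, none survive the
filter), `unaligned` (lifted but no HSPs), or `unlifted`. Calls can
optionally be annotated against subject genes with strand-specific Jaccard
and overlap coefficients, and a benchmarking module computes
confusion-matrix metrics (TPR, FPR, accuracy, precision, F1, with a
share-weighting rule for multi-prediction tools) against a truth mapping.

## Worked example

The package ships a synthetic fixture generator that emulates all five
inputs (query/subject genomes, lncRNA BED, subject gene annotation, chain
file) with planted, mutated orthologous copies and a ground-truth table:

```r
library(synorth)

bundle <- simulate_pair(sim_config(n_chroms = 2, chrom_len = 50000,
                                   n_lncrnas = 10, conserved_fraction = 0.5,
                                   sub_rate = 0.15, seed = 42))
paths <- write_fixtures(bundle, "fixtures")

config <- pipeline_config(
  lncrna_bed = paths[["lncrna_bed"]], query_fasta = paths[["query_fasta"]],
  subject_fasta = paths[["subject_fasta"]],
  subject_annotation = paths[["gene_bed"]], chain = paths[["chain"]],
  outdir = "run", flank_len = 500, merge_dist = 1000, bg_size = 100,
  seed = 7, quiet = FALSE)
run_pipeline(config)
read_pipeline_summary("run")
```

```
lift: 10 regions for 10 lncRNAs
synteny: 10 regions
align: 5 pruned HSPs
background: 5 distributions of 100 ranges
filter: 5 of 5 HSPs significant at alpha=0.05
classify: significant=5 unaligned=5

    lncrna      status best_chrom best_start best_end total_hsp_length total_score
1  lnc0001 significant      chrS1       9487     9890              403         226
2  lnc0002 significant      chrS1      18847    19513              666         315
3  lnc0003   unaligned       <NA>         NA       NA               NA          NA
...
10 lnc0010 significant      chrS2      47654    48442              788         422
```

The five lncRNAs simulated with a planted copy (15% substitution
divergence) are exactly the five called `significant`; their best spans
(e.g. `chrS1:9487-9890`, total HSP length 403 bp, summed raw score 226)
coincide with the planted copies, and the five lncRNAs without a planted
copy lift cleanly onto random sequence but produce no HSP at all
(`unaligned`). Output files under `run/` include `bestSignificant.bed`,
`significant.bed`, `insignificant.bed`, `unaligned.bed`, `unlifted.txt`,
per-stage intermediates and a JSON sidecar with per-chain HSP detail;
reruns with an unchanged configuration reuse completed stages via
`manifest.json`.

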