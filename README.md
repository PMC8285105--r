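# hetnuc

Analysis of H3K9me3 heterochromatin establishment across early embryonic
stages from low-input chromatin profiling.

## The problem

In the early embryo, constitutive heterochromatin is rebuilt from
scratch: the repressive mark H3K9me3 first appears at narrow,
single-nucleosome **nucleation sites** and then **spreads** to
neighbouring nucleosomes over successive developmental stages, until
broad domains cover the pericentromere, the repeat-rich (neo-)Y and
dispersed transposable-element (TE) insertions. Quantifying that process
from staged single-embryo ChIP-seq raises a chain of computational
problems that this package solves as tested, reusable components — for
anyone profiling chromatin marks across conditions with spike-in
normalization, and for TE biologists relating epigenetic state to
element structure, piRNAs and expression.

## What it computes

* **Enrichment tracks.** Per-base log2 enrichment with library-size
  normalization by the median autosomal 1 kb-window coverage and a
  pseudocount:
  `Enrichment = (ChIP/ChIP_median + 0.01) / (input/input_median + 0.01)`.
* **Spike-in quantile-bin normalization.** Spike-in enrichment
  distributions are matched to a cross-sample reference in quantile bins
  of 0.1 percentile; the per-bin shift (e.g. a bin at log2 3.2 whose
  reference counterpart is 4.0 shifts by +0.8) is applied, value-keyed,
  to the sample — undoing pull-down efficiency differences without
  flattening real biology.
* **Developmental peak taxonomy.** Post-processing of externally called
  peaks: replicate merging (< 100 bp gaps), phantom filtering against
  unrelated-mark ChIPs, persistent/temporary and old/new classification
  (enriched iff log2 enrichment > 0.5 around the summit), profiles,
  trajectories with bootstrap CIs, annotation overlap.
* **TE structure.** Projection of enrichment onto TE consensus
  coordinates; classification of LTR copies as full-length (same-strand
  LTRs within 10 bp) vs 5'/3'-truncated (LTR missing or > 5 kb away);
  terminal-kilobase enrichment contrasts with rank-sum tests; copy
  counts genome-wide and on the neo-Y.
* **piRNA / expression association.** 23–29 nt size filter, strand
  split, 5 kb window RPM, association with peak taxonomy, per-family
  consensus coverage, copy-number-scaled TE expression
  (RNA/gene-median over DNA/coverage-median) and stage fold changes.
* **Synthetic data.** A first-class generator
  (`generate_genome()`, `simulate_stage_tracks()`, `simulate_pirna()`,
  `simulate_expression()`) plants nucleation sites with stage-wise
  spreading, phantom sites, LTR truncation structure, spike-in
  distortions, piRNA rates and an expression model — so the entire
  pipeline runs end to end with known ground truth and no downloads.

## Worked example

```r
library(hetnuc)
res <- run_pipeline(sim_config(), seed = 1, outdir = "hetnuc_out")

res$accuracy
#> $phantom
#> [1] 1
#> $persistence
#> [1] 1
#> $novelty
#> [1] 1

res$truncation[res$truncation$stage == "s7", ]
#>   stage mean_full mean_truncated     fold            p
#> 5    s7   2.28951   -0.002777232 4.898321 1.636984e-06

res$expression$fold_by_group
#>     early      late      none
#> 1.376191  1.041236  0.9999912
```

The taxonomy labels (phantom/specific, persistent/temporary, old/new)
recover the planted truth exactly on this seed. The truncation contrast
shows what the method is built to detect: full-length LTR copies carry
~2.3 log2 units more H3K9me3 than 5'-truncated copies over their last
kilobase at the final stage — but only once spreading from the 5'
nucleation site has reached the element's 3' end (fold ≈ 1 at earlier
stages). Expression folds recover the planted stage 2→4 inductions
(1.41 / 1.01 / 0.97) within Poisson noise. `hetnuc_out/` contains every
standard-format output: bedGraph enrichment tracks, narrowPeak calls,
taxonomy TSVs, the consensus matrix, structure BED, piRNA window RPM,
expression tables and the ground-truth JSON.

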