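# linkbin

Barcode-aware read binning for metagenome assembly from linked-reads
(stLFR, TELL-Seq, 10x Genomics) and from short reads virtually barcoded by
their alignments to long reads.

## The problem

In linked-read sequencing every short read carries the barcode of the long
DNA fragment it came from, so the set of *co-barcoded* reads behaves like a
noisy pseudo-long-fragment from (usually) one genome. Assembling a complex
metagenome improves markedly if those co-barcoded sets are first grouped by
their genome of origin and each group is assembled on its own. `linkbin`
implements that grouping and its surroundings for people building
linked-read or hybrid assembly workflows:

* **Features.** Each barcode with ≥ 2 kb of sequence yields a 400-bin
  histogram of global 15-mer frequencies **X<sub>A</sub>** (an abundance
  fingerprint; frequencies > 4000 are discarded as repeats) and a
  136-dimensional canonical tetranucleotide frequency vector
  **X<sub>T</sub>** (a composition fingerprint), concatenated into a
  536-dimensional input.
* **Embedding.** A variational autoencoder (536 → 512 → 512 → 32 latent,
  batch-norm + dropout, softmax reconstruction heads) trained with the loss

  *Loss* = w<sub>A</sub>·L<sub>A</sub> + w<sub>T</sub>·L<sub>T</sub> +
  w<sub>KL</sub>·L<sub>KL</sub>,  
  w<sub>A</sub> = α/ln 400, w<sub>T</sub> = (1−α)/ln 136,
  w<sub>KL</sub> = β/32 (α = 0.1, β = 0.015),

  where L<sub>A</sub>, L<sub>T</sub> are cross-entropies and L<sub>KL</sub>
  the Gaussian KL term. Training batches are drawn with probability
  ∝ max(X<sub>A</sub>)² — low-abundance genomes peak harder in the
  histogram — which balances the training stream across abundances.
* **Clustering.** Latent means are grouped into
  k = round(8 × Shannon diversity) bins by k-means seeded with
  random-projection hashing (robust to very uneven bin sizes).
* **Low-abundance rescue.** Reads mapping to no contig with mean depth > t
  are re-collected for each t in {10, 30} (nested sets) for reassembly.
* **Connectivity tools.** Physical-fragment reconstruction from barcoded
  alignments (chain within 10 kb, keep fragments with ≥ 2 read pairs and
  ≥ 1 kb) and the barcode-specificity statistic N<sub>F/B</sub>; virtual
  barcoding of short reads from long-read alignments (≥ 60 aligned bases,
  seeded uniform tie-break).
* **MAG QC.** Quality tiers (near-complete / high / medium / low) from
  completeness, contamination, rRNA and tRNA annotations, plus the
  aligned-identity statistic.
* **Synthetic communities.** A seeded generator (genomes with controlled GC
  and distinct tetranucleotide signatures; fragment-per-barcode read model
  with ground truth) so the whole pipeline is testable without downloads.

External assemblers are pluggable command adapters, never bundled; built-in
mocks keep the pipeline hermetically testable.

## Worked example

```r
library(linkbin)

# a 3-genome mock community: abundances 100x/30x/10x, distinct signatures
community <- community_config()
genomes   <- simulate_genomes(community, seed = 1)
sim       <- simulate_linked_reads(genomes, linked_read_config(seed = 101),
                                   n_barcodes = 3000)

grouping <- group_by_barcode(sim$reads)          # 2 kb feature floor
ktab     <- build_kmer_table(sim$reads)          # global 15-mer counts
feats    <- barcode_features(grouping$groups, ktab)

vae <- train_embedder(feats, embedder_config(hidden_sizes = c(128, 128),
                                             max_epochs = 50, seed = 1))
glance(vae)
#> # A tibble: 1 × 7
#>   n_epochs best_epoch val_loss latent_dim n_train n_val early_stopped
#>      <int>      <int>    <dbl>      <int>   <int> <dbl> <lgl>
#> 1       42         32    0.899         32    2353   262 TRUE

mu   <- embed_barcodes(vae, feats)               # one 32-dim row per barcode
bins <- cluster_latent(mu, k = 3)

truth <- dplyr::summarise(sim$truth_pairs,
                          genome = names(which.max(table(genome))),
                          .by = barcode)
evaluate_binning(bins, truth)
#> # A tibble: 1 × 4
#>   precision recall   ari     n
#>       <dbl>  <dbl> <dbl> <int>
#> 1     0.926  0.926 0.760  2615

frags <- reconstruct_fragments(truth_alignments(sim$truth_pairs))
barcode_stats(frags)
#> # A tibble: 1 × 4
#>   n_barcodes n_fragments nf_per_b fraction_multi_fragment
#>        <int>       <int>    <dbl>                   <dbl>
#> 1       3000        4104     1.37                   0.323
```

Reading the numbers: training stopped early at its best validation epoch;
clustering the latent means at k = 3 assigns 92.6% of barcodes to bins
dominated by their own genome (precision), keeps 92.6% of each genome's
barcodes in its dominant bin (recall), and reaches an adjusted Rand index of
0.76 against ground truth — a stochastic quantity that varies by a few
hundredths across seeds. The recovered N<sub>F/B</sub> of 1.37 sits below
the configured 1.54 because on a 300 kb toy community nearby fragments of
one barcode merge during reconstruction; on wide communities the statistic
recovers the configured mean closely (the methods vignette quantifies this).

`run_binning_pipeline()` wires these stages together and writes one FASTQ
per bin plus a shared pool; `run_partition_pipeline()` and `run_ensemble()`
cover the depth partition and the (adapter-driven) merge.

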