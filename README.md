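# phyrn

Alignment-free phylogenetic inference for highly divergent protein
families, with a sequence-evolution benchmark harness.

Multiple sequence alignment collapses in the "twilight zone" (≤25%
pairwise amino-acid identity), and trees built on bad alignments inherit
the damage. `phyrn` sidesteps the alignment: every query sequence is
encoded as the vector of its **product scores** against a library of M
query-based position-specific scoring matrices (PSSMs). For the best local
alignment of a query to a profile,

    product score = %identity x %coverage
                  = (ids / alen) x (aqlen / plen)
                  = (1 - p_ARP) x (1 - w_g)

where `ids` counts query residues identical to the profile's seed, `alen`
is the alignment length including gaps, `aqlen` the query-resident length,
`plen` the profile length, `p_ARP = (plen - ids)/plen` the
alignment-restricted p-distance and `w_g = (alen - aqlen)/alen` the gap
weight. Scores fill an N×M matrix (0 = no positive-scoring alignment);
Euclidean distances between its rows feed neighbor joining, and column
resampling (bootstrap or 80% jackknife) gives branch support.

Because the true history of real divergent families is unknowable, the
package ships a simulator of protein evolution on ultrametric trees —
Dayhoff PAM substitution with Poisson indels and a simultaneously recorded
true alignment — plus Robinson–Foulds scoring, two-tree consensus branch
marks, deep-node recovery, and a benchmark runner comparing profile
distances against p-distance baselines at controlled divergence.

## Worked example

Simulate a 20-taxon family at mean pairwise divergence 400 PAM (~13%
identity) and recover its history from the sequences alone:

```r
library(phyrn)

cfg <- sim_config(n_taxa = 20, mean_seq_len = 300, mean_pairwise_pam = 400,
                  topology_mode = "balanced", seed = 42)
fam <- simulate_family(cfg)
family_stats(fam)
#> Divergence statistics:
#>   mean pairwise identity   : 0.1344 (13.44%)
#>   indel events / position  : 0.0364
#>   gap chars / position     : 1.2374
#>   average gap length       : 4.14
#>   indel/substitution ratio : 0.0465

inf <- phyrn_infer(fam$sequences)   # PSSM library -> N x M matrix -> NJ
rf_distance(fam$tree, inf$tree)     # 0   (max possible: max_rf(20) = 34)
deep_node_recap(fam$tree, inf$tree) # 100 (% of deep nodes recovered)

supp <- resample_support(inf$matrix, "jackknife80", replicates = 200,
                         seed = 1)
median(attr(supp, "support"))       # 96
```

At 13% mean identity — where pairwise alignments retain little signal —
the profile distances reproduce the true topology exactly, with high
jackknife support. `benchmark_run()` repeats this comparison over a
divergence grid against p-distance baselines; at mean pairwise 700 PAM
(~8.5% identity) profile distances degrade far more slowly than pairwise
p-distance.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/phyrn.R simulate --n-taxa 50 --pam 400 --out-dir sim
Rscript inst/cli/phyrn.R run --seed 1 --out-dir run1   # full pipeline
```

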