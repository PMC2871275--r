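# taxrep

Phylogenetic representativeness of taxon samples, from taxonomy alone.

Before sequencing a single gene, a phylogenetic study must pick which
species (or other operational taxonomic units, OTUs) will stand for the
whole group — and biased taxon sampling is one of the commonest causes of
misleading trees. `taxrep` screens a candidate sample using only what is
always available: the group's Linnean classification. It asks how widely
the sample spreads over the taxonomy of the complete *master list* of the
group, compared with random samples of the same size.

## The statistics

On the taxonomic tree (levels `t = 1..T`, lowest first, `S` OTUs at the
tips), the distance between two OTUs is the shortest unrooted path,
`ω_ij = 2 Σ_{t<c} l_t`, where `c` is the lowest level at which they share
an ancestor and `l_t` is the step length between levels `t` and `t+1` —
equal, or proportional to the loss of taxon richness `S_(t) − S_(t+1)`,
standardized so the longest possible path is 100. The package computes:

* **AvTD** (`Δ+`, average taxonomic distinctness) — the mean of all
  `S(S−1)/2` pairwise distances: the expected taxonomic breadth of a
  random pair;
* **VarTD** (`Λ`) — the variance of those distances, separating tree
  shapes with equal AvTD;
* **von Euler's imbalance index**
  `I_E = (AvTD_max − AvTD) / (AvTD_max − AvTD_min)`, anchored by
  totally-balanced and totally-imbalanced trees rebuilt from the sample's
  own taxon counts (defined even for trees with polytomies);
* **funnel plots** — mean, one-tailed 95% limit and observed extreme of
  AvTD/VarTD across `k` random subsamples at each dimension `s`, with
  one-tailed randomization p-values for a real sample
  (`p = (1 + #{replicate AvTD ≤ observed}) / (k + 1)`);
* **shuffling analysis** — stability of all funnel lines when the master
  list is repeatedly perturbed by the three moves of taxonomic revision
  (transfer, split, merge), banded at 2.5%/97.5% across perturbed lists.

## Worked example

The classic textbook tree — 9 species in 6 genera, 3 families, 1 order —
with unit step lengths:

```r
library(taxrep)
tree9 <- taxonomy(data.frame(
  species = paste0("sp", 1:9),
  genus   = c("G1","G1","G1","G2","G3","G4","G4","G5","G6"),
  family  = c("F1","F1","F1","F1","F1","F2","F2","F2","F3"),
  order   = "O1"))
distinctness(tree9, "unit")
#> Taxonomic distinctness (unit scheme), S = 9
#>   AvTD  = 5.0556   [min 4.5000, max 5.3333]
#>   VarTD = 1.8858
#>   I_E   = 0.3333  (> 0.25: possible biased sample)
```

AvTD 5.0556 is the average number of tree steps between two random
species; the bracket shows the extremes attainable with these taxon
counts (162/36 and 192/36), and `I_E = 1/3` places the tree a third of
the way from perfectly balanced to maximally lopsided.

Judging samples against a master list (here synthetic: 300 OTUs, 90
genera, 20 families):

```r
m <- synthetic_taxonomy(c(300, 90, 20, 1), seed = 1)
good   <- random_subsample(m, 25, seed = 2)
fams   <- names(sort(table(m$classification[, "L3"]), decreasing = TRUE))[1:2]
biased <- otu_names(m)[m$classification[, "L3"] %in% fams][1:25]
res <- run_representativeness(m, list(random = good, two_families = biased),
                              k = 100, seed = 3)
res$results
#>        sample  s    avtd    vartd        ie avtd_max avtd_min  scheme_kind
#>        random 25 99.7101  4.08074 0.0277778  99.7313  98.9688 proportional
#>  two_families 25 95.1906 58.53427 0.0757154  95.8573  87.0524 proportional
#>      p_avtd    p_vartd tail
#>  0.97029703 0.95049505  one
#>  0.00990099 0.00990099  one
```

The random sample sits comfortably inside the funnel (`p_avtd ≈ 0.97`:
97% of random subsamples are *less* distinct). The sample squeezed into
two families is flagged on both statistics at `p ≈ 0.01`: its AvTD falls
below every one of the 100 random replicates.

A command-line wrapper with subcommands `repr`, `shuffle`, `synth` and
`validate` ships at `system.file("scripts", "taxrep", package =
"taxrep")`; master lists are plain CSV/TSV tables (header = level names,
lowest level first, one row per OTU) and samples are plain lists of OTU
names, `#` comments allowed.

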