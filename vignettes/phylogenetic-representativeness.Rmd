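---
title: "Assessing taxon sampling with taxonomic distinctness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing taxon sampling with taxonomic distinctness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxrep)
```

## The problem

Phylogenetic studies analyse a *sample* of species (or other operational
taxonomic units, OTUs) chosen to stand for a much larger group, and biased
or too-narrow sampling is one of the commonest suspects when trees come out
wrong.  Most formal taxon-selection criteria presuppose a phylogeny or a
genetic distance matrix for the group — exactly what a new study does not
have.  What is almost always available is the group's Linnean taxonomy.
`taxrep` measures **phylogenetic representativeness**: how widely a sample
spreads over that taxonomy, compared with random samples of the same size
drawn from the complete *master list* of the group's OTUs.

This is an *a priori* screen, run before any sequencing.  It cannot detect
problems that only data reveal (long-branch attraction, uninformative loci,
outgroup misspecification); it guarantees wise taxonomic coverage of the
ingroup, not a good phylogeny.

## The tree metric

A Linnean classification over levels $t = 1, \dots, T$ (lowest first, e.g.
species < genus < family < order) is a rooted tree with the $S$ OTUs at the
tips, each taxon nested in exactly one parent, and a single taxon at level
$T$.  The distance $\omega_{ij}$ between OTUs $i$ and $j$ is the *shortest,
unrooted* path between them: with $l_t$ the length of the step between
levels $t$ and $t+1$ (the same in both directions),

$$\omega_{ij} = 2 \sum_{t=1}^{c-1} l_t, \qquad
  c = \text{lowest level where } i, j \text{ share an ancestor},$$

and $\omega_{ii} = 0$.  Three step-length schemes are provided:

* **unit** — every step has length 1, so $\omega$ counts steps; the
  textbook setting used in worked examples;
* **equal** — all steps equal, standardized so the longest possible path
  ($2(T-1)$ steps, two OTUs meeting only at the root) is 100:
  $l_t = 100 / (2(T-1))$;
* **proportional** (the default) — each step is weighted by the loss of
  biodiversity it represents on the *master* list, the decrease
  $L_t = S_{(t)} - S_{(t+1)}$ in the number of taxa between consecutive
  levels, rescaled to the same longest-path-100 convention:
  $l_t = 100\,L_t / (2\sum_u L_u)$.  Since $\sum_u L_u = S - 1$, the
  rescaling is always well defined for $S \ge 2$.

The proportional reading of "loss" is the absolute decrease, not a ratio;
under the longest-path standardization any constant multiple of the losses
gives identical distances, so only the relative sizes matter.
Standardization is what makes analyses comparable across taxonomies with
different depths, and it makes the indices invariant to the insertion of a
redundant rank (a level that copies the partition below it carries zero
loss, hence zero step length) — `insert_redundant_level()` exists precisely
to exercise that invariance in tests.  Step lengths are *always* derived
from the master list; a pruned sample tree is measured with master lengths,
so a sample's distances are exactly the master's distances restricted to
the sampled OTUs.  The implementation exploits this: funnels subsample a
precomputed $S \times S$ master distance matrix instead of rebuilding trees.

## The statistics

* **AvTD** ($\Delta^+$, average taxonomic distinctness): the mean of the
  $S(S-1)/2$ pairwise distances — the expected path length between a random
  pair of OTUs.  Higher is more taxonomically spread.  Presence/absence
  only; abundance-weighted variants are out of scope.
* **VarTD** ($\Lambda$, variation in taxonomic distinctness): the
  population variance of the same multiset of distances (divide by the
  number of pairs, not pairs − 1 — the distances are a complete population,
  not a sample of one).  Two trees can share an AvTD yet differ in shape;
  low VarTD indicates evenly subdivided taxa.
* **von Euler's imbalance index**
  $I_E = (\mathrm{AvTD}_{max} - \mathrm{AvTD}) /
         (\mathrm{AvTD}_{max} - \mathrm{AvTD}_{min})$,
  where the extremes are AvTDs of the totally-balanced and
  totally-imbalanced trees built on the *sample's own* per-level taxon
  counts and measured with the same scheme.  $I_E$ lives in $[0, 1]$, is
  invariant under uniform rescaling of step lengths, and works on trees
  with polytomies, which rules out most classical imbalance indices.
  Values above 0.25 often accompany biased samples; the package exposes
  this as a flag, not a verdict.

```{r tree9}
tree9 <- taxonomy(data.frame(
  species = paste0("sp", 1:9),
  genus   = c("G1", "G1", "G1", "G2", "G3", "G4", "G4", "G5", "G6"),
  family  = c("F1", "F1", "F1", "F1", "F1", "F2", "F2", "F2", "F3"),
  order   = "O1"))
distinctness(tree9, "unit")
```

### Extremal constructions

The imbalanced builder is bottom-up: at each level, lower taxa occupy
distinct upper taxa one by one until only one upper taxon is left, which
absorbs all the rest.  The balanced builder is top-down and must balance
*against every upper level at once*: each taxon is handed to the parent
whose chain of ancestor loads (own load first, then upward) is
lexicographically smallest, ties broken by index.  On counts $(9, 6, 3, 1)$
this yields 2 genera per family and, per family, one genus of 2 species and
one of 1 — the optimal arrangement.  Extremal trees are not unique; AvTD
differences between equally balanced arrangements are null or negligible,
and this deterministic tie-break is the package's documented choice.  When
the counts force a single shape ($\mathrm{AvTD}_{max} =
\mathrm{AvTD}_{min}$), $I_E$ is returned as 0 with a warning.

The two anchors differ in tightness.  The imbalanced tree concentrates the
maximum possible number of OTUs into a single taxon at *every* level
simultaneously, so $\mathrm{AvTD}_{min}$ is an exact lower bound for any
step lengths.  Perfect balance at all levels at once is not always
achievable (with counts $(12, 3, 2, 1)$, equal genus sizes force family
sizes $6/6$ versus $3/3/6$ genera — no arrangement balances both), so
$\mathrm{AvTD}_{max}$ is the canonical construction's value, which a
particular tree can exceed by a negligible margin (about 2% at worst in
randomized checks over degenerate count vectors).  $I_E$ is therefore
truncated into $[0, 1]$.

## Judging a sample: funnels and randomization tests

A raw AvTD number is uninformative; the reference is the master list
itself.  `funnel_analysis()` draws $k$ random subsamples (uniform, without
replacement, unstratified) at each dimension $s$ and summarizes the
replicate AvTD and VarTD distributions with the mean, the one-tailed 95%
limit and the observed extreme.  Because every pair of OTUs is equally
likely to enter a uniform subsample, the replicate mean at any $s$ is an
unbiased estimate of the whole-master AvTD — the funnel's centre line is
flat, which is what makes samples of different sizes comparable.  VarTD is
slightly biased low for very small $s$ (roughly $s \le 10$); visible in
funnels, negligible above that.

Quantiles are attained order statistics (sorted value at the ceiling
index, no interpolation), so every funnel line is a value some replicate
actually achieved.  One-tailed limits use the 5th (AvTD) and 95th (VarTD)
percentiles; the shuffling bands below use 2.5%/97.5%.

`significance_test()` is one-tailed by default: for representativeness
only an unusually *low* AvTD (or *high* VarTD) is bad — a sample more
distinct than random is welcome.  With $k$ replicates,

$$p_{\mathrm{AvTD}} = \frac{1 + \#\{\mathrm{AvTD}_{rep} \le
\mathrm{AvTD}_{obs}\}}{k + 1},$$

and symmetrically ($\ge$) for VarTD.  The `tail = "two"` option doubles
the smaller tail, recovering the original ecological test that flags both
degraded and pristine assemblages.  The default $k = 100$ follows the
standard funnel practice; an intermediate $k$ (100–1,000) is recommended
because as $k \to \infty$ the extreme lines converge on the absolute
attainable extremes and no sample can sit beyond them.  The AvTD replicate
distribution is typically slightly left-skewed; `distribution_summary()`
reports moment skewness and quantiles as a diagnostic.

## Stability under taxonomic revision

Taxonomies are revised, so the verdict should not hinge on one edition of
a classification.  `shuffling_analysis()` perturbs the master list with the
three moves taxonomists actually make — **transfer** (reparent a taxon,
levels $1..T-1$), **split** (bipartition a taxon's children into two new
taxa, levels $2..T-1$) and **merge** (fuse two taxa within one parent,
levels $2..T-1$) — producing many "reviewed" master lists, re-running the
funnel analysis on each (proportional step lengths are recomputed per list,
as counts change), and banding the four funnel lines with 2.5%/97.5%
quantiles across lists; for the max-AvTD and min-VarTD series the extreme
across lists is kept.  Narrow bands mean the original verdict survives
plausible revision.

Design choices worth knowing:

* Moves draw uniformly over the taxa for which the move is legal — the
  same law as rejection-sampling an arbitrary taxon and redrawing on an
  illegal pick, but guaranteed to terminate; an empty legal set is an
  immediate error, never a loop.  A split taxon must have at least two
  children (two non-empty parts must exist); a merge partner is drawn
  within the same parent.
* Split bipartitions are uniform over non-empty labeled two-part
  partitions; new taxa get deterministic names (`x_split1`, `a+b_merged`)
  so shuffled lists are diffable.
* Each shuffled list is generated under its own derived seed while all
  per-list funnels share one funnel seed (common random numbers): band
  width then measures the taxonomic perturbation, not resampling noise,
  and a zero-move specification collapses the bands exactly onto the
  single master's funnel.
* Move counts are deliberately user-supplied.  No objective criterion for
  the "right" amount of shuffling exists; revision intensity is a judgment
  about each group's taxonomic history.

## Synthetic master lists

`synthetic_taxonomy()` builds a random hierarchy with exact per-level
taxon counts: top-down, each level's taxa are attached by a random
surjection (one child per parent first, surplus placed uniformly), so no
internal taxon is ever empty.  It emulates the structure of real master
lists — polytomies, uneven taxon sizes — but not the historical
correlations of real classifications, so passing tests on synthetic
taxonomies validates the algebra and the sampling machinery, not any
biological claim.  Test and example sizes in this package (masters of
500 OTUs for funnel checks, 200 OTUs over five levels for shuffling
checks, 100 random taxonomies of up to 30 OTUs for oracle equivalence,
funnels of $k \approx 100$, band estimates over ~100 lists × 20
replicates) were chosen as the smallest problems on which the checked
properties are sharp; the machinery itself handles master lists of
thousands of OTUs.

## Numerical conventions and degenerate inputs

* Population (divide-by-$n$) variance throughout, including moment
  skewness $m_3 / m_2^{3/2}$ ($0$ when $m_2 = 0$).
* Quantiles: attained order statistic at the ceiling index, clamped to
  $[1, k]$.
* Trees need $S \ge 2$ and $T \ge 2$; a sample needs at least 2 OTUs.
  Duplicate OTU names, a taxon under two parents, missing cells and a
  non-unique top taxon are parse-time errors, with the offending taxon
  named.  Homonymous taxa under different parents must be spelled
  distinctly — the shuffling moves need unambiguous taxon addressing.
* Samples are lists of OTU names; representing a sample by higher taxa is
  unsupported.  Extinct OTUs are ordinary rows — a good sample spans the
  whole diversity of the group, fossils included.
* Any rank can serve as the OTU level (genus-level master lists are
  common); nothing in the machinery assumes species.

## Limitations

* The method inherits the subjectivity of the underlying taxonomy;
  the shuffling analysis quantifies, but cannot remove, that dependence.
* Only presence/absence enters the indices; abundance-weighted
  distinctness is out of scope.
* No name resolution or synonym handling: OTU names must match the master
  list exactly.
* The $I_E > 0.25$ screen is a rough guide — samples above it can still
  sit comfortably inside their funnels.
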