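---
title: "Methods: temporal co-occurrence networks, keystone taxa and enzyme profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal co-occurrence networks, keystone taxa and enzyme profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`rumennet` implements the downstream statistics for temporal
metatranscriptomes of microbial communities attached to fresh forage in the
rumen. The input is a post-annotation bundle: a gene x sample integer count
table, per-gene metadata (taxonomic family, genus, functional cluster,
optional enzyme tag such as `GH5`, `M24b` or `LuxS`, and CDS length), and a
sample design mapping each sample to a host animal and an incubation
timepoint in hours. Everything upstream — read QC, assembly, CDS prediction,
taxonomic and functional annotation — is out of scope; the package starts
where the annotated count table ends.

The study design the defaults encode is an in sacco incubation: three
rumen-cannulated animals, forage bags withdrawn at 1, 2, 4, 6 and 8 h, plus
one pooled pre-incubation (0 h) sample of plant-epiphytic prokaryotes. The
0 h sample represents an unrelated epiphytic community and is excluded from
every analysis by default.

# Pre-processing chain

Network construction operates on taxonomic families, in a fixed order that a
stage tag on the matrix enforces:

1. **Aggregation**: gene counts are summed per family per sample.
2. **Minimum-gene filter**: families with fewer than 10 *expressed* genes are
   removed. The source protocol does not define "expressed"; we count a gene
   as expressed if it has at least one read in at least one retained sample,
   the most permissive reading, and expose the threshold as `min_genes`.
3. **Sample-sum scaling**: each value is divided by its sample total and
   multiplied by the median of all sample totals, so every column sums to
   the median. This removes library-depth differences (and any effect shared
   by all families in a sample).
4. **IQR variable filter**: each family's inter-quartile range across samples
   is computed with type-7 quantiles (stated explicitly because the filter
   boundary depends on the interpolation rule), and families whose IQR is
   strictly below the 25th percentile of all family IQRs are removed. The
   protocol sentence is ambiguous between filtering on IQR and filtering on
   total expression; filtering on IQR matches the variable-filtering
   literature it cites and is the default, with `mode = "total"` as the
   alternative reading.
5. **Regularised log**: `log2(x + 1)` on the scaled values. This is a
   deliberate surrogate for shrinkage-based variance-stabilising transforms:
   the only downstream consumer is a *rank-based* correlation, and any
   strictly monotone transform yields the identical edge set, which the test
   suite asserts directly. Re-deriving a shrinkage estimator would change
   nothing downstream while adding an opaque dependency.

# Co-occurrence network

Spearman's rank correlation is computed between all family pairs across the
15 incubation samples; p-values use the t approximation
`t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom,
adequate at `n = 15` (an exact permutation option exists for very small
designs), and are Benjamini–Hochberg adjusted over the strict upper
triangle. An edge joins two families when `|rho| > 0.7` *and* the adjusted
p-value is below 0.1. The magnitude rule is a deliberate reading: the
protocol text says "larger than 0.7" while its network figure displays
negative (antagonistic) edges, so signed magnitudes must qualify; a
`signed = FALSE` switch restricts edges to positive correlations.

**Clustering.** Communities are detected by greedy modularity agglomeration
on the unweighted skeleton of the *positive* edges, cutting the dendrogram
at the modularity maximum (ties within 1e-12 go to the coarsest partition,
which keeps results stable against floating-point drift in merge scores).
Negative edges are excluded from clustering on purpose: in this design the
two colonisation phases are strongly anticorrelated, so the unsigned
skeleton is nearly complete bipartite between them and modularity on it
cannot separate the phases that the negative edges precisely delimit.
Negative edges remain in the graph and in all five measures below. Nodes
whose only edges are negative become singleton modules; isolated nodes get
no label.

The pipeline summary counts modules with at least five nodes as "clusters";
with 15 samples the edge rule admits roughly one chance edge per run among
unrelated families, so dyad or triad modules are sampling artifacts, and
they are reported separately (`n_modules_total`).

# Five network measures and keystone identification

Five graph-level measures are computed on the full, unsigned, unweighted
skeleton:

* transitivity: `3 * triangles / connected triples` (0 when no triple);
* density: `2E / (N(N-1))`;
* modularity `Q` of the (fixed) detected partition;
* average path length over *reachable* ordered pairs (0 when none);
* eigenvector centralisation: `sum(c_max - c_i) / (N - 1)` with scores
  scaled so the most central node has 1.

Eigenvector centrality needs a convention for disconnected graphs, which
arise constantly during node removal: we take the Perron vector of the
connected component with the largest spectral radius (ties broken by
component size, then smallest vertex id), computed by a dense symmetric
eigendecomposition, and score all other nodes 0. An iterative sparse solver
is not deterministic when the leading eigenvalue is degenerate (two tied
components), which is why the convention is pinned and implemented directly.

**Keystone procedure.** For every labelled node, the five measures are
recomputed on the graph minus that node, with the partition held fixed and
restricted to the remaining nodes (no re-clustering: deltas must isolate the
removed node's structural contribution, not the detection algorithm's
instability). Per cluster and per measure, nodes are ranked in the direction
a structurally load-bearing node moves the measure — transitivity and
density should *fall* on removal, modularity, average path length and
centralisation should *rise* — with average ranks for ties (deltas equal to
1e-10 are treated as tied, absorbing eigendecomposition round-off). The
Borda score is the exact sum of the five ranks; the lowest score per cluster
ranks first and the top two are flagged as putative keystones. Equal Borda
scores are reported as ties; node-id order is used only to make the output
ordering deterministic.

Measures are computed on the full network rather than the cluster subgraph
(a `scope = "subgraph"` switch exists) because the procedure perturbs the
community-wide structure while identification is performed within each
cluster's candidate set.

One behavioural consequence of the reachable-pairs path-length convention is
worth knowing: removing a *bridge* disconnects the graph, the long
cross-component pairs drop out of the average, and the path length falls
rather than rises, so pure bridges are rewarded on modularity and
centralisation but not on path length. The alternative convention (counting
unreachable pairs as paths of length N) is available via
`net_avg_path_length(unreachable_as_n = TRUE)` but is not the default, since
the default is applied consistently to both the full and perturbed graphs
and only rank differences feed the Borda aggregation.

# Temporal differential expression

Expression is summarised by (taxonomic family, functional cluster) feature;
genes without a cluster go to a reserved `"unclustered"` id with a warning.
The reference analysis used a negative-binomial likelihood-ratio engine; the
stage's contract here is defined on the p-value table so any engine can be
plugged in (`external_pvals`), and the default engine is a documented
surrogate: per feature, a linear model on regularised-log values with
additive animal and timepoint factors. The time p-value is the F-test of
`animal + time` against `animal`, the animal p-value against `time`; both
are BH-adjusted across features. Features passing the time screen (BH
< 0.1) minus those flagged for an animal effect (same threshold — the
reference excluded animal-interacting genes without stating a cutoff, so we
reuse the study-wide 0.1) proceed to all 10 pairwise timepoint contrasts,
computed from the same model's residual variance and BH-adjusted within
feature. The bespoke scientific content of this stage — contrast
enumeration, letter assignment, pattern grouping — is independent of the
engine choice.

**Significance letters.** Timepoints form a graph whose edges join pairs
*not* significantly different (adjusted p >= 0.1); its maximal cliques
(Bron–Kerbosch via igraph; at most 5 nodes here) each receive a letter in
order of their earliest timepoint, and a timepoint's label concatenates the
letters of every clique containing it. Two timepoints share a letter exactly
when they co-occur in some maximal clique — the package verifies this
biconditional exhaustively against subset search for all 1024 possible
5-timepoint non-significance graphs. Pattern keys re-index letters by first
appearance in time order, so two features have equal keys exactly when their
letter assignments agree up to renaming.

**Pattern grouping** restricts to features in the top 90% of cumulative
total expression (descending sort, minimal prefix reaching the fraction —
the cumulative-mass reading of "top 90% most highly expressed"; a per-gene
quantile cut would be the other reading and `top_fraction = 1` disables the
restriction), groups them by pattern key, and reports per-pattern feature
counts, per-timepoint summed expression (averaged over animals) and
per-family contribution proportions.

# Enzyme-family profiling

TPM is computed over every gene in the table
(`rate = count / length_kb`, scaled so each sample sums to 1e6). Genes
sharing an enzyme tag are summed per sample; LuxS (AI-2 quorum-sensing) genes
are summed per taxonomic family instead, because the biological question
there is which taxa signal, not which enzyme variant. Within each of GH and
peptidase separately, families outside the 95% most highly expressed
(cumulative share, as above) are excluded; LuxS rows are never filtered.
Each retained family is tested with a two-way fixed-effect ANOVA
(`TPM ~ animal + time`, no interaction, balanced design) and the time
p-values are BH-adjusted across families at 0.1. Significant families get
Tukey HSD letter groups: the Tukey–Kramer statistic
`q = |m_i - m_j| / sqrt((MSE/2)(1/n_i + 1/n_j))` referred to the studentized
range distribution with the model's residual degrees of freedom, fed through
the same maximal-clique letter routine. For two groups the studentized range
CDF reduces exactly to the two-sided t CDF and the implementation uses that
closed form (the numeric approximation in the standard distribution function
is only accurate to about 1e-4, which matters for the documented k = 2
equivalence). Per-taxon contributions report each taxonomic family's share
of each enzyme family's TPM per timepoint, averaged over animals; shares sum
to one where expression is non-zero and are missing otherwise.

# The synthetic-data generator

The generator is first-class, tested code: it emulates the statistical
structure the analysis assumes so every stage has a ground-truth test bed.

* **Trajectories.** The primary-block template declines monotonically from a
  1 h peak; the secondary template is its mirror image rising to 8 h.
  Member trajectories multiply the template by a lognormal family amplitude
  (SD 0.4) and per-timepoint lognormal jitter (SD 0.1), then are re-ordered
  to the template's rank order, so the rank correlation between any primary
  and any secondary trajectory is exactly -1 and within-block trajectory
  ranks are exact. Piecewise-linear interpolation extends the templates to
  non-default timepoints.
* **Counts.** Negative binomial (size 30; `Inf` gives Poisson) with mean =
  family trajectory x Dirichlet(1) gene weight x per-(family, animal)
  lognormal effect (SD 0.08) x per-(family, sample) biological
  overdispersion factor x lognormal library-size factor (SD 0.2). The
  per-sample biological factor is essential: without it every block member
  tracks the template almost perfectly, the blocks become complete cliques,
  and node removal cannot distinguish any member from any other.
* **Planted keystones** (2 per block, abundance 5% of the block template)
  are exactly proportional to the template and carry the smallest biological
  overdispersion (SD 0.05), while members draw theirs uniformly from
  [0.35, 0.65]. Faithful tracking is the planting mechanism: the keystones
  correlate more strongly with every member than members do with each other,
  making them the block's connector hubs, while remaining in the lowest
  decile of total expression. The member noise floor is deliberately far
  above the keystone's; members that tracked the template as well as the
  keystones would be indistinguishable from them, by construction and in
  fact.
* **Independent families** come in two tiers: a dominant high-expression
  tier (flat trajectories at 0.5-2.5x the block scale, emulating highly
  active families that interact with neither phase) and a low-abundance
  stable tier (0.03-0.06x). The stable tier is what occupies the bottom
  quartile of IQRs, so the IQR filter removes it rather than the planted
  keystones — mirroring the observation that real keystones survive to the
  network despite very low activity. Independent overdispersion is drawn
  from [0.15, 0.25]; pushing it lower makes the three-level animal effect
  the dominant variation and generates spurious correlations between
  unrelated families.
* **Baseline.** The 0 h sample draws from an unrelated flat epiphyte profile
  (0.002-0.02x scale) and is excluded by downstream defaults.
* **Annotations.** Gene lengths are uniform on 300-3000 bp; enzyme tags are
  assigned independently of block membership at configured fractions, with
  tagged genes placed in umbrella functional clusters (`FC_GH`,
  `FC_peptidase`, `FC_QS`); one genus per family except one two-genus family
  by default. Identical configuration and seed give bit-identical bundles.

**What the generator does not emulate.** Real communities have hundreds of
families with heavy-tailed abundances, phylogenetically correlated dynamics,
more than two colonisation guilds, compositional coupling between families,
and keystones whose importance is mediated by metabolite exchange rather
than correlation fidelity. Passing the planted-recovery tests therefore
shows the pipeline implements its contract — it recovers structure of the
kind it assumes — not that the keystone procedure identifies ecological
keystones in real data.

**Problem sizes.** Defaults simulate 48 families (12 + 12 block members,
2 + 2 keystones, 20 independents) with 20-35 genes each (~1,300 genes) over
16 samples. These sizes keep a full pipeline run in seconds while leaving
every filter with genuine work to do; the test suite runs replicate
pipelines and 200-graph brute-force comparisons within minutes on one CPU.

# Numerical choices and degenerate inputs

* Quantiles are type-7 everywhere (the IQR filter boundary depends on it).
* Spearman p-values at `|rho| = 1` are 0 by convention (the t statistic
  diverges); constant families give missing correlations and never edges.
* Near-constant responses (variance below 1e-20 relative) are reported as
  F = 0, p = 1 in both the DE screen and the enzyme ANOVA rather than
  letting floating-point noise decide a perfect-fit F ratio.
* Node-removal deltas are rounded at 1e-10 before ranking so structural
  ties receive average ranks.
* Removing a node from a graph whose remainder has no edges leaves
  modularity undefined both before and after; the delta is reported as 0.
* The dendrogram of the greedy clustering is cut at the modularity maximum
  with ties to the coarsest partition (a complete graph is one community
  with Q = 0, not n-1 communities with Q = -epsilon).

# Known limitations

* The linear-model DE surrogate on regularised-log values is not a
  negative-binomial likelihood-ratio test; at low counts its p-values are
  approximate. The stage accepts external p-value tables precisely so a
  dedicated count engine can be substituted without touching the contrast,
  letter or pattern machinery.
* With 15 samples, the edge rule admits occasional chance edges; the
  cluster summary is robust to them (size threshold) but individual spurious
  edges remain in the graph, as they would in the real analysis.
* Keystone identification is purely topological; abundance never enters the
  score, and the procedure inherits the documented bridge behaviour of the
  reachable-pairs path-length convention.
* The Borda ranking is computed within clusters; nodes are never competed
  across clusters.
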