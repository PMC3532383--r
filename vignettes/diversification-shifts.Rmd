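---
title: "Topology-based diversification analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-based diversification analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cladeshift asks one question of a species-level phylogeny: where, and when,
did lineages diversify faster than a homogeneous birth process would
predict?  It answers it purely from tree shape — no branch lengths are
needed until the final, temporal stage — which makes the method applicable
to composite trees in which many species are placed taxonomically rather
than from molecular data.

## The null model

Everything is calibrated against the equal-rates Markov (ERM) model of
clade growth: at every moment each extant lineage is equally likely to
split.  Its two consequences drive all the statistics:

* a clade of $n$ tips splits into left/right parts $(i, n-i)$ with
  probability $2/(n-1)$ for unequal parts and $1/(n-1)$ for equal halves
  (the *uniform split law*), independently across nodes;
* the continuous-time Yule (pure-birth) process has exactly this topology
  law, so `simulate_yule_dated()` and `simulate_erm_tree()` agree on
  shapes while the former also supplies node ages.

`simulate_erm_tree()` grows a labeled topology by iterated uniform tip
splitting.  The Monte-Carlo nulls never materialize labels: they recurse
over split sizes only (compiled code), which is what makes a
$10^4$-replicate null for a 2,263-tip tree a matter of seconds.

## Whole-tree imbalance

`whole_tree_test()` computes four indices per tree:

* **IC** (Colless): $\sum_v |l_v - r_v|$ over internal nodes; larger =
  more imbalanced.
* **B1**: $\sum_v 1/M_v$ over non-root internal nodes, $M_v$ the maximum
  edge-count depth below $v$; larger = more balanced.
* **MPi**, **Msig**: mean and population standard deviation of the
  per-node log ERM split probabilities $\ln p_v$, taken over nodes with at
  least 3 descendant tips.  Cherries are excluded because a 2-tip node has
  only one possible split and carries no shape information.  The product
  $\prod_v p_v$ over all internal nodes is exactly the ERM probability of
  the tree's shape, which gives these summaries a direct likelihood
  reading and an exact enumeration oracle for testing.

The published method this package re-implements inherits its two
log-probability indices from earlier tree-shape work without reprinting
their algebra; the operationalization above is this package's explicit,
tested commitment.  Any monotone variant would be calibrated identically
by the Monte-Carlo null, but absolute values of MPi/Msig reported by other
software need not be comparable.

P-values use the tie-inclusive convention $p = (1 + \#exceedances)/(1 +
n_{null})$, which cannot return 0 and makes the tests conservative rather
than anticonservative.  Tails point toward imbalance as specified for the
re-implemented procedure: greater for IC and Msig, lesser for MPi and B1.
A caveat worth stating: for large ERM trees the null mean of MPi sits
near $-1.15$, and which side of it a "more imbalanced" empirical tree
falls on depends on the balance between its surplus of uneven splits
(pushing $\ln p_v$ up) and its surplus of deep, large nodes (pushing
$\ln p_v$ down).  The tail conventions are therefore part of the
package's contract, not a law of nature, and `whole_tree_test()` reports
the observed values so users can inspect both tails.

## Soft polytomies

Polytomies are treated as statements of ignorance, never resolved at
parse time.  `resolve_polytomies()` replaces a degree-$k$ node by a
uniformly random labeled history of its $k$ children — the same ERM
growth process, run over child subtrees — so resolution adds no
systematic imbalance signal.  `whole_tree_test()` and `scan_shifts()`
recompute their statistics over `n_resolutions` independent resolutions
and report 2.5%/97.5% quantiles (or min/max on request) plus the median
as point estimate; the aggregation choice is ours, since the original
procedure does not state one.  One null sample is shared by all
resolutions of a tree — they have identical tip counts, so this is exact
and saves a factor of `n_resolutions` in simulation.

## The delta-1 branch statistic

For an internal branch whose child node is internal, the *local triplet*
is (outgroup clade $n_O$; the two basal ingroup clades $n_L$, $n_R$).
With $n_I = n_L + n_R$ and $n = n_O + n_I$:

* `node_shift_loglr(n, i)`: under homogeneous ERM the ingroup size $i$ is
  uniform on $1..n-1$; under a one-shift two-rate model it follows a
  truncated geometric $P(i \mid n, r) = r^i / \sum_j r^j$.  The statistic
  is $\ln \sup_r P(i|n,r)/(1/(n-1))$, solved through the score equation
  (the truncated-geometric mean is strictly increasing in $\ln r$, so a
  bracketed bisection on stable closed forms of $\log\sum_j e^{j\theta}$
  converges in all regimes).  It equals $\ln(n-1)$ exactly at $i \in \{1,
  n-1\}$ and 0 at even splits.
* `delta1()`: $\Delta_1 = \mathrm{loglr}(n, n_I) - \mathrm{loglr}(n_I,
  n_L)$ — evidence for a shift along the branch, net of the evidence
  already attributable to the child's own split.  It is symmetric in
  $n_L \leftrightarrow n_R$ and can be negative.

This two-rate likelihood-ratio construction is the package's
reconstruction of a statistic whose original algebra is not reprinted in
the source literature; per-branch values from other implementations may
differ even where the ranking of branches largely agrees.  The
reconstruction is pinned down by its boundary closed form, an optimizer
oracle, reflection symmetry and center monotonicity in the test suite.

`scan_shifts()` evaluates every eligible branch and offers two nulls:

* **pooled** (default, the procedure as published): $\Delta_1$ values of
  all eligible branches of `n_null` ERM trees of the same size, pooled.
  Branches with large inclusive clades inherit a mild excess of large
  null values from the small-clade-dominated pool, so per-branch type-I
  error is nominal *on average* (about 4–5% at $\alpha = 0.05$ in the
  shipped calibration tests) but not uniformly across clade sizes.
* **size-conditional**: the null is drawn conditionally on each branch's
  parent clade size (an eligible uniform split of that clade followed by
  a uniform nodal split).  This is the better-calibrated choice for
  per-branch inference and is what the power analyses use; it costs one
  null sample per distinct clade size.

Significance classes are `significant` ($p < 0.05$) and `marginal`
($0.05 \le p < 0.10$); `alpha_inclusive = TRUE` moves the boundary case
$p = 0.05$ into the significant class for comparability with reports that
treat the boundary as significant.  No multiple-testing correction is
applied, matching the procedure being re-implemented; with ~2,000
branches per scan, users
should read individual marginal calls accordingly.

## Composite trees

`graft_missing_species()` attaches each species lacking molecular data at
the MRCA of the sampled members of its lowest-ranked taxonomic group with
any sampled member (genus, then tribe, then subfamily, then family) —
"lowest rank first" being the only reading consistent with attachment to
the closest relative.  Missing congeners join the same node as one
polytomy rather than an arbitrary nested chain, since nothing orders them.
Grafted tips carry no ages: composite trees are topology-only objects,
which is precisely why the shift scan is built shape-only.  Species whose
entire family is unsampled are reported, not guessed at.  Coverage
accounting (`coverage_summary()`) uses nearest-integer percentages.

## The temporal stage

`epoch_shift_summary()` consumes a *dated* tree — in practice the
molecular tree, since grafted tips are undated — plus a shift report and
an epoch table.  Conventions, each configurable:

* a branch's statistic is dated by its child node (`attribute =
  "child"`); the child is the node whose clade the statistic describes,
  but `"parent"` is available;
* epochs are half-open young-side: a boundary age belongs to the younger
  epoch; the youngest epoch is closed at 0.  The default table runs
  Paleocene (65.5–55.8 Mya) through Quaternary (1.8–0 Mya), with the
  Oligocene/Miocene limit at 23.03 Mya (both 23.03 and the rounded 23.0
  are in common use; we apply the finer figure on both sides);
* `nodes = "eligible"` bins exactly the triplet-eligible branches;
  `"all-internal"` additionally includes the root, dated by its own
  nodal evidence $\mathrm{loglr}(n, i_{root})$, since it has no outgroup.
  Neither option reproduces every conceivable node-counting convention
  in the literature, which is why both are explicit.

Group comparison is a standard one-way fixed-effects ANOVA with Tukey HSD
(delegated to `stats::aov()`/`stats::TukeyHSD()`), on $|\Delta_1|$.

## The generators

The synthetic module defines the study conditions under which the
pipeline is validated:

* `simulate_yule_dated(n, lambda)`: crown-start pure birth; `lambda` is
  per-lineage per-Myr.  The default 0.2 gives trees a few tens of Myr
  deep at a few hundred tips, the scale of the empirical setting.
* `plant_rate_shift(..., s, shift_at_k = 8)`: one clade switches to rate
  `s * lambda`.  The default lineage-count trigger (at 8 lineages) plants
  an old shift whose clade is expected to be large — the regime the
  statistic is designed for; a time trigger is available and resamples
  (with a reported retry count) when the tree outruns it.
* `simulate_taxonomy_and_sampling(tree, f = 0.56)`: genera and families
  are height cuts at 1/3 and 2/3 of tree height, so ranks nest and every
  group is monophyletic by construction; each species is sampled
  independently with probability `f`, defaulting to the 56% coverage of
  the empirical species list.

What these generators deliberately do not emulate: extinction (the null
is pure ERM, so no birth–death machinery), non-random taxonomic sampling
(real sequence databases oversample some families), synonymy noise in
species lists, and phylogenetic error in the molecular tree.  Green
property tests therefore certify internal statistical consistency, not
robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* Ultrametricity tolerance for deriving ages from branch lengths:
  relative $10^{-6}$ of tree height; the worst-offending tip is named in
  the error.
* `node_shift_loglr` memoizes solved $(n, i)$ pairs across calls and uses
  series expansions near $\theta = 0$; boundary cases bypass the solver.
* Monte-Carlo defaults `n_null = 10000`, `n_resolutions = 1000`
  (whole-tree) and 100 (scan) are desk-scale; the published setting of
  $10^6$ null trees is supported by the same code path.  Tests and the
  acceptance script use 128–300-tip trees with $10^3$–$10^4$ replicates
  and one 2,263-tip scan, sizes chosen to exercise every code path at
  full statistical resolution.
* All-identical ANOVA inputs return $F = 0$, $p = 1$ rather than NaN;
  single-epoch binnings skip the group comparison with a message.
* `n_null < 100` is rejected outright — it cannot resolve
  $\alpha = 0.05$.

## Known limitations

* The delta-1 and MPi/Msig operationalizations are reconstructions (see
  above); cross-implementation numeric identity is not guaranteed and
  one published per-branch value is provably unreachable under this
  algebra from printed clade sizes alone.
* Pooled-mode per-branch p-values are size-confounded by construction;
  prefer size-conditional mode for inference on individual branches.
* Grafting restores species richness but not branch lengths; nothing
  here should be used to date composite nodes.
* The temporal stage inherits whatever dating uncertainty the input
  chronogram carries; it treats ages as known.
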