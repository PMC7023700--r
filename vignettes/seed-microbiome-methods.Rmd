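---
title: "Methods: eco-evolutionary analysis of seed microbiome communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-evolutionary analysis of seed microbiome communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`seedmb` implements the statistical core of an eco-evolutionary seed
microbiome study design: bacterial and fungal OTU tables over a panel of
host accessions (wild relatives and domesticated cultivars of a crop, each
with replicate seed samples), a host phylogeny, and a breeding pedigree.
The pipeline asks five questions: does host phylogeny leave a signature in
community composition (phylosymbiosis)? How much compositional variance
does domestication explain? Does domestication concentrate abundance into
fewer taxa? Which OTUs shift, and can they classify the host's
domestication status? And is the seed community maternally transmitted
along the pedigree?

Every stage is validated against a synthetic-community generator with
known ground truth, because the questions above are only meaningful if the
statistics recover signals that are planted and stay quiet when nothing
is.

# Normalization

Sequencing depth varies by orders of magnitude between libraries, and
rarefying discards reads. Two transforms are used, each where it suits:

* **Cumulative-sum scaling (CSS).** For sample $j$ the scale factor is
  $s_j = \sum_i c_{ij}\,[c_{ij} \le q_j]$, the sum of counts up to the
  chosen quantile $q_j$ of the sample's positive counts. Normalized values
  are $c_{ij}/s_j \times 1000$, then $\log_2(x+1)$. The output scale
  constant 1000 makes worked examples exact; log base 2 keeps downstream
  fold changes on the conventional scale. The quantile can be fixed
  (0.5 is the documented fallback) or chosen adaptively: the smallest
  quantile on a 0.05–0.95 grid at which the relative median absolute
  deviation of the per-sample cumulative-sum fractions exceeds 0.1. The
  quantile actually used and the per-sample scale factors are recorded on
  the returned object, since CSS-normalized results are method-faithful,
  not bit-portable, across quantile choices.
* **Hellinger** ($\sqrt{c_{ij}/\sum_i c_{ij}}$) for alpha diversity and
  Lorenz/Gini curves, where the square-root damps the influence of
  dominant taxa without discarding depth.

CSS is scale-equivariant (multiplying a library's counts by a constant
leaves its normalized column unchanged at a fixed quantile); this is
asserted in the test suite.

# Diversity and inequality

Alpha diversity reports observed OTUs, Shannon entropy (natural log),
Gini–Simpson $1-\sum p_i^2$ and inverse Simpson $1/\sum p_i^2$. Group
contrasts use the exact two-sided Wilcoxon rank-sum test for two groups
(normal approximation with tie correction when ties preclude exactness)
and one-way ANOVA with Tukey HSD for more.

Abundance inequality uses the Lorenz curve (cumulative abundance share
against cumulative OTU fraction, lowest to highest) and the Gini
coefficient, computed in the mean-absolute-difference form
$G = \sum_{ij} |x_i - x_j| / (2 n^2 \bar x)$, which equals the
Lorenz-area definition; the equality is verified to $10^{-9}$ on random
vectors. The Pareto fraction is the smallest fraction of OTUs (most
abundant first) whose cumulative share reaches a target (default 80%),
with a $\ge$ crossing rule so the statistic is deterministic. Inequality
statistics are computed on pooled per-group abundance profiles by default
(per-sample profiles remain available through `lorenz_gini()` directly):
the pooled profile is what the "x% of OTUs hold 80% of reads" statement
refers to.

# Ordination and variance partitioning

Bray–Curtis dissimilarities ($\sum_i|x_i-y_i| / \sum_i(x_i+y_i)$) are
computed on CSS-log values, or on presence/absence (the Sørensen
identity) for pedigree comparisons. PCoA reports **all** eigenvalues:
Bray–Curtis matrices are non-Euclidean and the negative part of the
spectrum is information, not noise. A consequence asserted in the tests:
the Euclidean embedding over positive axes can only stretch the original
dissimilarities, and the total squared stretch equals the negative
eigenvalue mass.

PERMANOVA partitions $SS_{total} = \frac1n \sum_{i<j} d_{ij}^2$ via the
Gower-centred inner-product matrix, with sequential sums of squares in
user order for multi-factor models and pseudo-$F$ tested by permuting
sample labels. CAP (distance-based RDA) regresses the positive-eigenvalue
PCoA axes on the constraint's dummy variables; constrained plus
unconstrained inertia equals the total by construction, and negative
eigenvalue mass is reported separately rather than folded in. All
permutation p-values use the add-one convention
$p = (1 + \#\{stat_{perm} \ge stat_{obs}\})/(n_{perm}+1)$, so $p$ can
never be zero and the floor $1/(n_{perm}+1)$ gives the familiar
significance floors such as $p < 10^{-5}$ at 99,999 permutations. Permutations are seeded and the
seed is carried in every result object.

# Phylosymbiosis

Community dendrograms are UPGMA (average-linkage) trees of Bray–Curtis
distances between accession-level communities, with ids sorted
lexicographically before clustering so ties break deterministically.
Congruence with the host phylogeny is the Robinson–Foulds distance on
non-trivial unrooted bipartitions, normalized by the maximum attainable
for the two trees ($2(n-3)$ when both are resolved); rooting is
irrelevant by construction.

Significance comes from randomized trees: by default the dendrogram's
leaf labels are shuffled (shape-preserving, the conservative choice);
uniformly random binary topologies are available as an alternative and
the model used is recorded in the result. The p-value is the add-one
fraction of randomized trees at least as congruent as observed. For up to
52 leaves the null loop encodes bipartitions as exact double-precision
bitmasks, which makes $10^5$ randomizations routine.

A caveat worth stating explicitly: the RF statistic is discrete, and a
random relabeling of one tree almost never shares a split with the other,
so under the null most of the probability mass sits at the maximal score
and the tie-counting p-value is conservative, not uniform. The test's
type-I error can therefore sit below the nominal level; it is never
anticonservative, and that validity (rather than strict uniformity) is
what the test suite asserts for the relabeling null. Under the full
simulated pipeline null (no host-tree signal, dendrograms estimated from
noisy communities) the measured rejection rate sits near the nominal 5%.

# Differential abundance

Zeros in amplicon tables mix "absent" with "not sampled deeply enough".
The differential stage models CSS-log values per OTU as a zero-inflated
Gaussian: a point mass at zero whose prior probability is a logistic
function of the sample's sequencing depth, plus a Gaussian with
group-specific means. An EM loop alternates the E-step (posterior
probability each observed zero is technical) with weighted
least-squares group means and a weighted logistic refit of the depth
model; convergence at $10^{-6}$ maximum parameter change or 100
iterations (with a warning, results still returned — the moderated test
downstream is robust to late-stage EM wobble).

Moderated $t$ statistics shrink per-OTU variances towards a common prior,
$s^2_{post} = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with $(d_0, s_0^2)$
estimated by moment matching of $\log s^2$ across OTUs (digamma/trigamma
equations, with a Newton inversion of the trigamma); $d_0 = 0$ recovers
the ordinary two-sample $t$ exactly, which the tests check. The
wild/domesticated contrast is always reported as domesticated minus wild,
and labels named exactly `wild`/`domesticated` are releveled so the sign
convention cannot silently flip. OTUs are called enriched at
$|\log_2 FC| > 2$ and BH-FDR $q < 0.01$.

Core OTUs are prevalence-based: an OTU is present in an accession if
detected in at least one of its replicates (configurable), and core if
present in at least 95% (bacteria) or 80% (fungi) of accessions.

# Classification

A random forest (1500 trees by default) is trained on a random two-thirds
of samples; held-out AUC (rank-based, ties counted half) and 10-fold CV
accuracy are reported with mean-decrease-Gini importances. The
feature-elimination curve retrains at each feature count of a decreasing
schedule, re-ranking importances **inside each CV fold** on the training
folds only — ranking once globally leaks the test fold into feature
selection and flattens the curve, so the global mode exists but is not
the default. `selected_k` is the smallest feature count whose CV error is
within 0.02 (absolute) of the full-model error; on simulated data with 20
informative OTUs the error curve stays flat until roughly those 20 remain
and rises sharply below them.

# Co-occurrence networks

Relative abundances are compositional, so plain correlations on fractions
are biased; the network stage re-implements the SparCC estimator. Per
outer iteration, fractions are drawn from a per-sample Dirichlet
(counts + 1) posterior; log-ratio variances
$t_{ij} = \mathrm{var}\log(x_i/x_j)$ are formed; basis variances solve
the sparsity approximation $\sum_j t_{ij} = (p-2)\omega_i + \sum_j
\omega_j$; and $\rho_{ij} = (\omega_i + \omega_j - t_{ij}) /
(2\sqrt{\omega_i\omega_j})$. An inner loop excludes the
strongest-correlated pair (while $|\rho| > 0.1$, up to 10 rounds,
guarding the linear system's conditioning) and re-solves, because
strongly coupled pairs violate the sparsity assumption. The final
estimate is the elementwise median of 20 outer iterations; clipping of
$|\rho|$ to 1 and clamped negative basis variances are counted and
reported.

Pseudo p-values permute every OTU's counts independently across samples
(destroying correlation, preserving marginals; a resample-with-replacement
mode exists), re-estimate with a reduced iteration count, and apply the
two-sided add-one rule per pair. Edges require $|\rho| > 0.3$ and
$p < 0.05$; isolated OTUs are dropped from the graph but reported, which
is why node counts can fall below the input OTU count. Centralities
(degree, betweenness, closeness on the unweighted unsigned graph;
eigenvector on the largest component) feed the hub rule: a hub strictly
exceeds the top-2% quantile of **both** degree and betweenness. The hub
cutoffs are data-derived quantiles recomputed per network, never fixed
constants.

One estimation-theory point: under the null at $n$ samples, no
correlation estimator can push the mean $|\rho|$ below the Pearson
sampling floor $\sqrt{2/\pi}/\sqrt{n-1}$ (about 0.057 at $n = 200$).
SparCC sits at that floor; the meaningful null guarantee — asserted in
the tests — is that no null pair crosses the 0.3 edge threshold.

# Vertical transmission

Cultivar pairs are classified from the maternal pedigree: `direct`
(mother–progeny), `vertical` (maternal chain of length ≥ 2), `kin`
(shared maternal ancestor, neither ancestral to the other — the shared
count is configurable; 1 is the default generalization of the study
design's three kin pairs), `intra_line`/`inter_line`, and `orphan`.
Binary Bray–Curtis distances between cultivar presence sets are compared
across classes with Wilcoxon tests and BH correction; both binary and
CSS-based distances are supported and the mode is an explicit argument,
because the two variants answer different questions (membership overlap
vs abundance similarity).

# The synthetic-community generator

Log basis abundance of OTU $i$ in a sample of host $h$ is
$$\mu_i + s\,B_{ih} + d\,\mathbb{1}[\text{enriched for } h\text{'s group}]
 + \varepsilon,$$
with $\mu_i \sim N(0, \sigma_{LN}^2)$ controlling inequality,
$B_{\cdot h}$ Brownian motion on the host tree (unit-depth covariance)
scaled by the phylosymbiosis strength $s \in [0,1]$, $d$ a log2-scale
domestication shift applied to designated wild- or
domesticated-enriched OTUs (asymmetric counts, mirroring the
wild-skewed enrichment of real seed panels), and $\varepsilon$ correlated
across OTUs according to a user-specified basis correlation matrix
(completed with a unit diagonal and shrunk towards the identity until
positive definite). Fractions are closed to one per sample, counts drawn
multinomially at a log-normal depth, and zeros injected by independent
Bernoulli masking. Defaults are the study-like conditions: 43 hosts
(17 wild), 3 replicates, 364 + 356 OTUs, mean depth 30,000, $s = 0.5$,
$d = 3$, 60/10 enriched OTUs per kingdom, 30% zero inflation. Kingdoms
are generated by two independent draws sharing the host tree and host
statuses.

What it does **not** emulate: taxonomic structure, chimeras or
misassignment, depth-dependent technical zeros in the generator itself
(masking is independent; the ZIG tests build depth-dependent masking
explicitly where that is what is being tested), overdispersion beyond the
log-normal/multinomial hierarchy, and the real depth distribution (the
log-normal depth is a stand-in and is flagged as such in the truth
record). Passing tests therefore demonstrate correctness of the
statistics under a faithful compositional model, not performance
guarantees on any particular real dataset.

The pedigree generator builds maternal breeding lines (founder, a kin
pair of first-generation daughters, then a descent chain) plus orphan
cultivars; progeny retain each maternal OTU with probability
`inherit_frac` and acquire novel OTUs only from outside the maternal set,
so retention 1 gives identical sets and retention 0 gives disjoint ones.

# Numerical choices and problem sizes

* Permutation and randomized-tree p-values: add-one convention
  throughout; seeds recorded.
* UPGMA ties: lexicographic id order. RF: unrooted non-trivial splits,
  bitmask encoding up to 52 leaves.
* EM: tolerance $10^{-6}$, cap 100 iterations; all-zero OTUs excluded
  with a reason. Trigamma inversion: Newton, 50 iterations cap.
* SparCC: basis variances clamped at $10^{-12}$ when the solve goes
  negative (counted), $|\rho|$ clipped to 1 (counted), exclusion stops
  before the linear system loses rank.
* The validation suite runs the statistics at deliberately modest sizes
  chosen to exercise the estimators well away from degeneracy while
  keeping the whole suite fast: null calibrations at 200 replicates with
  499 permutations; signal recovery at 19 hosts (phylosymbiosis), 50
  OTUs × 200 samples (SparCC), 300 OTUs × 60 samples (differential
  abundance and classifier); the acceptance script runs the full default
  conditions (720 OTUs × 129 samples) and, ahead of the network stage,
  applies the abundant-OTU screen (> 200 reads) capped at the 300 most
  abundant OTUs — pruning rare OTUs before estimating a several-hundred-
  dimensional basis-variance system is also what a real analysis does to
  keep the sparsity assumption and the linear algebra honest.

# Known limitations

* CSS results depend on the quantile rule; cross-study comparisons should
  fix the quantile explicitly.
* The RF congruence test is conservative for small trees (discreteness);
  with very few accessions, a non-significant phylosymbiosis result is
  weak evidence of absence.
* The ZIG depth model uses sample depth as the only zero covariate; batch
  or taxon-specific dropout is not modelled.
* SparCC assumes sparsity of the true correlation network; dense
  correlation structure biases basis variances, which is precisely why
  strongly coupled pairs are iteratively excluded.
* Pedigree classification trusts the recorded maternal chains; unrecorded
  crosses dilute the direct/vertical/kin contrast towards the orphan
  level.
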