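---
title: "Fair clustering with a Gibbs posterior: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fair clustering with a Gibbs posterior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairgibbs)
library(ggplot2)
```

## The problem

Clustering is routinely applied to data about people, and the resulting
groups can end up segregated along a *protected attribute* — gender, marital
status, race. The **balance** of a clustering measures how far it is from
such segregation: for a cluster $C_k$ and attribute levels $j_1, j_2$,

$$
\mathrm{Balance}(C_k) \;=\; \min_{j_1 < j_2}
\min\!\left\{ \frac{|C_k^{j_1}|}{|C_k^{j_2}|},
              \frac{|C_k^{j_2}|}{|C_k^{j_1}|} \right\},
\qquad
\mathrm{Balance}(C) = \min_k \mathrm{Balance}(C_k),
$$

where $|C_k^{j}|$ counts members of $C_k$ with attribute level $j$. Balance
1 means every cluster reproduces a perfectly even split; balance 0 means
some cluster misses a level entirely. `cluster_balance()` implements the
general multi-level formula, though the pipeline itself supports two levels,
whose counts must satisfy $N_2 = t\,N_1$ for an integer $t \ge 1$ (the level
with the smaller count is coded 1; ties go to the first level in sorted
order).

Optimization-based fair clustering returns a single balanced partition but
says nothing about how confident one should be in any particular cluster
assignment. Model-based (mixture) clustering quantifies uncertainty but is
brittle when the within-cluster distributions are misspecified. This package
takes the middle road of *generalized Bayes*: replace the likelihood by
$\exp(-\lambda \cdot \mathrm{loss})$, so the posterior concentrates on
low-loss configurations without committing to any data-generating
distribution.

## The model

**Fairlets.** A $(1, t)$-fairlet is a minimal balanced set: one label-1
observation plus $t$ label-2 observations. A fairlet decomposition is
encoded by a binary matrix $B \in \{0,1\}^{N_1 \times N_2}$ with row sums
$t$ and column sums 1: column $j$ carries its single 1 in the row of the
label-1 observation whose fairlet the $j$-th label-2 observation joins.
(The margin convention matters: column sums 1 is the only choice under
which every label-2 point belongs to exactly one fairlet, so the fairlets
partition all $N$ observations.) With the cost matrix
$L = (\,D(x_i, x_{N_1+k})\,)$, the decomposition loss is the trace inner
product $L_f = \langle B, L \rangle$, and the optimal decomposition
minimizes it over the fixed-margin polytope — a constrained binary optimal
transport problem whose linear-program optimum is automatically integral.

**Clustering.** Each fairlet is summarized by its center $u_i$ (the mean of
its $t + 1$ points), and the $m = N_1$ centers are clustered into a fixed
number $K$ of groups under a factorized loss
$L_c(C \mid u) = \sum_k \sum_{i \in C_k} D(u_i, u_{(k)})$, with two shipped
discrepancies: squared Euclidean ($u_{(k)}$ = cluster mean; the k-means
objective) and Manhattan ($u_{(k)}$ = componentwise median; k-medians).

**Posterior.** With uniform priors over decompositions and over partitions
with exactly $K$ nonempty blocks, the joint Gibbs posterior is

$$
\pi(B, C) \;\propto\;
\exp\{-\lambda_f \langle B, L\rangle\}\,
\exp\{-\lambda_c L_c(C \mid u(B))\}.
$$

Because every draw of $B$ is a fairlet decomposition and observations
inherit their fairlet's cluster, **every posterior draw has balance exactly
$1/t$** — fairness is structural, not a penalty to be traded off. Point
estimates derived from draws (the MAP draw, Dahl's least-squares draw)
inherit it.

## Sampling

`fair_gibbs()` alternates two updates (Metropolis-within-Gibbs):

1. **Decomposition update.** A checkerboard swap: pick a row pair and a
   column pair uniformly; if the induced $2 \times 2$ submatrix of $B$ is a
   checkerboard, propose flipping it to the opposite checkerboard (margins
   are conserved automatically). With entry weights
   $\omega_{ij} = e^{-\lambda_f l_{ij}}$, the weight-product ratio of the
   proposal equals $e^{-\lambda_f \Delta L_f}$; the acceptance probability
   multiplies it by $e^{-\lambda_c \Delta L_c}$, the induced change in
   clustering loss when the two affected fairlet centers move. This makes
   the update the exact full conditional of $B$ given $C$, so the joint
   chain targets $\pi(B, C)$ itself — the package verifies this on an
   exhaustively enumerable toy problem (six matchings by three partitions),
   where empirical frequencies match the enumerated law to total variation
   below 0.05. The standalone sampler over decompositions alone
   (`wrla_chain()`, a weighted rectangular-loop algorithm) drops the
   clustering term and targets $P(B) \propto \prod_{ij}
   \omega_{ij}^{b_{ij}}$, validated by chi-square goodness of fit against
   enumeration.
2. **Label sweep.** Each fairlet-center label is resampled from its full
   conditional: allocation to cluster $k$ has probability proportional to
   $\exp\{-\lambda_c(\mathrm{term}_k^{+i} - \mathrm{term}_k^{-i})\}$ with
   cluster $k$'s center recomputed with and without unit $i$. The suite
   checks this conditional against brute-force enumeration of the joint to
   $10^{-10}$, and the sweep chain's stationary law against the enumerated
   Boltzmann distribution over all two-block partitions of seven units.

`mode = "mcem"` fixes $B$ at the transport optimum and samples labels only —
cheaper, and appropriate when decomposition uncertainty is negligible.

Design choices worth knowing about:

* **Empty clusters.** The prior has support only on partitions with exactly
  $K$ blocks, so a unit that is currently a singleton must keep its label
  (its conditional is degenerate). This keeps the chain inside the prior's
  support; allowing the move and re-seeding would break the stationary law.
* **Center recomputation.** The affected clusters' centers are recomputed
  exactly after every label move (cluster sizes here are small enough that
  this costs less than maintaining incremental medians, and there is no
  floating-point drift to manage).
* **Scan order.** Sweeps visit units sequentially by default;
  `random_scan = TRUE` uses a fresh uniform permutation per sweep. Both
  leave the target invariant.
* **Ties.** Nearest-center assignment in the Lloyd initializer breaks ties
  toward the lowest cluster index; the componentwise median uses the lower
  median for even cluster sizes. Both make runs reproducible under a seed.
* **Label switching.** Stored partitions are canonicalized by first
  occurrence, so draw equality, the Dahl objective, and the MAP draw are
  well defined.
* **Degenerate inputs.** One-row decompositions (a single fairlet) form a
  singleton polytope: proposals are no-ops rather than errors. Datasets
  whose level counts are not an exact $1{:}t$ integer ratio are rejected
  with an input error, not approximated.

## Temperatures

$\lambda_f$ and $\lambda_c$ weight the two loss terms; larger values
concentrate the posterior at the loss minimizers, smaller values flatten it
and widen the uncertainty statements. Both default to 1, which on data of
unit scale gives a posterior concentrated near — but not degenerate at —
the two-step optimum; they are deliberately plain config values. Principled
calibration (e.g. matching a prior-to-posterior information-gain target) is
a separate exercise left to the user: the right temperature depends on the
units of the features and on how conservative the uncertainty statements
need to be, and no default can absorb that. When comparing runs across
losses, remember the two discrepancies live on different scales, so equal
temperatures do not imply equally concentrated posteriors.

The number of clusters $K$ is a fixed modelling choice, not an estimated
quantity: the loss-based posterior has no mechanism to trade off fit against
$K$, and letting $K$ vary under a Gibbs posterior is known to behave poorly.
Choose it by domain knowledge or an exploratory elbow rule.

## Posterior summaries

From $T$ stored draws the package computes (`summary` element of the fit,
surfaced by `tidy()` / `glance()`):

* the **co-clustering matrix** $\bar\eta$, with $\bar\eta_{ij}$ the fraction
  of draws placing $i$ and $j$ together (symmetric, unit diagonal);
* **Dahl's least-squares draw** $s_{LS}$, the stored draw minimizing
  $\sum_{ij} (\eta_{ij}(s) - \bar\eta_{ij})^2$ — being a stored draw, it is
  balanced by construction;
* the **MAP draw**, the stored draw with the highest log joint;
* **misclassification probabilities** $1 - \bar\eta_{i i^\star}$, where
  $i^\star$ is the medioid (under the configured discrepancy, at the
  observation level) of $i$'s MAP cluster. Medioids get exactly 0. The
  discrepancy used for medioids follows the run's loss, keeping the
  geometry of the summary consistent with the geometry of the fit.

The two-step estimator — optimal decomposition first, then MAP clustering of
its centers — is also computed (`cfcf_partition`) for comparison; it is an
approximation of the joint MAP and coincides with it when both temperatures
are large.

## The synthetic designs

Two generators emulate a two-cluster, two-attribute population of 100
points in the plane, with cluster-by-attribute cell counts
$(20, 30)$ / $(30, 20)$ — the attribute is globally balanced ($t = 1$)
while each true cluster has balance $2/3$, so an unconstrained clustering
that recovers the truth is necessarily unfair:

* `simulate_well_specified()`: isotropic Gaussian components with means
  $(4,4), (2,2), (10,10), (8,8)$ and covariance $4 I_2$;
* `simulate_misspecified()`: the same layout with bivariate Student-$t$
  components, scale $3 I_2$ and $\nu = 2$ degrees of freedom, whose
  variance does not exist — gross outliers are expected, probing behavior
  under model misspecification.

These defaults are the package's reference study conditions and are not
meant to be dialed per run. What the generators do **not** emulate: more
than two attribute levels, unequal global level counts (non-integer $t$),
unequal cluster scales, correlated features, dimensions beyond two, or
cluster counts beyond two. Tests passing on these designs therefore say
nothing about, e.g., high-dimensional behavior or multi-level attributes.

On the heavy-tailed design, an unconstrained 2-means fit occasionally
isolates a single extreme outlier as its own cluster, collapsing balance
toward zero; across replicate seeds the typical (median) unconstrained
balance sits near 0.55–0.58 on both designs, below the perfect-recovery
value $2/3$ because boundary misassignments almost always hurt the minimum
ratio. The fair fit reports balance exactly 1 on every draw, every seed.

A related subtlety shows up when comparing the two losses on the
heavy-tailed design (`run_reproduce("sim_l1_vs_l2", ...)` reports both
medians and means of the adjusted Rand index across replicates): the
Manhattan loss's robustness advantage is concentrated in the replicates
with extreme outliers, where the squared-Euclidean fit collapses while the
Manhattan fit does not. Averages over replicates therefore favor the
Manhattan loss, while the replicate *median* — which discards exactly those
tail replicates — can narrowly favor either loss. Robustness claims should
be read against the whole replicate distribution, not a single summary.

## Problem sizes used by the test suite

The suite validates sampler correctness on exhaustively enumerable
instances (polytopes of up to six matchings, partition spaces of up to 127
two-block partitions, a joint space of 18 states) with chains of $10^5$ to
$2 \times 10^5$ iterations, and runs the full pipeline on the 100-point
reference designs with chains of 150–800 iterations and about 20 replicate
datasets where replication is called for. These sizes were chosen so the
enumeration oracles stay exact and a full run of the suite remains a
morning-coffee affair; the samplers themselves are compiled and handle
substantially longer chains comfortably.

## Worked example

```{r example, fig.width = 6, fig.height = 4}
d <- simulate_well_specified(seed = 11)
fit <- fair_gibbs(d, attribute, K = 2, features = c("x1", "x2"),
                  n_iterations = 600, burn_in = 200, seed = 1)
glance(fit)
autoplot(fit)
plot_coclustering(fit)
```

```{r vanilla}
vanilla <- gibbs_kmeans(d, K = 2, attribute = attribute,
                        features = c("x1", "x2"),
                        n_iterations = 600, burn_in = 200, seed = 1)
glance(vanilla)[, c("balance_map", "balance_ls")]
```

## Known limitations

* Exactly two attribute levels, in an exact $1{:}t$ integer ratio; other
  inputs are rejected rather than approximated. Generalizing to $(p, q)$
  fairlets (for ratios like 4:5) or multi-level attributes would change the
  decomposition machinery.
* $K$ is fixed; there is no posterior over $K$.
* Exact sampling from the decomposition law is not provided; only MCMC,
  whose mixing on very large, tightly concentrated polytopes should be
  monitored via the stored `log_joint` trace.
* The misclassification summary is anchored to the MAP draw; under severe
  multimodality the co-clustering matrix itself is the more faithful
  uncertainty report.
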