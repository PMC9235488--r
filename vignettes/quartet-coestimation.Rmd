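---
title: "Quartet co-estimation of species trees and gene trees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet co-estimation of species trees and gene trees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetco)
```

## The problem

Gene trees estimated from individual loci disagree with each other and with
the species tree, both for biological reasons — incomplete lineage sorting
(ILS), as modeled by the multispecies coalescent (MSC) — and because a few
hundred to a few thousand sites per locus simply do not pin a topology down.
Summary methods (estimate each gene tree, then combine point estimates) are
scalable but inherit every gene-tree estimation error, and those errors are
not symmetric noise: with one short and one long pair of branches,
maximum-likelihood gene trees are biased toward joining the long branches
(long-branch attraction), and that bias propagates into the species tree.
Full Bayesian co-estimation of all gene trees and the species tree handles
uncertainty correctly but does not scale past tens of species.

`quartetco` implements a middle road. Gene-tree *distributions* (not point
estimates) are inferred independently per locus by any standard tool; the
species tree is then inferred one quartet of species at a time by maximizing
a likelihood that marginalizes over gene-tree topologies; finally the
per-gene topology posteriors are updated conditional on the inferred species
tree — which is what makes the procedure a co-estimation rather than a
summary method.

## The quartet model

Fix four species. There are three unrooted gene-tree topologies. Throughout
the package the four taxa are kept in lexicographic order $(a, b, c, d)$ and
the topologies are indexed $1 = ab|cd$, $2 = ad|bc$, $3 = ac|bd$
(`quartet_key()` fixes this once, so every permutation of the same four
labels yields identical indices).

The quartet species tree is parameterized as $\theta = (t, d)$: the topology
$t \in \{1,2,3\}$ and the internal branch length $d \geq 0$ in coalescent
units. Under the MSC the gene-tree topology distribution is

$$P(G_i = j \mid \theta) = \begin{cases}
1 - \tfrac{2}{3}e^{-d} & j = t\\[2pt]
\tfrac{1}{3}e^{-d} & j \neq t,
\end{cases}$$

implemented in `gene_tree_topology_prob()`. At $d = 0$ all three topologies
are equiprobable; as $d \to \infty$ discordance vanishes.

Let $P$ be the $3 \times k$ matrix whose column $i$ is gene $i$'s posterior
over the three topologies given its sequence data. Assuming (i) a uniform
prior over unrooted gene-tree topologies, and (ii) substitution-unit branch
lengths and other continuous nuisance parameters unlinked from $\theta$ and
across genes, the species-tree log-likelihood marginalized over all $3^k$
joint gene-tree topology assignments collapses to a per-gene sum,

$$\ell(t, d; P) = \sum_{i=1}^{k}
\log\!\left(P_{t,i} + e^{-d}\left(\tfrac{1}{3} - P_{t,i}\right)\right)$$

up to an additive constant that does not depend on $(t, d)$
(`quartet_loglik()`). Two consequences of dropping that constant are worth
stating: reported log-likelihoods are *relative*, comparable across the
three topologies of one quartet but not across quartets (which may also
differ in their number of informative genes); and when every column of $P$
is 0/1 (no gene-tree uncertainty), the maximizing topology is exactly the
most frequent topology among genes — the method then degenerates to
most-frequent-quartet voting, and its added value comes entirely from soft
posteriors. Both facts are asserted in the test suite.

The assumption of unlinked substitution-unit branch lengths is a
no-common-mechanism-style simplification: it buys arbitrary rate variation
across genes and branches without any clock model, at the cost of ignoring
shared rate information across genes.

## Building the posterior matrix

Two routes produce $P$:

* `build_P_from_samples()` — per-gene MCMC tree samples (plain newick, one
  tree per line, or NEXUS with a translate table as written by standard
  Bayesian samplers). Each retained sample is restricted to the four taxa
  (`induced_quartet_topology()`, invariant to rooting) and the posterior is
  the sample frequency. The default burn-in is 25% of each chain,
  configurable: samplers rarely document a universal choice and this matches
  common MCMC practice. A sample whose induced quartet is a star contributes
  1/3 to each topology — the unique assignment that keeps columns normalized
  without favoring any topology (binary samplers never produce this; it
  matters for user-supplied forests). A gene missing any of the four taxa is
  masked for that quartet and the effective $k$ shrinks accordingly.
* `build_P_from_loglik()` — per-topology maximum log-likelihoods (the style
  of IQ-TREE's `-wql` output, or this package's own
  `quartet_loglik_table()`), normalized and exponentiated per gene with
  log-sum-exp stabilization.

Before optimization every entry receives a pseudo-count:
$p \mapsto (p + 10^{-8}) / (1 + 3\cdot 10^{-8})$ (`regularize()`, applied
exactly once). This keeps $\ell$ finite when a gene is certain and $d$ is
large.

## Maximizing the likelihood

For fixed $t$, substituting $x = e^{-d}$ makes every term
$\log(P_{t,i} + x(1/3 - P_{t,i}))$ log-affine in $x$, so the objective is
concave in $x$ on $(0, 1]$ and has at most one interior stationary point in
$d$. `profile_max()` exploits this: the sign of the analytic derivative at
$d = 0$ and at the cap decides boundary optima outright, and an interior
optimum is found by root-finding on the first derivative (absolute tolerance
$10^{-9}$ in $d$; the documented contract is $10^{-6}$). The first and
second derivatives are available as `quartet_loglik_deriv()` and are checked
against central finite differences in the tests; the maximizer itself is
checked against a $2 \times 10^5$-point grid oracle.

The branch length is capped at `D_MAX` $= -\log 10^{-8} \approx 18.42$:
beyond that, $e^{-d}$ is below the pseudo-count floor and the likelihood is
flat to machine precision. Results at the cap are flagged `AT_CAP` rather
than reported as infinite — note that a cap is *expected* whenever every
column has $P_{t,i} > 1/3$ (each term is then monotone increasing in $d$),
e.g. when all genes agree moderately; it is not an optimizer failure.
`ml_quartet()` profiles all three topologies and picks the argmax, breaking
exact ties (within $10^{-9}$) toward the lowest index with a `tie` flag so
callers can treat such quartets as unresolved; tied quartets are excluded
from amalgamation exports.

## The co-estimation update

Given the inferred $\hat\theta = (\hat t, \hat d)$,
`update_gene_posteriors()` replaces each gene's posterior with

$$P(G_i = j \mid D_i; \theta) \;=\;
\frac{P_{j,i}\, P(G_i = j \mid \theta)}{\sum_{a} P_{a,i}\, P(G_i = a \mid \theta)}.$$

Mass can only move toward the species-tree topology (monotonically in $d$),
so re-running `ml_quartet()` on the updated matrix returns the same species
tree: iterating the update cannot change the answer, and the implementation
guards against accidental loops by refusing to update an already-updated
matrix. Per-gene MAP topologies before and after the update are recorded so
users can measure how often the update corrects (or, when the species tree
itself is wrong, degrades) gene trees. For more than four species the
updated distributions are per-quartet objects; recombining them into full
updated gene trees requires an external quartet amalgamation step and is
deliberately out of scope — the package exports the per-quartet TSVs.

## Beyond four species

With $n$ species the package analyzes a set of quartets and amalgamates:

* For modest $n$, `all_quartets()` enumerates all $\binom{n}{4}$.
* For large $n$, `select_quartets()` takes a user-supplied guide tree with
  support values, contracts every branch with support below a threshold
  (default 1.0 — only maximally supported branches survive; branches with
  *no* support value are treated as support 0 and contracted, on the view
  that an unannotated branch should not constrain the search; percentage
  supports are auto-rescaled), and samples quartets around each remaining
  polytomy. A polytomy of degree $\delta$ receives
  $\lfloor 1200/\delta \rfloor$ rounds (budget configurable); each round
  draws one leaf per side — or per each of 12 sides re-drawn uniformly each
  round when $\delta > 12$, which maximizes side coverage across rounds —
  and emits all quartets of the drawn leaves, so every sampled quartet has
  its leaves on four distinct sides. Leaves are drawn by walking from the
  polytomy toward the tips, choosing a child uniformly at each node: a leaf
  is reached with probability $\prod 1/(\text{children})$ along its path,
  favoring leaves close to the polytomy, which are the most informative for
  resolving it. Quartets are deduplicated globally.
* `exact_supertree()` combines quartet trees for $n \leq 8$ by scoring all
  $(2n-5)!!$ unrooted binary topologies (10395 at $n = 8$ — instant) against
  the inputs, optionally restricted to refinements of the contracted guide.
  Ties are broken by the deterministic enumeration order and flagged. For
  larger $n$, `export_for_amalgamation()` writes one 4-taxon newick per
  quartet with the internal branch set to $\hat d$, plus the guide, in the
  format standard quartet-amalgamation tools consume; re-implementing those
  search heuristics is a non-goal.

## The simulators

Two generators make every claim in the package testable without downloads.

**Long-branch-attraction quartets** (`felsenstein_condition()`). The species
tree is the balanced quartet $((A,B),(C,D))$ with internal branches $d/2$
and terminal branches $\tau_1$, all in coalescent units. Gene trees follow
the censored MSC (`msc_gene_trees()`: within each species branch, each
lineage pair coalesces at rate 1; survivors enter the parent branch). The
expected gene-tree terminal extension above a speciation node is
$\tau_2 = 1 - \tfrac{1}{3}e^{-d}$ — exactly $2/3$ at $d = 0$ — which the
tests verify by Monte Carlo. Each species branch carries one of two
mutation rates: solving
$l = \mu_l \tau_1 + \mu_s \tau_2$ and $s = \mu_s(\tau_1 + \tau_2)$ gives
$\mu_s = s/(\tau_1+\tau_2)$ and $\mu_l = (l - \tau_2 s/(\tau_1+\tau_2))/\tau_1$
(`derive_rates()`, which rejects conditions with $\mu_l \leq 0$ or
$\mu_l > 10^6$). Choosing $\tau_1 = 1 - \tau_2 = \tfrac{1}{3}e^{-d}$ makes
the expected internal branch $s$ as well, so the unrooted gene trees have
two long branches ($A$, $C$ — non-sisters) of expected length $l$ and all
other branches short, the classic long-branch-attraction regime when $l/s$
is large. `apply_two_rate_map()` converts each gene tree by splitting every
branch into the time segments it spends in each species branch (a branch
may traverse up to three) and multiplying each segment by that branch's
rate; segments above the species root use $\mu_s$, consistent with the
terminal-extension bookkeeping. The expected unrooted terminal lengths
($l$ for $A/C$, $s$ for $B/D$) are verified by simulation. One detail found
in independent case analysis and deliberately *not* asserted: the expected
unrooted internal gene-tree branch is exactly 1 coalescent unit at
$d \to 0$ but mildly $d$-dependent for $d > 0$, so no test pins it to 1.

**Anomaly-zone caterpillar** (`anomaly_condition()`). A 6-taxon caterpillar
with every internal branch at 0.1 coalescent units — well inside published
anomaly-zone bounds for caterpillars — built ultrametric with the cherry at
depth 1.0 (so terminal lengths run 1.0–1.4; an all-equal-terminals
caterpillar cannot be ultrametric, and terminal branch lengths do not affect
gene-tree topology distributions since a single lineage cannot coalesce).
These defaults are this package's own stand-in choice and are configurable.
Substitution lengths come from a relaxed clock: coalescent length ×
overall rate 0.02 × an independent Gamma(shape 5, scale 1/5) multiplier per
branch (mean 1, variance 1/5), creating deviations from ultrametricity.

Sequences evolve under JC69 (`simulate_jc69()`): uniform root sequence, each
site resampled uniformly with probability $1 - e^{-4b/3}$ along a branch of
length $b$. JC69 was chosen so the downstream likelihood engine is exact and
dependency-free; alignments are plain FASTA so external simulators can be
substituted. What the synthetic data does *not* emulate: indels and missing
data, substitution-model misspecification (no GTR, no among-site rate
variation), linked rates across genes, and real MCMC behavior (posteriors
from the likelihood surrogate are deterministic; chain autocorrelation and
convergence failures are absent). Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
real-data pathologies.

**Quartet likelihood surrogate.** `quartet_topology_loglik()` maximizes the
JC69 likelihood of a 4-taxon alignment over the five branch lengths
(Felsenstein pruning over site patterns, analytic gradient, L-BFGS-B with
box $[10^{-9}, 10]$, two deterministic starts — a fixed point and a
JC-distance-based one). Tests check it against an exhaustive sum over the
16 internal-state pairs, an independent coordinate-descent optimizer, and an
external pruning implementation. `quartet_posteriors_from_alignments()`
chains it into the posterior matrix.

Every per-gene RNG stream is derived from the condition seed and the gene
index, so single genes are reproducible in isolation and
`simulate_condition()` reruns are bit-identical.

## Problem sizes used by the test suite

Monte Carlo checks run at $3 \times 10^4$ draws in the module tests and
$10^5$ in the acceptance checks (tolerances 0.005–0.02 absolute, 4–5 standard
errors). The optimizer is validated against a $2\times10^5$-point grid on
500 random posterior matrices and 1000 one-hot instances. The simulation
benchmark uses a six-condition grid at 200 genes per replicate with
$(d, l, s, \text{bp})$ values from the long-branch-attraction design —
easy condition $(0.3, 0.1, 0.04, 1600)$ at 20 replicates, five harder ones
(including two with $l/s = 10$) at 5 replicates — comparing the
marginalized-likelihood quartet against the most-frequent-MAP-topology
baseline. The six-taxon anomaly pipeline runs 2000 genes with exact
gene-tree topologies (hard posteriors), where quartet voting is consistent
and the exact supertree must recover the model tree.

## Known limitations

* Quartets are analyzed independently; there is no joint likelihood across
  quartets, and amalgamation is heuristic (exact only for $n \leq 8$).
* Gene-tree branch lengths are marginalized away and never reported.
* Reported log-likelihoods are relative; do not compare them across
  quartets.
* The guide tree is taken as given: support values are read, never
  computed.
* The likelihood surrogate is JC69-only by design.
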