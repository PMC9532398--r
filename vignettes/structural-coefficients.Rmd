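---
title: "Structural similarity and complementarity: models, nulls and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural similarity and complementarity: models, nulls and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structcoef)
```

## The two relational principles and their motifs

Two nodes can interact because they are *similar* — both close to each other
in some latent feature space — or because they are *complementary*: different
in a specific, synergistic way, like a key and a lock, an enzyme and its
substrate, or an adviser and an advisee. The two principles leave different
fingerprints in a simple undirected graph.

Similarity is metric. If $i$ is close to $j$ and to $k$, then $j$ and $k$ are
close too, so 2-paths tend to close: triangles abound, and connected nodes
share neighbors. Complementarity cannot be modeled as unconstrained
heterophily (in $\mathbb{R}^k$ there is no farthest point), but on the
surface of a sphere every point has exactly one antipode. If nodes link
preferentially to the far side of such a space, two connected nodes share few
neighbors, yet the 1-hop neighborhood of each approximates the 2-hop
neighborhood of the other. Then 3-paths close: the characteristic motif is
the *strong quadrangle* — a 4-cycle with neither diagonal present — and the
local structure is dense and bipartite-like. Chordlessness is what ties
quadrangles to bipartivity; 4-cycles with chords are compatible with plain
clustering.

## The coefficient family

Everything is built from one edge-level census (`path_census()`). For an
ordered edge $(i,j)$ we count triangles $T_{ij}$, wedge triples $(k,i,j)$ and
head triples $(i,j,k)$ (closed forms $d_i-1$ and $d_j-1$), strong quadrangles
$Q_{ij}$, and wedge/head quadruples — 3-paths $(j,i,k,l)$ and $(i,j,k,l)$
over four distinct nodes. Chords are allowed in the quadruple (denominator)
counts and forbidden only in the quadrangle (numerator) count, so every
coefficient is a fraction of paths that close into its motif:

* t-clustering $s^W_i = 2T_i/t^W_i$ (Watts–Strogatz local clustering),
  t-closure $s^H_i = 2T_i/t^H_i$ (local closure coefficient), and the
  structural similarity $s_i = 4T_i/(t^W_i + t^H_i)$, their weighted
  average; $s_i = 1$ iff $i$ sits in a complete component.
* q-clustering $c^W_i = 2Q_i/q^W_i$, q-closure $c^H_i = 2Q_i/q^H_i$, and the
  structural complementarity $c_i = 4Q_i/(q^W_i + q^H_i)$; $c_i = 1$ iff $i$
  sits in a complete bipartite component.
* edgewise $s_{ij} = 2n_{ij}/(d_i+d_j-2)$ and
  $c_{ij} = 2Q_{ij}/(q^W_{ij}+q^H_{ij})$, plus the Sørenson structural
  equivalence $H_{ij} = 2n_{ij}/(d_i+d_j)$;
* global $s = 3T/\sum_i \binom{d_i}{2}$ (classical transitivity) and
  $c = 4Q/\#\{\text{3-paths}\}$.

Each nodewise value is sandwiched between its clustering and closure
coefficients and between the extremes of its edgewise values; similarity is
bounded by the structural equivalence of neighbors, and complementarity by
the maximum Asymmetric Excess Sørenson index
$H_{kj|i} = (n_{jk}-1)/(d_k-1-a_{jk})$ over neighbors and 2-hop neighbors.
The test suite asserts these bounds on every random graph it generates.

Two counting conventions deserve a note, because the ratio definitions only
cohere under one resolution of each:

* The global quadruple total is the number of *distinct 3-paths*,
  $\sum_{(i,j)\in E}[(d_i-1)(d_j-1)-n_{ij}]$ over unordered edges. On the
  4-cycle this gives 4, so that $c(K_{2,2}) = 4\cdot 1/4 = 1$ exactly, and
  in $G(n,p)$ a 3-path closes chordlessly with probability $p(1-p)^2$,
  making $\mathbb{E}[c] = p(1-p)^2$ hold in expectation.
* The global triple count is $\sum_i \binom{d_i}{2}$, so that $s$ *is* the
  classical global clustering coefficient.

A ratio with a zero denominator is undefined and propagates as `NA`, never
as 0: a degree-1 node has no wedge triples, and a star center has no
quadruples at all because degree-1 neighbors generate none. Averages skip
`NA`s; significance testing marks such nodes untestable.

## Generators: what the synthetic data emulates

The package generates all of its own test inputs.

* `gen_fixture()` produces the extremal graphs (complete, complete
  bipartite, cycle, path, star) that pin the coefficients to their
  analytic values.
* `gen_er(n, p)` is the maximally unstructured baseline with known
  expectations $\mathbb{E}[s]=p$, $\mathbb{E}[c]=p(1-p)^2$.
* `gen_sphere(n, theta, dim, mode)` samples points uniformly on the unit
  `dim`-sphere (normalized Gaussians) and links pairs with angular distance
  below `theta` (similarity) or above `pi - theta` (complementarity). A hard
  threshold is the simplest link function monotone in distance and makes
  every graph bit-reproducible under a seed; the latent dimension defaults
  to 1 because the circle is the smallest space realizing both regimes, and
  there the angular distance of a uniform pair is itself uniform, so the two
  modes have identical expected density at the same `theta` — matched
  comparisons need no tuning.

Two limits of the circle model are worth knowing. With
$\theta < \pi/2$ a similarity-mode circle graph contains *no* chordless
4-cycle at all (four arcs shorter than $\theta$ cannot wrap the circle), and
a complementarity-mode graph no triangle, so the opposing statistic is
exactly zero rather than merely small. Comparisons of calibrated values
treat an exactly-zero observed statistic as maximally depleted (ranked below
every defined log-ratio). Real data are noisier in several ways the
generators do not emulate — degree heterogeneity, measurement error
(a single spurious chord destroys a strong quadrangle), community structure
— so passing these tests shows correctness of the machinery and qualitative
discriminating power, not robustness to noise.

## The configuration null model

Observed coefficients depend on the degree sequence even in random graphs,
so cross-network comparison and significance both condition on degrees via
the Undirected Binary Configuration Model: the maximum-entropy distribution
over simple graphs with a given *expected* degree sequence, i.e. the ERGM
with degrees as sufficient statistics. Each node gets a fitness $x_i \ge 0$
and pairs link independently with $p_{ij} = x_ix_j/(1+x_ix_j)$.

`fit_ubcm()` solves $\sum_{j\ne i} p_{ij} = d_i$ by damped Newton iteration
on $\theta_i = \log x_i$, with a ridge fallback for near-singular Jacobians
and step clamping for stability; default tolerance is a maximum absolute
expected-degree error of `1e-8`, typically reached in well under fifty
iterations. Degree-0 nodes are fixed at $x_i = 0$ exactly. Saturated nodes
($d_i = n-1$, e.g. any complete graph, or a star hub relative to its
leaves) drive $x_i \to \infty$; $\theta$ is capped at $\pm 45$, large
enough that a saturated node's residual is orders of magnitude below the
tolerance while all products stay finite in double precision. The observed
degree sequence is used verbatim, never binned.

## Calibration and significance

`calibrate()` reports the average natural-log ratio of the observed
statistic to its values in `R` null samples,
$\mathcal{C} = \tfrac{1}{R}\sum_r \log(x(G)/x(G_r))$ — a dimensionless
enrichment score that is 0 when the degree sequence alone explains the
statistic. Null samples with a zero or undefined statistic are dropped and
counted; the estimate is declared undefined if fewer than half of `R`
survive. The natural log is used throughout.

`node_pvalues()` implements degree-bucketed one-sided testing. Because
degrees are the UBCM's sufficient statistics, nodes with equal observed
degree share a null distribution; the null values of all such nodes across
all `R` samples are pooled into one bucket (at least `R` observations per
node, more whenever degrees repeat). The bucket is summarized by
`n_quantiles` empirical quantiles at levels $0, 1/q, \dots, (q-1)/q$, and
$p = 1 - \alpha_{\max}$ with $\alpha_{\max}$ the largest level whose
quantile is *strictly below* the observed value. This grid is the one
convention that yields both $p = 1$ when the observed value does not exceed
the bucket minimum and a floor of $1/q$ (0.01 at 100 percentiles,
$R \ge 100$) when it exceeds every quantile, keeping $p \in (0,1]$. The
strict inequality makes ties count against rejection, so for heavily
discrete nulls (mean degree below about 5) the test is conservative, never
anti-conservative.

Raw p-values are adjusted with the Benjamini–Krieger–Yekutieli two-stage
linear step-up FDR procedure (`adjust_fdr_bky()`): a first BH pass at
$\alpha/(1+\alpha)$ estimates the number of true nulls, a second pass runs
at the correspondingly sharpened level. Adjusted values are scaled so that
rejection is simply `p_adj <= alpha`; they are specific to the chosen
$\alpha$, which the API therefore takes explicitly.

The p-value floor interacts with the FDR level: with a 100-percentile grid
the smallest attainable raw p-value is 0.01, while the two-stage first pass
rejects only at $p \le \alpha/(1+\alpha)$, which is *below* 0.01 when
$\alpha = 0.01$. Testing at an $\alpha$ at or below the grid floor can
therefore never reject after FDR correction, whatever the data say. The
package's default level is $\alpha = 0.05$ for this reason; smaller levels
require a finer quantile grid backed by correspondingly more null samples.

One calibration subtlety is documented rather than hidden: on observed data
the null is fitted to the *realized* degree sequence, which is an
overdispersed estimate of the generating expected degrees. Null samples
therefore carry slightly more degree heterogeneity — hence slightly more
triangles — than the data-generating process, and the end-to-end pipeline
is mildly conservative even when the data are pure UBCM noise. The package
verifies exact uniformity of the p-values in the clean experiment (testing
a sampled graph against the very model it was drawn from) and treats the
refit conservatism as a property of the procedure.

## The diversity index

For a graph tested at level $\alpha$, let $p_S, p_C, p_B, p_N$ be the
fractions of nodes significant for similarity only, complementarity only,
both, or neither. Conditioning on the significant part,
$p_{X|N'} = p_X/(1-p_N)$, the structural diversity index is

$$\mathbb{S}_\alpha = \frac{(1-p_N)\,\mathbb{H}(p_{S|N'}, p_{C|N'}, p_{B|N'})}{\log_2 3},$$

with $\mathbb{H}$ Shannon entropy in bits. The conditional proportions are
the entropy argument — the only reading under which the $\log_2 3$
normalizer maps the index into $[0,1]$. The $(1-p_N)$ prefactor (with
$0\cdot\mathbb{H} := 0$) penalizes graphs that are mostly indistinguishable
from their configuration model: an Erdős–Rényi graph scores
$\mathbb{S}_\alpha \approx 0$, while a graph whose nodes split evenly among
the three significant classes scores 1. Entropy terms with a zero
proportion contribute 0, and the final value is clamped against
$\pm 10^{-16}$-scale float noise.

## Numerical and design choices, in one place

* Defaults mirror typical practice: $R = 100$ null samples for
  significance, $R = 500$ offered for calibration, 100 percentiles, and
  $\alpha = 0.05$ (the smallest level the percentile grid supports after
  FDR correction; vary $\alpha$ for sensitivity analyses).
* All stochastic entry points take an explicit `seed`; one master seed
  drives a single RNG stream per run, and the caller's RNG state is always
  restored. Identical seeds reproduce byte-identical outputs, including
  through the command-line interface.
* Duplicate edges in input collapse silently (count retained as an
  attribute); a strict mode raises instead. Node ids follow first
  appearance in the file. Extra edge-list columns are ignored with a
  warning — the methods are defined for simple undirected unweighted
  graphs only. Isolated nodes enter via a node-list sidecar, which matters
  for the null model and for node proportions.
* Aggregation guards: node-to-global division by 3 (triangles) and 4
  (quadrangles) must be exact; a remainder raises rather than rounding,
  as it can only mean a corrupted census.
* The brute-force `oracle_census()` (subset classification and literal
  path enumeration) is restricted to $n \le 15$ and exists to verify the
  fast census; the suite checks exact agreement on hundreds of random
  graphs.
* Problem sizes in the test suite (ER graphs up to $n=300$, sphere models
  at $n=150$, 20-replicate calibration experiments with $R=100$) were
  chosen as the smallest scales at which the stochastic checks have
  comfortable power; all run on one CPU in minutes.

## Limitations

Directed and weighted graphs are out of scope; so are link-prediction
scores, microcanonical (edge-swap) randomization, and coefficients based on
weak (chorded) quadrangles. Strong quadrangles are fragile by construction:
one spurious chord deletes them, so on noisy data complementarity is
measured conservatively. The sphere generator's hard threshold is a
deliberate simplification; soft link functions and degree-corrected
geometric models would interpolate between it and the configuration model.
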