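---
title: "Expression-weighted network enrichment: model, null distributions, and design choices"
author: "ppigo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted network enrichment: model, null distributions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppigo)
```

## The question the method answers

Standard functional enrichment asks whether an annotation's proteins are
over-represented among the differentially expressed ones, after an arbitrary
significance cut has split proteins into "changed" and "unchanged". This
package asks a different question: are the proteins of an annotation both
*dysregulated* between two conditions and *close to one another* in the
protein–protein interaction (PPI) network once interactions between
dysregulated proteins are shortened? No per-protein cut-off is involved;
every quantified protein contributes through its fold-change, and every
unquantified protein contributes neutrally.

## Model

The PPI network is an undirected simple graph $G = (V, E)$. For a protein
$v$ the fold-change $f(v)$ is the ratio of its mean expression in the
numerator condition over its mean in the denominator condition (missing
values are dropped from each mean; proteins without usable quantifications
get $f(v) = 1$). Each edge $e = (v_1, v_2)$ receives the weight

$$ w(e) = \begin{cases} \bar m & \bar m \le 1 \\ 1/\bar m & \bar m > 1
\end{cases}, \qquad \bar m = \tfrac{1}{2}\,(f(v_1) + f(v_2)), $$

i.e. $w(e) = \min(\bar m, 1/\bar m) \in (0, 1]$. Strong up- *and*
down-regulation of an edge's endpoints both shrink its weight, so
dysregulated interacting proteins become close; unchanged neighbourhoods
keep unit weights.

The clustering of a protein set $S_T$ (the proteins of annotation $T$ that
are present in the network) is its total pairwise distance

$$ \mathrm{TPD}(S_T) = \sum_{v_i, v_j \in S_T,\; i<j} s(v_i, v_j), $$

where $s$ is the weighted shortest-path distance. Small TPD means the set
is concentrated in a (possibly dysregulated) region of the network.

Significance is judged against per-size Monte-Carlo null models: for each
set size $n$, random sets of $n$ annotated proteins are drawn — uniformly,
or with probability proportional to each protein's annotation count
("weighted sampling", the default, which reflects that multiply-annotated
proteins influence many terms at once) — and the sampled TPDs are
summarized by their mean $\mu_n$ and standard deviation $\sigma_n$. The
clustering p-value of an observed TPD $\alpha$ is the lower normal tail
$\Phi\!\left((\alpha - \mu_n)/\sigma_n\right)$: the probability of a TPD at
least as small as $\alpha$. The normal approximation extends significance
below the $1/\text{n}_{\text{samples}}$ resolution of the raw Monte-Carlo
counts.

Confidence is controlled empirically. The term–protein association table is
shuffled by repeated random pairwise swaps that preserve every term's size
and every protein's annotation count (a swap is rejected, consuming the
attempt, if the two associations share a term or either term already
annotates the other protein). Scoring the shuffled catalog with the same
null models gives a reference set of biologically meaningless p-values, and

$$ \mathrm{FDR}(p) = \frac{\#\{\text{shuffled terms with } p\text{-value} < p\}}
{\#\{\text{real terms with } p\text{-value} < p\}} $$

estimates the false discovery rate of calling everything below $p$.
Finally, the same analysis run on the all-ones-weight network identifies
terms whose proteins are innately clustered in the interactome regardless
of expression; terms significant only in the expression-weighted network
("unique to weighted") are the method's actual readout — dysregulated,
clustered annotations.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `hub_cutoff` | 1000 | drop proteins with ≥ 1000 interactors; they condense the network and mask clusters |
| `min_size`, `max_size` | 3, 1000 | term sizes considered; very small terms carry no stable signal, very large ones little biological interest |
| `min_coverage` | 0.5 | fraction of a term's proteins that must be in the network |
| `n_samples` | 1e4 (`ppigo()`), 1e6 (pipeline) | Monte-Carlo samples per set size; production analyses use 1e6–1e7, runtime is linear in it |
| `null_sampling` | `"weighted"` | null draws proportional to annotation counts; `"uniform"` is the simpler alternative |
| `swap_multiplier` | 1000 | shuffle length = 1000 × number of associations |
| `fdr_target` | 0.001 | FDR at which terms are called |
| STRING `min_score` | 400 | keep combined scores strictly above 0.4; `inclusive = TRUE` makes the bound non-strict |

## Numerical and procedural choices

**Filter order.** Duplicate/self-loop removal → largest connected component
(LCC) → hub removal → LCC again. The statistic needs finite pairwise
distances, so connectivity must be re-established after hubs are removed;
`retake_lcc = FALSE` stops after the hub filter for users who want the
literal order "LCC, then hub filter".

**Distances.** One Dijkstra run per source on positive weights, which is
exactly equivalent to Floyd–Warshall; the test suite cross-checks against an
independent Bellman–Ford implementation to 1e-5 relative. Distances are kept
in a dense double matrix; p-value arithmetic is double precision throughout.

**Weighted sampling without replacement** renormalizes the remaining
weights after each draw (sequential sampling). The inclusion probability of
a heavily annotated protein is checked in the tests against the analytic
value for a pair draw.

**Degenerate nulls.** When a modelled size equals the eligible pool, every
sample is the full set and $\sigma_n = 0$; the p-value convention is 1 at or
above $\mu_n$ and the smallest positive double below it.

**Swap accounting.** Rejected swaps consume an attempt, keeping the shuffle
linear in `n_swaps`; at the default 1000× multiplier the distinction from
resampling-until-acceptance is immaterial. The shuffled catalog is passed
through the same size/coverage filters as the real one before scoring, so
the FDR ratio compares like with like, and the shuffle's marginal
preservation is asserted in the tests after every run.

**FDR evaluation.** The curve is a step function evaluated at the distinct
observed p-values of real terms, with strict `<` counts matching the
estimator's definition, plus an *inclusive* column giving the estimate for a
threshold sitting infinitesimally above each observed p-value. Threshold
selection uses the inclusive column: with strict counts a lone best term
could never certify itself, because the count at its own p-value excludes
it. No monotonization is applied by default (`monotone = TRUE` enables a
cumulative minimum).

**The fallback rule.** On full-scale data the original calling rule falls
back, when no threshold reaches FDR < 0.001, to the point with the smallest
positive FDR — which there lands near the target (e.g. 0.0013–0.0029).
`operative_threshold()` implements exactly that. The `ppigo()` driver
nevertheless defaults to `fallback = FALSE`: with tens to hundreds of terms
the smallest estimable positive FDR is of order one over the term count —
on a pure-noise run it is close to 1 — and the fallback would promote
low-confidence calls wholesale. Enable it only at production scale, where
the shuffle resolution rather than the signal is what keeps the FDR above
target.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds a connected scale-free-like network
(preferential attachment; `topology = "gnm"` gives a homogeneous
Erdős–Rényi alternative), a catalog of random annotation terms, and a
two-condition expression table with log-normal noise (default 10% per
sample, three replicates per condition).

A planted signal emulates a *dysregulated pathway that is only partially
annotated*: a connected region of `region_scale × module_size` proteins
(default 30) is grown by breadth-first expansion and all its proteins
receive the fold-change effect (default 4); the signal term annotates a
`module_size` (default 10) subset of the region chosen by farthest-point
hop spread. The term's proteins are therefore linked by short dysregulated
paths — the weighted analysis sees them as tightly clustered — while their
plain hop distances are indistinguishable from a random set's. This is the
configuration the weighted-vs-unweighted contrast exists to detect: a term
whose proteins form a compact ball would be flagged by the unweighted
analysis too, at any effect size, because *any* connected 10-subgraph of a
200-vertex small-world network is strongly hop-clustered (z ≈ −4 in our
measurements).

Two regimes deliberately differ from real data. First, background terms
are random protein sets, whereas real GO terms are themselves innately
clustered in the interactome (the bulk of full-scale significant terms);
passing tests therefore demonstrate detection and calibration machinery,
not realistic proportions of significant terms. Second, network size: at
200 vertices a preferential-attachment hub enters nearly half of all random
10-sets, making the TPD null a mixture with a heavy left tail that a normal
underestimates; in a full-size PPI network (hub degree < 1000 among ~16k
proteins) the dominant hub enters a negligible fraction of random sets and
the normal is a conservative upper bound for strong clusterings. The
homogeneous `"gnm"` topology reproduces that full-scale tail regime at desk
scale (positive TPD skew, light left tail) and is what the conservativeness
test uses, for set sizes 5–20; at size 3 the TPD null is too discrete for
any normal summary, under every topology we tried.

## Problem sizes used in the checks

The test suite runs entirely on generated data: networks of 100–200
proteins, 20–50 terms, null models at 1e4 samples per size (1e5 where tail
behaviour is probed), and 20-seed replications for the calibration and
recovery studies. A full run at these sizes takes a few seconds; the whole
suite a few minutes. The acceptance script repeats the planted-signal study
(10 runs) and the null-calibration study (5 runs) from a single command-line
seed.

## Known limitations

- Directed or signed interactions are out of scope; the graph is simple and
  undirected.
- Fold-changes are condition-mean ratios; per-sample variance does not enter
  the edge weights (no t-statistic weighting), and up- versus down-regulated
  sets are not distinguished.
- Annotations must arrive pre-propagated; no ontology reasoning is done.
- The empirical FDR inherits the granularity of the shuffled catalog: with
  few terms its call resolution at stringent targets is one term (see the
  fallback discussion above). Averaging over several shuffles stabilizes the
  curve but not the extreme tail.
- Null models assume the eligible pool (annotated network proteins) is the
  right sampling frame; proteins never annotated by any term are invisible
  to the significance machinery, exactly as in the original procedure.
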