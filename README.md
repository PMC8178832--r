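# ppigo — expression-weighted PPI-network enrichment of GO terms

`ppigo` is for analysts of quantitative proteomics (or any per-protein
quantification) who want functional enrichment that uses *all* of the data
instead of a differential-expression cut-off. It detects annotations — e.g.
Gene Ontology terms — whose proteins are simultaneously **differentially
expressed** between two conditions and **clustered** in a protein–protein
interaction (PPI) network.

## The statistic

Every protein gets a fold-change $f(v)$ (ratio of condition means; 1 when
unquantified). Each network edge $e=(v_1,v_2)$ is weighted by

$$w(e) = \min(\bar m,\ 1/\bar m), \qquad \bar m = \tfrac12\big(f(v_1)+f(v_2)\big) ,$$

so interacting proteins that are strongly up- *or* down-regulated become
close. The clustering of a term's protein set $S_T$ is its **total pairwise
distance**

$$\mathrm{TPD}(S_T) = \sum_{v_i,v_j \in S_T,\ i<j} s(v_i,v_j),$$

the sum of weighted shortest-path distances over all pairs. Small TPD =
concentrated, dysregulated neighbourhood. Significance comes from
per-set-size Monte-Carlo null models (random annotated proteins, drawn
uniformly or proportionally to their annotation counts) summarized by a
normal approximation; confidence from an empirical FDR in which the
term–protein association table is shuffled preserving both bipartite
marginals. A parallel run on the all-ones-weight network removes terms that
are innately clustered in the interactome regardless of expression: the
terms **unique to the weighted network** are the dysregulated, clustered
annotations.

## Worked example

The package ships a synthetic-data generator that emulates the full input
bundle — a scale-free PPI network, a two-condition expression table, an
annotation catalog — with one planted dysregulated module (10 proteins
inside a 4-fold-changed pathway region of 30):

```r
library(ppigo)
fx  <- generate_fixture(synthetic_spec(seed = 42))
fit <- ppigo(fx$network, fx$catalog, expression = fx$expression,
             conditions = fx$conditions, n_samples = 1e4, seed = 42)
fit
#> PPI-guided functional enrichment
#>   terms tested: 50 (of 50 input; 50 shuffled controls)
#>   weighted network: 2 significant (p < 0.0122 at FDR 0)
#>   unweighted network: 0 significant (no operative threshold)
#>   unique to the expression-weighted network: 2

summary(fit)
#>    term_id ... size_in_network   tpd  p_value fdr significant unique_to_weighted
#> 1     T001 ...              10  44.7 9.03e-05   0        TRUE               TRUE
#> 43    T043 ...              12 103.2 1.22e-02   0        TRUE               TRUE
```

The planted term `T001` is the top hit: its TPD of 44.7 in the
expression-weighted network is far below the null mean for size-10 sets
(p ≈ 9e-05), no shuffled term undercuts it (per-term FDR 0), and it is
invisible to the unweighted analysis — exactly the expression-driven
clustering the method is built to isolate. `plot(fit, "fdr")` draws both
FDR curves; `plot(fit, "null")` the null-model envelope.

File-based runs use the same machinery:

```r
run_pipeline(list(network = "biogrid.txt", annotations = "go.gmt",
                  expression = "expr.tsv", conditions = "map.tsv",
                  numerator = "HER2", denominator = "TN",
                  n_samples = 1e6, seed = 1, out_dir = "results"))
```

writing per-network result TSVs, null-model caches, and a JSON manifest
that reproduces the run byte-identically. A command-line wrapper lives at
`inst/scripts/run_ppigo.R` (see `--help`).

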