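# netquant

Network-guided isoform transcript quantification for RNA-Seq.

Most reads mapped to a multi-isoform gene are compatible with several
isoforms, so read data alone often under-determine isoform proportions.
`netquant` augments the read likelihood with prior knowledge from protein
domain-domain interactions (DDI): transcripts whose protein products
interact tend to be co-expressed, so the expression of a transcript's
network neighbors carries information about its own abundance. The package
is for transcriptomics researchers who have transcript-level alignments
(or precomputed read equivalence classes) and a transcript interaction
network, and want isoform proportions that borrow strength across genes.

## Model

For gene *i* with transcripts *k*, each read is sampled from one
transcript; with read-origin probabilities `p_ik` and per-base sampling
probabilities `q_ek = 1/(l_ik - l_r + 1)`, the per-gene log-likelihood over
read equivalence classes `e` (multiplicity `c_e`) is

    l_i(p) = sum_e c_e log( sum_k p_ik q_ek )

maximized by EM (the *base model*). The network contributes a Dirichlet
prior per gene: the prior read count of transcript *ik* is its length
times the mean expression (reads per base) of its network neighbors,
`phi_ik = l_ik * mean(pi[neighbors])`, with Dirichlet parameters
`alpha_ik = lambda * phi_ik + 1`. All genes are estimated jointly by
coordinate ascent on the resulting pseudo-likelihood: per gene, EM with the
prior held fixed proposes an update, and an acceptance guard keeps it only
if the objective — including the feedback on neighboring genes' priors —
strictly increases. `lambda = 0` recovers the base model exactly. Outputs
per transcript: `p` (read-origin probability), `rho` (length-normalized
relative abundance) and `pi = |r_i| p / l` (expression, reads per base).

The package also ships the network builder (domain annotations + DDI
tables, with a PPI filter for predicted interactions), network statistics
and randomization nulls, a co-expression/interaction overlap analysis, and
a simulator that plants network-correlated ground truth for recovery
experiments.

## Worked example

Simulate a small dataset with network-correlated truth, fit both models,
and compare recovery:

```r
library(netquant)
d <- simulate_dataset(n_genes = 30, n_reads = 6e4, seed = 42)
fit <- net_quantify(d$compat, d$net, lambda = 0.1)
head(fit, 5)
#>   gene_id transcript_id         p       rho       pi zero_reads
#> 1   G0001      G0001.T1 0.4572357 0.3407774 2.878470          0
#> 2   G0001      G0001.T2 0.2743189 0.3245782 2.741639          0
#> 3   G0001      G0001.T3 0.2684454 0.3346444 2.826666          0
#> 4   G0002      G0002.T1 0.3442682 0.1714755 1.169419          0
#> 5   G0002      G0002.T2 0.2505940 0.2846520 1.941253          0

attr(fit, "diagnostics")[c("rounds", "accepted", "rejected")]
#> $rounds    [1] 5
#> $accepted  [1] 45
#> $rejected  [1] 80

base <- net_quantify(d$compat, net = NULL, lambda = 0)
evaluate_recovery(base, d$truth, d$catalog, "all_multi_isoform")
#> [1] 0.8622817
evaluate_recovery(fit, d$truth, d$catalog, "all_multi_isoform")
#> [1] 0.8847422
```

Each row is one transcript: `p` is the probability a read from that gene
came from that transcript, `rho` its molar proportion after length
normalization, `pi` its reads-per-base expression. The recovery numbers
are Pearson correlations between `log2(pi + 1)` of estimate and ground
truth over multi-isoform transcripts — the network prior improves on the
base EM here because the simulated truth is correlated along the network.

A command-line front end for shell pipelines is installed at
`system.file("scripts", "netquant", package = "netquant")` with
subcommands `quantify`, `build-net`, `netstats`, `simulate`, `coexpr`.

## Vignette

`vignettes/network-guided-quantification.Rmd` documents the model and
algorithm, the numerical choices (acceptance ties, log floors, factorized
reductions), what the simulator does and does not emulate, and the known
limitations of heavy priors and near-empty networks.
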