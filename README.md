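# ictonet

Directed EEG functional connectivity and brain network ictogenicity in R.

`ictonet` is for researchers who study how large-scale brain networks
reorganize during epileptogenesis from *background* EEG — epochs free of
overt epileptiform discharges. It turns multichannel recordings into
directed functional networks, quantifies how far those networks drift from
hemispheric symmetry, and uses a spiking network model to ask which nodes
matter most for generating pathological activity. Because suitable
recordings are rarely shareable, the package ships a synthetic multichannel
EEG generator with planted, known structure, so the entire analysis chain is
testable end to end.

## What it computes

**Directed connectivity.** For channels `x_i`, `x_j` the lagged
cross-correlation

    r(x_i, x_j)(tau),   normalized by sqrt(r(x_i,x_i)(0) * r(x_j,x_j)(0))

is evaluated in 21 sliding 500 ms windows per 1 s segment. Lags below 2 ms
(volume conduction) and above 250 ms are discarded; the sign of the lag
gives the direction (`x_i` leading `x_j` contributes to `c_ij`). Three
readings of the masked correlogram define three network variants: the
largest positive value (`C^MAX`), the magnitude of the deepest negative
value (`C^MIN`), and their maximum (`C^ABS`). Each element is tested
against 100 ensembles of univariate IAAFT surrogates (Wilcoxon rank-sum,
Bonferroni over the `n(n-1)` elements, FWER < 0.05) and significant
elements are rescaled as

    c_ij = (median_data - median_surr) / (1 - median_surr)

then averaged over segments and normalized to unit total weight.

**Network asymmetry.** Node-level degree imbalance (weighted outdegree
minus indegree), a 20-measure global battery (norms, path measures,
PageRank, assortativity, s-metric, Laplacian spectra, and the degree of
asymmetry — the spectral norm of the Laplacian's skew-symmetric part),
Frobenius distances between matrices with classical MDS embedding, top-5%
edge maps, and the fraction of contralateral (mirror-electrode) connections
among the strongest edges.

**Ictogenicity.** Each node becomes a theta neuron,
`dtheta/dt = 1 - cos(theta) + (1 + cos(theta)) I(t)`, with
`I(t) = I0 + I_noise xi(t) + omega * sum_j c_ji (1 - cos(theta_j -
theta*)) / N`, `I0 = -1.2`, `I_noise = 6`. Brain network ictogenicity (BNI)
is the mean fraction of time nodes spend in the active state; the coupling
`omega_50` is calibrated by bisection so BNI = 0.5. Node ictogenicity is
the normalized activity drop after virtually resecting node `i`:
`NI_i = (0.5 - BNI_post) / 0.5`, averaged over 10 noise realizations.

**Statistics.** Rank-sum and Kruskal-Wallis tests, Benjamini-Hochberg FDR,
AUROC effect sizes, and a per-node cohort comparison that reports nodes
passing both FDR < 0.1 and an AUROC gate (< 0.2 or > 0.8).

## Worked example

Recover a planted directed coupling (channel `b` is a noisy copy of `a`,
delayed by 12 samples = 60 ms at 200 Hz):

```r
library(ictonet)
set.seed(1)
base <- rnorm(212)
seg <- rbind(a = base[13:212],                            # leads
             b = 0.9 * base[1:200] + rnorm(200, sd = 0.3))
C <- segment_connectivity(seg, fs = 200, method = "abs",
                          n_surrogate_sets = 20, seed = 7)
round(C$weights, 3)
#>      [,1]  [,2]
#> [1,]    0 0.773
#> [2,]    0 0.000
```

The surviving weight sits in `c_12` only: `a` drives `b`, not the reverse.

Virtual resection on a 6-node network where node 2 drives all others:

```r
set.seed(2)
W <- matrix(runif(36, 0, 0.2), 6); diag(W) <- 0
W[2, -2] <- W[2, -2] + 1.2
W <- W / sum(W)
pars <- theta_params(n_steps = 1e5, n_runs = 5)
cal <- calibrate_omega(W, pars, seed = 11)
cal$omega_50             #> 1024
round(cal$bni_achieved, 3)  #> 0.509
ni <- node_ictogenicity(W, cal$omega_50, pars, seed = 12)
transform(ni$ni, ni = round(ni, 3))
#>   node    ni
#> 1    1 0.058
#> 2    2 0.571
#> 3    3 0.092
#> 4    4 0.068
#> 5    5 0.078
#> 6    6 0.040
```

At the calibrated coupling the network spends half its time active;
removing the hub (node 2) cuts that activity by 57%, an order of magnitude
more than removing any spoke — the hub is the ictogenic node.

A full synthetic experiment (cohorts, preprocessing, connectivity, metrics,
statistics) runs from one configuration via `run_pipeline(pipeline_config(...),
out_dir)`; see `vignettes/ictonet-methods.Rmd` for the methods and the
parameter choices.

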