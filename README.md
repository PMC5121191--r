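# covgraph

Tools for studying how **covariance graphs** (marginal dependence,
$\Sigma_{ij} \neq 0$) relate to **concentration graphs** (conditional
dependence, $\Theta_{ij} = (\Sigma^{-1})_{ij} \neq 0$) in Gaussian
graphical models, and for benchmarking sparse graph-reconstruction methods
in the high-dimensional regime ($p > n$) typical of gene-expression and
protein-interaction data.

The package is built around one identity: writing the precision matrix as
$\Theta = D(I - A)D$ with a zero-diagonal structure matrix $A$, the
covariance is the **transitive closure** of the concentration graph,

$$\Sigma = D^{-1}\bigl(I + A + A^2 + \cdots\bigr)D^{-1}
         = D^{-1}(I + A^*)D^{-1}, \qquad A^* = (I - A)^{-1} - I,$$

so every marginal correlation is a sum of weight products over paths in
the true graph — which is why simple correlation thresholding sees
indirect edges.  On top of this the package provides

* **closure algebra**: Neumann-series and exact closures, closed forms for
  star graphs, the minimal (shortest-path) closure, the tree product rule
  $C_{ij} = \prod_{\text{path}} C_{kl}$, and the 3-node maximum-likelihood
  covariance completion;
* **network deconvolution**: the scaled transform
  $\tilde A = \alpha\Sigma_M(I+\alpha\Sigma_M)^{-1}$, the exact
  self-loop-corrected variant, Kac–Murdock–Szegő closed forms for chain
  graphs, the quadratic whose roots make $\alpha$ delete a *direct* edge,
  and a per-order discriminative-ratio diagnostic;
* **synthetic models**: chain / cluster / scale-free / hub topologies,
  positive-definite transform $\hat A = wA + \gamma I$, correlation-strength
  calibration, Cholesky sampling;
* **five estimators** with one tuning parameter each: hard-thresholded
  covariance (plus a scale-free threshold-selection criterion), covariance
  Lasso (majorization–minimization), nodewise regression Lasso, graphical
  Lasso, adaptive Lasso;
* an **evaluation harness**: confusion counts, the distance
  $d_E = \sqrt{(T_R - C_{pred})^2 + (T_R - T_{pred})^2}$, ROC curves,
  truth-optimal parameter selection, resampling experiments with a matched
  random-guessing baseline, and drivers reproducing the four-topology
  comparison, the correlation-strength sweep and the data-driven selection
  protocols.

## Worked example

The closure of a 3-node star with both spokes weighted 0.4
(`c = 1 - 0.32 = 0.68`):

```r
library(covgraph)
A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 0.4; A[1, 3] <- A[3, 1] <- 0.4
round(star_closure(A, k = 1)$A_star, 4)
#>        [,1]   [,2]   [,3]
#> [1,] 0.4706 0.5882 0.5882
#> [2,] 0.5882 0.2353 0.2353
#> [3,] 0.5882 0.2353 0.2353
```

The leaf pair, non-adjacent in the truth, picks up closure weight
$0.4 \cdot 0.4 / 0.68 = 0.2353$; the diagonal holds closed-walk weight.
On the correlation scale the indirect entry is exactly the product of the
two direct ones (the tree product rule):

```r
model <- covariance_from_concentration(concentration_model(diag(3) - A))
round(model$C, 4)
#>        [,1]   [,2]   [,3]
#> [1,] 1.0000 0.4364 0.4364
#> [2,] 0.4364 1.0000 0.1905
#> [3,] 0.4364 0.1905 1.0000
verify_product_rule(model, weighted_graph(A))$max_residual
#> [1] 2.775558e-17
```

A miniature reconstruction benchmark — a 50-node chain calibrated to
moderate correlation strength ($\sigma \approx 0.19$), $n = 30$ samples,
10 resamples, each method at its truth-optimal parameter:

```r
g <- make_chain_graph(50)
w <- calibrate_weight(g, sigma_target = 0.19)   # 0.2597
m <- correlation_from_graph(g, w)
res <- resample_experiment(m, g, methods = c("thresh_cov", "nodewise"),
                           n = 30, n_resamples = 10, seed = 42)
aggregate(cbind(TP, T_pred, sensitivity) ~ method, data = res, FUN = mean)
#>              method   TP T_pred sensitivity
#> 1          nodewise 30.7   45.0  0.69599625
#> 2   random_nodewise  1.8   45.0  0.04153509
#> 3 random_thresh_cov  2.0   51.9  0.03858099
#> 4        thresh_cov 33.4   51.9  0.64890388
```

Of the 49 true chain edges, nodewise regression recovers on average 30.7
while predicting 45 edges (sensitivity, i.e. correct/total predicted,
0.70); hard thresholding of the sample correlation recovers 33.4 of 51.9
predicted (0.65); matched random guessing sits at 0.04.  At this
correlation strength roughly a third of the true edges are simply not
identifiable from 30 samples.

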