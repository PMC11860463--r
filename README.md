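# fimvc — incomplete multi-view clustering with entropy-weighted feature reconstruction and fuzzy information fusion

`fimvc` clusters samples that are described by **two feature views**
when some — possibly all — samples are missing one view. The motivating
setting is multiphase contrast-enhanced CT of liver tumours, where each
patient ideally contributes two imaging phases (two views of the same
lesion) but privacy constraints and acquisition gaps leave many
patients with a single phase. The package is aimed at researchers who
have per-view feature matrices plus an availability mask and want
unsupervised groupings with an evaluation harness around them.

## Method

Given views $X^v \in \mathbb{R}^{N\times D_v}$ ($v=1,2$) and a mask
$M \in \{0,1\}^{N\times 2}$, the model minimises

$$\mathcal{L} = \mathcal{L}_{\mathrm{fusion}} + \lambda_1\,\mathcal{L}_{\mathrm{rec}} + \lambda_2\,\mathcal{L}_{\mathrm{pre}},
\qquad \lambda_1 = 0.1,\ \lambda_2 = 0.01,$$

where

* $\mathcal{L}_{\mathrm{rec}}$ — per-view autoencoders with a softmax
  latent layer, squared reconstruction error on available rows;
* the latents are **entropy-reweighted**: each latent column $j$ gets
  $W_j = (1 - E_j)/(m - \sum_k E_k)$ from the Shannon entropy $E_j$ of
  its share distribution across the batch, and $L^v = Z^v\,\mathrm{diag}(W)$
  shrinks uninformative (high-entropy) features; $\sum_j W_j = 1$;
* $\mathcal{L}_{\mathrm{pre}}$ — cross-view generators $G_{12}, G_{21}$
  predict each view's weighted latent from the other
  ($\lVert G_{12}(L^1)-L^2\rVert_2^2 + \lVert G_{21}(L^2)-L^1\rVert_2^2$
  on paired samples, cycle consistency
  $G_{21}(G_{12}(\cdot)) \approx \mathrm{id}$ when no pairs exist), and
  impute missing-view latents;
* $\mathcal{L}_{\mathrm{fusion}}$ — every batch sample acts as a fuzzy
  cluster centre: memberships $U_{ij} \propto (d_{ij}^2+\varepsilon)^{-1/(m_f-1)}$,
  per-view similarities $S^v_{ij} = \frac{1}{V}U_{ij}^2 d_{ij}^2$,
  probability matrices $P^v = \mathrm{rowsoftmax}(-S^v)$, joint
  $J \propto P^1 (P^2)^\top$, and the loss
  $-\sum_{ij} J_{ij} \log\bigl(J_{ij} / (r_i c_j)^{\alpha+1}\bigr)$
  with marginals $r, c$ and $\alpha = 9$ — a mutual-information
  objective with entropy-balanced marginals.

Training is Adam (lr $10^{-4}$, batch 256, 500 epochs by default) on a
built-in reverse-mode autodiff tape (there is no R torch here — the
tape is ~20 matrix operations whose adjoints are finite-difference
checked in the tests). Clusters come from seeded k-means on the fused
latents. Everything is bit-reproducible from one seed.

## Worked example

```r
library(fimvc)

# two-view synthetic cohort: 200 samples, 2 classes, 30% missing one view
spec <- synthetic_spec(n_samples = 200, n_clusters = 2, dims = c(20, 24),
                       separation = 6, seed = 1)
data <- apply_missing(simulate_multiview(spec), missing_spec(0.3, seed = 8))
data
#> imvc_dataset: 200 samples, 2 views (20, 24 features)
#>   paired samples: 140; view-1 only: 31; view-2 only: 29
#>   labels: 2 classes

model <- imvc_train(data, imvc_config(epochs = 100, seed = 1))
model
#> imvc_model: latent dim 128, 100 epochs trained
#>   final losses: fusion -95.37, recon 44.23, pred 1.715e-05, total -90.95

assign_clusters(model, data)
#> imvc_clustering: 200 samples in 2 clusters
#>   ACC 1.000 | NMI 1.000 | ARI 1.000
```

The fusion loss is large and negative because its magnitude is
dominated by the $\alpha$-powered marginal terms; what matters is its
decrease. ACC/NMI/ARI are measured against the generator's planted
labels (ACC under optimal cluster-class matching), so 1.0 means the
planted two-cluster structure was recovered exactly despite 30% of
samples missing a view.

The same pipeline is scriptable from a shell:

```sh
FIMVC=$(Rscript -e 'cat(system.file("scripts/fimvc.R", package = "fimvc"))')
Rscript $FIMVC simulate --n 200 --seed 7 --missing-rate 0.3 --out cohort/
Rscript $FIMVC train --data cohort/ --out run/ --epochs 100 --seed 1
Rscript $FIMVC sweep --rates 0.1,0.3,1.0 --seeds 1,2,3 --out sweep/
Rscript $FIMVC ablate --rate 0.3 --out ablation/
```

Real data use the same directory layout: headerless CSVs `view1.csv`,
`view2.csv`, `mask.csv` and optional `labels.csv` (see
`?load_dataset`).

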