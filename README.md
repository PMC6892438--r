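# latentomics

Multi-omics integration with stacked variational autoencoders, for cancer
genomics. `latentomics` learns a small set of **non-negative latent
factors** that jointly summarize gene expression, somatic mutations and
gene-level copy number for a tumor cohort, then uses those factors to
discover subtypes, predict patient survival, interpret what each factor
means, and judge which cancer cell lines are faithful models of the tumors.
It is aimed at computational biologists who have per-modality feature ×
sample matrices (FPKM/RPKM-like expression, a binary nonsynonymous-mutation
matrix, GISTIC-style segment means) and want one latent space for all of
them.

## The model

Each sample's stacked, unit-scaled profile $x \in [0,1]^d$ is modeled with
a variational autoencoder: an encoder network maps $x$ to a diagonal
Gaussian posterior $q_\theta(z\mid x) = N(\mu(x), \mathrm{diag}\,\sigma^2(x))$
over $k$ latent factors, a decoder maps the code back through a sigmoid
output layer, and training minimizes the negative evidence lower bound

$$\ell \;=\; -\mathbb{E}_q \log p_\phi(x \mid z) \;+\; \beta\,
D_{KL}\!\big(q_\theta(z \mid x)\,\|\,N(0,I)\big),
\qquad z = \mu + \sigma\epsilon,\ \epsilon \sim N(0,I),$$

with one batch-normalized ReLU hidden layer on each side ("stacked"), the
KL weight $\beta$ warmed up from 0 by $\kappa$ per epoch, and the code
rectified so the factor matrix $Z = \mathrm{ReLU}(\mu(x)) \ge 0$. Around
this core the package provides:

* **netsmooth** — random-walk-with-restarts diffusion of binary mutations
  over a protein–protein interaction network,
  $F_{t+1} = \alpha A F_t + (1-\alpha)F_0$, with matching closed form;
* **interpretation** — Spearman associations between factors and input
  features, per-factor Cox models (age/sex/stage-adjusted) to select
  clinically relevant factors, and an exact hypergeometric
  over-representation test for GMT gene sets;
* **survival** — Efron-tie Cox regression (optionally ridge-penalized),
  Harrell's c-index with event-stratified cross-validation, Kaplan–Meier
  tables and the multivariate log-rank test;
* **benchmarks** — nested-CV one-vs-rest linear SVM label prediction with
  macro-averaged ROC, k-means (1,000 restarts) with adjusted mutual
  information, per-cluster differential expression, and a compound score
  (mean of auROC, AMI, $-\log_{10}p$, c-index) for selecting the
  architecture;
* **cell lines** — latent-space 5-nearest-neighbor fitness scoring,
  an artificial-contamination experiment, and subtype assignment of
  retained lines;
* **synthetic data** — generators for multi-omics cohorts with planted
  clusters, proportional-hazards survival, block-model PPI networks and
  pseudo-cell-lines, so the whole pipeline is testable offline.

## Worked example

A 200-sample synthetic cohort with four planted clusters, integrated and
analyzed end to end:

```r
library(latentomics)

gen <- generate_multiomics(n_samples = 200, n_expr = 200, n_mut = 50,
                           n_cnv = 30, separation = 3, seed = 21)
scaled <- lapply(gen$matrices, function(m) scale_features(m)$scaled)
stack  <- stack_modalities(unname(scaled))
stack
#> <omics_stack> 280 features x 200 samples (expression=200, mutation=50, cnv=30)

fit <- train_vae(stack, vae_config(n_hidden = 128, n_latent = 16,
                                   epochs = 150, batch_size = 50, seed = 5))
Z  <- vae_transform(fit$model, stack)     # 200 x 16, all entries >= 0
cl <- kmeans_cluster(Z, K = 4, n_init = 100, seed = 9)
cl
#> <cluster_result> K=4, wcss=264.6, sizes: 47/57/53/43
ami(cl$labels, gen$truth$clusters)
#> [1] 0.817
```

The AMI of 0.82 against the planted labels is essentially the ceiling for
this noise level — k-means on the *true* latent matrix scores about the
same. Survival analysis on the same factors:

```r
surv <- generate_survival(gen$truth, beta_star = 1, seed = 22)
rel  <- clinically_relevant_factors(Z, surv)
rel$selected
#> [1] "LF1"  "LF4"  "LF5"  "LF7"  "LF11" "LF12"
cv <- cv_cindex(unclass(Z)[, rel$selected], surv, seed = 3)
cv$best_penalty; cv$best_mean_c
#> [1] 10
#> [1] 0.800
logrank_multivariate(surv, cl$labels)
#> $chisq 145.7   $df 3   $p 2.26e-31
```

Six factors carry independent prognostic signal after BH correction; a
ridge-penalized Cox model on them reaches an out-of-fold concordance of
0.80, and the four clusters have sharply different survival curves.

A YAML-configured end-to-end run (simulate → train → interpret → cluster →
cell lines) is available as `run_pipeline("config.yaml")`, with a thin
command-line wrapper in `inst/cli/latentomics.R`.

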