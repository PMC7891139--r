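# batchgan

Two-stage adversarial batch effect removal for single-cell RNA-seq
expression profiles, with a single-cell-level evaluation metric, probe-based
gene-importance scores and a fully seeded synthetic benchmark.

## The problem and the model

Datasets produced on different platforms or in different runs carry
systematic non-biological variation. Integration must *mix* the cell
populations shared between batches while *keeping apart* populations that
exist in only one batch. `batchgan` does this in two stages.

**Stage one — batch-ignorant content codes.** The expression profile
$x \in \mathbb{R}^d$ (log-TPM) is modelled as a function of biological
content and a one-hot batch indicator $b$. An encoder $E$ and two
generators $G_1, G_2$ reconstruct $G(E(x),b) = f(G_1(b) + G_2(E(x),b))$
($f$ = ReLU) and are trained under

$$\lambda_c\,\mathbb{E}\lVert E(G(E(x),\tilde b)) - E(x)\rVert^2
  + \lambda_r\,\mathbb{E}\lVert G(E(x),b) - x\rVert^2,
  \qquad \lambda_c = 3,\ \lambda_r = 1,$$

where $\tilde b$ is a freshly resampled random batch indicator. The
$l$-dimensional codes $E(x)$ are used to pair cells across batches.

**Stage two — distribution matching on rwMNN pairs.** Mutual nearest
neighbours between a batch and the anchor pool are found in code space
($k = \max(1, \lfloor s_{\mathrm{eff}}/100 \rfloor / 2)$, subsample cap
$s = 3000$) and extended by within-batch random walks of length $m = 50$
over $k_1$-neighbourhoods — the rwMNN pairs. A residual generator
$G'(x) = \mathrm{ReLU}(F(x) + x)$ is trained against a critic $D'$ under
the Wasserstein objective with gradient penalty, using *only* cells in
rwMNN pairs; the trained $G'$ then transforms every cell of the batch into
the anchor's style. The anchor batch (largest total variance, or
user-chosen) is never modified. Multiple batches are integrated
incrementally, each corrected batch joining the anchor pool.

The package also implements the positive / true-positive mixing metric
(neighbourhood type purity plus a three-sigma batch-composition rule),
probe classifiers with expected-gradients gene attributions, readers and
writers for 10x-style Matrix Market directories, dense CSV/TSV and HDF5,
and a negative-binomial multi-batch simulator with planted markers,
designated batch-diagnostic genes and full ground truth.

## Worked example

```r
library(batchgan)

sim <- simulate_batches(default_benchmark_design("small"), seed = 1)
es  <- preprocess(sim$data, hvg_n = 200)     # QC, log-TPM, shared genes, HVG
fit <- integrate_batches(es, epochs_stage1 = 100, epochs_stage2 = 100,
                         l = 32, widths = c(256, 128), w3 = 128,
                         minibatch_stage1 = 64, minibatch_stage2 = 64,
                         seed = 1)
print(fit)
#> batch_integration of 2 batches, 800 cells x 200 genes
#>   anchor: batch2 (uncorrected)
#>   batch1: 78 seed pairs, 3978 rwMNN pairs

before <- mixing_summary(mixing_report(pca_embedding(es$matrix),
                                       es$celltype, es$batch))
after  <- mixing_summary(mixing_report(pca_embedding(fit$corrected$matrix),
                                       es$celltype, es$batch))
round(rbind(before, after), 3)
#>        positive true_positive
#> before    1.000         0.248
#> after     0.986         0.485
```

The two numbers per row are the proportion of cells whose neighbourhoods
are at least 50% their own cell type (`positive`: biology preserved) and
the proportion of positive cells whose neighbourhood batch composition is
within three binomial standard deviations of their type's global batch
composition (`true_positive`: batches mixed *where they should be* — for
batch-specific types this rewards staying pure). Correction raises the
true-positive proportion from ~0.25 to ~0.5-0.6 (the exact value varies
with the adversarial training seed; the test suite measures a median of
~0.58 over three seeds) while keeping positivity high. On this design the
metric's ceiling, measured on data simulated with no batch effect at all,
is ~0.75 (see the methods vignette).

Gene-level accounting of what a probe uses, on a simulation with
designated presence/absence batch-diagnostic genes:

```r
design <- default_benchmark_design("small")
design$type_jitter_sd   <- 0.4       # markers dominate type identity
design$diagnostic_genes <- c(0L, 3L) # plant 3 platform-signature genes
sim2 <- simulate_batches(design, seed = 1)
es2  <- preprocess(sim2$data, hvg_n = 200)
probe <- train_batch_probe(es2$matrix, es2$batch, seed = 1)
imp   <- gene_importance(probe, es2$matrix[seq(1, 800, 10), ],
                         es2$matrix[seq(1, 800, 40), ])
head(rank_importance(imp), 5)
#> [1] "gene9"   "gene140" "gene135" "gene50"  "gene117"
sim2$truth$diagnostic$batch2        # the planted signature genes
#> [1] "gene9"   "gene135" "gene7"
```

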