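# mpdc — multi-perspective dynamic consistency segmentation

Semi-supervised segmentation of 2-D medical image slices for settings
where pixel-level annotation is scarce: a few labeled scans and many
unlabeled ones. The package trains a three-branch encoder–decoder network

* a **positive** branch predicting foreground structure,
* a **reverse** branch whose scores are negated before softmax
  (`P_rev = softmax(−O_rev)`), pushing it to learn background structure,
* a **fusion** branch fed by a perspective fusion module,
  `f_fus = f_pos − softmax(−f_pos) ⊙ softmax(f_rev)`, which amplifies
  responses where the two perspectives disagree (typically blurred object
  boundaries),

and regularizes unlabeled slices with a dynamically thresholded, decoupled
consistency objective. The threshold starts at `1/C` and follows a
progress-weighted EMA of the batch mean maximum confidence,
`γ_i = min(γ_i^pos, γ_i^rev)`. Pixels where both branches beat `γ` form the
consistent part and exchange argmax pseudo-labels (pairwise cross-pseudo
supervision, gated between a 2-term and a 6-term form at mean confidence
0.95); the rest form the inconsistent part, where each branch's
low-confidence predictions are pulled toward the other branch's detached
high-confidence predictions (direction consistency). A channel-compressed
feature-consistency term ties each encoder to its decoder. The total loss
is the unweighted sum

```
L = (sup_p + sup_r + sup_f) + L_cps + L_dc + L_feat
```

Because no deep-learning framework exists for R in this toolchain, the
package ships its own training engine: reverse-mode automatic
differentiation over plain arrays with compiled (Rcpp) kernels for
convolution, pooling, up-sampling and batch normalization. Every
operator's gradient is tested against finite differences.

## Worked example

Train on a generated low-contrast dataset (no downloads needed):

```r
library(mpdc)

spec  <- fixture_spec(n_scans = 20, slices_per_scan = 4, image_size = 32, seed = 100)
pairs <- lapply(generate_fixture_dataset(spec), preprocess_slice, size = 32)
scan  <- sapply(pairs, function(p) p$scan_id)
sc    <- unique(scan); set.seed(200); perm <- sample(sc)
data  <- list(labeled   = pairs[scan %in% perm[7]],      # 1 labeled scan (10%)
              unlabeled = pairs[scan %in% perm[8:20]],
              val       = pairs[scan %in% perm[5:6]],
              test      = pairs[scan %in% perm[1:4]])

cfg <- train_config(iterations = 600, batch_size = 8, labeled_per_batch = 4,
                    network = network_config(n_classes = 2, base_width = 4, depth = 3),
                    val_every = 100, seed = 1)
fit <- mpdc_fit(cfg, data)
evaluate_model(fit$net, data$test, use_best = fit$best$snap)$aggregate
#>       dice  jaccard hd95       asd n_empty
#> 1 83.44238 71.60415    1 0.2166746       0
```

`dice`/`jaccard` are percentages over the held-out test scans (non-background
class, scans re-stacked to volumes); `hd95`/`asd` are the 95th-percentile
Hausdorff and average surface distances in voxels — boundary-quality
metrics, lower is better. The same data trained supervised-only
(`branches = "pos"`, `unsup_weight = 0`) reaches Dice 80.77 under this
seed: the consistency machinery extracts the extra accuracy from the 13
unlabeled scans. At this tiny scale the margin varies by seed — some
initializations collapse — which is why the test suite judges the
comparison over a majority of three fixed seeds. The training log (`fit$log`) records every loss
component, the dynamic threshold `gamma`, the mean confidence `m`, the
consistent-pixel fraction and validation Dice per step.

A thin CLI covers the same workflow from a shell (`exec/mpdc`):

```sh
mpdc synth --spec spec.yaml --out data/
mpdc train --config cfg.yaml --data data/ --out run/
mpdc eval  --ckpt run/last.rds --config cfg.yaml --data data/ --split test
```

Ablation switches from `train_config()`/`network_config()`: branch set
(`pos`, `pos+rev`, `pos+pos+fus`, `pos+rev+fus`), shared vs separate
encoders, dynamic vs fixed threshold, cross-pseudo-supervision pair subset,
prediction-map vs ground-truth inversion.

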