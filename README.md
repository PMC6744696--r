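# proxidet

Nucleus detection in stained microscopy images by pixel-to-pixel
proximity-map regression, in pure R (compiled convolution kernels, no
deep-learning framework).

## What it does, and for whom

Quantitative histology usually starts from the positions of cell nuclei.
Given RGB tissue tiles with point annotations of nucleus centers,
`proxidet`:

1. encodes each annotation set as a **proximity map** — at distance *D*
   from the nearest center a pixel carries
   *s*·(e^{α(1−D/d)} − 1)/(e^α − 1) for *D* ≤ *d* and 0 beyond
   (defaults α = 3, d = 15 px, scale s = 5);
2. trains a **fully convolutional residual encoder–decoder** (concat
   skips, multi-context aggregation, blocks indexed 1..10 for freezing)
   to regress the map from the image, under a **weighted MSE**
   ½ Σ (y + λ·ȳ)(o − y)² that suppresses the all-zero trivial solution
   (λ = 5), with SGD + Nesterov momentum, dynamic patch cropping and
   joint augmentation;
3. localizes nuclei on the predicted map by suppressing values below
   ξ·max(p) and extracting local maxima;
4. evaluates detections against annotations by **Hungarian one-to-one
   matching** inside 16-px gold regions: precision, recall, F1, mean
   Euclidean distance, PR curves, and validation-based ξ selection.

Transfer experiments are first-class: fine-tune from a checkpoint with
the first *k* blocks frozen, or train on a mixture of target and
auxiliary sources under the balance weight γ (loss γ·L_T + L_A).

Because the tissue images this family of methods is trained on are not
redistributable, the package also ships a seeded generator of H&E-like
synthetic tiles (textured eosin background, clutter smudges, dark
elliptical nuclei, touching objects, multiple "organ" styles), so every
experiment in the package runs end to end from a seed.

## Worked example

```r
library(proxidet)

## seeded synthetic corpus: 30 tiles of 64x64, split into
## train / validation / test
corpus <- generate_dataset(synth_style(), 30, 64, 64, seed = 42)
sp <- split_dataset(corpus, seed = 43)

## desk-scale network and a short training run
set.seed(42)
net <- build_network(network_spec(base_width = 8, min_input = 32))
fit <- train(net, data_source(sp$train), sp$val,
             desk_config(max_iterations = 300, eval_every = 100, seed = 42),
             lparams = loss_params(lam = 5))

## detect on one held-out image at the validation-selected threshold
map <- predict_map(fit$network, sp$test[[1]])
det <- detect(map, xi = fit$best_xi)
print(metrics(match_detections(det, sp$test[[1]]$centers, radius = 16)))
```

Output of the final line on this seed:

```
P 1.0000  R 1.0000  F1 1.0000  mean ED 0.649  (TP 7 FP 0 FN 0)
```

meaning all 7 nuclei in the tile were recovered with no false positives,
at a mean localization error of 0.6 px — far inside the 16-px matching
radius. (A single easy tile; corpus-level desk-scale F1 is typically
0.92–0.95 with precision near 1.)

## Documentation

The methods vignette (`vignettes/proximity-regression.Rmd`) describes
the encoding, loss, architecture, training and evaluation in detail,
along with what the synthetic study conditions do and do not establish
about real tissue.
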