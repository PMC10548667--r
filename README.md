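# wheatlfanet

Lightweight real-time detection and counting of wheat heads in field
images, implemented from scratch in R.

Wheat heads (spikes) are the grain-bearing organs counted in phenotyping
and yield studies. Field photographs contain dozens of small, elongated,
mutually occluding heads on cluttered canopy background, and practical
deployments need detectors that run on modest hardware. `wheatlfanet`
implements **WheatLFANet**, a single-stage anchor-based global-regression
detector built for that regime: a compact encoder (stem + three
cross-stage-partial stages, widths 32/64/128), a SimCSPSPPF
pyramid-pooling neck, a cross-stage fusion decoder with prediction heads
at strides 8 and 16, and a composite loss

```
L = 0.05 * L_loc + 0.7 * L_obj + 0.3 * L_cls
```

where `L_loc` is a complete-IoU box loss (overlap + center distance +
aspect term) and the objectness/classification terms are binary
cross-entropy weighted by a missing-label attenuation factor
`alpha(x) = 1 - exp((x - 1) / (a + e))`. The default configuration has
**721,028 trainable parameters (0.72 M)** and **4.06 GFLOPs at 640x640**
(2 ops per multiply-accumulate, convolutions only).

The network engine — convolution, batch normalization, pooling,
upsampling and reverse-mode gradients — is written in the package itself
(R arrays + Rcpp/RcppArmadillo kernels), so training and inference run on
a single CPU with no deep-learning framework. The package also provides
GWHD-style CSV and normalized-box annotation I/O, a 7:2:1 dataset split,
greedy NMS, detection metrics (precision/recall/AP/F1-confidence area),
counting metrics (MAE/RMSE/MAPE/R^2), a synthetic wheat-canopy generator
calibrated to field count statistics (per-image counts: median 24,
mean 42), an SGD + cosine-schedule training loop, and a command-line
interface.

## Worked example

Generate a small synthetic dataset, train the desk-scale preset and
evaluate on held-out scenes:

```r
library(wheatlfanet)

# inspect the default architecture
net <- build_network(network_config())
network_info(net, 640)
#> params: 0.72 M (721028)
#> flops: 4.06 GFLOPs @ 640x640

# desk-scale end-to-end run: 200 easy synthetic scenes at 320 px,
# quarter-width network, 15 epochs (~9 minutes on one CPU)
res <- run_desk_training(desk_preset(seed = 0), verbose = TRUE)
res$report
#> detection:  Pr 0.870  Re 0.826  F1 0.847  AP 0.857  AFC area 0.711
#> counting:   MAE 2.32  RMSE 4.72  MAPE 5.1%  R2 0.977  (n = 50)
```

`Pr`/`Re`/`F1` are precision, recall and F1 at confidence 0.25; `AP` is
the area under the precision-recall curve at matching IoU 0.5; the AFC
area integrates F1 over the confidence threshold. The counting block
compares per-image detection counts with ground truth: on 50 held-out
scenes the detector miscounts by 2.3 heads per image on average and
explains 97.7% of the count variance.

Detection on your own images:

```r
ann <- annotated_image("field01", read_image("field01.png"))
rz  <- resize_to_input(ann, 640)
dets <- detect_images(net, rz$ann$image, conf_thresh = 0.25)[[1]]
detections_to_original(dets, rz$transform)
```

## Command line

A thin script over the same functions:

```sh
Rscript inst/cli/wheatlfanet.R synth  --n 200 --out data --seed 0
Rscript inst/cli/wheatlfanet.R train  --data data --out run --seed 0
Rscript inst/cli/wheatlfanet.R detect --checkpoint run/checkpoint.rds --images data --out dets
Rscript inst/cli/wheatlfanet.R eval   --checkpoint run/checkpoint.rds --data data --out eval
Rscript inst/cli/wheatlfanet.R count  --checkpoint run/checkpoint.rds --images data
Rscript inst/cli/wheatlfanet.R info
Rscript inst/cli/wheatlfanet.R fuse   --checkpoint run/checkpoint.rds
```

`info` prints the parameter and FLOP budget; `fuse` folds batch
normalization into the convolutions for faster inference with identical
outputs.

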