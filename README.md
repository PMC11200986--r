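# promptpose

Top-down animal pose estimation trained jointly from images and language.
Every keypoint (nose, left elbow, ...) owns a natural-language prompt built
from sentence templates; `q` learnable context vectors, each shifted by an
image-conditioned token `alpha = g(pool(I_p))` from a small non-linear
meta-network, make the prompts *dynamic* — every image sees its own version
of the learned context. Prompt embeddings and keypoint-local image features
are aligned by a symmetric contrastive loss on their cosine matrix `Q`;
prompt-to-feature-map cosines give spatial similarity maps `S`; a heatmap
head fuses `S` with the image features and decodes per-keypoint heatmaps to
coordinates. The composite objective is

    L = L_heatmap + beta * L_match + beta * L_spatial,   beta = 2,

and evaluation follows the Object Keypoint Similarity (OKS) protocol

    OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) [v_i > 0] / sum_i [v_i > 0]

with AP/AP50/AP75/APM/APL/AR over the threshold grid 0.50, 0.55, ..., 0.95
and the medium/large area partition at 32² and 96² px².

The package is fully self-contained: COCO keypoint JSON I/O for the
17-keypoint `ap10k` and 20-keypoint `animalpose` schemas, a deterministic
synthetic quadruped generator (so nothing needs downloading), small pure-R
transformer encoders differentiated by a built-in reverse-mode autodiff
tape, OKS evaluation, and a `promptpose` model object with the usual
`print`/`summary`/`coef`/`predict`/`plot`/`residuals`/`simulate` methods.
A `promptpose` command-line script (in `exec/`) exposes
`generate | train | infer | evaluate | ablate`.

## Worked example

Generate a small synthetic dataset, train the desk-scale model for 200
optimizer steps, and score it:

```r
library(promptpose)

schema <- load_keypoint_schema("ap10k")          # 17 keypoints
gen <- synth_config(n_images = 64, image_size = 64,
                    instances_per_image = 1,
                    scale_mix = c(medium = 1, large = 0),
                    occlusion_rate = 0.05, seed = 107)
train <- generate_synthetic_dataset(gen, schema, dir = "synth_train")

cfg <- ppose_config(epochs = 13, batch_size = 4, lr = 3e-3,
                    lr_decay_epochs = integer(0), max_steps = 200, seed = 1)
fit <- promptpose(train, config = cfg)
print(fit)
#> promptpose model: schema 'ap10k' (M = 17), 64px input, D_I = 32, D = 32, q = 8
#> trained 13 epochs on 64 instances; total loss 29.9427 -> 6.3760

metrics <- evaluate_dataset(predict(fit, train), train)
print(metrics)
#> OKS metrics over 64 instances (64 medium, 0 large):
#>   AP 96.2 | AP50 100.0 | AP75 100.0 | APM 96.2 | APL - | AR 96.2
```

The loss falls from 29.9 to 6.4 over 200 steps, and the fitted model
localizes its training instances to an OKS AP of 96.2 — the median
per-keypoint localization error is about 1.3 px at this 64 px crop size (see
`residuals(fit, train)`). `summary(fit)` reports the parameter count and
the learned matching temperature; `plot(fit)` draws the per-component loss
curves.

From the shell, the same pipeline is:

```sh
promptpose generate --out synth_train --n-images 64 --image-size 64 --seed 107
promptpose train --data synth_train --out model.rds
promptpose infer --checkpoint model.rds --data synth_train --out results.json
promptpose evaluate --gt synth_train/annotations.json --pred results.json
```

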