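# laalign

Segmentation of the left atrial appendage (LAA) in 2-D transesophageal
echocardiography (TEE) with adversarial latent-space alignment, in pure
R/C++.

The LAA is a finger-like, often multi-lobed pouch of the left atrium and the
dominant site of thrombus formation in atrial fibrillation; its size and
shape drive occluder selection for LAA occlusion (LAAO). Segmenting it in
TEE is hard: the cavity is a hypoechoic region with weak, speckle-corrupted
edges and highly variable anatomy. `laalign` implements a segmentation
framework that injects anatomical *shape priors* into the image encoder:

* **Segmentation network G** — a U-shape encoder–decoder whose encoder is a
  ConvNeXt (stem 4×4/4; stages of depth (3,3,9,3); depthwise 7×7 + inverted
  1×1 bottleneck blocks; layer normalization and GELU throughout; 2×2/2
  downsamplers between stages), trained with
  `L_seg = λ_CE·L_CE + λ_Dice·L_Dice` (λ = 1, 1).
* **Mask reconstruction auto-encoder** — the same ConvNeXt encoder applied
  to the binary label masks, with a skip-free decoder and per-pixel L1 loss
  `L1 = Σ|g_i − r_i|`; its bottleneck latent k is a learned shape prior.
* **Latent space alignment** — a least-squares adversarial game between the
  image latent G(x) and the frozen mask latent k,
  `min_D ½E[(D(k)−1)²] + ½E[D(G(x))²]`, `min_G ½E[(D(G(x))−1)²]`,
  where D is five 3×3 convolutions (LeakyReLU 0.2 + batch norm) and a fully
  connected head; plus an InfoNCE contrastive loss on pooled unit-norm
  latents, `L_CL = −log exp(q·k₊/τ) / Σ_i exp(q·k_i/τ)` with τ = 0.1 and
  in-batch negatives. The joint alignment loss is
  `L_LA = λ_GAN·L_GAN + λ_CL·L_CL` (λ = 1, 1).

Training is two-stage: (1) fit the mask auto-encoder; (2) freeze it and
train G against `L_seg + L_LA` with an alternating discriminator update
(Adam, lr 1e-4, β₁ = 0.9, polynomially decaying; batch 8; ±10° rotation
augmentation; patient-level 4:1:1 train/val/test split).

Because clinical TEE data cannot be redistributed, the package ships a
seeded **synthetic TEE generator**: sector-shaped field of view, unit-mean
multiplicative Gamma speckle, Gaussian point-spread blur, a hypoechoic
lobed cavity with a narrow neck as the segmentation target, per-patient
anatomical correlation, and per-patient thrombus flags (bright blob inside
the cavity). The full evaluation suite (Dice, IoU, accuracy, G-mean,
Cohen's kappa, AUC; mean ± sd overall and per thrombus subgroup) is
included. All network layers and their gradients are implemented in
C++ (Rcpp/RcppArmadillo) — no external deep-learning framework is needed.

## Worked example

Desk-scale end-to-end run (64×64 images, a 16/32/64/128-wide backbone):

```r
library(laalign)

net_cfg   <- network_config(depths = c(1, 1, 2, 1), dims = c(16, 32, 64, 128),
                            input_size = c(64, 64))
train_cfg <- train_config(input_size = c(64, 64), recon_steps = 300,
                          steps = 300, batch_size = 8, seed = 1)

man <- generate_dataset(n_patients = 10, images_per_patient = 20,
                        thrombus_fraction = 0.5, size = c(64, 64),
                        seed = 1, out_dir = tempfile())
man <- split_by_patient(man, seed = 1)               # patient-level 4:1:1

recon <- train_reconstruction(man, net_cfg, train_cfg)   # stage 1
seg   <- train_segmentation(man, recon, net_cfg, train_cfg, loss_weights())

rows  <- which(man$records$split == "test")
preds <- lapply(rows, function(i)
  laa_predict(seg$network, read_image_png(man$records$image_path[i])))
evaluate(preds, man, records = rows)
```

Output (about 7 minutes on one CPU core):

```
LAA segmentation metric report
  overall (n = 40):
    dice   0.852 +/- 0.030
    iou    0.743 +/- 0.046
    acc    0.982 +/- 0.004
    gmean  0.924 +/- 0.033
    kappa  0.842 +/- 0.032
    auc    0.995 +/- 0.002
```

The rows read as: on the 40 images of the held-out test *patients*, the
predicted LAA masks overlap the ground truth with mean Dice 0.852 (IoU
0.743); pixel accuracy is high mostly because the LAA covers only a few
percent of each image, which is why the imbalance-robust G-mean, kappa and
AUC matter.

A command-line wrapper covering the same pipeline is installed at
`system.file("cli", "laalign", package = "laalign")` with subcommands
`synth`, `train-recon`, `train-seg`, `eval` and `predict`.

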