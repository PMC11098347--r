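# lungsev

Severity grading of lung involvement on 2-D chest-CT slices, as a fully
self-contained R package: adaptive denoising, neural lung-field
segmentation, handcrafted + deep texture features, and a hybrid
four-class classifier — together with a seeded synthetic CT-phantom
generator so that every stage is testable on one CPU with no external
data.

## Who this is for

Researchers and students who want a transparent, dependency-light
reference implementation of a slice-level severity pipeline — each stage
readable in plain R, each numeric claim covered by a test against an
independent oracle — rather than a clinical tool. The four severity
classes follow the standard CT vocabulary: **0** negative, **1**
air-space consolidation, **2** crazy paving, **3** ground-glass opacity
(GGO).

## The pipeline

1. **Denoising** — an improved Wiener filter: per pixel, with local mean
   μ, variance σ² and median `Med` over an odd window,

   `S = Med + r · (Img − Med)`, `r = max(0, σ² − V²) / σ²`,

   with noise variance `V²` estimated as the mean local variance (a
   `tanh`-compressed literal variant is selectable). Quality is scored
   by the 255-peak `PSNR = 10·log10(255²/MSE)`, a harmonic-mean SNR
   `10·log10(H²/2·Var)`, and their product.
2. **Segmentation** — a modified SegNet: 13 + 13 convolutional layers
   (VGG16 channel plan, width-scalable), five *mixed stochastic pooling*
   stages `γ·max(a) + (1−γ)·mean(a) + a_l` with `a_l` drawn with
   probabilities `p_i = a_i⁺/Σa_k⁺` (training only), nearest-neighbour
   upsampling in the decoder, and a *hard tanh–softplus* output
   activation: −1 for `x < −1`, `x(x+1)` on `[−1,1]`,
   `1 + log(1+eˣ)` for `x > 1`, thresholded at 0.
3. **Features** — `f_set = [Mldn | Elbp | shape | deep]`: modified local
   directional number patterns from paired 8-direction compasses (the
   classical Kirsch bank and a derivative-of-Gaussian bank; 56-code
   histograms on a 4×4 grid each),
   median-robust LBP histogram + Shannon entropy, shape descriptors
   (area, perimeter, convex hull, solidity), and features from seeded
   ResNet/VGG16-style backbones.
4. **Classification** — an attention-augmented SqueezeNet (fire modules,
   scaled dot-product attention `softmax(QKᵀ/√d_k)V`, trained with a
   Tversky-modulated loss `(1 − TI) · mean(σ(x)+tanh(x)+1)/3`, χ = ½)
   and a plain CNN trained with cross-entropy; class probabilities are
   averaged and arg-maxed.
5. **Evaluation** — Dice and Jaccard for masks; the nine standard
   confusion-matrix metrics (accuracy, precision, sensitivity,
   specificity, FNR, FPR, F-measure, MCC, NPV), one-vs-rest and macro.

The methods vignette (`vignettes/severity-pipeline.Rmd`) gives the full
model descriptions, parameter meanings, and the reasoning behind every
open design choice.

## Worked example

```r
library(lungsev)

# a crazy-paving phantom with exact ground truth
s <- generate_phantom(phantom_spec(label = 2, image_size = 64, seed = 11))
s
#> <phantom_sample> 64x64, label 2, lung 979 px, lesion 218 px

# denoise and score against the clean slice
clean <- generate_phantom(phantom_spec(2, 64, noise_sigma = 0, seed = 11))$image
image_quality(clean, s$image)$psnr          # noisy input
#> [1] 26.50686
image_quality(clean, improved_wiener(s$image))$psnr  # after filtering
#> [1] 27.48572

# train the segmenter briefly on this one slice and score the mask
seg <- build_msegnet(input_size = 64, seed = 1)
seg <- train_segmenter(seg, list(s$image), list(s$lung_mask),
                       epochs = 150, lr = 1e-2, batch_size = 1, seed = 2)
mask <- segment(seg, s$image)
dice(mask, s$lung_mask)
#> [1] 1

# the worked sensitivity value from printed confusion counts
classification_metrics(list(tp = 884, tn = 0, fp = 0, fn = 120))$sensitivity
#> [1] 0.8804781
```

The PSNR rises by ≈1 dB after filtering; the overfit segmentation
reproduces the ground-truth lung mask exactly (Dice 1); and the
confusion counts 884/120 give sensitivity 884/1004 ≈ 0.880.

`run_pipeline(pipeline_config("out"))` executes the whole chain —
simulate, denoise, train + segment, extract, train + classify,
evaluate — writing every artifact (images, masks, `features.csv`,
`predictions.csv`, `report.json`) under `out/`, reproducibly from one
seed. A thin command-line front end over the same functions is included
at `inst/cli/lungsev.R`.

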