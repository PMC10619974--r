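# cspd — contrast-free super-resolution power Doppler

Super-resolution ultrasound microvessel imaging without contrast agents.
Ultrasound localization microscopy (ULM) resolves micrometer-scale
vessels by localizing injected microbubbles over tens of seconds of
ultrafast acquisition; power Doppler needs only a fraction of a second of
contrast-free data but is diffraction-limited. `cspd` implements the
learned bridge between the two — and, because no public paired data set
exists, the complete synthetic study needed to exercise it end to end:

* a **synthetic microvasculature simulator**: random branching vessel
  trees with spline-smoothed centerlines, scatterers advected along the
  lumen at the local speed with optional cardiac pulsatility, including a
  tagged pair of parallel vessels separated by half a PSF width as a
  built-in two-point resolution probe;
* a **linear forward model**: subpixel PSF deposition per scatterer plus
  a low-rank quasi-static tissue clutter field and electronic noise,
  realizing `U(x,z,t) = Σₙ aₙ P(x−xₙ(t), z−zₙ(t)) + c(x,z,t) + e(x,z,t)`;
* **Doppler processing**: SVD clutter filtering on the Casorati matrix,
  power Doppler (mean |u|² over slow time), slow-time spectral
  flow-separation augmentation, temporal truncation/interpolation, and
  sliding-window reconstruction series;
* **ULM reference reconstruction**: matched-filter localization with
  subpixel centroid refinement and Dirac accumulation on an R-fold grid;
* the **learned reconstruction** `f[U(x,z,t); θ] ≈ S(x,z)`: a U-Net
  encoder–decoder (slow-time frames as input channels, two extra
  bilinear stages for R = 4 output upsampling) trained with L1,
  L1 + λ₁·feature-space, or L1 + λ₂·adversarial (weight-clipped
  Wasserstein critic) objectives, λ₁ = 0.001, λ₂ = 0.01 — implemented
  from scratch in base R, including backpropagation and Adam;
* **evaluation metrics**: PSNR, SSIM (3×3 Gaussian window), vessel
  cross-section FWHM and FWHM ratio, MSE of normalized longitudinal
  intensity profiles (MSE-NIP), and Fourier-domain global resolution
  from exponential fits to iso-frequency curves.

The package follows the classic R modelling idiom: `cspd()` is the
fitting function; the returned object has `print`, `summary`, `predict`
and `plot` methods.

## Worked example

Simulate a small study (7 imaging planes: 6 for training, 1 held out),
train the L1-mode model, and compare the reconstruction against the
power Doppler baseline on the held-out plane:

```r
library(cspd)

cfg <- experiment_config(
  n_planes = 7,
  pair = training_pair_config(n_blocks = 3, block_frames = 64,
                              ulm_frames = 1500,
                              pulsatility = pulsatility_profile(0.5, 0.2)),
  augmentation_factor = 4,
  train = train_config(epochs = 13, seed = 11),
  master_seed = 101)
ds <- build_dataset(cfg)

fit <- cspd(ds$planes[1:6],
            generator = generator_spec(in_frames = 64, base_channels = 16),
            loss = loss_spec("L1"), config = cfg$train)
print(fit)
#> Contrast-free super-resolution power Doppler model
#>   loss: L1 | input: spatiotemporal | R = 4 | 72 samples (7 validation)
#>   trained 13 epochs; best validation loss 0.01847

test <- ds$planes[[7]]
img  <- predict(fit, test$blocks_raw[[1]])   # held-out contrast-free block
pd   <- power_doppler(test$blocks_raw[[1]])

nrm <- function(m) (m - min(m)) / diff(range(m))
ssim(nrm(img$intensity), test$ulm$intensity)          # 0.806
ssim(upsample_bilinear(nrm(pd$intensity), 4),
     test$ulm$intensity)                              # 0.058
```

The reconstruction agrees with the ULM reference far better than the
diffraction-limited baseline (SSIM 0.81 vs 0.06 — the baseline carries
blurred vessels plus residual clutter texture everywhere). On the
built-in sub-diffraction vessel pair (two parallel vessels 38.5 µm
apart, half the lateral PSF width), the cross-sectional profile of the
reconstruction shows two peaks where power Doppler shows one, and the
FWHM of the designated vessel drops from 50.1 µm (power Doppler) to
20.3 µm — an FWHM ratio of 2.5.

Long acquisitions reconstructed with a sliding window preserve the
cardiac waveform imposed on the flow:

```r
puls <- pulsatility_profile(modulation_depth = 0.5, cardiac_period = 0.2)
# ... synthesize a 320-frame pulsatile block on the held-out tree ...
r <- run_pulsatility_analysis(raw, puls, model = fit,
                              window = 64, step = 16, roi_native = roi)
r$cor_pd_waveform     # 0.96
r$cor_cspd_waveform   # 0.89
```

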