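# iqtask

Task-based image-quality assessment of deep-learning super-resolution
with numerical observers, on fully simulated phantom data.

## The problem

Super-resolution networks are usually graded with traditional
image-quality metrics (ensemble MSE, PSNR, SSIM).  For medical images the
relevant question is different: does super-resolution preserve — or
destroy — the information an observer needs to perform a diagnostic task?
`iqtask` answers this with a controlled simulation study:

1. **Phantoms.** Clustered lumpy backgrounds (CLB) — Poisson-distributed
   clusters of Gaussian-scattered elongated exponential blobs,
   `l(r, Rθ) = exp(−α‖Rθr‖^β / L(Rθr))` — emulate mammographic texture.
   Signals are either a Rayleigh pair/line (two impulses separated by
   L−2 px vs. a line of length L, blurred with a σ = 1.375 px Gaussian)
   or a synthetic microcalcification cluster inserted multiplicatively,
   `f1 = fb(c·sMC + 1)`, `c ~ U[0.05, 0.06]`.
2. **Imaging.** HR images are object + noise; LR images add a Gaussian
   blur (σ = 1.5 px), for the MC task also decimation by 2 and bilinear
   upsampling back; noise is pixel-wise IID mixed Poisson–Gaussian with
   std √(σp² + σg²).
3. **Super-resolution.** A small trainable convolutional chain (SRCNN
   family, depths 2–8, MSE loss, Adam) maps LR to SR.
4. **Observers.** Hotelling (`w = K⁻¹Δf̄`), regularized Hotelling via the
   truncated SVD pseudoinverse (`σ_P ≥ λσ_1`, λ selected on validation
   data over 10⁻⁹…10⁻⁴), a 60-channel Gabor channelized Hotelling
   observer, and learned residual-network observers (warm-startable from
   an RHO template) approximating the ideal observer.
5. **Evaluation.** Empirical (Mann–Whitney) AUC with DeLong variance and
   95% confidence intervals, next to ensemble MSE / PSNR / SSIM, with
   experiment drivers for signal-length, SR-depth and observer-capacity
   sweeps.

## Worked example

Fit a regularized Hotelling observer on a reduced-scale Rayleigh task and
measure its detection performance on HR versus LR images:

```r
library(iqtask)

clb <- clbParams(meanClusters = 150 / 4, fieldSize = 64L, amplitude = 2.802)
ens <- buildTaskEnsembles("rayleigh", 300,
                          specs = list(clb = clb,
                                       signal = rayleighSignalSpec(7L)),
                          seed = 1)

split <- function(e, idx) {
  list(h0 = images(e)[, , labels2(e) == "H0" & seq_len(nImages(e)) %in% idx],
       h1 = images(e)[, , labels2(e) == "H1" & seq_len(nImages(e)) %in% idx])
}

for (rc in c("hr", "lr")) {
  e <- ens[[rc]]
  tr <- split(e, 1:400); va <- split(e, 401:500)
  model <- fitCovarianceModel(tr$h0, tr$h1, crop = 32L)
  sel <- selectLambda(model, va$h0, va$h1)
  rho <- rhoTemplate(model, sel$lambda)
  print(deLongCI(applyLinear(rho, e[501:600])))
}
```

On this configuration the run prints

```
AUC = 0.9623 (95% CI 0.9319-0.9926, DeLong)
AUC = 0.8936 (95% CI 0.8323-0.9549, DeLong)
```

— the HR images support noticeably better two-point/line discrimination
than their blurred LR counterparts (the regularization parameter selected
on validation data is reported in `rho@lambda`).  The same pattern, swept
over signal lengths, SR depths and observer capacities, is produced by
`runSignalLengthSweep()`, `runDepthSweep()` and `runCapacitySweep()`.

The methods vignette (`vignettes/task-based-sr-assessment.Rmd`) documents
the object models, observer mathematics, calibration anchors and the
reduced problem sizes used throughout.

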