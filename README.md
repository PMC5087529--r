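# ecgmdfx

Multi-domain ECG heartbeat recognition in R: wavelet denoising with an
improved threshold function, nonlinear features from kernel independent
component analysis (KICA), frequency features from wavelet band
statistics reduced by Fisher discriminant analysis, and a one-vs-one
RBF support vector machine tuned by a genetic algorithm. Beats are
classified into five classes: normal (N), left/right bundle branch
block (LBBB, RBBB), premature ventricular contraction (PVC) and atrial
premature beat (APC).

## Method

Each candidate beat is a 250-sample window around the R peak
(100 before, 150 after). The processing chain is:

1. **Denoising** — 5-level `sym6` discrete wavelet transform; detail
   coefficients pass through the improved shrinkage rule

   $$\hat w = u\,w + (1-u)\,\mathrm{sign}(w)(|w|-(1-b)\lambda),\qquad
     u = 1 - e^{-a(|w|-\lambda)^2},\quad |w|\ge\lambda,$$

   with a quartic taper $b\,\mathrm{sign}(w)\,w^4/\lambda^3$ below the
   universal threshold $\lambda = \sigma\sqrt{2\ln N}$,
   $\sigma = \mathrm{median}(|d_1|)/0.6745$. The rule is continuous,
   odd, shrinking and asymptotically unbiased, interpolating between
   soft and hard thresholding.
2. **Nonlinear features** — PCA to 20 dimensions, then KICA: minimize
   the kernel canonical-correlation contrast
   $C(W) = -\tfrac12\log\lambda_M$ over orthogonal unmixings $W$
   ($\lambda_M$ = smallest generalized eigenvalue over centered RBF Gram
   matrices). The estimated base signals $S$ give per-beat features
   $A = XS^{+}$.
3. **Frequency features** — 4-level `db2` transform per beat; max, min,
   mean and standard deviation of the five bands (20 values), reduced
   to 4 Fisher discriminant coordinates.
4. **Classification** — the 24-dimensional feature vector feeds a
   one-vs-one RBF SVM; penalty $C \in (0,100]$ and kernel width
   $\delta \in (0,1000]$ (gamma $=1/(2\delta^2)$) are tuned by a
   binary-coded genetic algorithm with 5-fold cross-validated accuracy
   as fitness.

Performance is reported as per-class sensitivity, specificity and
positive predictivity plus overall accuracy from the 5×5 confusion
matrix. See the vignette (`vignettes/ecg-beat-recognition.Rmd`) for
definitions, parameter rationale and numerical conventions.

## Worked example

```r
library(ecgmdfx)

# 1. simulate labelled beats and contaminate them
beats <- generate_beats(n_per_class = 40, seed = 1)
noisy <- add_noise(beats, noise_spec(white_sigma = 0.05,
                                     powerline_amp = 0.1, seed = 2))

# 2. denoise one beat and quantify the improvement
den <- denoise_signal(noisy$data[1, ])$denoised
cat(sprintf("SNR before %.2f dB, after %.2f dB\n",
            snr(beats$data[1, ], noisy$data[1, ]),
            snr(beats$data[1, ], den)))
#> SNR before 6.06 dB, after 12.36 dB

# 3. run the full pipeline at a reduced desk scale
cfg <- pipeline_config(seed = 1)
cfg$synth$n_per_class <- 40L
cfg$classifier$population <- 4L
cfg$classifier$max_iteration <- 3L
res <- run_pipeline(cfg)
res$metrics
#> Per-class metrics (%):
#>       Se  Sp  Pp
#> N    100 100 100
#> LBBB 100 100 100
#> RBBB 100 100 100
#> PVC  100 100 100
#> APC  100 100 100
#> Average: Se 100.00  Sp 100.00  Pp 100.00
#> Accuracy: 100.00%
res$confusion
#>       predicted
#> true    N LBBB RBBB PVC APC
#>   N    20    0    0   0   0
#>   LBBB  0   20    0   0   0
#>   RBBB  0    0   20   0   0
#>   PVC   0    0    0  20   0
#>   APC   0    0    0   0  20
```

At the full default scale (360 beats per class, 900 train / 900 test)
a run takes about half a minute and typically exceeds 99% test
accuracy on the synthetic task.

Real recordings enter through `read_ecg_record()` (WFDB format 212/16
with binary annotations, or CSV with a sibling `_ann.csv` annotation
file) followed by `segment_beats()`; only beats annotated with the five
retained symbols (`N`, `L`, `R`, `V`, `A`) are kept.

There is also a command-line entry point:

```sh
Rscript inst/cli/ecgmdfx.R run --seed 1 --out results/
Rscript inst/cli/ecgmdfx.R simulate --n-per-class 50 --seed 2 --out beats.csv
```

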