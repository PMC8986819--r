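# relaxstab

Stability analysis of multiexponential decay parameter estimation in one,
two, and three dimensions, in the setting of magnetic resonance
relaxometry.

## The problem

Many experiments produce signals that are sums of decaying exponentials,

S(t) = Σᵢ cᵢ e^(−t/τᵢ),

and the analysis task is to recover the component amplitudes cᵢ and time
constants τᵢ. This inverse problem — a discrete inverse Laplace transform —
is notoriously ill-conditioned: very different parameter sets produce
nearly identical curves (run `lanczos_demo()` for the classic example: two
biexponentials with time-constant pairs (20, 150) and (40, 163) never
differ by more than 2% of the initial signal). In the presence of noise,
fitted parameters are therefore extremely unstable when the time constants
are similar.

Magnetic resonance relaxometry can extend the experiment into a second or
third dimension that is differentially sensitive to the components:
inversion-recovery T1 preparation multiplies each component by
(1 − 2e^(−TI/T1ᵢ)), and diffusion weighting by e^(−b·ADCᵢ). The
two-component models implemented here are

- 1D (CPMG): S(TE) = c₁ e^(−TE/T₂,₁) + c₂ e^(−TE/T₂,₂)
- 2D (IR-CPMG): each term gains a factor (1 − 2e^(−TI/T₁,ᵢ))
- 3D (IR-CPMG + diffusion): each term additionally gains e^(−b·ADCᵢ)

When the components differ in the added (indirect) dimension, the
conditioning of the estimation problem improves dramatically — even on an
equal-measurement-time basis where the 1D experiment is granted a
√n_indirect SNR advantage. The package quantifies this with three tools:

1. **Linearized (Cramér–Rao type) theory.** The estimate covariance is
   Cov(p*) = (BᵀB)⁻¹σ², where B is the analytic Jacobian of the vectorized
   signal evaluated at the true parameters and σ the Gaussian noise SD
   (`eval_jacobian()`, `nonlinear_covariance()`). The 2-norm condition
   number of B measures noise amplification (`condition_number()`,
   `model_condition_number()`).
2. **Monte-Carlo simulation.** Repeated Gaussian-noise realizations are
   fitted by unconstrained Levenberg–Marquardt nonlinear least squares with
   the analytic Jacobian; fitted components are relabeled by ascending T2
   (`run_mc()`, `fit_nlls()`).
3. **A synthetic two-gel phantom experiment.** Repeated 1D CPMG (2048
   echoes, TE 0.4–819.2 ms, SNR ≈ 9000) and 2D IR-CPMG (24 inversion
   times, 15 ms – 2 s, SNR ≈ 2000) acquisitions of a two-component gel
   (c = 0.47/0.53, T2 = 36.3/45.9 ms, T1 = 157/405 ms), fitted per repeat
   with the amplitude sum-to-one constraint (`gel_experiment()`,
   `emulate_experiment()`, `analyze_emulated()`).

Parameter sweeps tie these together (`sweep_1d_coalescence()`,
`sweep_2d_T1separation()`, `sweep_condition_numbers()`, `sweep_3d()`), and
JSON-configured pipeline stages make runs reproducible from a config file
alone (`load_config()`, `run_stage()`, `write_results()`).

## Worked example

Stability of a well-separated biexponential (T2 = 60/150 ms, amplitudes
0.3/0.7) on the standard 64-echo grid at SNR 10⁴:

```r
library(relaxstab)
m <- mc_model(c(0.3, 0.7), T2 = c(60, 150))
g <- acq_grid(TE = seq(8, 512, by = 8))
nonlinear_covariance(m, g, noise_spec(snr = 1e4))
#> Linearized stability report (sigma = 9.261968e-05 )
#>   condition number: 179.2
#>   parameter SDs:
#>        c1        c2      T2_1      T2_2
#> 0.0009702 0.0010210 0.1301000 0.0904600

run_mc(m, g, noise_spec(snr = 1e4), n_realizations = 1000, seed = 1)
#> Monte-Carlo summary: 1000 realizations (0 failed), sigma = 9.26197e-05
#>             c1       c2    T2_1      T2_2
#> mean 0.2999910 0.700010 59.9989 149.99800
#> sd   0.0009794 0.001029  0.1307   0.09131
```

The Monte-Carlo SDs reproduce the linearized prediction to about 1% at
this SNR: for example T2,2 is recoverable with an SD of ≈ 0.09 ms. The
sigma line shows the noise SD implied by SNR 10⁴ against the maximum
noiseless signal.

Conditioning across dimensionality, on matched settings (T2 = 60/45 ms,
T1,1 = 1000 ms, sweeping T1,2):

```r
sweep_condition_numbers(c(500, 1000, 2000))$rows
#>   T1_2  cond_1d   cond_2d
#> 1  500 11377.64  1921.187
#> 2 1000 11377.64 11379.043
#> 3 2000 11377.64  1469.854
```

With equal T1s the indirect dimension adds no discriminating information
and the 2D condition number matches the 1D one to 0.01%; a factor-2 T1
disparity in either direction improves it by roughly an order of
magnitude. Conditioning is unit-dependent; these values use the package
convention (relaxation times in seconds — see the methods vignette).

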