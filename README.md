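# periloc

Quantitative analysis of transcription-driven gene-locus relocation to
the nucleoid periphery in *E. coli*, with a fully synthetic, ground-truth
test bed.

## The problem

When a single chromosomal gene is switched on, the number of RNA
polymerases transcribing it, their positions, and the position of the
locus itself can all be read out of time-lapse single-molecule
fluorescence images. periloc implements the computations this kind of
study needs, for researchers analysing (or simulating) such experiments:

* **Transcription kinetics.** The number of transcribing polymerases per
  cell follows an immigration–death process with on-rate k_on and
  off-rate k_off; its population mean is the single exponential
  a(1 − e^(−bt)) with a = k_on/k_off and b = k_off. Fitting the induction
  curve yields k_on, k_off, the elongation rate L·k_off for gene length
  L, and the elongation and promoter-search times.
* **Intensity quantification.** Focus intensity per cell is measured by
  the ROMIF (the 5×5-pixel window of maximal integrated fluorescence
  inside the cell), background-corrected, baseline-subtracted and
  calibrated to polymerase counts with a single-fluorophore unit.
* **Localization.** Foci are fitted with 2D Gaussians at sub-pixel
  precision and mapped into cell-normalized, first-quadrant-folded
  coordinates (membrane at 0.5 along each axis).
* **Radial-displacement geometry.** A cylindrical Monte Carlo confines
  spots to a nucleoid of normalized radius l, applies the ~70-nm
  localization error, displaces them radially and relates the projected
  mean-|x| shift to a physical displacement in nm, including the inverse
  problem solved under common random numbers.
* **mRNA decay and expression ratios.** Log-linear half-life fits and the
  steady-state correction production ratio = abundance ratio ×
  (half-life ratio), plus two-probe onset ramps for an independent
  elongation-rate measurement and Miller-unit activity.

All inputs can be generated synthetically (`sim_config()`,
`simulate_transcription_counts()`, `render_frames()`, ...) with full
ground truth, so every estimator is testable without any external data.

## Worked example

```r
library(periloc)

# simulate 30,000 cells at k_on = 0.46 /min, k_off = 1.12 /min,
# sampled every 10 s for 6 min after induction
cfg <- sim_config(n_cells = 30000, k_on_per_min = 0.46,
                  k_off_per_min = 1.12, duration_s = 360, seed = 101)
tr  <- simulate_transcription_counts(cfg)
ser <- data.frame(time_s = tr$times_s, count = colMeans(tr$counts))
fit_induction(ser, gene_length_bp = 4500)
#> Transcription kinetic estimate
#>   a (plateau)      : 0.4087 polymerases/cell
#>   k_on             : 0.452 /min  (search time 133 s)
#>   k_off            : 1.107 /min  (elongation time 54 s)
#>   elongation rate  : 83 bp/s over 4500 bp
```

The fitted plateau (~0.41 transcribing polymerases per cell) and rate
constant recover the generating parameters: k_off ≈ 1.11 /min implies a
~54-s elongation time over 4.5 kb, i.e. an elongation rate of ~83 bp/s.

```r
# cylindrical Monte Carlo: 100,000 spots confined to l = 0.35 with 70-nm
# localization error; a 61-nm mean radial step and its inversion
m <- cylinder_model(l = 0.35, scale_nm = 860, loc_error_nm = 70,
                    n_spots = 100000, seed = 2026)
s <- relocation_shift(m, 61)      # projected mean-|x| shift: 0.0413
invert_shift(s, m)$displacement_nm
#> [1] 61.03516
```

The numbered scripts under `analysis/` run the full narrative —
simulate, quantify, localize, fit kinetics, geometry — and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify.R
Rscript analysis/03_localize.R
Rscript analysis/04_kinetics.R
Rscript analysis/05_geometry.R
```

`run_pipeline()` offers the same flow as a single function with a YAML
configuration, a seed registry and a machine-readable summary; see the
methods vignette (`vignettes/transcription-locus-relocation.Rmd`) for
the models, parameter choices and known limitations.

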