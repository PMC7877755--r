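# rhythm4C

Detection of 24-hour rhythms in chromatin contact profiles measured by
circular chromosome conformation capture sequencing (4C-seq).

4C-seq profiles how often a fixed "bait" locus — typically a gene
promoter — contacts every restriction fragment on its chromosome. When
the same bait is assayed in tissue collected around the clock (e.g.
liver sampled every 4 h, Zeitgeber times ZT0–ZT20), the question becomes
statistical: which promoter–enhancer loops oscillate with a 24-h period,
at what phase, and which differ between two conditions (two times of
day, or wild type versus a clock-knockout genotype)? rhythm4C implements
the complete inference chain for users analysing such time-resolved
viewpoint data, plus a seeded synthetic-data generator with planted
ground truth used to validate every stage.

## The model in brief

After sample QC (a library fails if >75% of fragments in the ±1 Mb bait
window have no count) and masking of the bait fragment ±5 flanking
fragments, counts are normalized to cis fractions *c* and
variance-stabilized as *Y* = log10(*c·p* + 1) with *p* = 500. At each
fragment the signal is fitted by locally weighted multilinear
regression:

    S = argmin_{a,b} Σ_{i,j,r} W_ij (Y_ijr − a_i − b_j)²,
    W_ij = w_g,i × w_s,ij

with a Gaussian positional kernel *w_g* (σ = 2500 bp, truncated at 4σ)
and a condition weight *w_s* equal to the fraction of replicates with a
non-zero count; fragment effects *a_i* absorb ligation/digestion bias
and condition effects *b_j* (constrained to sum to zero) carry the
biology. Rhythms are detected from the 24-h Fourier coefficient of the
six *b_j*, *f* = (1/6) Σ_j b_j e^(−i2πt_j/24), standardized by
propagated standard errors and referred to a chi-square distribution
with 2 df; amplitude = 2|f| and peak time = (24/2π)·atan2(−Im f, Re f).
Two-condition contrasts use Z = Δb / √(se₁² + se₂² − 2cov₁₂) with the
covariance from the joint fit. Binned temporal coverage tracks (500-bp
bins, 7-bin running average) get a per-bin 24-h harmonic regression and
an HSV phase colouring (hue = peak time, value from Hill saturations of
amplitude and −log10 p with n = 5, k_a = 0.5, k_p = 4.5).

See `vignettes/rhythmic-4c-analysis.Rmd` for the full account.

## Worked example

Simulate a six-time-point experiment with one oscillating loop planted
30 kb from the bait (enrichment fold 3, relative amplitude 0.5, peaking
at ZT16), then recover it:

```r
library(rhythm4C)

cfg <- sim_config(chrom_length = 1.2e5, bait_position = 6e4,
                  n_replicates = 2, reads_per_sample = 5e4, rng_seed = 11)
pk <- planted_peak(center = 9e4, width = 2000, fold = 3,
                   rel_amplitude = 0.5, peak_time = 16)
sheet <- sample_sheet_grid(times = seq(0, 20, 4), n_replicates = 2)
x <- simulate_experiment(cfg, list(pk), sheet)
x$map
#> fragment_map: 235 fragments on chrS [0, 120000), bait frag_000103

prof <- smooth_profile(x$counts, x$map, x$sheet, condition_by = "time")
res <- rhythm_analysis(prof, alpha = 0.01)
subset(res, rhythmic & abs((start + end) / 2 - 9e4) < 4000,
       select = c(start, end, amplitude, peak_time, chi2, p))
#>  start   end amplitude peak_time chi2        p
#>  85116 87461    0.0327      15.0 16.0 3.41e-04
#>  87461 87595    0.0490      15.3 30.3 2.60e-07
#>  87595 87705    0.0504      15.3 31.9 1.20e-07
#>  87705 87755    0.0514      15.3 32.9 7.24e-08
#>  87755 89386    0.0599      15.3 44.8 1.85e-10
#>  89386 89572    0.0652      15.3 56.0 6.92e-13
#>  89572 91092    0.0657      15.3 59.1 1.50e-13
#>  91092 91645    0.0602      15.4 50.7 9.65e-12
#>  91645 92111    0.0553      15.4 43.6 3.38e-10
#>  92111 92262    0.0519      15.5 38.6 4.11e-09
#>  92262 93523    0.0428      15.6 28.1 7.84e-07
#>  93523 94116    0.0299      15.8 15.5 4.25e-04
```

A contiguous block of fragments centred on the planted locus (~90 kb) is
called rhythmic at p < 0.01, with estimated peak times of ZT15.0–15.8 —
within about an hour of the planted ZT16. `amplitude` is on the
variance-stabilized log10 contact scale (peak-to-mean of the fitted
24-h cosine); `chi2`/`p` test the null of no 24-h rhythm.

The same pipeline is available as one call, `run_rhythm()`, which also
writes smoothed per-time bedGraph tracks, a BED9 peak-time colour track
and a −log10(p) bedGraph; `run_compare()` produces per-fragment Z and
p tracks for a two-condition contrast; `run_track_rhythm()` colours
binned temporal coverage tracks by phase. A thin command-line wrapper
over these functions lives in `inst/scripts/rhythm4c.R`.

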