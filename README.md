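# cenepi

Susceptibility distortion correction for **centric single-shot EPI from a
single k-space** — no reversed-polarity companion scan, no separate field
map.

## The problem and who this is for

EPI's low phase-encode (PE) bandwidth turns B0 inhomogeneity into
geometric distortion: a voxel with off-resonance *f* (Hz) is displaced by
*d = f · T_ro* voxels along PE, where *T_ro* is the total readout time,
with the sign set by the PE blip polarity.  Reversed-polarity ("topup")
field mapping estimates *f* from two images distorted in opposite
directions — normally two acquisitions.

In pseudo-centric single-shot EPI the trajectory fills k-space from the
centre outward and the two halves of the PE axis carry **opposite blip
polarities inside one shot**.  This package, aimed at MR-physics and
neuroimaging methods researchers, extracts the two oppositely distorted
inputs from that single k-space and estimates the field map from them:

1. split the k-space at the DC row, sharing the blip-free centre line
   between both halves;
2. complete each partial half by POCS with an adaptive smoothed-phase
   constraint;
3. iterate automatic brain masking (Otsu + triangular dilation, then
   field-driven mask warping) with uniformity correction (division by a
   masked, max-filled lowpass with constant or location-dependent width)
   to equalise the two inputs — three passes;
4. estimate the displacement field *d(y)* by a reversed-polarity
   registration minimising
   `sum( up(y+d)(1+d') - down(y-d)(1-d') )^2 + lambda * ||Laplacian(d)||^2`
   with multi-resolution Levenberg–Marquardt;
5. correct the distortion by opposite-direction unwarping of the two
   complex halves, combined by complex averaging or per-column
   least-squares restoration.

A synthetic study generator (digital brain phantom, smooth B0 field,
centric k-space assembly with partial Fourier, double-echo GRE reference
pair, toy pCASL perfusion series) makes every stage testable without
scanner data, and the evaluation suite implements Dice, Hausdorff,
perfusion SNR/tSNR, field-map correlation, and CBF quantification
(`CBF = (dM/M0) * 6000*lambda*exp(PLD/T1b) / (2*alpha*T1b*(1-exp(-tau/T1b)))`).

## Worked example

```r
library(cenepi)

params  <- acq_params(c(64, 64))                   # pf 0.75, T_ro 32 ms
phantom <- make_phantom(c(64, 64), seed = 1)
truth   <- make_field_map(c(64, 64), amplitude_hz = 90, seed = 101)
k       <- simulate_cenepi_kspace(phantom, truth, params)
k
#> k-space: 64 x 64 (centric_1shot), 48/64 PE lines acquired

fit <- estimate_field_cenepi(k)                    # the whole chain
fit$field
#> B0 field map (topup): 64 x 64, range [-9.474, 93.52] Hz

mask <- otsu_mask(Mod(phantom))
fieldmap_correlation(fit$field, truth, mask)       # 0.952
fieldmap_rmse_voxels(fit$field, truth, mask, params)  # 0.106 voxels

corrected <- correct_cenepi(k, fit$field)          # least-squares restoration
distorted <- Mod(ifftc(k$data))
dice(otsu_mask(distorted), mask)                   # 0.866
dice(otsu_mask(corrected$magnitude), mask)         # 1
```

The estimated field correlates at r = 0.95 with the simulated truth
(residual ~0.1 voxel RMSE inside the brain), and unwarping with it
restores the brain outline to full overlap with the undistorted phantom,
up from Dice 0.87 for the raw distorted reconstruction.

A thin command-line front end over the same functions ships in
`inst/cli/cenepi.R` (`simulate | estimate | correct | evaluate | ablate |
demo`).  The methods vignette
(`vignettes/centric-epi-distortion.Rmd`) documents the model, the
parameter choices, and the simulator's limitations.

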