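# nsctfusion

Multimodal medical image fusion in R: combine two co-registered images of
the same anatomy — CT + MRI, MR-T1 + MR-T2, or an anatomical scan + a
pseudo-color functional image (SPECT/PET) — into a single image that keeps
the salient detail of both. The package is for researchers evaluating
multiscale fusion rules and for anyone needing a reproducible, scriptable
fusion pipeline with a built-in quality-metric suite and synthetic test
data.

## Method

Each source image is decomposed with the **nonsubsampled contourlet
transform (NSCT)**: an undecimated pyramid filter bank splits the image
into scales, and undecimated directional fan filter banks split each
bandpass into `2^d` orientation subbands. Nothing is ever downsampled —
coarser scales and finer orientations are reached by *à trous* (zero-
inserted) upsampling of the filters, so every subband keeps the source
size and the transform is shift-invariant. Each two-channel bank satisfies
the Bezout perfect-reconstruction identity

    h0 * g0 + h1 * g1 = δ,

which makes the inverse transform exact (the identity is verified at load
time and survives every filter upsampling used in the tree).

Subband pairs are fused by a **pulse-coupled neural network (PCNN)**: one
spiking neuron per pixel with feeding channel `F`, linking channel `L`,
internal activity `U = F(1 + βL)`, and an exponentially decaying dynamic
threshold `H` recharged by `V_h` at each fire. Running `N = 100` iterations
on each band's normalized stimulus yields a firing-count map `T`; the
fused band copies, per pixel, the coefficient of the source whose neuron
fired more (`T_A > T_B` selects A, otherwise B — the rule selects, never
blends). The fused pyramid is inverted to produce the result. Defaults:
4 pyramid levels, `pyrexc`/`vk` filters, directional depths (3, 3, 2, 2),
`β = 3`, `α_L = 1`, `V_L = 1.8`, `α_θ = 0.2`, `V_θ = 20`, `N = 100`.

A seven-metric evaluation suite accompanies the pipeline: entropy (EN),
mutual information (MI), edge-preservation Q^AB/F, PSNR, standard
deviation (SD), average gradient (AG), and the nonlinear correlation
information entropy (Q_ncie) — each validated in the tests against an
independent brute-force implementation.

## Worked example

Synthetic complementary-modality phantoms (shared "skull" and interior,
structures visible in only one modality each) exercise the whole pipeline
without clinical data:

```r
library(nsctfusion)

ph <- make_phantom_pair(phantom_spec(size = 256, seed = 1))
fused <- fuse_images(ph$A, ph$B)        # reference configuration
fusion_report(ph$A, ph$B, fused)
```

```
Fusion quality report
  EN       5.3360 bits
  MI       4.0509 bits (AF 1.5522, BF 2.4987)
  QABF     0.7881
  PSNR    22.4952 dB
  SD      74.1705
  AG       7.4604
  QNCIE    0.9737
```

EN says the fused image carries ~5.3 bits/pixel of intensity information;
MI is the total information it shares with the two sources; Q^AB/F ≈ 0.79
means most source edge strength/orientation survives fusion; SD and AG are
contrast and sharpness on the 8-bit scale. Averaging the sources instead
(`fusion_config(rule = "average")`) drops SD by ~4.4 intensity units —
the firing-count selection keeps contrast that blending halves.

The command-line interface wraps the same functions:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "nsctfuse.R", package = "nsctfusion"))')
Rscript $cli phantom -o /tmp/ph --size 256 --seed 1
Rscript $cli fuse -a /tmp/ph_A.png -b /tmp/ph_B.png -o /tmp/fused.png --report /tmp/report.csv
Rscript $cli metrics -a /tmp/ph_A.png -b /tmp/ph_B.png -f /tmp/fused.png -o /tmp/metrics.csv
```

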