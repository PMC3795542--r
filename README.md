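# rmpenhance

Contrast enhancement of low-contrast greyscale biomedical images by
**rotational morphological processing (RMP)**, with quantitative
evaluation by the contrast improvement ratio (CIR).

Subtle structures — mass lesions in mammograms, nodules in chest
radiographs — often differ from their surroundings by a few grey levels on
a spatially uneven background. `rmpenhance` enhances such targets
selectively instead of amplifying the whole image:

1. **Extraction.** White and black top-hat transforms
   (`WTH = f − γ_B(f)`, `BTH = φ_B(f) − f`) pull bright and dark
   structures smaller than the structuring element `B` off the background,
   independently of the local background level. To avoid the orientation
   artefacts of a fixed SE, the opening `γ` and closing `φ` are computed
   rotationally: the image is rotated through `N` directions spanning a
   half circle (`θ_i = πi/N`), filtered, derotated, and combined pixelwise
   by max (opening) or min (closing). `N = 8` for disc/square elements,
   36 for lines.
2. **Greyscale modification.** Each top-hat image is histogram-equalized
   and then linearly stretched to the display range (`ν`), so that even
   faint extracted structures contribute at full contrast.
3. **Recombination.** The enhanced image is
   `λ = f + ν(WTH′) − ν(BTH′)`, clipped to the display range.

Enhancement strength is scored by the CIR: with local contrast
`C = |p − a|/(p + a)` (`p`, `a` = mean intensities of an 11×11 centre
window and the surrounding 41×41 annulus),
`CIR = Σ(C − C̃)² / ΣC²` over the evaluation region.

The package also ships the two standard baselines used for comparison —
multiscale retinex (MSR, scales 5/15/25, weights 1/3) and CLAHE (9×9-pixel
blocks) — a synthetic low-contrast phantom generator so the whole pipeline
is testable without any external data, and lossless greyscale I/O
(PNG, TIFF, PGM).

## Worked example

```r
library(rmpenhance)

# a 218 x 238 phantom: six low-contrast blobs on an uneven background
ph <- generate_phantom(phantom_spec(seed = 1))
f <- ph$image
f
#> grey_image: 218 x 238 pixels, display range [0, 255], values [94.3215, 164.609]

# full enhancement: disc SE of diameter 31, 8 rotation directions
enh <- enhance_lambda(f, enhance_config(se_shape = "disc", se_size = 31))

# contrast improvement, proposed method vs the two baselines
cfg <- cir_config(rc = 11, rn = 41)
cir(f, enh, cfg)
#> [1] 35.21457
cir(f, msr(f), cfg)
#> [1] 16.45117
cir(f, clahe(f, block = 9), cfg)
#> [1] 0.1001472
```

The rotational top-hat operator raises the local target/surround contrast
far more than either baseline (a larger CIR means a larger change in
windowed local contrast relative to the original): the blobs are pushed
towards the top of the display range while the background ramp is left in
place. CLAHE's CIR is small because its per-tile equalization mostly
re-spreads the background; MSR enhances globally and lands in between.

A thin command-line front end over the same functions is installed with
the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/rmpenhance.R", package = "rmpenhance"))')
Rscript "$CLI" synth --out phantom.png --mask mask.png --seed 7
Rscript "$CLI" enhance phantom.png --out enhanced.png --se disc --size 31
Rscript "$CLI" cir phantom.png enhanced.png --rc 11 --rn 41
```

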