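# pialtof

Quantitative tools for time-of-flight (TOF) MR angiography of mesoscopic
pial arteries — cortical surface vessels of 50–300 µm, at or below the
voxel size of high-resolution 7 T protocols.

TOF contrast arises because inflowing blood has seen few RF pulses and is
brighter than RF-saturated static tissue. For a spoiled gradient echo the
tissue steady state is the Ernst equation

    Mz_tissue = M0 (1 − E1) / (1 − E1 cosθ),   E1 = exp(−TR/T1)

and blood that entered the slab fully relaxed carries, just before its
n-th pulse (n = t_delivery / TR),

    Mz_blood(n) = Mz_blood_ss + (E1b cosθ)^(n−1) (M0 − Mz_blood_ss).

The flow-related enhancement FRE = (Mz_blood − Mz_tissue)/Mz_tissue is the
contrast of interest. When the vessel is a cylinder of diameter d centred
in an isotropic voxel of edge l, the measurable contrast factorizes as
FRE_PV = V(d, l) · FRE with V the blood volume fraction — constant while
the voxel is inside the vessel (l ≤ d/√2), falling as πd²/4l² once the
vessel is smaller than the voxel. Voxel size, not blood delivery time, is
what makes or breaks mesoscopic vessel visibility. The package also
models the velocity-dependent vessel displacement Δy = −v_y (TE − t_pe),
generates fully labelled synthetic 3D angiogram phantoms (branching
trees, two echoes, Rician noise, bias fields), segments vessels by
thresholding plus region growing with skeleton-length quantification, and
removes pial veins by their short two-echo T2\*.

For whom: researchers planning or analysing high-resolution TOF
angiography protocols, and anyone needing a self-contained, ground-truthed
test bed for mesoscopic vessel segmentation.

## Worked example

```r
library(pialtof)
acq <- acquisition_params(tr_ms = 20, flip_deg = 18)   # TE 7.05/14 ms
tis <- tissue_params()                                 # 7 T defaults

ernst_angle_deg(20, 1950)
#> Ernst angle: 8.2 deg
for (d in c(100, 300, 500, 1000))
  cat(d, "ms ->", optimal_flip_deg(acq, tis, d), "deg\n")
#> delivery  100 ms -> optimal flip 37 deg, FRE 3.726
#> delivery  300 ms -> optimal flip 21 deg, FRE 2.024
#> delivery  500 ms -> optimal flip 16 deg, FRE 1.087
#> delivery 1000 ms -> optimal flip 11 deg, FRE 0.198
```

Longer delivery times flatten the optimum toward the Ernst angle. The
partial-volume model quantifies what resolution buys for a 300 µm artery:

```r
for (v in c(0.8, 0.5, 0.4))
  fre_gain_percent(acq, tis, flow_params(300), 0.3, v, 0.3)
#> voxel 0.8 -> 0.3 mm: FRE gain 611%
#> voxel 0.5 -> 0.3 mm: FRE gain 178%
#> voxel 0.4 -> 0.3 mm: FRE gain 78%
```

End to end on synthetic data — phantom, segmentation, vein removal:

```r
ph  <- build_phantom(phantom_config(), seed = 1)
ts  <- steady_state_mz(acq, tis, 1950) * exp(-acq$te_ms[1] / tis$t2s_tissue_ms)
e1  <- add_rician_noise(ph$clean[[1]], ts / 15, seed = 101)  # SNR 15
e2  <- add_rician_noise(ph$clean[[2]], ts / 15, seed = 201)
seg <- segment_vessels(e1, segmentation_config(ts * 1.7, ts * 1.5, 10))
seg
#> segmentation_result: 487 vessel voxels in 3 components; skeleton 29.4 mm
dice_coefficient(seg$vessel_mask, ph$maps$mask$data > 0)
#> Dice vs ground truth: 0.876
remove_veins(seg, t2star_map(e1, e2, diff(acq$te_ms)), 19)$decision
#>   label voxels p90_t2s_ms venous
#> 1     1    150   46.69874  FALSE
#> 2     2    140   40.80023  FALSE
#> 3     3    197   16.44174   TRUE
```

The two arterial trees (T2\* percentile near tissue) are retained; the
vein component (p90 T2\* 16.4 ms < 19 ms) is removed.

A command-line interface covers the same ground
(`fre`, `pvfre`, `shift`, `simulate`, `segment`, `veinfilter`):

```sh
Rscript -e 'pialtof::run_cli()' simulate --seed 1 --out-prefix /tmp/ph
Rscript -e 'pialtof::run_cli()' segment --in /tmp/ph_echo1.nii \
    --primary 0.24 --secondary 0.21 --out-prefix /tmp/seg
```

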