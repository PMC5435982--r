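# cordscan

Atlas-free segmentation of the cervical spinal cord on midsagittal
T2-weighted MR images.

## Why

Assessing cervical spondylotic myelopathy — the commonest adult cord
disorder — means measuring cord compression on the midsagittal
T2-weighted slice. Atlas- and registration-based cord segmenters falter
exactly in the stenotic segments where those measurements matter, because
the bright CSF rim that drives local contrast is effaced. `cordscan`
takes the opposite route: no atlas, no training data. Anatomical
knowledge enters as hard constraints, and every structure is recovered as
the optimal path of a banded dynamic program (DP).

## Method in brief

Given a sagittal series \(I^1 \ldots I^{13}\) (320 × 320 px,
0.6875 mm/px):

1. **Midsagittal selection.** \(k_{\mathrm{MSP}} = \arg\min_k \frac1m \sum_j
   D(I^j, I^{2k-j})\) over integer and half-integer \(k\) with at least
   four mirror pairs, where \(D\) is the population SD of the pixelwise
   gray-level differences.
2. **Intensity classes.** A ≤4-component Gaussian mixture fitted to the
   gray-level histogram by greedily grown EM labels every gray level
   air / hypo / iso / hyperintense relative to the cord; the upper
   isointense threshold is guarded against windowing artifacts
   (kept in [64, 128], else recomputed as \(\mu_{iso} + 2\sigma_{iso}\)
   clamped to [127, 159], or reset to 128).
3. **Structure chain by DP.** Eight fitness fields drive a shared
   engine — paths move ≤1 column per row, maximize cumulative fitness
   inside per-row bands: coarse cord \(B^1\) (isointense run length),
   refined cord \(B^2\) (local homogeneity, ±40 px of \(B^1\)), PLL
   \(B^3\) and ligamentum flavum \(B^4\) (darkness \((256-I)^2\), 30 px
   on either side of the cord), ALL \(B^5\) (darkness backed by 16
   marrow pixels), truncated ALL \(B^6\) (darkness + 65536 × sub-threshold
   count over 20 posterior pixels).
4. **Vertebrae and disks.** Column pixels between \(B^6\) and \(B^3\)
   thresholded at the bimodal-histogram midpoint \(t_{VB}\), 4-connected
   region growing (> 150 px = vertebral body, > 100 px void = disk); C2
   recognised as the tall region (~1.5× a lower body) with > 5 bodies
   below and the next centre within 70 px; canal extent from the C2
   region and a T1 extent extrapolated from the C3/C7 centres. Manual
   canal override replaces a failed labeling.
5. **Cord edges.** A median cord profile \(c_z\) (11 × 31 window around
   \(B^2\)) feeds compound fitnesses \(f^7/f^8\) (similarity to \(c_z\),
   homogeneity, edge contrast, non-cord penalty); DP inside
   \([B^3{+}1, B^2]\) and \([B^2, B^4{-}1]\) yields the anterior and
   posterior edges \(B^7, B^8\). The cord is everything between them.

Agreement metrics: Jaccard \(J = TP/(TP+FP+FN)\) over the canal rows,
Dice \(D = 2J/(1+J)\), symmetric Hausdorff distance between edge curves.

A seeded phantom generator builds synthetic stacks with full ground truth
(masks, curves, labels, planted midsagittal position, cord signal drift,
optional stenosis) for testing and calibration.

## Worked example

```r
library(cordscan)

ph  <- generate_phantom(phantom_spec(seed = 1))   # 13-slice synthetic series
res <- run_pipeline(ph$series, pipeline_config(seed = 1))

print(res$msp)
#> <msp_candidate> k_MSP = 7 (slices 7), score = 4.176 over 6 pairs
print(res$fit)
#> <gmm_fit>
#>   air   mean    5.1  sd   2.9  weight 0.518
#>   hypo  mean   45.6  sd   9.1  weight 0.382
#>   iso   mean   80.2  sd   3.8  weight 0.060
#>   hyper mean  175.3  sd   3.2  weight 0.040
#>   iso range [72, 104]
print(res$spine)
#> <labeled_spine> C2 C3 C4 C5 C6 C7 T1 T2; canal rows 30..209
print(res)
#> <cordscan_result> slice 7, canal rows 30..209, cord area 2160 px

agreement_report(res$segmentation$mask, ph$truth$cord_mask,
  auto_curves = list(anterior = res$segmentation$B7,
                     posterior = res$segmentation$B8),
  ref_curves  = list(anterior = ph$truth$cord_anterior,
                     posterior = ph$truth$cord_posterior),
  canal = ph$truth$canal)
#> <agreement_report> J = 0.984, D = 0.992, Hausdorff ant/post = 0.00/0.00 px (0.00/0.00 mm)
```

Reading the output: slice 7 minimised the pairwise asymmetry (the planted
centre); the mixture put the cord peak at gray 80 with iso range
[72, 104], no threshold repair needed; all eight vertebral bodies were
labeled and the canal extent (rows 30–209) came within two rows of the
planted truth; the segmented cord overlaps the ground truth at
Jaccard 0.984 with both edges exactly on the planted interfaces.

A thin CLI wraps the same functions
(`Rscript inst/cli/cordscan.R segment --input DIR --out DIR`, plus
`phantom`, `select`, `classify`, `evaluate` subcommands).

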