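# marginpin

Mechanistic models and quantification tools for auxin–PIN–CUC patterning
on the leaf margin.

## The scientific problem

Leaf serrations and leaflets initiate where auxin accumulates locally
along the margin. The direction of auxin flow is set cell by cell by the
polar membrane localization of the PIN1 efflux carrier, and boundary-domain
CUC transcription factors mark where outgrowths may form — acting through
WAG kinases that phosphorylate PIN1. `marginpin` is for developmental
biologists and modelers who want to explore, on a small margin cell grid,
whether patterned PIN phosphorylation is sufficient to repolarize the
margin and create a new auxin maximum, and to quantify cell-resolution
polarity data and leaf-shape complexity with the same conventions.

The core model: each cell carries auxin `a_i` and a PIN allocation
`P_ij` per membrane (summing to `P_tot`), with

    da_i/dt = sigma_src 1_src(i) + sigma_bg - mu_a a_i
              + D sum_j (a_j - a_i) - sum_j J_ij,
    J_ij    = T (eff_i P_ij a_i - eff_j P_ji a_j),

and PIN relaxing toward rule-dependent targets. A static CUC pattern sets
the phosphorylated PIN fraction `phi = cuc^h / (K_c^h + cuc^h)`, which
either switches the allocation rule from up-the-gradient to with-the-flux
(**PMM**) or multiplies transport efficiency by `epsilon` (**EMM**); a
UTG-only control has no CUC effect. The package also implements the
cell-table quantifications used around such models (membrane-segment
polarity calls, reversal-position estimation, polarity frequency
contingency analysis with chi-squared, point-biserial correlation,
per-sample expression regression, ROI selection), leaf-silhouette
morphometrics including the Normalized Difference Margin Complexity

    NDMC = (P_contour - P_hull) / (P_contour + P_hull),

and seeded synthetic-data generators with planted ground truth so every
quantification stage is testable without microscopy data.

## A worked example

```r
library(marginpin)

tpl <- make_template("wt")                     # 20 x 5 margin, CUC band, tip source
sim <- run_to_steady_state(tpl, margin_params("pmm"))
summary(sim)
#> Margin patterning simulation (pmm, template 'wt')
#>   t = 740.6; converged: TRUE; residual max|da/dt| = 9.99e-07
#>   auxin range: [0.0263, 7.91]; clamps: 0
#>   polarity classes: apical=17, basal=40, lateral=40, bipolar=3, nonpolar=0
#>   convergences (row, col): (1,3) (2,3) (19,3) (20,3)
#>   emergent auxin maxima on middle column: row 19 (0.406 a.u.)
```

Reading this: the convergence cluster at rows 1–2 of the middle column is
the distal source maximum; the 40 basal cells include the CUC band, whose
with-the-flux switch canalizes auxin proximally; and the second
convergence cluster at rows 19–20 with the auxin maximum at row 19
(0.406 a.u.) is the emergent auxin site at the base of the CUC domain —
the position where a new outgrowth would initiate. Running the same
parameters on `make_template("cuc_mutant")` yields a monotone profile and
no emergent structure.

Quantification works the same way on any cell table with the documented
columns; on a synthetic table with a reversal planted at 30 µm and a
point-biserial correlation of 0.6 planted between the CUC channel and
basal polarity:

```r
g <- gen_cell_table(synth_cells_spec(seed = 42))
reversal_position(g$table)
#> [1] 33.34808
point_biserial(g$table$ch_cuc, g$truth$basal)
#> t = 6.6047, df = 58, p-value = 1.348e-08
#>      r_pb
#> 0.6551769

ndmc(leaf_silhouette(cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))))
#> [1] 0.03800301
```

A thin command-line wrapper over the same functions is included at
`inst/scripts/marginpin.R` (subcommands `simulate`, `ensemble`,
`quantify`, `morphometry`, `synth`).

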