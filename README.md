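# hicbound

Spectral detection and differential analysis of TAD boundaries in Hi-C
contact matrices.

Topologically associated domains (TADs) partition chromosomes into
self-interacting blocks, and their boundaries shift, appear, merge and
split across cell types, conditions and time. `hicbound` is for
researchers who have chromosome-specific Hi-C contact matrices from two or
more conditions and want a bin-by-bin, statistically grounded answer to
*which boundaries changed, and how*.

## The method

A contact matrix `C` is treated as the weighted adjacency matrix of a
contact graph. From the normalized form
`L = D^(-1/2) C D^(-1/2)`, `D = diag(1ᵀC)`, the two leading eigenvectors
(by absolute eigenvalue) are computed in windows sliding along the
diagonal (radius 15 bins by default). After projecting the eigenvector
rows onto the unit circle, the **eigenvector gap**
`D_i = ‖Z_i − Z_{i−1}‖ ∈ [0, 2]` spikes at domain junctions. Gaps are
log-normal, so the **boundary score**

    B_i = (ln D_i − μ) / σ  ~  N(0, 1)

is a Z-score whose magnitude reads as boundary strength; `B_i ≥ 3` calls a
boundary. Two matrices `P` and `R` are compared through the
**differential boundary score**

    DB_i = [(ln D_P,i − ln D_R,i) − (μ_P − μ_R)] / √(σ_P² + σ_R²)  ~  N(0, 1),

and bins with `|DB| ≥ 2` are classified as Complex, Split, Merge, Shifted
or StrengthChange boundary changes. Replicates aggregate by the median
(consensus) score; ordered time points yield six temporal patterns
(highly common, early/late appearing, early/late disappearing, dynamic);
permutation tests quantify colocalization of boundary sets with
annotation tracks (CTCF, RAD21, ...). A synthetic generator plants domain
structure with power-law decay, per-boundary insulation, Poisson noise
and sparsity for validation.

## Worked example

Simulate a chromosome with nine planted boundaries, delete the one at bin
75 in the matrix of interest, and ask what changed:

```r
library(hicbound)

base <- simulation_spec(n = 150, boundaries = seq(15, 135, 15), beta = 0.15)
pr   <- apply_change(change_scenario(base, "merge", boundary = 75))
cmp  <- tad_compare(pr$P, pr$R)
summary(cmp)
#> Differential boundary analysis (chrS): 150 retained bins
#>   boundaries in at least one matrix: 9
#>   differential boundaries: 1 (11.1% of boundaries)
#>
#>         Complex           Split           Merge         Shifted  StrengthChange
#>               0               0               1               0               0
#> NonDifferential     NonBoundary
#>               8             141

cmp$table[cmp$table$bin %in% c(60, 75, 90),
          c("start", "end", "score_P", "score_R", "diff_score", "category")]
#>   start     end score_P score_R diff_score        category
#> 2360000 2400000  3.3147   3.159     0.0255 NonDifferential
#> 2960000 3000000 -0.1296   3.159    -2.3646           Merge
#> 3560000 3600000  3.3052   3.159     0.0189 NonDifferential
```

The deleted boundary is recovered at exactly its bin: it scores 3.16 in
the reference but −0.13 in the matrix of interest, the differential score
−2.36 crosses the threshold, and because its flanking boundaries are
shared and unchanged the bin is labelled `Merge` — the domain on its left
and right fused in `P`. The eight untouched boundaries stay
`NonDifferential` with `|DB| < 0.1`.

`write_results(cmp$table, "changes.bed")` saves the table as BED;
`plot(cmp)` draws both score profiles and the differential track.

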