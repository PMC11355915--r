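# revasym

Topological quantification of left–right asymmetry in paired greyscale
images, with the downstream population stages needed to relate such
asymmetry to other bilateral traits, genomic homozygosity and survival.

## The problem and the statistic

Bilateral organs such as the retina should be mirror images of each other;
the extent to which they are not (fluctuating asymmetry) is of interest in
developmental biology and epidemiology. Comparing two fundus photographs
pixel by pixel is fragile — small misalignments swamp the signal — so
`revasym` compares their *topology* instead.

A greyscale image is a field `z(i, j)` on an `N × M` pixel lattice. Its
sublevel-set filtration includes every pixel with `z ≤ l` as the threshold
`l` grows, producing a nested family of cubical complexes. Cubical
persistent homology tracks when connected components (dimension 0) and
loops (dimension 1) are born and die along this family, giving a
persistence diagram `PDk = {(bᵢ, dᵢ)}` per dimension. Each diagram is
rotated and rescaled to mean-age/lifetime pairs `mᵢ = (bᵢ + dᵢ)/2`,
`lᵢ = dᵢ − bᵢ`, and summarised by the accumulative persistence function

```
APFk(m) = Σ lᵢ · 1(mᵢ ≤ m),
```

a non-decreasing step function. The asymmetry of a left/right pair is the
signed supremum difference

```
ReVA.k = APFk_R(m_max) − APFk_L(m_max),   m_max = argmax_m |APFk_R(m) − APFk_L(m)|,
```

computed after a unit (min–max) or z (standardising) intensity transform.
Identical images give exactly 0; the sign records which side carries more
accumulated persistence. The implementation pairs a union-find sweep for
dimension 0 with a dual-graph union-find for dimension 1 (exact on planar
grids, where every square kills a loop), and is validated against an
independent flood-fill/Euler-characteristic oracle.

Downstream, the package mirrors a full bilateral-asymmetry study: signed
residuals `left − right` for twenty clinical trait pairs, absolute
residuals max-normalised to `[0, 1]` per trait, per-body-part group means
(retina, ophthalmic, ankle–brachial pressure, audiometry), top-decile
flags, the four-set Venn overlap of multi-asymmetry cases, Pearson
correlation tables against runs-of-homozygosity (ROH) summaries, and Cox
proportional-hazards models with the study's reference levels. A
synthetic-data module generates everything the pipeline consumes: paired
vessel-tree images with a controllable asymmetry level `a` (`a = 0` gives
bit-identical fields), and cohort tables in which a latent per-subject
propensity drives trait asymmetries, ROH counts (closed-form calibrated to
a target correlation) and censored survival times.

## Worked example

```r
library(revasym)

# a left/right pair with injected asymmetry a = 0.3
pr <- make_pair(c(64, 64), a = 0.3, seed = 11)
compute_reva_pair(pr$left, pr$right)
#> # A tibble: 1 × 6
#>   reva0  reva1 m0_max m1_max transform normalized
#>   <dbl>  <dbl>  <dbl>  <dbl> <chr>     <lgl>
#> 1 -2.87 -0.245  0.466  0.824 unit      FALSE
```

`reva0 = -2.87` says the left image accumulates 2.87 more units of
component persistence than the right by mean age `0.466` (on the unit
intensity scale) — the perturbed vasculature differs most in its component
structure there; the loop-level difference (`reva1`) is smaller. For an
identical pair (`a = 0`) both values are exactly 0.

```r
coh <- simulate_cohort(cohort_config(n_subjects = 2000, seed = 11))
ch  <- asymmetry_chain(coh)
ch$overlap
#> <reva_overlap> 2000 subjects (63 with an unclassifiable group)
#>   multiple asymmetries (>= 2 flags): 186 (9.3%)
#>   n_flags     n
#> 1       0  1476
#> 2       1   338
#> 3       2   111
#> 4       3    66
#> 5       4     9
```

With the default shared-propensity effect, 9.3% of subjects sit in the top
decile of two or more body parts — above the 5.2% expected if the four
groups were independent, because one latent propensity drives them all.
Setting `shared_effect = 0` recovers the independent regime.

```r
correlation_matrix(coh, c("roh_count", "roh_total_kb"), against = "u")
#> # A tibble: 2 × 4
#>   trait          r_u      p_u   n_u
#> 1 roh_count    0.243 2.45e-28  2000
#> 2 roh_total_kb 0.215 2.64e-22  2000
```

The generator's closed-form calibration targets a 0.229 correlation
between the latent propensity `u` and the ROH segment count; the fitted
`r = 0.243` at `n = 2000` is within Monte-Carlo error. `run_pipeline()`
composes all stages end to end and writes every table, the resolved YAML
config and a run log to an output directory, byte-reproducibly for a fixed
seed.

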