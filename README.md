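# phagekit

Analytics for phage susceptibility testing (PST) of bacterial clinical
isolates — for microbiology labs and phage-therapy groups who need to
turn plate-reader growth curves and plaque-assay call tables into
quantitative, reproducible decisions: which phages kill which strains,
how virulent each phage is, how well the two standard assays agree,
which strains are multidrug-resistant, and which phage cocktail covers
the most patients.

## What it computes

* **Planktonic killing assay (PKA).** For each phage–strain pair, the
  normalized area under the OD600 curve over 24 h,
  `AUC_norm = AUC(infected) / AUC(control)`, with the strict lysis call
  `AUC_norm < 0.8`, and the time of lysis (first sampled time the
  expanding-window ratio crosses the cutoff).
* **Virulence indices.** From an MOI ladder (1 … 1e-4): the local index
  `vi = 1 − AUC_infected/AUC_control` integrated to the control's
  stationary-phase onset, and the global index `vp = Ap / Amax`, the
  normalized area under the vi-versus-log10(MOI) curve (0 = no killing,
  1 = instantaneous complete killing at every MOI).
* **Host range & concordance.** Per-phage coverage summaries over
  DPA/PKA call matrices and the six-group pairwise concordance
  classification (concordant = both-lysis or both-no-lysis).
* **MRGN classes.** EUCAST-style zone-diameter interpretation (S/I/R)
  and German RKI 3MRGN/4MRGN multidrug-resistance classes from the four
  lead substances.
* **Therapeutic ranking.** A 3–10-point rubric over DPA coverage, PKA
  coverage, vp and genomic safety.
* **Cocktail design.** Maximum-coverage optimization of k-phage
  cocktails, exhaustive (with full co-optimal enumeration) or greedy.
* **Synthetic data.** Seed-deterministic generators for growth curves
  (logistic growth, MOI-dependent lysis, regrowth, noise), host-range
  matrices (with plantable unique optima) and antibiograms, so the
  whole pipeline is testable without laboratory data.

All user-facing functions take data frames (or light S3 containers
built from them) and return tibbles, so results chain with the pipe;
fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a small plate with known ground truth, run the PKA pipeline,
and design a cocktail:

```r
library(phagekit)

truth <- tibble::tibble(
  phage  = rep(c("PA-myo1", "PA-podo2"), each = 3),
  strain = rep(c("BW01", "BW02", "BW03"), 2),
  truth  = c("lysis", "lysis", "no_lysis", "no_lysis", "lysis", "lysis"))

plate <- simulate_plate(truth, seed = 42, replicates = 3)
res <- pka_analyse(plate)
res
#> # A tibble: 6 × 9
#>   phage    strain   moi auc_with auc_without auc_norm call     time_of_lysis
#>   <chr>    <chr>  <dbl>    <dbl>       <dbl>    <dbl> <chr>            <dbl>
#> 1 PA-myo1  BW01     0.1     1.90        23.8   0.0796 lysis             3.75
#> 2 PA-myo1  BW02     0.1     1.90        23.8   0.0797 lysis             3.75
#> 3 PA-myo1  BW03     0.1    23.8         23.8   1.00   no_lysis         NA
#> 4 PA-podo2 BW01     0.1    23.8         23.8   1.000  no_lysis         NA
#> 5 PA-podo2 BW02     0.1     1.88        23.8   0.0789 lysis             3.75
#> 6 PA-podo2 BW03     0.1     1.89        23.8   0.0792 lysis             3.75
```

Every simulated lysis pair comes back with `AUC_norm` far below the 0.8
cutoff and a ~3.75 h time of lysis; the null pairs sit at `AUC_norm ≈ 1`.
Convert the calls to a host-range matrix and summarise:

```r
m <- pka_to_matrix(res)
coverage_summary(m)
#> # A tibble: 2 × 7
#>   phage    n_lysis n_reduced n_no_lysis n_total pct_lysis pct_lysis_int
#> 1 PA-myo1        2         0          1       3      66.7            67
#> 2 PA-podo2       2         0          1       3      66.7            67

optimize_cocktail(m, k = 1)
#> <cocktail_result> k = 1 (exhaustive): 2/3 strains (67%), 2 co-optimal set(s)
#>   best: PA-myo1
```

Both phages lyse 2 of 3 strains, so at `k = 1` there are two co-optimal
cocktails (at `k = 2` the pair covers all three). Virulence from an MOI
ladder:

```r
vir <- virulence_analyse(
  simulate_moi_series(phage = "PA-myo1", strain = "BW01", seed = 42))
dplyr::select(vir, phage, strain, stationary_onset, vp)
#> # A tibble: 1 × 4
#>   phage   strain stationary_onset    vp
#> 1 PA-myo1 BW01               11.8 0.810
```

`vp = 0.81` means the phage suppresses most of the control's growth
area across the whole MOI range — a strongly virulent phage.

A thin command-line wrapper over the same functions ships in
`inst/cli/pst.R` (subcommands `pka`, `virulence`, `coverage`,
`concordance`, `mrgn`, `rank`, `cocktail`, `simulate`).

## File formats

Delimited text (comma or tab, auto-detected). Plate series are long
format (`time_h`, `well`, `od600`); plate maps are `well`, `strain`,
`phage`, `moi`, `replicate`, `role` (`phage`/`moi` empty for controls).
Host-range matrices have strains in the first column, one column per
phage, cells `0/1/2` or `no_lysis/reduced_growth/lysis` (`NA` =
untested). Antibiograms are long (`strain`, `antibiotic`, `zone_mm`);
breakpoint tables carry `antibiotic`, `abx_class`, `lead`, `s_min_mm`,
`r_max_mm`. Writers emit UTF-8, LF, deterministic row order.

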