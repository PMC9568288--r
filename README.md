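# implantrisk

Risk scoring, diagnosis and cohort statistics for peri-implant disease.

Dental implants fail through peri-implant mucositis (soft-tissue
inflammation, no bone loss) and peri-implantitis (inflammation with
progressive crestal bone loss). `implantrisk` is for clinicians and
clinical researchers who want a structured, reproducible way to grade
per-implant risk from routine examination data, classify disease state,
and test which risk factors associate with diagnosis in a cohort.

## The model

Each implant is scored on nine parameters; every graded level carries a
risk percentage and the **total risk** is the plain sum:

```
R = Σ_k r_k(x_k),   r_k ∈ {0, 2.5, 5.0, 7.5, 10.0, 12.5}
```

where the parameters k are: previous periodontal history + therapy
compliance (0–12.5%), modified plaque index MPI 0–3 (0–7.5%), modified
gingival index MGI 0–3 (0–7.5%), random blood glucose bands in mg/dl
(0–12.5%), smoking in cigarettes/day bands (0–12.5%), residual cement
(0/12.5%), occlusal overload (0/12.5%), keratinized-mucosa width <2 mm
(0/12.5%) and alcohol consumption (0/10%). R is a multiple of 2.5 in
[0, 100] and maps to a category:

```
R < 25  → low       25 ≤ R ≤ 50 → moderate       R > 50 → high
```

Diagnosis is a separate three-way classifier on MGI, MPI, suppuration,
mean six-site probing depth and crestal bone loss, with bone loss >2 mm
separating peri-implantitis from mucositis (pragmatic mode; a literal
strict mode is also provided). Cohort evaluation cross-tabulates each
factor against diagnosis and computes uncorrected Pearson chi-square
tests, dropping all-zero categories before the degrees of freedom.
The rubric itself is data-driven YAML, so alternative weightings can be
loaded and assessed with the same machinery.

See `vignettes/peri-implant-risk.Rmd` for the full model account,
boundary conventions and design decisions.

## Worked example

The package ships a deterministic 21-implant, 13-patient study cohort
(`study_fixture()`) reconstructed from published factor-by-diagnosis
margins:

```r
library(implantrisk)
library(dplyr)

fx <- study_fixture()

assess_risk(fx) |> count(category)
#> # A tibble: 2 × 2
#>   category     n
#>   <fct>    <int>
#> 1 low         15
#> 2 moderate     6

glance(classify_implants(fx))
#> # A tibble: 1 × 6
#>   n_implants n_healthy n_mucositis n_peri_implantitis n_indeterminate mode
#>        <int>     <int>       <int>              <int>           <int> <chr>
#> 1         21         0          17                  4               0 pragmatic

evaluate_cohort(fx)
#> Cohort evaluation: 21 implants in 13 patients (pragmatic mode)
#>
#>             factor statistic df p_value
#>                sex     2.471  1   0.116
#>        suppuration        NA NA      NA
#>        pdl_history     4.118  2   0.128
#>      plaque_status     5.507  3   0.138
#>    gingival_status     5.868  2   0.053
#>           diabetes        NA NA      NA
#>            smoking     3.070  1   0.080
#>    residual_cement        NA NA      NA
#>  occlusal_overload     1.373  1   0.241
#>  keratinized_width     1.868  1   0.172
#>             others     5.219  1   0.022
#>             result     5.219  1   0.022
```

Fifteen implants are low risk and six moderate; every one of the 21 is
diseased (17 mucositis, 4 peri-implantitis). Of the factor-by-diagnosis
tests, alcohol ("others") and the risk category itself ("result") reach
p < 0.05: moderate-risk implants are concentrated among those with
peri-implantitis. Factors with a single observed level in this cohort
(suppuration, diabetes, residual cement) are reported as `NA` —
a chi-square test is undefined for them. A single implant assesses the
same way:

```r
assess_risk(fx[19, ]) |> select(total_percentage, category)
#> # A tibble: 1 × 2
#>   total_percentage category
#>              <dbl> <fct>
#> 1             47.5 moderate
```

`generate_cohort(cohort_spec(...))` draws seeded synthetic cohorts with
configurable prevalence and factor probabilities; `run_pipeline()` ties
reading, assessment, classification and evaluation together and writes
CSV reports. A thin command-line front end with `assess`, `classify`,
`evaluate`, `simulate` and `fixture` subcommands is in
`inst/cli/implantrisk.R`.

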