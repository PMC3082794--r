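# crcbias

Capture-recapture assessment of publication bias in systematic reviews.

## The problem

A systematic review retrieves studies from several incomplete sources —
electronic databases, the reference lists of included studies, gray
literature (conference databases, contact with experts and
manufacturers). None of these sources is complete, so some eligible
studies are found by no source at all. Conventional publication-bias
diagnostics (funnel plots, the Begg and Egger tests, trim-and-fill)
infer suppression from funnel asymmetry; they cannot say *how many*
eligible studies the search simply missed.

Capture-recapture turns the overlap between sources into exactly that
estimate. Treating the three sources as capture occasions, the studies
retrieved by each subset of sources form seven observed cells of a
2×2×2 incidence table whose eighth cell — studies captured by **no**
source — is unobserved. A Poisson log-linear model fitted to the seven
observed cells,

```
log mu(i,j,k) = u + u_A i + u_B j + u_C k  [+ pairwise terms u_AB ij, ...]
```

extrapolates that missing cell as `X = exp(u)`, giving an estimated
total of eligible studies `N = n_obs + X` and a **search completeness**
of `100 * n_obs / N` percent. Eight hierarchical models are available
(main effects plus any subset of the three pairwise source-dependence
terms); the model minimizing `AIC = G^2 - 2*df` is selected, with
`BIC = G^2 - ln(n_obs / 2*pi) * df` as an alternative. Profile-likelihood
intervals are reported for `X`.

The package also implements the conventional diagnostics the method is
compared against — funnel-plot export, the Begg adjusted rank
correlation test (with an exact permutation option), the Egger
regression asymmetry test, Duval–Tweedie trim-and-fill — plus
fixed/random-effects (DerSimonian–Laird) pooling with Q, I², τ², and
synthetic-data generators for dependent multi-source capture processes
and selectively published meta-analyses.

Intended users: meta-analysts and methodologists who want to quantify
search completeness alongside the usual small-study diagnostics.

## Worked example

The bundled worked example is a systematic review of anamnestic immune
response to hepatitis B booster vaccination: 34 included studies, with
per-source totals of 21 (databases), 26 (reference lists) and 6
(personal contact / gray literature), 17 studies (50%) found by at
least two sources and 2 (6%) by all three. The individual overlap cells
were never published; `hbv_review_table()` recovers them by enumerating
every cell configuration consistent with those summaries (15
candidates) and keeping the single one that reproduces the reported
independence-model deviance.

```r
library(crcbias)
tab  <- hbv_review_table()
fits <- crc_fit_all(tab)
fits
#> Log-linear models fitted to three sources
#>           model df   g2      p n_est x_hat ci_lower ci_upper   aic   bic
#>           A B C  3 3.10 0.3767    39     5      0.6     15.4 -2.90 -1.97
#>        A B C AB  2 3.09 0.2131    40     6      0.0     37.3 -0.91 -0.28
#>        A B C AC  2 1.84 0.3992    38     4      0.3     13.6 -2.16 -1.54
#>        A B C BC  2 1.98 0.3715    41     7      0.9     19.9 -2.02 -1.40
#>     A B C AB AC  1 1.73 0.1890    37     3      0.0     26.7 -0.27  0.04
#>     A B C AB BC  1 0.48 0.4896   Inf   Inf       NA       NA -1.52 -1.21
#>     A B C AC BC  1 0.91 0.3406    39     5      0.5     17.5 -1.09 -0.78
#>  A B C AB AC BC  0 0.00 1.0000   Inf   Inf       NA       NA  0.00  0.00

sel <- crc_select(fits, "aic")
crc_completeness(tab, sel)
#>              source observed estimated completeness ci_lower ci_upper
#> 1         Databases       21        39         53.8     42.5     60.6
#> 2   Reference lists       26        39         66.7     52.7     75.1
#> 3  Personal contact        6        39         15.4     12.2     17.3
#> 4 All three sources       34        39         87.2     68.9     98.2
```

Reading the output: the no-interaction (independence) model fits well
(G² = 3.10 on 3 df, p = 0.38) and minimizes both AIC and BIC, so it is
selected. It estimates X ≈ 5 eligible studies missed by all three
sources, an estimated total of 39, and an overall search completeness
of 87.2%. Reference lists were the most complete single source (66.7%),
gray literature the least (15.4%). Two models — `A B C AB BC` and the
all-pairwise model — have divergent missing-cell estimates (their
sufficient statistics involve an empty overlap cell) and are flagged
non-identifiable rather than reported numerically.

The same analysis runs from a shell on any records CSV
(`study_id, source_a, source_b, source_c`):

```sh
Rscript inst/cli/crcbias.R crc --input studies.csv --criterion aic --out report.json
Rscript inst/cli/crcbias.R bias --input effects.csv --tests begg,egger,trimfill --out bias.json
Rscript inst/cli/crcbias.R fixture paper --out table.csv
Rscript inst/cli/crcbias.R simulate capture --n-true 5000 --pa 0.4 --pb 0.5 --pc 0.2 --seed 1 --out sim.csv
```

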