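# chapmanbias

Bias of two-sample mark-recapture abundance estimates for stream fish when
the population is open to dispersal — exact theory, survey-design tools, and
an individual-based simulator.

## What this is for

Inland fishery managers estimate reach-scale fish abundance with the
two-sample mark-recapture method: mark *m* fish in sample 1, catch *c′* fish
in sample 2 of which *r′* are marked, and apply Chapman's estimator

    N̂* = (m + 1)(c′ + 1)/(r′ + 1) − 1,

the moment-stable modification of the classical ratio estimator
N̂ = c′m/r′. Both assume no fish crosses the study-reach boundary between
samples. When fish disperse, sampling variation pushes the estimator down
while dispersal pushes it up, and the net bias can be severe in the small
populations typical of stream reaches.

For audiences working on fisheries assessment and survey design, the
package provides:

* **Estimators** (`mrr_estimate()`, `chapman_estimate()`,
  `estimate_abundance()`, `capture_mle()`) and the exact multinomial
  outcome model (`outcome_pmf()`, `conditional_chapman_mean()`).
* **Exact moments and relative biases** of Chapman's estimator for closed
  reaches (`closed_moments()`), reaches open to dispersal sampled the
  standard way (`standard_moments()`), and the modified expanded-reach
  design in which only a central zone is marked (`modified_moments()`),
  plus total-population benchmarks (`total_population_moments()`). Every
  expectation has the geometric form E(N̂*) = Ω − φλ^(x−1), and an
  exhaustive enumeration oracle (`chapman_expectation_exact()`) verifies
  the formulas exactly on small populations.
* **Design evaluation**: effort-standardized capture probabilities
  (`capture_probability_from_effort()`, `effort_equivalent_capture()`),
  the five-zone design-comparison model (`five_zone_bias()`,
  `table1_grid()`), and critical abundances at which the asymptotic bias
  becomes a good approximation (`asymptotic_bias()`,
  `critical_abundance()`, `table2_grid()`).
* **An individual-based simulator** of the two-sample experiment with
  continuous fish positions and a Beta(4,4) movement kernel
  (`simulation_config()`, `run_simulation()`), with `tidy()`, `glance()`
  and `autoplot()` methods.
* **A CLI** (`exec/chapmanbias`, or `cli_main()` from R) with subcommands
  `estimate`, `table1`, `table2`, `ncrit`, `five-zone`, `simulate`.

## Worked example

Dahl's classical trout-tarn experiment — 100 fish marked, 150 caught in the
second sample, 50 of them marked:

```r
library(chapmanbias)
estimate_abundance(tibble::tibble(m = 100, c_prime = 150, r_prime = 50))
#> # A tibble: 1 × 6
#>       m c_prime r_prime   mrr mrr_defined chapman
#>   <dbl>   <dbl>   <dbl> <dbl> <lgl>         <dbl>
#> 1   100     150      50   300 TRUE           298.
```

Half the marked fish were recaptured, so the stock is about 300 fish; the
Chapman estimate is 298.04. How biased is such an estimate in a small closed
population with weak sampling? Exactly:

```r
dplyr::select(closed_moments(100, 0.1, 0.1), expected_value, rel_bias_n)
#> # A tibble: 1 × 2
#>   expected_value rel_bias_n
#>            <dbl>      <dbl>
#> 1           70.1     -0.299
```

With n = 100 and 10% capture probabilities, Chapman's estimator is expected
to return about 70 fish — a −30% relative bias from sampling variation
alone. Opening the reach to dispersal changes the picture; in the balanced
five-zone design comparison, an expanded reach sampled the standard way at
equal effort still carries bias:

```r
five_zone_bias(50, p0 = 0.1, q0 = 0.1, reach = "expanded", scheme = "standard")$prb
#> [1] -16.39862
```

and the modified design needs roughly 482 fish in the expanded reach before
its (asymptotically zero) bias approximation is trustworthy at these capture
probabilities:

```r
critical_abundance(asymptotic_bias(0.1, 0.1, "expanded", "modified"))[, c("n_crit", "b_inf")]
#> # A tibble: 1 × 2
#>   n_crit b_inf
#>    <int> <dbl>
#> 1    482     0
```

The individual-based simulator checks the theory against spatially explicit
movement (here a quick 2,000-iteration run; 10,000 is the study default):

```r
cfg <- simulation_config(n_per_zone = 100, q0 = 0.3, delta = 60, n_iter = 2000)
dplyr::select(glance(run_simulation(cfg, seed = 1)),
              p_bar, i_bar, est_mean, theory_e, b_bar, iqr)
#> # A tibble: 1 × 6
#>   p_bar i_bar est_mean theory_e b_bar   iqr
#>   <dbl> <dbl>    <dbl>    <dbl> <dbl> <dbl>
#> 1 0.183  54.8     366.     367.  21.9  75.8
```

About 18% of study-reach fish exited and ~55 immigrants entered per
iteration; the empirical mean estimate (366) sits next to the theoretical
expectation (367) computed from the measured dispersal rates — a +22%
bias with respect to the true abundance of 300. The same scenario under the
modified scheme drops the bias to about +3%.

From the shell:

```sh
chapmanbias estimate 100 150 50
chapmanbias table2 --out table2.csv
chapmanbias simulate --config scenario.yml --seed 1 --n-iter 10000
```

## Documentation

The vignette (`vignettes/dispersal-bias.Rmd`) describes the probability
model, the geometric bias decomposition, the effort-standardization and
critical-abundance machinery, the simulator's conventions, and known
limitations.
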