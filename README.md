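# mnarsim

Monte Carlo simulation of how **selective non-response** biases
estimated associations between risk factors and an ordinal health
outcome — and how much of that bias disappears when a study retains at
least *some* respondents with extreme levels of health problems.

## The problem

In longitudinal surveys, people with the heaviest health problems
respond least. When their non-response depends on the (unobserved)
outcome itself, the data are **missing not at random (MNAR)**, and
neither complete-case analysis nor the standard MAR machinery (FIML,
multiple imputation) can fully repair the damage. For study planners
the operative question is not *how to model* MNAR after the fact but
*how to prevent* it: is it worth spending recruitment resources on the
hardest-to-reach extreme scorers, even if they stay under-represented,
rather than pushing the overall response rate higher?

mnarsim answers this by simulation. Each replication:

1. draws `n = 1000` units with predictors `x1, x2, x3 ~ N(0, 1.15)` and
   a continuous latent outcome
   `y = 0.20·x1 + 0.30·x2 + e`, `e ~ N(0, 1)`;
2. assigns non-response from a latent liability
   `L = b_non1·(x1 + x2 + x3) + b_non2·y + e_L`, `Var(L) = 1.15`, with
   the top-liability units missing on the outcome — and, in the
   contrasting mechanism, the top 10% of the outcome *totally* removed
   with the liability cut recalibrated to hold the response rate fixed;
3. observes the outcome on a 4-point ordinal scale (cuts at −1, 0, +1
   SD; 5-point, 2-point and continuous variants available);
4. estimates the `x1`/`x2` associations by ordered probit (latent
   residual variance 1) under complete-case analysis, FIML with `x3`
   as auxiliary variable, and multiple imputation by predictive mean
   matching, reporting standardized coefficients
   `bs = b·SD(x)/SD(u*)`, `SD(u*) = √(bᵀV(x)b + 1)`, so the unbiased
   values are exactly 0.20 and 0.30;
5. aggregates 500 replications into **relative bias**
   `100·(true − mean estimate)/true`, **95% coverage**, and the
   **preventable-bias percentage** `100·(R1 − R2)/R1`, where `R1`/`R2`
   are the relative biases with extremes totally missing / present.

## Worked example

Contrast the strongest-dependency condition (`b_non1 = b_non2 = 0.3`,
70% response) with extreme scorers totally missing versus present:

```r
library(mnarsim)

sc_rem <- scenario(miss = missingness_scenario(b_non1 = 0.3, b_non2 = 0.3,
                                               response_rate = 0.70,
                                               extremes_removed = TRUE),
                   methods = "CC", n_replications = 200)
run_scenario(sc_rem, base_seed = 1)
#> Scenario 'rr70_removed_bn1-0.3_bn2-0.3_k4' (200 replications)
#>                         scenario method predictor mean_estimate mean_se
#>  rr70_removed_bn1-0.3_bn2-0.3_k4     CC        x1         0.132  0.0400
#>  rr70_removed_bn1-0.3_bn2-0.3_k4     CC        x2         0.224  0.0404
#>  relative_bias coverage95 n_replications n_converged
#>           33.9         62            200         200
#>           25.3         49            200         200

sc_pre <- scenario(miss = missingness_scenario(0.3, 0.3, 0.70, FALSE),
                   methods = "CC", n_replications = 200)
run_scenario(sc_pre, base_seed = 1)
#>  ...
#>  rr70_present_bn1-0.3_bn2-0.3_k4     CC        x1         0.141  0.0395
#>  rr70_present_bn1-0.3_bn2-0.3_k4     CC        x2         0.242  0.0400
#>  relative_bias coverage95 n_replications n_converged
#>           29.3         68            200         200
#>           19.5         69            200         200
```

Reading the output: with the top decile of the outcome absent, the true
`x1` association of 0.20 is estimated at 0.132 on average (34% relative
bias) and the nominal-95% interval for `x2` covers the truth in only
49% of replications. Merely having the extreme scorers present — still
heavily under-represented — lifts the estimates to 0.141 and 0.242 and
the coverage toward nominal. The preventable-bias decomposition makes
the comparison explicit:

```r
R1 <- run_scenario(sc_rem, base_seed = 1)$summary$relative_bias
R2 <- run_scenario(sc_pre, base_seed = 1)$summary$relative_bias
round(prevention_percentage(R1, R2), 1)
#> [1] 13.6 22.9
```

Even in this worst condition, 14–23% of the bias is prevented; in
weak-dependency conditions the same decomposition reaches 100%
(`run_grid(study_grid())` reproduces the full factorial, writes tidy
and formatted tables, and renders the bar-chart figures;
`followup_grid()` adds the 5-category, 2-category and
continuous-outcome variants). A thin command-line front end is
installed at `inst/cli/mnarsim` (`mnarsim simulate|grid|summarize`).

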