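# permtail

Tail-based estimation of small permutation-test P-values in R.

## The problem

Permutation tests are the workhorse of significance assessment in
computational biology (differential expression, gene-set enrichment, and
any setting where no parametric null is trustworthy). The usual estimator
compares the observed statistic x0 with N permutation values and reports

    P_ecdf = #{ v_i >= x0 } / N,

the fraction of permutation values at least as extreme as x0. Its floor is
1/N: with the standard N = 1000 permutations nothing below 10^-3 can be
resolved, and a good estimate of a P-value P needs roughly 10/P
permutations. The small P-values — the interesting ones — are exactly the
ones this estimator cannot reach.

`permtail` implements the extreme-value alternative. The N_exc permutation
values exceeding a threshold t (the *exceedances*, shifted by t) follow a
generalized Pareto distribution (GPD) under the classical
peaks-over-threshold limit,

    F(z) = 1 - (1 + xi * z / sigma)^(-1/xi),      sigma > 0,

and the P-value is estimated from the fitted tail:

    P_gpd = (N_exc / N) * (1 - F(x0 - t)).

The switch rule: when at least ten permutation values reach x0, `P_ecdf`
is already reliable and is returned; below ten the tail model takes over.
The GPD fit (probability weighted moments by default; maximum likelihood
and method of moments available) is accepted only if an Anderson-Darling
goodness-of-fit test cannot reject it — starting from 250 exceedances and
trimming by 10 until acceptance; if nothing ever looks like a tail, no
estimate is returned rather than a wrong one. On top of the point
estimate the package provides percentile-bootstrap confidence intervals,
two heuristic convergence criteria (a log10 coefficient of variation and a
full-vs-10%-subsample rank-sum comparison), and an optional
variance-minimizing order-preserving power transform of the exceedances.

## Worked example

Simulate one "event" with a known truth: 1000 exponential permutation
values and the observed statistic placed at the exact 10^-4 upper-tail
point (x0 = log(10^4) ≈ 9.21), i.e. a true P-value of 10^-4, one decade
below the empirical floor.

```r
library(permtail)
col <- synthetic_column("exponential", n = 1000, x0_tail_p = 1e-4,
                        seed = 8, label = "geneA")
p_ecdf(col$x0, col$values)
#> [1] 0
res <- analyze_column(col, perm_config(seed = 42))
res
#> P-value estimate 'geneA': 7.738949e-05  [gpd, N = 1000, 0 value(s) >= x0]
#>   CI: [0.000000e+00, 5.598867e-04]
#>   tail: t = 1.3762, N_exc = 250, shape = -0.0032, scale = 0.9822, power = 1
```

The empirical estimator returns 0 — no permutation value reaches x0 — while
the tail estimate 7.7e-5 sits within a factor of 1.3 of the truth. The
fitted shape ≈ 0 correctly identifies the exponential tail; 250
exceedances above t = 1.38 passed the goodness-of-fit gate on the first
try. The convergence diagnostics know that N = 1000 is thin for this
target:

```r
check_convergence(col, perm_config(), seed = 42)
#> Convergence: no (CV = 0.280 [pass], rank-sum P = 6.53e-09 [fail])
```

The CV criterion passes, but bootstrap estimates from a 10% subsample
differ in median from the full-sample ones — more permutations would be
needed before calling this estimate stable.

Files are processed column-per-event (optional header row, statistic on
the first data row, permutation values below; `.csv` comma-separated,
anything else tab-delimited):

```sh
Rscript inst/cli/permtail estimate mydata.tsv --method pwm --seed 17 --out results
Rscript inst/cli/permtail simulate --family exponential --columns 5 --n 1000 \
        --tail-p 1e-4 --seed 3 --out fixture.tsv
```

`estimate` writes `results.tsv` (labels, estimates, CI bounds, optional
1/0 convergence flags) and `results.png` (−log10 estimates with CI
whiskers). Estimates are upper-tail; submit |statistic| and absolute
permutation values for a two-sided test.

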