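# spatscale

Urban scaling laws with spatial interactions: generative modelling, joint
inference of the scaling exponent and the interaction range, and Bayesian
model comparison by description length.

## The problem

Scaling analyses relate an urban observable *y* (GDP, mortality counts,
road miles) to city population *x* through *y* ∼ *x*<sup>β</sup>, and the
exponent is conventionally estimated by least squares of log *y* on
log *x*. That regression cannot use cities with *y* = 0, weighs a village
and a megacity equally, and — crucially — treats cities as spatially
independent, although municipalities embedded in a large metropolitan
region plainly are not.

`spatscale` is for quantitative geographers, epidemiologists and
complex-systems researchers who want the exponent and the spatial
interaction range inferred *together*, from an explicit generative model,
with rigorous model comparison.

## The model

*Y* tokens (dollars, deaths, miles) are allocated at random to the *X*
individuals of *N* spatial units. The attractiveness of an individual in
unit *i* is the kernel-weighted population sum

&nbsp;&nbsp;&nbsp;&nbsp;*A<sub>i</sub>* = Σ<sub>i′</sub> *x<sub>i′</sub>* ·
*a*(*d<sub>ii′</sub>*; α),

with great-circle distances *d* and one of three kernels, all normalised
to *a*(0) = 1 and (for G, E) calibrated so that *a*(α; α) = 1/2:

* **C** (city): *a*(*d*) = δ(*d*) — interactions only within the unit;
* **G** (gravitational): *a*(*d*) = 1/(1 + (*d*/α)²);
* **E** (exponential): *a*(*d*) = e<sup>−*d* ln2/α</sup>.

A token lands in unit *i* with probability *p<sub>i</sub>* ∝
*x<sub>i</sub>* *A<sub>i</sub>*<sup>β−1</sup>, and the observed counts are
one multinomial draw of size *Y*. The per-capita null model **P** is the
β = 1 (or α → ∞) limit. Parameters are estimated by MAP under flat priors
(β ∈ [0, 2], α ∈ [0, 6371] km), uncertainties by parametric bootstrap, and
model classes are compared by the description length
*D* = −log₂ *P*(*M*, *D*)/8 bytes, with the marginal likelihood integrated
numerically over the parameters. See the vignette
`vignettes/spatial-scaling-models.Rmd` for the full account.

## Worked example

Simulate a 100-unit system, allocate a million tokens with the
gravitational kernel (α = 20 km, β = 1.2), and let the four models compete:

```r
library(spatscale)

sys0 <- sample_city_system(100, seed = 1)
d    <- distance_matrix(sys0)
y    <- sample_tokens(sys0, d, "G", alpha = 20, beta = 1.2, Y = 1e6, seed = 2)
sys  <- with_counts(sys0, y)

compare_models(sys, d, B = 100, seed = 3)
```

```
<scaling_comparison> reference: P  winner: G 
 family alpha  beta sigma_beta D_bytes delta_D post_prob tie
      P    NA 1.000         NA  3326.4     0.0  0.00e+00    
      C    NA 1.157    0.00095   545.4 -2781.0  0.00e+00    
      G 19.59 1.198    0.00110   105.6 -3220.8  1.00e+00   *
      E 18.08 1.193    0.00110   108.2 -3218.2  5.22e-07    
log-log linear fit: beta = 1.1364 (0 zero-count units excluded)
```

Reading the table: the gravitational model wins (smallest description
length, negative ΔD against per-capita), recovering the generating range
(α̂ = 19.6 km vs. 20) and exponent (β̂ = 1.198 ± 0.001 vs. 1.2). The
spatial-blind city model must distort the exponent to 1.157 to absorb the
interactions it cannot represent, and the log-log regression lands at
1.136 — the kind of shift that ignoring spatial structure produces.

Real data enter as a CSV with columns
`unit_id, lat, lon, population, count` via `read_city_system()`; a
precomputed distance matrix (e.g. commuting times) can replace centroid
distances via `read_distance_matrix()`.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "spatscale", package = "spatscale"))') \
    compare --input units.csv --out-dir results
```

Subcommands: `simulate`, `fit`, `profile`, `compare`, `bootstrap`; all
randomness flows through `--seed`.

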