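# symcat

Symmetry and parity of category systems across languages.

Languages divide semantic domains — days around "today", seasons, compass
points, sibling kin types — into named categories, and the *number* of
categories a language uses is not arbitrary. `symcat` implements a
symmetry account of one cross-linguistic regularity: domains whose
underlying structure has certain symmetries are forced toward category
systems of a particular *parity* (odd or even size), and surveys of
attested systems should over-represent that parity.

The package is organised as an analysis workflow: the computation lives in
the package (`R/`), and the numbered scripts under `analysis/` run the
study end to end on synthetic surveys, writing tables under `results/`.

## The model in brief

A domain is a **structure**: a finite space $\mathcal{S}$ plus
transformations $t:\mathcal{S}\to\mathcal{S}$ expressing its symmetries. A
category system is a partition of $\mathcal{S}$ with same-category relation
$R_C$; it is **symmetric** when

$$R_C(x, y) = R_C(t(x), t(y)) \quad \text{for every } t.$$

Exhaustive enumeration over four canonical structures proves the parity
table: a plain linear continuum (reversal symmetry, group $D_2$) admits
symmetric systems of both parities; a linear continuum bisected by a
privileged centre ("today") admits only odd ones; a circle bisected by a
privileged axis (solstices, east–west; reflection + half-turn, $D_4$) and
binary feature spaces (sibling kin types; one value-swap per feature) admit
only even ones, excluding the trivial one-category system.

On the statistical side, for records $i$ with language family $f(i)$ and
optionally language $l(i)$,

$$y_i \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}(\alpha + u_{f(i)} + v_{l(i)})\right),
\qquad u_f \sim N(0, \sigma_f^2),\; v_l \sim N(0, \sigma_l^2),$$

with Student-t(3, 0, 2.5) priors (half-t for the SDs), fitted by an
adaptive Metropolis-within-Gibbs sampler written in the package (4 chains,
split-$\hat R$ convergence gate). The estimand is
$\mathrm{logit}^{-1}(\alpha)$ — the probability that a domain's system is
even — and a domain is classified odd-preferring / even-preferring /
inconclusive according to whether its 95% credible interval falls below,
above, or across 0.5. A frequentist intercept-only logistic analogue is
included. Kin-term extension counting, glottocode deduplication,
largest-system-per-language filtering, colour-naming consensus counts, and
a synthetic-survey generator (languages nested in families, sawtooth size
distributions) complete the pipeline; see the methods vignette
(`vignettes/parity-of-category-systems.Rmd`) for details and design
rationale.

## Worked example

```r
library(symcat)

# 1. prove a parity theorem by exhaustion
classify_parity("bisected_circular", c(4, 8))
#> <parity verdict: bisected_circular -> even | resolutions 4, 8 |
#>   nontrivial parities attested: even >

# 2. count an English-style sibling terminology from its extensions
tab <- tibble::tibble(
  language = "English",
  term = rep(c("brother", "sister"), each = 6),
  kin_type = c("mB", "meB", "myB", "fB", "feB", "fyB",
               "mZ", "meZ", "myZ", "fZ", "feZ", "fyZ")
)
extract_category_system(tab, "siblings")
#> [1] 2

# 3. estimate a synthetic domain's parity preference
recs <- simulate_survey(survey_preset("seasons", n_families = 15,
                                      languages_per_family = 6, seed = 41))
fit <- fit_parity_model(
  parity_dataset(as.integer(recs$parity == "even"), recs$family),
  config = sampler_config(seed = 5)
)
fit
#> <parity fit | n = 90 | 15 families >
#>   P(even) = 0.682  95% CI [0.575, 0.797]
#>   R-hat: alpha 1.002, sigma_family 1.007
classify_preference(fit$ci95)
#> [1] "even_preferring"
```

The verdict line reads: in this simulated seasons-like survey the posterior
probability that a system is even is about 0.68, the credible interval
excludes and lies above 0.5, so the domain is classified even-preferring —
matching the preference planted by the generator.

## The analysis workflow

```sh
Rscript analysis/01_parity_theorems.R     # verdicts + witness systems
Rscript analysis/02_synthetic_surveys.R   # surveys + size distributions
Rscript analysis/03_kinship_extraction.R  # kin-term and colour counting
Rscript analysis/04_parity_regression.R   # model fits + verdict table
```

Each script states what it found on stderr and writes its tables under
`results/` (TSV/JSON). Step 4 produces `results/domain_verdicts.tsv`, one
row per domain with the posterior probability-even, its 95% interval, the
frequentist estimate, the convergence flag, and the verdict.

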