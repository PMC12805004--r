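---
title: "Symmetry, parity, and category systems: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry, parity, and category systems: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symcat)
```

# The question

Languages carve semantic domains — days around "today", seasons, compass
points, sibling kin types — into named categories, and the *number* of
categories varies across languages. `symcat` implements a symmetry account
of one robust regularity: some domains prefer an odd number of categories,
others an even number. The claim has two halves, and the package implements
both:

1. **A combinatorial half.** Each domain is modelled as a *structure*: a
   finite space $\mathcal{S}$ together with transformations
   $t:\mathcal{S}\to\mathcal{S}$ that express the domain's symmetries. A
   category system $\mathcal{C}$ is a partition of the space, summarised by
   the same-category relation $R_C(x,y) \in \{0,1\}$. The system is
   *symmetric* when $R_C(x,y) = R_C(t(x), t(y))$ for every pair and every
   transformation. Exhaustive enumeration then shows that some structures
   only admit symmetric systems of one parity.
2. **A statistical half.** If languages prefer symmetric systems, surveys of
   attested systems should over-represent the structurally forced parity. A
   hierarchical Bayesian logistic model estimates, per domain, the
   probability that a system is even, pooling languages within families.

# Structures and their parity theorems

Four canonical structures are built by `make_structure()`:

| kind | space | generators | group | parity |
|---|---|---|---|---|
| `linear` | path, $n$ even | reversal | order 2 | both |
| `bisected_linear` | path, $n$ odd, privileged centre | reversal | order 2 | odd |
| `bisected_circular` | cycle, $n$ even, privileged axis | axis reflection, half-turn | order 4 | even |
| `binary_feature` | $2^k$ feature bundles | one swap per feature | order $2^k$ | even |

The parity column is not assumed: `classify_parity()` *proves* it at each
requested resolution by enumerating every connected partition
(`enumerate_connected_partitions()`), filtering by the pairwise invariance
check (`is_symmetric()`), and inspecting the sizes that occur. Exhaustion at
bounded resolution is the contract; no asymptotic argument is attempted.

```{r theorems}
classify_parity("bisected_linear", c(5, 7))
classify_parity("bisected_circular", c(4, 8))
```

Why the theorems hold, mechanically: on a bisected line the reversal fixes
the privileged centre, so a symmetric system has one self-mirrored central
category plus mirror pairs — an odd total. On a bisected circle the
half-turn rotation moves every arc, so it pairs the blocks of any
nontrivial symmetric system without fixed points — an even total (the test
suite asserts this fixed-point-free involution directly). Feature swaps act
the same way on feature spaces. The one-block system is symmetric on every
structure and is excluded from evenness verdicts; `witnesses` in the
verdict carry the smallest nontrivial symmetric system per attested parity.

## Discretization choices

The circular and linear continua must be sampled to finite point sets, and
the sampling convention matters:

* **Offset circular sampling.** `bisected_circular` places $n$ points at
  angles $(i + 1/2)/n$ turns, so no sample point lies on the privileged
  axis or its perpendicular; the two privileged points are carried as edge
  markers (`axis_angles`). If axis points were sample points, the
  reflection would fix them and the two-category summer/winter split — which
  the continuum clearly admits — would be spuriously forbidden. The even
  theorem survives offset sampling because the half-turn remains fixed-point
  free on arcs. The axis itself stays abstract (solstices or equinoxes —
  the engine does not commit to a calendrical anchoring).
* **Even vs odd line lengths.** `linear` requires even $n$ so that no
  accidental centre point is created; `bisected_linear` requires odd $n$
  so the privileged centre is a real sample point that must be assigned to
  a category.
* **Stability check.** Verdicts are computed at two or more resolutions and
  must agree; disagreement raises an error, because it would signal a
  discretization artifact rather than a property of the continuum.
  Alternative conventions can be explored through `custom_structure()`
  rather than by silently changing the canonical ones.

Internally, permutations are index arrays over points `0..n-1` and
composition is right-to-left; these conventions are tested but not part of
the user-facing surface. Partitions are canonicalized by first-occurrence
labelling, so a same-category relation is enumerated exactly once — labels
are immaterial to the invariance condition. Systems with unassigned points
("holes") are supported behind the `holes` argument of
`category_system()` — the hole set must then be mapped onto itself by every
transformation — and are off by default. Enumeration is direct over cut
edges for paths and cycles ($2^{n-1}$ and $1 + \sum_{k\ge2}\binom{n}{k}$
partitions respectively) and falls back to full set-partition enumeration
with a connectivity filter for feature and custom spaces; a configurable
cap guards against combinatorial blow-up, as does the group-closure cap
(default 10,000 elements) for malformed custom generator sets.

# Counting attested systems

The statistical half needs one size per language per domain, and the
counting rules differ by data type:

* **Kin-term tables** (`extract_category_system()`): restrict each term's
  extension to the subdomain's kin-type inventory, drop terms with empty
  restricted extensions, and count *distinct* extension sets — synonyms and
  orthographic variants collapse, while overlapping categories (*brother*
  alongside *younger brother*) count separately. The sibling inventory is
  fixed at 12 types (`mB/mZ/meB/meZ/myB/myZ` and female-speaker
  analogues), deliberately excluding the underspecified `mG`/`fG` so the
  counted extensions are proper subsets of the subdomain. Inventories for
  the other five subdomains ship as editable configuration
  (`inst/extdata/kin_inventories.csv`); they are package-default
  reconstructions, clearly marked, because no canonical list is fixed in
  code.
* **Colour matrices** (`count_color_terms()`): a term counts when at least
  60% of participants (inclusive boundary, configurable threshold) used it
  for at least one chip.
* **Curation** (`dedupe_by_glottocode()`, `largest_per_language()`): one
  record per glottocode, and where duplicates disagree in parity the record
  *contradicting* the domain's predicted parity is kept — the conservative
  choice, biasing against the hypothesis being tested. Social-classification
  domains keep only each language's largest system (moieties nest inside
  sections inside subsections). Records without a glottocode are retained
  but flagged, since they cannot be assigned a family. Every curation step
  logs records in and out, and the counts telescope through the pipeline
  report.

# The parity-preference model

For domain records $i$ with family $f(i)$ (and optionally language
$l(i)$):

$$y_i \sim \text{Bernoulli}(\text{logit}^{-1}(\alpha + u_{f(i)} + v_{l(i)})), \quad
u_f \sim N(0, \sigma_f^2), \; v_l \sim N(0, \sigma_l^2)$$

with a Student-t(3, 0, 2.5) prior on $\alpha$ and half-Student-t(3, 0, 2.5)
priors on the SDs. The estimand is $\text{logit}^{-1}(\alpha)$, the
probability that a system is even, reported as a posterior mean with a
central 95% credible interval; `classify_preference()` reads the interval
against 0.5 (entirely below → odd-preferring, entirely above →
even-preferring, otherwise inconclusive). `fit_parity_glm()` provides the
frequentist analogue (intercept-only logistic fit, Wald interval mapped to
the probability scale, explicit complete-separation reporting).

**Family intercepts as the phylogenetic control.** Genetic relatedness is
controlled with family-level random intercepts (plus language intercepts
when a language contributes several records), not a tree-structured
covariance: the available language taxonomies lack branch lengths, and for
an intercept-only estimand the family exchangeability assumption is the
operative part. A tree-covariance extension would slot in where the family
deviations enter the linear predictor; exact numeric replication of
published interval endpoints is not claimed.

**Sampler.** Fitting is by an adaptive random-walk Metropolis-within-Gibbs
on $(\alpha, z_f, z_l, \log\sigma_f, \log\sigma_l)$, written in the
package: group deviations are non-centred ($u = \sigma_f z_f$, avoiding the
funnel at small group counts), and because families are conditionally
independent given $(\alpha, \sigma)$, all family deviations update in one
vectorized Metropolis sweep with per-group accept/reject. Step sizes adapt
during warmup toward a target acceptance rate of 0.44 — the optimum for
one-dimensional random-walk proposals. (This plays the role that a target
average acceptance probability of ~0.95 plays for Hamiltonian samplers;
that value is specific to HMC step-size adaptation, and tuning a random
walk to it would force vanishing steps and non-convergent chains, so it is
*not* the default here.) Defaults are 4 chains of 3000 iterations with
1500 discarded as warmup. Convergence is gated on split-$\hat{R} \le 1.01$
for $\alpha$ and the SDs; $\hat{R}$ is computed on the SD draws directly
rather than $\log\sigma$, because when a group SD concentrates near zero
the log transform stretches that mass and flags spurious non-convergence.
Non-converged fits are returned with a warning and `converged = FALSE`;
the remedy, as in standard practice, is longer chains (the bundled
analysis scripts lengthen to 8000/4000 where the gate trips). One master
seed yields per-chain seeds deterministically; all reported numbers are
bit-for-bit reproducible given the seed, and relabelling families
bijectively leaves the draws identical.

The test suite cross-checks the sampler two independent ways: against a
JAGS fit of the identical model (posterior mean and interval endpoints) and
against `lme4::glmer` point estimates, plus an analytic Beta-posterior
limit when the hierarchy is shrunk away.

# The synthetic surveys

No field data ship with the package; `simulate_survey()` generates surveys
with the statistical shape the analyses assume: languages nested in
families, a per-domain even-probability $\theta$ on the logit scale with
family (and optionally language) deviations, and *sawtooth* size
distributions — separate weight maps over odd and even sizes, so mass
alternates between adjacent parities as it does in parity-preferring
domains. Generator defaults define the study conditions used throughout the
tests: 30 families × 5 languages, $\sigma_f = 0.5$, and parameter-recovery
checks at $\theta = 0.7$ (interval coverage over 50 replicate surveys) and
$\theta = 0.8$ (detection of the even preference). The domain presets
(`survey_preset()`: day-naming-like with modal size 5 and odd preference,
seasons-like with modal size 4, kinship-like with duplicate per-language
sources, and a balanced control) are qualitative fixtures, not estimates of
any archived data set. `simulate_kin_table()` plants a known partition of a
kin-type inventory and emits synonym terms per block, so extraction has an
exact round-trip ground truth; `simulate_color_matrix()` plants a known
number of consensus terms.

What the generator deliberately does *not* emulate: realistic phylogenies
with branch lengths, elicitation bias (ethnographers anchored on Western
four-term systems may inflate size-4 counts for lunar and cardinal
domains — no correction is attempted, summaries only report), dual-symmetry
day-name systems that reuse forms across past and future (disconnected
categories; noted, not modelled), and non-random missingness of
glottocodes. Passing tests therefore certify the machinery and its
statistical calibration under the assumed generative structure, not claims
about any particular field data set.

# Problem sizes and numerical choices

Enumeration verdicts use paths at $n \le 9$, cycles at $n \le 12$, and
feature spaces at $k \le 3$ by default — thousands of partitions per
structure, where exhaustion is instant and the oracle-equivalence property
(pairwise invariance ⟺ every transformation permutes the blocks) is
asserted over every partition. Model checks run 4 chains; replicate
harnesses use 2000-iteration chains, which recover coverage comfortably at
the study's survey sizes. Ties in `largest_per_language()` keep the first
record; the dedupe rule keeps the first record when duplicate parities
agree and warns when asked to dedupe mixed parities with no predicted
parity. A system size of 1 counts as a power of two ($2^0$) in
`parity_summary()`'s flag; the substantive powers-of-two observation
concerns sizes 2, 4, 8.

# Limitations

Parity theorems are proved by exhaustion at bounded resolution, not in the
continuum; the bisected-circular conclusions depend on the documented
offset-sampling convention (alternatives are expressible via
`custom_structure()`). The family-intercept approximation discards
within-family tree structure. The random-walk sampler is adequate for
intercept-only models of this scale but would not be the right tool for
high-dimensional extensions. Non-sibling kin inventories are
reconstructions. Real-data idiosyncrasies listed above are out of the
generator's scope by design.
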