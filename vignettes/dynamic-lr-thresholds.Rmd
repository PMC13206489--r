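---
title: "Dynamic likelihood-ratio thresholds for DNA database searching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic likelihood-ratio thresholds for DNA database searching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r load}
library(dynlr)
```

## The problem

A DNA database search compares a crime-scene profile (often degraded to a
handful of typed STR loci) against every reference profile and reports the
candidates whose genotypes match exactly at all shared loci. Operational
practice filters the raw match list with static rules: a minimum number of
shared loci, or a fixed likelihood-ratio cutoff. Both rules ignore two
things that drive the adventitious-match rate:

* **which** loci are shared — a four-locus match at highly polymorphic
  markers can carry more evidential weight than a six-locus match at
  low-diversity ones; and
* **how many comparisons** the search performs — the expected number of
  coincidental matches grows linearly with database size at any fixed
  cutoff.

`dynlr` replaces the static rule with a threshold computed per match, from
the exact discrete distribution of the total log10 likelihood ratio that
unrelated individuals achieve on the match's own loci set, inverted at a
false-positive budget the laboratory chooses.

## The coancestry model

Population substructure is modelled with a single coancestry coefficient
$\theta$ (0.01 by default, the common forensic choice; 0.03 for more
conservative reporting). With allele frequencies $p_i$, the probability
that a random person carries a genotype is

* homozygote $a_i a_i$: $\theta p_i + (1-\theta) p_i^2$,
* heterozygote $a_i a_j$: $2 (1-\theta) p_i p_j$,

and the probability that a second, unrelated person carries the *same*
genotype, given it has been seen once (the match probability that the
likelihood ratio is built from), follows the NRC II Recommendation 4.10
form:

* homozygote: $\dfrac{(3\theta + (1-\theta)p_i)(2\theta + (1-\theta)p_i)}
  {(1+\theta)(1+2\theta)}$,
* heterozygote: $\dfrac{2(\theta + (1-\theta)p_i)(\theta + (1-\theta)p_j)}
  {(1+\theta)(1+2\theta)}$.

The single-locus likelihood ratio of an equal-genotype observation is the
reciprocal of the match probability, so it is always at least 1, and the
total log10 LR of a multi-locus match is the sum of the per-locus log10
LRs.

Frequencies are used only after the minimum-frequency correction
`apply_pmin()`: alleles rarer than $p_{min} = 5/2N$ ($N$ = individuals
typed) are floored to $p_{min}$ and the locus renormalized, guarding
against alleles unobserved in the reference sample. The correction is
final — corrected tables are returned unchanged on a second application
(renormalization can push a floored frequency fractionally below the
floor again, so "apply once" is the defined behavior).

## The exact distribution of the log10 LR

For a locus with $K$ alleles there are $K(K+1)/2$ genotypes. Each
genotype $g$ contributes an atom of probability

$$m(g) = P(g)\; P(g \mid g)$$

(the probability that two unrelated people *both* carry $g$) at the value
$\log_{10} LR(g)$. Summed over genotypes this is a *sub*-probability
distribution: its total mass is the locus's full-match probability, well
below one. Atoms are placed on a uniform grid of width $\Delta$ (0.001
log10 LR units by default) by rounding half away from zero; genotypes
landing in the same bin are clumped.

Because loci are independent given the subpopulation, the multi-locus
distribution is the convolution of the single-locus ones. `convolve_fft()`
computes it by multiplying characteristic functions (via `stats::fft`) on
an array of $2^{16}$ bins by default ($2^{15}$ suffices for the study
sizes used below); an aliasing guard refuses arrays shorter than the
combined support, tiny negative round-off (magnitude below $10^{-12}$) is
clamped to zero, and `convolve_direct()` — a sparse brute-force
accumulation — serves as the oracle in the test suite, agreeing with the
FFT to better than $10^{-10}$ per bin on every loci subset checked.

```{r toy}
path <- system.file("extdata", "example_frequencies.csv", package = "dynlr")
ft <- apply_pmin(read_freq_table(path))
pmf <- convolve_fft(lapply(c("LOC01", "LOC03", "LOC05"),
                           single_locus_pmf, table = ft))
pmf
```

## From risk budget to threshold

A search of a stain against $N$ profiles performs $T = N$ comparisons
(database-to-database: $T = N(N-1)/2$). If each comparison has
false-positive probability $\alpha$, the count of adventitious matches is
well approximated as Poisson with mean $\mu = \alpha T$. The laboratory
states its budget either as $\mu$ directly or as "at most $U$ false
positives with probability $\beta$", which `mu_from_upper_bound()` inverts
through the Poisson CDF (computed by `stats::ppois`, i.e. the regularized
incomplete gamma function; the closed-form gamma-quantile identity is used
as an independent cross-check in the tests).

The dynamic threshold for a match with loci set $M$ is the smallest grid
value whose tail mass in the distribution of $M$ does not exceed
$\alpha = \mu / T$:

```{r threshold}
spec <- risk_spec(500000, "stain", mu = 1)
thr <- threshold_from_alpha(pmf, spec$alpha)
c(alpha = spec$alpha, threshold = thr,
  achieved = alpha_from_threshold(pmf, thr))
```

Two conventions matter and are deliberate:

* **Conservative rounding.** The threshold is the smallest bin whose tail
  is *at or below* $\alpha$, so the achieved rate never exceeds the
  budget. On a discrete, spiky distribution the achieved rate can sit
  visibly below $\alpha$ when a large atom straddles the boundary — the
  framework then under-spends rather than overdraws.
* **Saturation.** If $\alpha$ already exceeds the loci set's total match
  probability, no filtering is needed and the threshold is 0; if $\alpha$
  is below the largest atom's mass, the threshold sits one bin above the
  support and nothing is reported.

The threshold depends on the *identity* of the shared loci, not just
their number: across the 4-locus subsets of a realistic 24-locus panel
the thresholds at fixed $\alpha$ spread over more than half a log10 unit,
which is precisely the heterogeneity a locus-count rule erases.

## Synthetic populations

All evaluation runs on synthetic data, generated by seeded, first-class
package code:

* `synth_freq_table()` emits STR-like panels. Real STR frequency profiles
  are unimodal across repeat lengths (stepwise mutation keeps most
  chromosomes near the modal repeat count), so each ladder's frequencies
  follow a discretized bell perturbed by lognormal noise. Ladder sizes
  (6–20) and bell widths vary across loci, spanning low-diversity,
  one-dominant-allele markers up to highly polymorphic ones. The default
  panel has per-locus heterozygosities of roughly 0.66–0.93 and per-locus
  full-match probabilities of roughly 0.011–0.18 — the range of real
  extended panels.
* `dirichlet_subpop_frequencies()` draws subpopulation frequencies from a
  Dirichlet with concentration $p_i (1-\theta)/\theta$. This is the
  stationary parameterization of the coancestry model: the mean equals
  the baseline, $\mathrm{Var}(q_i) = \theta p_i (1-p_i)$, and (checked
  algebraically) two profiles sampled within one such draw have exactly
  the Balding–Nichols pairwise match probabilities on average. One shared
  draw per study mirrors the assumption the LR model makes.
* `degrade_profiles()` keeps a uniformly random subset of typed loci;
  `simulate_relatives()` builds parent–child pairs (one allele identical
  by descent at every locus) and full siblings (IBD state 2/1/0 with
  probability 0.25/0.5/0.25 per locus).

```{r study}
cfg <- sim_config(seed = 7, db_size = 500, n_stains = 50, stain_loci = 4:6,
                  relatives = "full-sibling")
study <- generate_study(cfg, ft)
study$db
```

## Searching

`search_profiles()` finds every exact full match and filters it with one
of three methods: `"dynamic-lr"` (per-match threshold from a
`risk_spec`), `"static-lr"` (fixed log10 LR cutoff) or `"locus-count"`
(minimum shared loci). Multi-locus distributions are memoized per loci
set (`pmf_cache()`), so a search touches each distinct overlapping loci
set once.

```{r search}
spec <- risk_spec(500, "stain", mu = 1, T = 500 * 50)
res <- search_profiles(study$stains, study$db, ft, "dynamic-lr",
                       spec = spec, n_fft = 32768L)
head(res[, c("stain_id", "candidate_id", "n_shared_loci", "log10_lr",
             "threshold", "decision")])
```

## Validation machinery and its conventions

Evaluation functions are deliberately desk-scale (minutes on one CPU);
all sizes below are package choices, and everything scales up if given
larger arguments and more time.

**Calibration** (`run_calibration()`): 50 batches of 1000 three-locus
stains searched against a fresh 5000-profile database per batch
($T = 5\times10^6$), counting adventitious matches that clear the dynamic
threshold at targets $\mu \in \{1, 5, 10\}$. Means track the targets
within sampling error and ~95% of batch counts fall inside the two-sided
95% Poisson band (convention: $L$ = largest integer with
$P(X < L) \le 0.025$, $U$ = smallest with $P(X \le U) \ge 0.975$). The
stain locus count must suit the budget: at this $T$, four-locus subsets
of a realistic panel have *median* full-match probability below
$\mu/T$ already at $\mu = 10$, so a four-locus study at desk scale sits in
the saturation regime (thresholds at 0, observed counts honestly but
uninformatively below target) rather than the calibration regime; three
loci keep every subset observable. At full operational scale
($T = 5\times10^7$ and beyond) the same crossover appears only at much
larger $\mu$, where mild conservatism is expected and acceptable.

**ROC comparison** (`run_roc()`): degraded stains (3–7 loci) with donors
planted in the database; every raw full match is scored three ways —
shared-locus count, total log10 LR, and the tail probability of the
match's own log10 LR in its loci-set distribution (the quantity the
dynamic threshold cuts on; sweeping $\alpha$ traverses exactly this
ranking, so the ROC uses the score directly rather than a finite grid of
thresholds). False-positive rates are reported per comparison; the AUC is
computed on the FPR axis normalized to its maximum, which equals the AUC
over the pool of adventitious matches. Expected ordering, reproduced by
the acceptance tests: locus-count is clearly dominated, while static-LR
and dynamic-LR rank matches almost identically (AUC difference below
0.01) — the dynamic method's advantage is not discrimination but the
automatic, database-size-aware placement of the operating point.

**Monte-Carlo convergence** (`mc_convergence()`): samples matching pairs
directly (Dirichlet-urn allele draws, rejection on genotype equality) and
compares them with the FFT distribution conditioned on a full match,
using the Wasserstein-1 distance normalized by the FFT distribution's
standard deviation (the spread-relative convention adopted here). At
$10^5$ trials the normalized distance is well under 0.01.

**Continuous baseline** (`gaussian_tail_comparison()`,
`gap_analysis()`): multi-locus log10 LR distributions are right-skewed
with heavier-than-Gaussian far tails, and their supports contain genuine
zero-probability gaps (log10 LR values that no genotype combination can
produce). A Normal with matched mean and variance misstates exactly the
tail probabilities that thresholds are built from — the reason the
package computes the discrete distribution instead of approximating it.
Gap detection treats bins below $10^{-9}$ of the total mass as empty,
since FFT round-off deposits relative masses of order $10^{-16}$ in
structurally empty bins.

**Relatives** (`relatives_passthrough()`): parents/children and full
siblings of stain donors are injected into the database. Relatives match
far more often than unrelated profiles, but most lack the statistical
weight to clear a threshold calibrated against unrelated coincidence;
siblings at higher locus counts are the residual leak, and their
surviving matches carry genuinely high LRs.

## Numerical choices, in one place

* Bin width $\Delta = 0.001$ log10 LR; binning by rounding half away
  from zero with a $10^{-12}$ pre-snap absorbing float noise.
* FFT array $2^{16}$ bins by default ($2^{15}$ in the desk-scale
  studies); aliasing guard compares combined support to array length
  before transforming.
* Negative convolution round-off clamped at $-10^{-12}$; anything more
  negative is an error, not a warning.
* Threshold = smallest grid value with tail $\le \alpha$ (conservative);
  `alpha_from_threshold()` is its exact inverse on the grid.
* Poisson machinery delegates to `stats::ppois`/`qpois`/`uniroot`;
  nothing is hand-rolled.

## Known limitations

* A widely circulated reference table for the Poisson bounds prints
  $U_{95} = 27$ at $\mu = 20$; the definition (smallest $k$ with
  cumulative probability $\ge 0.95$) gives 28, since
  $P(X \le 27) = 0.94752 < 0.95$. The printed 27 matches the Gaussian
  approximation $20 + 1.645\sqrt{20} = 27.36$ rounded down. This package
  returns 28.
* Matching is exact; wildcard/one-mismatch searching is out of scope.
* The Poisson model treats comparisons as independent; databases dense
  in relatives violate this, which is why the relatives study exists.
* Synthetic panels emulate the statistical shape of real ones; casework
  requires the laboratory's own validated frequency tables (readable via
  `read_freq_table()`).
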