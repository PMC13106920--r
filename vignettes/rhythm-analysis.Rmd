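---
title: "Categorical rhythm analysis of phrase-structured song"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorical rhythm analysis of phrase-structured song}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Singing primates such as the indri organize their song into *phrases*:
runs of notes separated by longer gaps. Two adjacent inter-onset
intervals (IOIs) — the time from one note's onset to the next — stand in
a rhythmic relationship captured by the ratio

$$ r_k = \frac{t_k}{t_k + t_{k+1}} \in (0, 1). $$

Equal intervals (isochrony) give $r_k = 1/2$; an interval followed by one
twice as long gives $1/3$ (a 1:2 relation); the mirror case gives $2/3$
(2:1). When a song's ratios *cluster* around such small-integer values the
rhythm is categorical, a property shared with human music. This package
implements the full analysis chain used to study how such categories
emerge across development: annotation ingest, interval and ratio
computation, on/off-integer classification, mixed-model significance
tests, regularity quantification, density-peak description, and ternary
representation of interval triples — plus a synthetic song generator that
stands in for field recordings.

## From annotations to ratios

The pipeline starts from note onset annotations (Praat TextGrid interval
tiers or a flat onset CSV), never from audio. `compute_iois()` takes
successive onset differences and discards any interval longer than the
**cap** of 5 s, the conventional upper bound for meter perception; the
position of a discarded interval is remembered as a *break*, and no ratio
or triple is ever computed across a break. The rationale is conservative:
a ratio straddling a discarded interval would smuggle the excluded
duration back into the analysis. A stricter variant
(`drop_adjacent = TRUE`) also discards the two intervals flanking an
over-cap gap, for users who prefer to treat long silences as corrupting
their neighbours; the default keeps the flanking intervals, because they
are themselves valid sub-cap durations.

Ratios are computed within one individual contribution only. Scale
invariance ($r_k$ unchanged when all onsets are multiplied by a positive
constant), reversal antisymmetry (time reversal maps $r_k$ to $1 - r_k$ in
reverse order), and exact isochrony ($r_k \equiv 1/2$) are enforced by
the test suite as properties, not spot checks.

## The on/off-integer bin scheme

Each rhythmic category has an **on-integer** range centred on its
small-integer ratio and two flanking **off-integer** control ranges. The
boundaries are the exact fractions

$$ \tfrac{1}{3.5},\ \tfrac{1}{3.25},\ \tfrac{1}{2.75},\ \tfrac{1}{2.5},\
   \tfrac{1}{2.25},\ 1-\tfrac{1}{2.25},\ 1-\tfrac{1}{2.5},\
   1-\tfrac{1}{2.75},\ 1-\tfrac{1}{3.25},\ 1-\tfrac{1}{3.5}, $$

which tile $[1/3.5,\, 1 - 1/3.5]$ without gaps. We store the fractions,
not their rounded three-decimal displays: published displays of these
numbers are rounded inconsistently (the same boundary appears as 0.285
and 0.287 in different sentences of the literature), whereas the
fractions are unambiguous. Membership is half-open $[lo, hi)$ with the
single global maximum closed — a choice the source texts leave open; we
picked the convention that guarantees a partition, so every ratio in the
covered span lands in exactly one bin. `classify_ratio()` is verified
against an independent brute-force boundary comparator on $10^5$ random
ratios.

## Peak significance: the offset Poisson mixed model

Whether a category is *really* produced is tested by comparing counts in
its on-range against its off-ranges. For each age class we fit

$$ \text{count}_{ij} \sim \text{Poisson}(\mu_{ij}), \quad
   \log \mu_{ij} = \log w_j + (\text{bin} \times \text{sex})\beta + u_i, $$

with one row per contribution $\times$ bin, $w_j$ the bin's width in
ratio units entering as an offset (on- and off-ranges are unequally wide,
so the model compares *densities*, counts per unit ratio width), and
$u_i \sim N(0, \sigma^2_u)$ a random intercept per individual.
Estimation is by Laplace approximation (`lme4::glmer`), with adaptive
Gauss–Hermite quadrature available through `nagq`. The full model is
compared to a null containing only the offset and the random intercept by
likelihood ratio test; bin contrasts within each sex are Tukey-adjusted
pairwise comparisons of estimated marginal means (`emmeans`, averaging
over companion factors with equal weights — the package's conventional
default). A category is declared significant for a sex when the LRT
rejects *and* the on-vs-off contrast is positive with adjusted $p$ below
$\alpha$. A zero-inflation self-check compares observed zero counts to
$\sum_i e^{-\hat\mu_i}$.

Model-fitting choices worth knowing:

* the optimizer is `bobyqa` with a generous evaluation budget, which on
  wide factorial designs avoids the spurious gradient warnings of the
  default optimizer;
* non-convergence is a *flag* on the returned fit, not an exception, so
  pipeline summaries can report it; `pairwise_contrasts()` refuses
  unconverged fits unless explicitly allowed;
* with `group = NULL` the same interface fits an ordinary Poisson
  regression — the exact $\sigma^2_u = 0$ limit, used by the test suite
  as an equivalence oracle;
* an age class whose counts are all zero is returned as a degenerate
  result (LRT $p = 1$, nothing significant) rather than fitted.

## Rhythmic regularity: the beta mixed model

Regularity around a category is the width-weighted on-integer proportion

$$ \frac{n_{on} w_{on}}{n_{on} w_{on} + n_{off} w_{off}} \in [0, 1], $$

missing when a contribution has no observation near the category. We read
the weighting as multiplying each bin's count by that bin's own width in
both numerator and denominator; this preserves the endpoints (1 = all
on-integer, 0 = all off-integer) and reduces to the raw proportion when
widths are equal. An alternative reading — weighting by the density mass
over the bin — cannot be excluded from the method descriptions in the
literature; it is noted here but not implemented.

Regularity is modelled with a beta likelihood (logit link, precision
$\phi$) via `glmmTMB`, fixed effects sex $\times$ age class, and a
random intercept on the individual contribution — as the source analysis
prescribes. Since each contribution supplies a single value per category,
that intercept variance is only weakly identified against $\phi$; the
fitter warns, and individual-level grouping is one `model_spec()` away.
Exact 0/1 responses are shrunk with the standard compression
$y' = (y(n-1) + 0.5)/n$ before fitting, because the beta support is open.
By default the regularity models cover the 1:2 and 1:1 categories (the
ones typically significant in at least two age classes of both sexes);
the category set is a configuration knob.

## Densities, peaks, triples

Descriptive density curves use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth on a 512-point grid extending three bandwidths
past the data — the common density-plot convention; none of the inference
depends on these choices. Peaks are interior grid maxima with prominence
of at least 1% of the curve maximum, a floor that suppresses
floating-point ripple while passing any genuine mode of a smooth kernel
estimate. Peaks are reported in increasing location order; for interval
densities the first (shortest) peak is the intra-phrase mode and the
second the inter-phrase mode. Triples of consecutive intervals are
normalized to the 2-simplex ($\hat t_k = t_k / (t_k + t_{k+1} + t_{k+2})$)
for ternary scatter plots; isochrony maps to the centre $(1/3, 1/3, 1/3)$.

## The synthetic song generator

The generator emulates the architecture the analysis assumes, not any
particular recording: notes grouped into phrases, within-phrase IOIs
with mean 2 s, between-phrase gaps at twice the within mean (so interval
densities are bimodal near 2 s and 4 s and the within/between alternation
creates ratios near 1/3, 1/2 and 2/3), lone notes followed by long pauses,
and a class-dependent probability that a between-phrase gap exceeds the
5 s cap entirely. Interval noise is gamma-distributed, parameterized by
mean and coefficient of variation — the simplest positive noise family
with a controllable CV; nothing in the literature quantifies the real
within/between variance, so the CVs are knobs, not estimates. Counts of
phrases and of notes per phrase are shifted Poisson draws. A lognormal
per-individual tempo multiplier (SD 0.1 by default) creates the
random-intercept structure the mixed models assume.

The class presets are *invented*, and tuned only to reproduce the
qualitative developmental pattern: adults have low CVs and few over-cap
gaps, so all three categories emerge in both sexes; juvenile males keep
most between-phrase gaps over the cap and noisy, so only isochrony
survives; young females add frequent lone notes. In the zero-noise limit
(all CVs and pause probabilities zero) the generated ratios hit
$\{1/3, 1/2, 2/3\}$ *exactly*, which the test suite uses as a closed-form
oracle. What passing tests on synthetic cohorts shows is that the
*machinery* — capping, classification, models, contrasts — recovers a
known generative structure; it says nothing about any real population's
parameter values, and printed peak values from field datasets are not
reproduction targets.

## Reproducibility and problem sizes

All randomness flows from explicit seeds: `simulate_cohort()` consumes
one seed for a whole cohort, and `run_pipeline()` records its seed in the
run manifest; reruns with the same configuration produce byte-identical
tables. The test suite works at deliberately modest sizes — cohorts of a
few dozen individuals, parameter-recovery designs of 50–200 groups, a
500-replicate null simulation for the likelihood-ratio test's type-I
error — sizes at which the asymptotics the tests check have taken hold
while the whole suite stays comfortably quick on a laptop.

## Known limitations

* The TextGrid reader supports the long text format (UTF-8/UTF-16) only;
  the compact short format is rejected with a pointer to re-save from
  Praat.
* No audio processing, chorus-overlap resolution, or speaker diarization:
  the unit of analysis is the annotated individual contribution, taken as
  atomic.
* The default scheme covers the three classic categories (1:2, 1:1, 2:1);
  the scheme object is a plain data frame and extensible, but other
  categories ship untested.
* Beta-model regularity compares age classes cross-sectionally; no
  longitudinal (within-individual trajectory) modelling is attempted.
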