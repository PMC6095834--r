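---
title: "Dropout-screen hit calling across genotyped panels: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dropout-screen hit calling across genotyped panels: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

This vignette documents the statistical model behind `poolscreen`, the
parameters that matter and their defaults, what the built-in screen
simulator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## The screening model

A pooled dropout screen measures, per hairpin, the change in barcode
abundance between a reference timepoint T0 (taken right after library
selection) and an endpoint T1 (after two to three weeks of culture).
Hairpins whose knockdown kills or arrests their host cells deplete; the
analysis problem is deciding, per gene and per cell line, whether that
depletion is real and consistent enough across a gene's hairpins to call
the gene lethal — and then, across a genotyped panel, whether lethality
tracks a mutation.

### Normalization

Samples differ in sequencing depth. `size_factors()` uses the
median-of-ratios estimator: with counts $k_{ij}$ (hairpin $i$, sample $j$),

$$ s_j = \mathrm{median}_{i \,:\, k_{i\cdot} > 0}
   \; \frac{k_{ij}}{\left(\prod_v k_{iv}\right)^{1/m}} $$

over hairpins with strictly positive counts in all $m$ samples. The
estimator is robust to a minority of genuinely depleted hairpins, which is
exactly the situation a dropout screen creates; it fails (with an explicit
error) only when no hairpin is positive everywhere.

### Dispersion

Counts are modeled negative-binomially, $\mathrm{Var} = \mu + \alpha\mu^2$.
`estimate_dispersions()` computes a raw method-of-moments $\alpha$ per
hairpin from replicate variance of normalized counts (pooled across the two
timepoints, shot noise subtracted, floored at zero), then fits the
mean-dispersion relation $\alpha(\mu) = a_0 + a_1/\mu$ by a robust linear
fit (`MASS::rlm` on $1/\mu$, coefficients clamped at zero). The working
dispersion is $\max(\alpha_\text{raw}, \alpha_\text{fit}(\mu))$ — with only
2–3 replicates the raw estimate is extremely noisy, and taking the maximum
is deliberately conservative: a hairpin is never granted less variance than
either its own replicates or the library-wide trend support. With a single
replicate per condition the per-condition path refuses to run; pooling all
samples must be requested explicitly (`method = "blind"`), because it
absorbs true signal into the variance estimate and costs power.

### The exact conditional test

`nb_exact_test()` tests depletion of one hairpin from its replicate counts.
Conditioning on the total $K$ of both timepoints' summed counts, each sum is
negative binomial with mean proportional to its summed size factors and
variance carrying $\alpha$; the two-sided p-value sums the conditional
probabilities of all splits $(a, K-a)$ no more probable than the observed
one (minimum-likelihood rule):

$$ p = \frac{\sum_{a+b=K,\; \Pr(a,b) \le \Pr(k_{T0}, k_{T1})} \Pr(a,b)}
            {\sum_{a+b=K} \Pr(a,b)}. $$

Numerical points worth knowing:

* **Enumeration and the large-$K$ window.** For $K \le 5000$ the sum runs
  over all $K+1$ splits. Beyond that, it runs over the $1 - 10^{-14}$
  quantile window of each marginal (always including the observed split);
  the excluded terms carry negligible mass in numerator and denominator
  alike, so the truncated sum agrees with the full one to ~$10^{-9}$ while
  keeping runtime bounded. The test suite checks both the exact equivalence
  with brute-force enumeration for $K \le 200$ and the full-vs-truncated
  agreement at $K \approx 10^4$.
* **Ties.** Probabilities equal to the observed one up to a relative
  $10^{-7}$ are counted into the tail, so exact symmetric cases (equal
  sums, equal factors) give $p = 1$ rather than $1 - \epsilon$.
* **Degenerate input.** $K = 0$ returns $p = 1$ with a `degenerate`
  attribute: a hairpin absent from both timepoints carries no information.
* **Dispersion dependence.** Over the range real screens occupy
  ($\alpha \approx 0.01$–$1$) the p-value increases with $\alpha$ — more
  overdispersion, less significance. At extreme $\alpha$ (say 10) this
  reverses: the conditional distribution becomes U-shaped, central splits
  become the *least* probable outcomes, and the minimum-likelihood rule
  counts little besides them. That regime is far outside screen-like data
  but is worth knowing when experimenting with the function directly.
* **What is and is not scale-invariant.** Multiplying a sample's column by
  a constant is absorbed by the size factors, so normalized means and fold
  changes are unchanged (exactly so at pseudocount 0). The exact p-value,
  however, conditions on the *raw* summed counts, which such a rescaling
  changes; p-values therefore shift slightly. This is a property of the
  conditional construction, not an implementation artifact. What does hold
  exactly is invariance under a common rescaling of all size factors.

### Fold changes, pseudocount and abundance floor

Fold change is $(\bar q_{T1} + c)/(\bar q_{T0} + c)$ over normalized means,
with pseudocount $c = 0.5$ (configurable) applied to the fold change
*only*, never to the test — it prevents zero or infinite fold changes on
dropouts without distorting inference. Hairpins whose normalized T0 mean
falls below 30 (configurable) are dropped and reported separately: a
hairpin that never established itself in the population cannot show
depletion, only noise.

## Gene-level hit calling

A gene is called a lethal hit in a line when all four criteria hold
(`hit_criteria()`, defaults shown):

1. at least one hairpin with fold change $< 0.3$ *and* unadjusted
   $p < 0.1$ — significant, strong toxicity from at least one reagent;
2. geometric-mean fold change over the gene's retained hairpins $< 0.8$ —
   the majority of hairpins must lean the same way;
3. gene rank $\le 100$ under second-best ranking — hairpins are ranked
   ascending by log2 fold change (ties broken by smaller p, then hairpin
   id, making the ranking deterministic), each gene is scored by the rank
   of its *second*-most-depleted hairpin, and genes are ordered by that
   score;
4. at least two retained hairpins (single-hairpin genes get a sentinel
   worst rank and can never be hits).

The p threshold is applied unadjusted, and by default it must be met by the
same hairpin that meets the fold-change threshold (the stricter of the two
plausible couplings; `p_scope = "gene"` relaxes it to the gene's minimum p).
Benjamini–Hochberg adjusted p-values are reported alongside but never gate.

### What the hit definition can and cannot reject

The second-best rule exists to stop a single off-target hairpin from
carrying a gene, and it does. But simulations with planted off-target
effects expose a quantified leak worth understanding: one hairpin with a
*strong* off-target effect (true fold change ~0.2) pulls a five-hairpin
gene's geometric mean to $0.2^{1/5} \approx 0.72 < 0.8$ on its own,
satisfies criterion 1 by construction, and on a screen where few genes
carry real effects the rank criterion is weakly competitive (100 of 535
genes pass it by definition). Under the simulator's default 2% off-target
rate, roughly 2–9 such genes per line pass all four criteria. Every one of
them carries a planted effect — in our null simulations the pipeline
produced *zero* pure-noise hits — but at the gene level they are false
positives, and per-line precision against strict gene truth averages ~0.70.
Two things follow. First, single-line hit lists from this (or the
published) criterion set need orthogonal validation with independent
reagents, which is how such screens are actually practiced. Second, the
cross-line comparison largely repairs the problem: off-target effects are
properties of the hairpin and recur in every line, so they surface as
common lethals, not genotype-specific ones.

## Cohort analysis

`build_hit_matrix()` assembles per-line calls into a gene × line boolean
matrix with genotype labels. `common_lethals()` ranks genes by hit fraction
(ties by mean gene rank). `genotype_specific()` scores each gene by

$$ \text{specificity} = \frac{n_\text{hit,mut}}{n_\text{mut}}
 - \frac{n_\text{hit,wt}}{n_\text{wt}} \in [-1, 1], $$

ranking by descending specificity with a two-sided Fisher exact p as
tiebreak. The score, not the p-value, leads: with 9 mutant and 5 wildtype
lines the most extreme table (9/9 vs 0/5) reaches $p \approx 5\times10^{-4}$,
but plausible real patterns (6/9 vs 0/5) do not clear conventional
significance, and the published style of analysis is a ranked short-list,
not a significance claim. In the recovery tests a gene is counted as a
mutant-specific candidate when its specificity score is at least 0.5 —
lethal in at least half the mutant lines more, proportionally, than in
wildtype lines.

`fisher_exact_2x2()` implements the minimum-likelihood two-sided rule
(summing hypergeometric probabilities of all tables with the observed
margins that are no more probable than the observed table), with the same
$10^{-7}$ tie tolerance as the exact test and $p = 1$ on empty margins.
This is the convention under which the sensitivity-by-genotype table
built from 1/5 wildtype and 7/9 mutant sensitive lines gives
$p = 0.0909$.

Drug sensitivity is classified from a single reference dose: relative
growth = mean signal at dose / mean untreated signal (replicates averaged
*before* the ratio, matching how a stained-plate measurement is normalized
to its control), sensitive ⇔ relative growth strictly below 0.5 at 250 nM
by default. No dose-response curve is fitted; the published classification
is a single-dose cutoff and the package follows it.

`sample_size_two_group()` is the normal-approximation closed form
$n = \lceil 2 (z_{1-\alpha/2} + z_{\text{power}})^2 (\mathrm{cv}/\Delta)^2 \rceil$
for comparing two group means whose standard deviation is
$\mathrm{cv} \times$ control mean against a relative reduction $\Delta$;
at $\alpha = 0.05$, power 0.8, $\Delta = 0.5$, cv 0.25 it gives 4 per
group.

## The simulator

`simulate_screen()` generates screens with known truth. Per hairpin, a
log-normal baseline abundance (sd 0.5 in log10 — real hairpin libraries
are strongly skewed, which keeps normalization honest); per sample, a
sequencing depth of coverage × number of hairpins allocated by a
multinomial draw whose probabilities carry gamma noise of the requested
dispersion — the standard gamma-Poisson construction for negative-binomial
marginals, with the fixed depth coupling hairpins the way a sequencing
lane does. T1 expected abundances are the T0 expectations times each
hairpin's true fold change in that line. Planted effects come in three
kinds: common lethals (all lines), genotype-specific lethals (mutant lines
only), and off-target effects — by default 2% of hairpins in non-lethal
genes get a fold change drawn from [0.2, 0.8], attached to the *hairpin*
(the same in every line), since off-target toxicity is a property of the
sequence. Per-hairpin lethal fold changes default to uniform [0.1, 0.3].

Defaults mirror the screening design the package targets: 535 genes × 5
hairpins, triplicates, 14 lines (5 wildtype + 9 mutant in
`simulate_cohort()`), coverage 1000 — i.e. 1000× library representation —
and dispersion 0.05, a typical replicate-level overdispersion for pooled
screens.

What the simulator does *not* emulate: infection and selection dynamics
(MOI, bottlenecking over passages), sequencing error or read-level
artifacts, GC/abundance-dependent amplification bias, correlated hairpin
behavior within genes beyond the planted effect, and partial-knockdown
phenotypes. Passing recovery tests on these simulations therefore
demonstrates that the statistics do what they claim under the stated noise
model — not that any particular wet screen meets that model.

At these defaults, single-hairpin fold-change estimates carry roughly 18%
relative sampling noise (three replicate pairs at coverage 1000,
$\alpha = 0.05$), so accuracy guarantees in the tests are stated for
aggregates — the mean relative error across planted hairpins and the
per-gene geometric means — rather than per hairpin, where ±25% would be
exceeded by noise alone in about a fifth of cases.

## TSS metaprofiles

`tss_matrix()`/`average_profile()` compute strand-aware average signal
around transcription start sites from a base-resolution coverage track.
Conventions, stated once to avoid off-by-one drift: BED and bedGraph are
0-based half-open; the TSS of a `+` feature is its start, of a `-` feature
its end − 1; the window is $[\text{tss}-f, \text{tss}+f)$ with flank
$f = 3000$ bp and 50 bp bins by default (120 bins; the bin width is a
display resolution choice, not a statement about the data). Windows of `-`
regions are reversed so downstream is always rightward. The per-bin
statistic is the *mean* of per-base values, which makes profiles
depth-comparable across window sizes; the per-bin spread is the standard
error over regions. Positions outside the covered genome read zero;
regions on chromosomes absent from the track contribute all-zero rows and
a warning tally rather than an error, since annotation/track chromosome
mismatches are routine. No between-track normalization is applied —
comparability of, say, treated and untreated tracks is the caller's
responsibility.

## Problem sizes and determinism

The test suite runs full-library lines (535 × 5 hairpins at coverage 1000)
where the claim under test is about the screening design, and scaled-down
libraries (50–150 genes) where it is about the statistics; the whole suite
completes in under two minutes on one CPU, and every stochastic test fixes
its seed. `scripts/acceptance.R` re-runs the headline analyses —
full 14-line cohort recovery, no-effect calibration over 10 seeds, the
Fisher association and the sample-size calculation — from a single
command-line seed in a few minutes.

## Known limitations

* The depletion test is the classic two-group conditional exact test: no
  GLM shrinkage, no multi-factor designs, no moderated fold changes. For
  T0/T1 screen designs this is the method the hit criteria were defined
  against; for richer designs use a GLM framework instead.
* Barcode counting is exact substring matching of a fixed-length library
  prefix (default 21 nt): no mismatches, no quality use. Reads matching
  zero or multiple hairpins are discarded (and accounted for). This is a
  deterministic, auditable stand-in for whatever read-assignment a
  sequencing core applies; with real data, compare its discard rate
  against the provider's.
* ΔΔCt assumes amplification efficiency exactly 2 per cycle (exposed as a
  parameter), replicate Cts averaged on the cycle scale; percent-input
  needs the true input fraction (default 1%), and results on real ChIP
  data are meaningless if that fraction is wrong.
* The genotype-association ranking subsumes, but does not pick among,
  plausible short-listing rules (e.g. "no wildtype hits allowed"); it
  returns the full ranked table and leaves the cut to the analyst.
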