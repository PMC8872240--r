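---
title: "Coverage sufficiency for ancient-DNA methylation inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage sufficiency for ancient-DNA methylation inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleometh)
```

## The problem

Post-mortem cytosine deamination lets ancient-DNA data carry an epigenetic
signal: unmethylated cytosines deaminate to uracil (sequenced as T, giving
CpG→UpG-derived patterns), while 5-methylcytosine deaminates directly to
thymine, and does so at a faster rate. The excess of C→T observations at CpG
sites relative to the non-CpG background therefore estimates the local
methylation fraction — without bisulfite treatment, on molecules that no
longer exist in their original state. The practical question `paleometh`
addresses is *how much sequencing coverage this inference needs*: at what
mean genome coverage do per-CpG methylation estimates stop improving enough
to justify further sequencing of a given specimen?

The package answers this with a fully simulated titration: it generates an
ancient-DNA read set with known methylation ground truth, estimates
methylation at the full coverage and at a grid of down-sampled coverages, and
quantifies how fast the down-sampled estimates converge to the full-coverage
ones.

## Generative model

`generate_reference()` builds a chromosome whose background sequence is free
of CG dinucleotides and plants `n_cpg` CpG sites at uniformly sampled,
non-adjacent positions. Making the background CG-free is a deliberate
simplification: the planted coordinate list is then provably exhaustive, so
every downstream component can treat it as a perfect CpG map (on real data
that map comes from the reference genome anyway).

`generate_methylome()` emulates the bimodality of vertebrate methylomes:
consecutive blocks of `block_len` CpGs share one level drawn from
`Beta(8, 2)` (mode near 0.9) with probability `p_high = 0.75`, otherwise from
`Beta(1, 9)`. The defaults reflect the common observation that roughly
three-quarters of vertebrate CpGs are highly methylated while CpG-island-like
regions are nearly unmethylated, and that methylation is locally correlated
on scales much larger than one site. `block_len = 50` makes an NCPG = 25
estimation window usually (but not always) homogeneous, which is the regime
the windowed estimator is designed for.

`simulate_reads()` draws fragments with lognormal lengths (median 55 bp,
truncated to 20–150 bp, typical of ancient libraries), uniform start and
strand, and a Poisson fragment count targeting the requested mean coverage.
Damage is applied in each fragment's own strand frame. A cytosine at distance
$i$ from the fragment's 5′ end deaminates with probability

$$\delta_u(i) = \delta_{bg} + (\delta_{max} - \delta_{bg})\,\lambda^i,
\qquad
\delta_m(i) = \min\{1,\ \rho\,\delta_u(i)\},$$

using $\delta_m$ when the molecule is methylated at that CpG (state drawn per
molecule as Bernoulli($m_s$)) and $\delta_u$ otherwise, so the marginal
conversion probability at a CpG cytosine is
$m_s\delta_m(i) + (1-m_s)\delta_u(i)$. Non-CpG cytosines are treated as
unmethylated — vertebrate non-CpG methylation is negligible, and this
assumption is also what lets the estimator use them as a damage calibrator.
Reverse-strand damage appears as G→A in the forward reference frame. An
independent sequencing error `eps` finally substitutes each emitted base
uniformly among the three alternatives.

Defaults: $\delta_{max} = 0.30$, $\lambda = 0.30$ per position,
$\delta_{bg} = 0.01$, $\rho = 2$, `eps = 0.001`, non-UDG. A well-preserved
sample is emulated by lowering $\delta_{max}$ to 0.15 (the `"SF12-like"`
preset); 0.30 stands for typical preservation (`"ans017-like"`,
`"stuttgart-like"`). $\rho > 1$ is essential: with $\rho = 1$ a non-UDG
library carries no methylation signal at all, and the estimator detects and
reports this non-identifiability rather than returning an arbitrary value.
In `"UDG"` mode deaminated unmethylated cytosines are excised (gaps, not
observations) while 5mC-derived thymines persist; both modes are supported,
and non-UDG is the analysis default since library treatment of typical
specimens cannot be assumed.

Read positions are capped at $I_{max} = 25$: damage is terminal and
geometric, so positions beyond the cap are pooled with it, which bounds all
per-position tables.

## Estimation

`build_pileup()` tabulates C/T observations per cytosine site per read
position, folding reverse-strand sites in as complemented observations and
pooling the two strands of a CpG under the position of its C.
`estimate_damage_profile()` then estimates $\delta_u(i)$ as the pooled T
fraction of non-CpG cytosines at read position $i$ — the empirical,
assumption-light damage calibration.

`mask_mutations()` removes CpG sites whose *interior* observations
($i \ge 10$, where damage is near background) are almost all T
(fraction ≥ 0.9 with ≥ 5 observations): such sites are C>T (or complemented
A>G) genotype variants that would masquerade as full methylation. The rule's
parameters are deliberately conservative; on mutation-free simulations it is
a verified no-op, and its behaviour on hand-built variant pileups is unit
tested. A full genotype-likelihood treatment is out of scope.

`estimate_f()` maximizes, for each focal CpG pooled with its `ncpg = 25`
downstream neighbours (window truncated at the chromosome end), the binomial
likelihood with per-position T probability

$$p_T(f, i) = q + \tfrac{\varepsilon}{3}(1 - q), \qquad
q = f\,\delta_m(i) + (1 - f)\,\delta_u(i)$$

in non-UDG mode, and $p_T(f,i) = f\delta_m(i) + \varepsilon/3$ in UDG mode,
with $\delta_u(i)$ taken from the empirical profile and
$\delta_m(i) = \min(1, \rho\,\delta_u(i))$. $\rho$ is a fixed configuration
constant (default 2), not estimated: the data contain little information to
separate $\rho$ from $f$, and a mis-set $\rho$ rescales $f$ monotonically
without changing the coverage-convergence behaviour that this package
measures. `f_hat` is missing exactly when the focal CpG itself has no usable
observation ("non-covered"); windowed neighbours alone do not rescue a
non-covered focal site.

### Numerical choices

* The likelihood is concave in $f$ (a sum of logarithms of affine
  functions), so the maximizer is found by a dense grid of step $10^{-3}$
  followed by golden-section refinement to $10^{-6}$ within the bracketing
  cells; ties and flat stretches resolve to the smallest maximizing $f$.
* $p_T$ is clamped to $[10^{-300}, 1 - 10^{-12}]$ so zero-probability cells
  with zero counts contribute 0 rather than NaN.
* A profile that assigns zero T probability while T observations exist is an
  error (degenerate input); a profile with $\delta_m \equiv \delta_u$ yields
  a flagged non-identifiable track, never an arbitrary interior estimate.
* All randomness flows from one master seed through fixed per-stage
  sub-seeds; reruns are byte-identical, and this is asserted on written
  artifacts in the tests.

## The titration experiment

`run_experiment()` simulates the full-coverage read set once, then produces
each grid level by Bernoulli thinning with $p = c_{target}/c_{current}$.
Levels are thinned successively out of the next-higher level: composed
Bernoulli thinnings leave every level's marginal distribution identical to
direct thinning of the full set, while making the levels nested, as
successive down-sampling of a single alignment would be. Nesting makes the
non-covered CpG count monotone in coverage within one experiment, and the
equivalence of one-step and two-step thinning routes is checked
statistically in the test suite.

Per level the pipeline re-runs in full (pileup, empirical damage profile,
variant mask, estimation), then:

* $\Delta f_s = f_c(s) - f_{full}(s)$ over sites defined at both levels
  (range $[-1, 1]$, asserted);
* the sample standard deviation (n−1) of $\Delta f$ per level;
* a trendline fit of SD against coverage;
* the threshold rule: with `sd_ref` the SD at the *highest down-sampled
  level below full* — $\Delta f$ at the full coverage itself is identically
  zero, so that is the only non-degenerate reading of "the value calculated
  from the maximum coverage" — recommend the smallest level whose SD does
  not exceed `factor * sd_ref` (default factor 2).

The default trendline is the sampling-theory form
$SD(c) = a\sqrt{1/c - 1/c_{full}} + d$: for an estimator that is
approximately linear in its observations, the excess variance of a nested
subsample at coverage $c$ over the full data is proportional to
$1/c - 1/c_{full}$. Power and exponential families are available as
alternatives (`fit_trendline(form=)`), since the shape of the decay is an
empirical question; `analysis/04_precision.R` reports all three on the same
series. A caveat the experiments make visible: $f$ is bounded in $[0, 1]$,
so at very low coverage (1×, windows with a handful of observations) the
estimate is heavily boundary-clipped and SD($\Delta f$) saturates well below
what the unbounded sqrt-law extrapolates; the sqrt-law's fit quality suffers
accordingly, while the bounded-plateau shape of the exponential family
tracks the measured series more closely. The default nevertheless stays with
the theoretically motivated sqrt-law; the form is a configuration choice,
not a tuning knob.

## Study conditions and scale

The reference conditions used by the tests and the acceptance script are a
0.5-Mb reference with 5,000 planted CpGs (one per 100 bp, comparable to the
genome-wide CpG density of a real chromosome, and a deliberate scale-down
from the ~700k CpGs of a full human chromosome), NCPG = 25, seeds 1–3, and
three sample presets: full coverage 24× with terminal deamination 0.30
(`"ans017-like"`), 38× with 0.15 (`"SF12-like"`), and 19× with 0.30
(`"stuttgart-like"`); each preset's grid is capped strictly below its own
full coverage. One preset run takes tens of seconds on a single core at
these sizes.

Under these conditions the 2×-SD rule recommends 15× for the 24× preset and
20× for the deeply sequenced, weakly deaminated 38× preset — the
well-preserved sample needs *more* coverage, because weak deamination means
fewer informative molecules per site, exactly the preservation paradox the
presets are designed to exhibit.

## What the simulation does and does not show

The generator covers fragmentation, terminal-decay deamination with a 5mC
rate excess, strand symmetry, UDG excision, sequencing error, and Poisson
coverage. It deliberately omits: alignment and mapping error, indels,
reference bias, single-stranded-library 3′ G→A asymmetry, contamination
mixtures, genotype polymorphism (the variant mask is exercised only by
constructed fixtures), CpG-density heterogeneity (islands), and bisulfite
chemistry. Passing tests therefore demonstrate the correctness of the
statistical machinery and the qualitative coverage conclusions under a
clean, known-truth regime — not performance on real alignments, where
mapping artefacts and contamination add error modes this package does not
model.

Absolute accuracy of $f$ at these damage settings is modest (the signal
lives in roughly the first two read positions of each fragment), which is
faithful to the method's real information budget; the titration statistics
are differences against the full-coverage track and are insensitive to this
baseline noise level in their qualitative conclusions.
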