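# paleometh

How much sequencing coverage does an ancient genome need before its
methylation map stops improving? `paleometh` answers this question for
paleoepigenomics — the inference of CpG methylation in ancient specimens from
post-mortem cytosine deamination — with a fully simulated, ground-truth
coverage titration.

In ancient DNA, unmethylated cytosines deaminate to uracil (read as T) while
5-methylcytosines deaminate directly to thymine at a faster rate. The excess
of C→T observations at CpG sites over the non-CpG background therefore
carries the methylation signal. `paleometh` implements:

* **a generative simulator** of ancient-DNA read sets: planted-CpG reference,
  bimodal vertebrate methylome, lognormal fragment lengths, terminal-decay
  deamination δ<sub>u</sub>(i) = δ<sub>bg</sub> + (δ<sub>max</sub> −
  δ<sub>bg</sub>)·λ<sup>i</sup> with methylated rate δ<sub>m</sub>(i) =
  min(1, ρ·δ<sub>u</sub>(i)), both library modes (non-UDG and UDG),
  sequencing error;
* **damage calibration and variant masking**: the unmethylated deamination
  profile estimated from non-CpG cytosines, and removal of C>T / A>G
  genotype variants by an interior-read-position allele-frequency rule;
* **a windowed binomial maximum-likelihood methylation estimator**: per focal
  CpG pooled with its NCPG (default 25) downstream neighbours, maximizing
  the likelihood of the C/T counts under p<sub>T</sub>(f, i) =
  f·δ<sub>m</sub>(i) + (1−f)·δ<sub>u</sub>(i) (+ error terms) over
  f ∈ [0, 1];
* **the coverage titration**: Bernoulli thinning across a coverage grid,
  Δf = f<sub>c</sub> − f<sub>full</sub> per CpG, the sample SD of Δf per
  level, decay trendlines (sqrt-law, power, exponential), and the 2×SD
  threshold rule that turns the SD curve into a minimum-coverage
  recommendation.

Three presets emulate ancient samples of different depth and preservation:
`"ans017-like"` (24×, 30% terminal deamination), `"SF12-like"` (38×, 15% —
exceptionally preserved, hence *less* methylation signal per read), and
`"stuttgart-like"` (19×, 30%).

## Worked example

```r
library(paleometh)
res <- run_experiment(preset_config("ans017-like", seed = 1))
print(res)
```

```
<ExperimentResult> ans017-like: full 24x, grid {1,3,5,10,15,20}, NCPG=25, seed=1
  coverage_level sd_delta_f n_compared n_noncovered
1              1  0.4874170       3075         1925
2              3  0.3993301       4754          246
3              5  0.3603272       4967           33
4             10  0.2933341       4999            1
5             15  0.1944783       4999            1
6             20  0.1371294       5000            0
<TrendFit> sqrt-law: a=0.3847, d=0.1689; R^2 = 0.8674
<CoverageRecommendation> threshold 0.2743 (= 2 x SD 0.1371 at 20x); recommended: 15x
```

Reading the output: at 1× only 3,075 of the 5,000 CpGs have an estimate at
both 1× and full coverage, and the per-site estimates scatter widely around
their full-coverage values (SD(Δf) ≈ 0.49). The dispersion shrinks as
coverage grows; the threshold rule takes the SD at the highest down-sampled
level (0.137 at 20×), doubles it, and recommends the smallest level below
that threshold — here **15×**: sequencing this sample beyond ~15× no longer
moves its methylation track appreciably. The same experiment on the
`"SF12-like"` preset recommends **20×** (median over seeds 1–3): the
better-preserved sample needs *more* coverage because fewer of its molecules
are deaminated.

The numbered scripts under `analysis/` run the study as a narrative
(simulate → damage profile → methylation recovery → titration for all three
presets) and write their tables and figures under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_damage_profile.R
Rscript analysis/03_methylation.R
Rscript analysis/04_precision.R
```

The methods vignette (`vignettes/coverage-sufficiency.Rmd`) documents the
model, its assumptions, the numerical choices, and what the simulation does
and does not establish.

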