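# cel7tools

Comparative analysis toolkit for glycoside hydrolase family 7
cellobiohydrolases (GH7 CBHs) — the processive tunnel-active-site enzymes
that do most of the work in fungal (and industrial) cellulose degradation.
It is written for enzymologists and structural bioinformaticians comparing
close CBH orthologs, where small loop-sequence differences shift
processivity, off-rates and thermal stability.

The package implements four analysis stages plus seeded generators that
make the whole pipeline testable without any external downloads:

1. **Processive kinetics** — a three-state model of pre-steady-state
   cellulose hydrolysis (free enzyme E_f, processively active E_a,
   stalled/bound E_b):

   E_f →(k_on·S) E_a →(k_cat/n) E_b →(k_off) E_f,  dP/dt = k_cat·E_a

   with closed-form simulation, Levenberg–Marquardt fitting of
   (k_on, k_cat, k_off, n) from cellobiose progress curves, correlation
   diagnostics, and seeded parameter-recovery studies. The steady-state
   slope is k_cat·E0 / (1 + (k_cat/n)(1/(k_on·S) + 1/k_off)).
2. **Michaelis–Menten inhibition** — v = Vmax·S/(K_M(1+I/K_ic) + S(1+I/K_iu)),
   fit by statistically weighted least squares (Σ(v_obs−v_calc)²/v_calc)
   with automatic mixed→competitive model selection (K_iu > 10·K_ic) and
   absorbance-to-rate conversion for p-nitrophenol assays.
3. **Reverse conservation analysis (RCA)** — Dayhoff ML distances, NJ trees
   with bootstrap, empirical-Bayes per-site rates (Felsenstein pruning,
   discrete gamma), standardized S scores, 7-column sliding-window W
   scores per lineage, and detection of type-1 divergent sections
   (W ≥ 1 in one lineage, W ≤ 1 in the other).
4. **Structure/trajectory statistics** — superposition, per-residue RMSF
   with 2.5 ns block averaging, native-contact totals (side-chain centroid
   within 6.5 Å of a reference Cα), minimum inter-loop distances with
   histograms, and Cα B-factor profiles mergeable with RCA output.

## Worked example

Fit the processive model to a noisy synthetic progress curve generated from
the published constants of the *T. atroviride* enzyme (3.3 g/L bacterial
cellulose, 50 nM enzyme, 0–200 s):

```r
library(cel7tools)

p    <- processive_params(k_on = 0.0071, k_cat = 8.3, k_off = 0.0071, n = 97)
cond <- assay_conditions(substrate_load = 3.3, enzyme_total = 50)
curve <- gen_progress_curves(p, cond, noise_cv = 0.025, reps = 1, seed = 42)[[1]]
fit_progress_curve(curve)
#> Processive model fit (converged)
#>   k_on  = 0.006762 +/- 0.00044
#>   k_cat = 8.801 +/- 0.62
#>   k_off = 0.006773 +/- 0.00046
#>   n     = 99.08 +/- 3.1
#>   SSR = 0.1187 over 8 start(s)
steady_state_rate(p, 3.3, 50)
#> [1] 24.84458   # nM/s long-time slope
```

The four constants come back within a few percent of the generating values;
the ± values are Jacobian-based standard errors, and `$corr` exposes the
strong parameter correlations typical of burst-phase fits. Inhibition
kinetics on the chromogenic substrate, from a noisy rate grid at the ten
assay substrate levels with and without 100 µM cellobiose:

```r
truth <- mm_params(k_cat = 0.067, enzyme_conc = 0.12, K_M = 0.90, K_ic = 49)
d <- gen_mm_dataset(truth, noise_cv = 0.02, reps = 1, seed = 42)
fit_inhibition(d)
#> Inhibition fit (competitive): weighted SSR 5.119e-05, RMSD 3.08%
#> MM params: k_cat 0.0655 s^-1, [E] 0.12 uM, K_M 0.836 mM, K_ic 47.1 uM, K_iu Inf uM
```

The mixed model was tried first, the fitted uncompetitive constant exceeded
ten times the competitive one, so the competitive model was selected — with
K_i recovered near the generating 49 µM. An end-to-end RCA run on a
two-lineage alignment with a divergent window planted at columns 200–211:

```r
g   <- gen_divergent_alignment(hot_window = c(200, 12, 10), seed = 42)
res <- run_rca_pipeline(g$alignment)
res$scan
#> RCA scan (window 7, threshold 1): 3 divergent section(s)
#>   start end
#> 1   200 209
#> 2   214 214
#> 3   360 361
```

The planted window is recovered at its true location (200–209 plus a
fragment at 214); the short section at 360–361 illustrates the chance calls
that finite per-lineage information produces — see the methods vignette
(`vignettes/cel7tools-methods.Rmd`) for why single narrow sections should
be treated as hypotheses.

A thin command-line wrapper is installed at `exec/cel7`
(`cel7 --help` lists the subcommands: simulate-kinetics, fit-kinetics,
recovery, fit-inhibition, rca, structdyn, synth, report).

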