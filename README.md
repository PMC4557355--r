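# smcount

Single-molecule subunit counting for membrane protein oligomers.

When a fluorescently labelled membrane protein is imaged as immobile,
diffraction-limited particles on a supported bilayer, two observables encode
each particle's number of labelled subunits: its integrated brightness and
the staircase of discrete photobleaching steps in its intensity trace.
`smcount` implements the full inference chain from either observable to the
distribution of true oligomer sizes, developed around the Bax self-assembly
system, where the question is whether the membrane-inserted protein
populates one complex or a ladder of species built from dimer units.

Three mutually independent estimators of the labelled-subunit distribution
$L_m$ are provided:

1. **Constrained Gaussian mixture** — the brightness histogram is fitted by
   $\sum_n A_n\,\mathcal N(i;\, n\mu_1, \sqrt n\,\sigma_1)$ with component
   means and widths pinned to a single-fluorophore calibration
   $(\mu_1, \sigma_1)$ and only the areas $A_n \ge 0$ free (a linear
   nonnegative least-squares problem).
2. **p.d.f. convolution** — an empirical monomer brightness density is
   self-convolved into $N$-mer densities and the sample density decomposed
   on them, with no Gaussian assumption.
3. **Step census** — photobleaching steps are counted after forward–backward
   Chung–Kennedy filtering.

Because only a fraction $p$ of subunits is labelled, $m \sim
\mathrm{Binomial}(N, p)$, and the observed $L_m$ relates to the true size
distribution $S_N$ through $L = B^\top S$ with
$B[N,m] = \binom{N}{m} p^m (1-p)^{N-m}$. `correct_labelling()` solves this
system ($1 \le m, N \le 6$), clips negative solutions to zero and
renormalizes.

The package also contains a ground-truth-annotated synthetic data generator
(movies and traces), sparse-spot detection with Poisson maximum-likelihood
2D-Gaussian fitting, and a particle-based reaction–diffusion simulation of
oligomer assembly on vesicles (Rcpp), validated against a Gillespie
well-mixed oracle.

## Worked example

Simulate a field of 800 particles drawn from a 45% dimer / 35% tetramer /
20% hexamer mixture at 80% labelling efficiency, then run all three
estimators and correct for partial labelling:

```r
library(smcount)
report <- run_pipeline(
  n_particles   = 800,
  species_probs = c("2" = 0.45, "4" = 0.35, "6" = 0.20),
  label_p       = 0.8,
  seed          = 7)
print(report)
```

```
Stoichiometry pipeline report (seed 7, config 000834ef)
  particle density: 0.477 per um^2
Monomer brightness calibration
  mu1 = 1060 counts, sigma1 = 280 counts (n = 176)
  max resolvable stoichiometry n_max = 3 (c = 2)
method gaussian: corrected fractions
   S1    S2    S3    S4    S5    S6
0.027 0.487 0.037 0.297 0.050 0.102
method pdf: corrected fractions
   S1    S2    S3    S4    S5    S6
0.048 0.467 0.082 0.250 0.101 0.052
method steps: corrected fractions
   S1    S2    S3    S4    S5    S6
0.060 0.461 0.072 0.259 0.097 0.053
max pairwise deviation: 0.051
```

The calibration ($\mu_1$, $\sigma_1$, and the number of single-step
particles it used) comes from the data themselves; all three corrected
distributions recover the dominant even-sized species, and the pairwise
deviation quantifies their agreement. With 3,000 particles and three
replicate experiments the Gaussian route recovers each input fraction to a
few percent (see the acceptance script below).

The assembly model runs at the published scale by default:

```r
tc <- run_assembly(assembly_config(seed = 1))   # 7 um box, 1163 Bax, 10 min
luv_occupancy_fraction(tc)                      # fraction of vesicles with Bax
even_odd_mass_ratio(tc)                         # dimer-unit signature
plot(tc)
```

A 1/8-volume, 1/10-duration configuration with identical concentrations
(`box_side_um = 3.5, n_bax = 145, n_cbid = 290, n_luv = 182,
duration_s = 60`) reproduces the model's qualitative behaviour in about two
minutes.

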