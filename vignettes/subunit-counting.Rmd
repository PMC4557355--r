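---
title: "Counting subunits of membrane protein oligomers at the single-molecule level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting subunits of membrane protein oligomers at the single-molecule level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcount)
```

## The problem

A membrane-inserted protein such as Bax assembles into oligomers whose size
distribution is the quantity of biological interest: does the protein sit in
the membrane as monomers, as one defined complex, or as a ladder of species?
When fluorescently labelled protein is imaged on a supported bilayer at
densities where individual particles are diffraction-limited and immobile,
each particle's **integrated brightness** and its **photobleaching
staircase** both encode the number of labelled subunits it carries. `smcount`
implements the complete inference chain from such data to the oligomer-size
distribution, together with a synthetic-data generator and a particle-based
simulation of the assembly process itself, so that every stage can be
validated against known ground truth.

## From brightness to subunit counts

### Monomer calibration

All brightness-based counting rests on the single-fluorophore brightness
distribution. Particles whose intensity trace shows exactly one bleaching
step carry one fluorophore; a Gaussian fitted to the histogram of their
brightnesses gives the monomer mean $\mu_1$ and spread $\sigma_1$
(`calibrate_monomer()`). Because the brightnesses of co-localized
fluorophores add independently, an $N$-mer has mean $N\mu_1$ and standard
deviation $\sqrt{N}\sigma_1$ (`nmer_params()`).

The component overlap grows with $N$: adjacent means stay $\mu_1$ apart
while widths grow as $\sqrt{N}\sigma_1$. We treat components as resolvable
while the separation exceeds $c$ times the component width, giving

$$N_{\max} = \min\!\left(6,\ \left\lfloor\left(\frac{\mu_1}{c\,\sigma_1}\right)^{2}\right\rfloor\right),$$

with $c = 2$ by default and a hard cap of six because brighter species
cannot be assigned a stoichiometry reliably (`max_resolvable()`). The cap
and the factor are configurable; the rule is monotone in $\mu_1/\sigma_1$.

### Constrained Gaussian mixture

`fit_gaussian_mixture()` fits the brightness histogram with

$$\phi(i) = \sum_{n=1}^{N_{\max}} A_n\,
\mathcal{N}\!\left(i;\ n\mu_1,\ \sqrt{n}\sigma_1\right),$$

where **only the areas $A_n \ge 0$ are free** — means and widths are pinned
to the calibration. This turns a notoriously degenerate free-mean mixture
problem into a linear nonnegative least-squares problem with a unique,
stable solution (solved with `pracma::lsqnonneg`). The normalized areas
estimate the fractions $L_m$ of particles carrying $m$ labelled subunits.
Particles brighter than $(N_{\max}+0.5)\,\mu_1$ are excluded from the fit
and reported separately; they indicate species beyond the resolvable range,
not a fit failure.

Numerical choices: bin width $\sigma_1/3$ (fine enough to sample the
monomer peak, coarse enough that bins are well populated at $n \approx
500$–$3000$ particles); design-matrix entries are bin-integrated normal
probabilities rather than midpoint densities, so narrow components are
handled exactly. The test suite checks that fractions move by less than a
few percent under half-bin phase shifts. We examined inverse-variance
weighting of the bins and rejected it: upweighting sparse tail bins
amplifies their Poisson noise and roughly triples the downstream error in
recovered species fractions.

### Model-free p.d.f. fitting

The mixture fit assumes Gaussian components. The p.d.f. route drops that
assumption: an empirical monomer brightness distribution is built from the
level of each trace's **last plateau before complete bleaching** (with
overwhelming probability one remaining fluorophore;
`monomer_reference_from_traces()`), smoothed with a Gaussian kernel of width
$\sigma_1/5$ on a uniform grid of spacing $\sigma_1/20$ over
$[0, (N_{\max}+2)\mu_1]$. The $N$-mer densities follow by $(N-1)$-fold
discrete self-convolution (`build_nmer_pdf()`), and the sample's empirical
p.d.f. is decomposed on these components by nonnegative least squares
(`fit_pdf_mixture()`). Whether the original analysis fitted the density by
least squares or likelihood is not documented; nonnegative least squares on
the density was adopted for symmetry with the histogram method. Last-plateau
levels that still contain two merged fluorophores are removed by a single
median-based trim (values above 1.75 times the median, about mean plus three
standard deviations for realistic brightness spreads).

### Photobleaching step counting

The third, independent route counts discrete bleaching steps. Traces are
denoised with a forward–backward **Chung–Kennedy filter** (`ck_filter()`):
the output at frame $t$ mixes the mean of the preceding $K$ frames and the
mean of the following $K$ frames, weighted by each predictor's inverse mean
squared prediction error raised to a sharpness exponent. On a plateau both
predictors agree (running-mean behaviour); at an edge the straddling
predictor is switched off, so edges stay sharp. Defaults: window $K = 4$
frames (typical working range three to four), exponent 10.

`count_steps()` normalizes the filtered trace by its maximum and segments it
into plateaus. A level drop counts as a bleaching step when it reaches
`min_step_fraction` (default 0.5) of the monomer step and is sustained for
at least two frames. The default 0.5 splits the "one step versus none"
ambiguity symmetrically; it also means that genuinely dim fluorophores —
brightness below half the monomer mean, about 2.3% of fluorophores when
$\mu_1/\sigma_1 = 4$ — are invisible to this method by design.

Several engineering layers sit between the filter and the census, all
validated against constructed staircases:

* candidate edges are scored with two-frame means at a **lower bar** (half
  the acceptance threshold); acceptance itself uses plateau-level
  differences, which average over many frames and are far less noisy
  (hysteresis);
* change-point positions and plateau levels are estimated on the **raw**
  trace, because the filter smears plateaus shorter than its window;
* a level change larger than 1.25 monomer units triggers a two-edge refit
  (a merged double step); the split is kept when it improves the squared
  error by more than eight noise variances — below that, the best
  constrained two-edge refit of pure noise wins too often;
* short plateaus entered and left by opposite-signed changes with agreeing
  flanking levels are pruned as noise transients (bleaching never steps
  back up);
* the census (`census_from_steps()`) uses only **fully bleached** traces
  (final level below half a monomer unit): an unbleached fluorophore hides
  one step, so incomplete traces systematically undercount.

Simultaneous bleaches within the temporal resolution merge into one step and
are deliberately **not** corrected by step-size quantization; the only
correction applied to the census is the labelling correction below.

### Correction for partial labelling

Only a fraction $p$ of subunits carries a functional fluorophore (typically
0.7–0.8 for maleimide labelling), so an $N$-mer presents $m \sim
\mathrm{Binomial}(N, p)$ labelled subunits. With $B[N,m]$ the binomial
matrix (`binomial_matrix()`), observed fractions $L_m$ and true fractions
$S_N$ are linked by $L = B^{\!\top} S$ over $1 \le m, N \le 6$.
`correct_labelling()` solves this square triangular system exactly, sets any
negative solution components to zero, and renormalizes — negative entries
arise from measurement noise and indicate an absent species. The `clipped`
attribute records when this happened.

Unlabelled particles are invisible, so the observed $L$ is conditioned on
$m \ge 1$. By default the raw binomial rows are used and the solution is
renormalized afterwards; `condition_on_detection = TRUE` instead divides row
$N$ by $1-(1-p)^N$ before solving. The two differ measurably for
$p \lesssim 0.7$; both are provided because the original procedure cannot be
determined from its description. Note that the inversion amplifies noise:
small anticorrelated errors in adjacent $L_m$ produce large oscillations in
$S_N$, which is why replicate experiments should be averaged **after**
correction (the reference protocol averages at least three experiments; the
acceptance checks do the same over three seeds).

## What the generator emulates — and what it does not

`sample_ground_truth()`, `render_movie()` and `synthesize_traces()` produce
ground-truth-annotated data with the statistical structure the analysis
assumes: immobile particles with a minimum separation; true sizes drawn from
a configurable species distribution; binomial labelling; one brightness draw
per fluorophore from a positive-truncated $\mathcal{N}(\mu_1, \sigma_1)$
(particle-to-particle variation — this is what makes the monomer histogram
width $\sigma_1$); single-step irreversible exponential photobleaching;
integrated-Gaussian pixel rendering; Poisson shot noise plus Gaussian read
noise, clipped at zero.

Defaults mirror the reference acquisition: 500 frames of 1 ms illumination
at 91 ms spacing, $\mu_1 = 1000$, $\sigma_1 = 250$ counts
($\mu_1/\sigma_1 = 4$), labelling $p = 0.8$. The mean bleaching lifetime is
not documented for the original setup; the default of **150 frames** was
chosen so that up to six sequential bleaching events usually resolve within
a 500-frame acquisition while bleaching still completes with high
probability ($P(\text{survive}) = e^{-500/150} \approx 3.6\%$ per
fluorophore). Trace noise defaults to $\mu_1/3$, i.e. a step-to-noise ratio
of 3 for a typical monomer step.

Not modelled, hence not validated by passing tests: blinking and other
reversible dark states, EMCCD gain-register noise, diffusing particles,
evanescent-field depth profiles, astigmatic or otherwise non-Gaussian PSFs,
day-to-day illumination drift. Real data also violate the independence of
brightness and position (field inhomogeneity) and can contain aggregates
far brighter than hexamers; the brighter-than-cutoff exclusion count is the
package's handle on the latter.

A consequence worth stating plainly: under these study conditions the step
census carries an intrinsic deficit that the labelling correction does not
model — dim fluorophores below the 0.5-monomer threshold, bleaches in the
first frame, and near-simultaneous bleaches each hide a step. An idealized
counter applying this package's own counting rules perfectly still
misattributes several percent of the corrected mass from even to odd
species, so on synthetic data the census agrees with the brightness methods
to within roughly 0.1 per species rather than the few percent the two
brightness methods achieve between themselves. The brightness methods are
unaffected because every labelled fluorophore contributes its brightness
whether or not its step is resolvable.

## Spot detection and photometry

`detect_spots()` implements the standard sparse-emitter chain — Gaussian
smoothing, local maxima, threshold above the frame median, minimum
separation with brighter-wins ties, border exclusion. `fit_spot_mle()`
refines each candidate by maximizing the Poisson likelihood of a
bin-integrated 2D Gaussian plus flat background (L-BFGS-B); the reported
brightness is the fitted volume $2\pi A \sigma^2$, robust to background in a
way fixed-aperture sums are not. Particles are immobile, so
`measure_movie()` fits the position once on the average of the first five
frames and then refits brightness per frame at fixed position by linear
least squares — the per-frame problem is linear in (brightness, background),
and the 100-fold speedup over per-frame MLE costs little at these
signal-to-noise ratios. The per-particle brightness used for histogramming
is the mean over the frames before the first detected bleaching event
(`initial_brightness()`).

## The assembly simulation

`run_assembly()` is a particle-based reaction–diffusion engine (written in
C++ via Rcpp) for the self-assembly model: soluble monomers (Bax), soluble
activator (cBid) and vesicles (LUVs) diffuse in a reflective box; particles
are volume-less points and second-order reactions fire on encounter within a
binding radius (`binding_radius()` inverts the Smoluchowski rate
$k = 4\pi D r$, floored at the vesicle radius of 0.1 µm because geometric
contact dominates at these scales). The published geometry is the default:
a 7 µm box, 1,163 Bax, twice as many cBid, 1.25× as many LUVs, 50 µs steps,
10 minutes.

The reaction scheme encodes the dimer-unit hypothesis:

* soluble activator binds any vesicle on contact and unbinds at
  `k_cbid_off`;
* soluble monomer binds a vesicle **only** if that vesicle carries bound
  activator or already-bound protein (autoactivation) — each vesicle hosts
  at most one complex, and an arriving monomer joins it;
* a bound monomer detaches at `k_mono_off` unless dimerization has
  stabilized it; complexes shrink at `k_shrink`;
* parity bias is applied symmetrically: growth **into** an even size is
  favoured by the multiplier `even_stabilization` (capture probability 1
  versus $1/\text{multiplier}$ into odd sizes) and dissociation **out of**
  an even size is slowed by the same factor. At multiplier 1 the dynamics
  are parity-blind.

The kinetic parameter values behind the published figure live in a
supplementary table that is not part of the available text; the defaults
here ($k_\mathrm{mono,off} = 1\,\mathrm{s}^{-1}$,
$k_\mathrm{shrink} = 0.1\,\mathrm{s}^{-1}$, multiplier 10, $D_\mathrm{cBid}
= 100$, $D_\mathrm{Bax} = 60$, $D_\mathrm{LUV} = 2.5$ µm²/s, contact-radius
binding) are demonstration values chosen once to land in the qualitative
regime of the published model — partial vesicle occupancy and even-size
enrichment — and are all explicit configuration. Boundary conditions
(reflective) and the release distance after unbinding (1.5 binding radii)
are likewise undocumented in the source and chosen here.

Correctness is checked against a hand-written Gillespie implementation of
the reduced scheme $A + L \rightleftharpoons AL$
(`well_mixed_reference()`) and its closed-form stationary distribution
(`equilibrium_bound_fraction()`). In the fast-diffusion limit the
fixed-step engine's effective association rate is
$\tfrac{4}{3}\pi r^3/\Delta t$ (`wellmixed_on_rate()`) — successive
positions decorrelate, so the per-step reaction probability is the volume
fraction of the binding sphere — and the engine's equilibrium occupancy
matches the oracle to within a few percent. Mass conservation is asserted
inside the engine at every sample.

Problem sizes: the tests and the acceptance script exercise the engine at
1/8 of the published box volume and particle counts for 1/10 of the
published duration (a 3.5 µm box, 145/290/182 particles, 60 s), which
preserves all concentrations; the full-scale configuration is the default
of `assembly_config()` and runs unchanged, only longer. At this desk scale
with the default rates the simulation reproduces partial vesicle occupancy
(roughly a quarter of vesicles carry protein) and strong even-size
enrichment, and with multiplier 1 the even/odd mass split is statistically
indistinguishable from parity blindness.

## Known limitations

* $N_{\max}$ is capped at six; octamers and beyond are counted in the
  exclusion tally only.
* The binomial inversion assumes $p$ is known exactly; uncertainty in $p$
  is not propagated.
* The step census under-counts in proportion to the dim-fluorophore
  fraction and the bleach-time collision rate, as quantified above; its
  corrected distribution is best treated as a cross-check on the brightness
  methods, which is how the original study used it.
* The assembly engine resolves encounters at one event per particle per
  step; at the default time step the fastest species moves about one
  vesicle radius per step, which slightly under-samples encounters (the
  engine warns). The well-mixed validation quantifies the residual at a few
  percent.
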