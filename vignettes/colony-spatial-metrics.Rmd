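---
title: "Quantifying filamentous growth with CSR-normalised spatial metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying filamentous growth with CSR-normalised spatial metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(colonymetrics)
```

## The measurement problem

Dimorphic yeasts such as *Saccharomyces cerevisiae* switch, under nitrogen
or glucose limitation, from budding as a compact colony to producing
pseudohyphae: chains of unseparated cells that radiate outward from the
colony margin, and that may also invade the agar. Conventional assays
summarise this phenotype by colony area or volume, which says how much the
colony grew but not *where* — two colonies of equal area can be a smooth
disk and a star of filaments. colonymetrics quantifies the spatial
patterning itself, from a top-view binary mask of a single colony: each
image pixel is a lattice site, occupied (1) where the colony covers it.

## The model: counts normalised against complete spatial randomness

A colony at one time point is an occupancy grid: a set of occupied integer
lattice sites inside a disk of radius $R$ centred on the colony's centre
of mass, where $R$ is the largest distance from the centre to an occupied
site. With $n$ occupied sites the mean-field density is
$\rho = n / (\pi R^2)$. Every metric asks the same question: *compared
with $n$ sites scattered uniformly at random over the same domain (the
complete spatial randomness, CSR, state), where are the occupied sites
over- or under-represented?* Each metric is a binned count divided by its
CSR expectation, so 1 means "as random", above 1 aggregation, below 1
segregation.

* **Radial metric.** Distances $|\mathbf v|$ of the occupied sites are
  counted in $L$ equal-width annular bins over $[0, R)$; the count in bin
  $i$ is divided by $\rho\,\pi\Delta_r^2(2i-1)$, the bin's area times the
  density. On an annular domain $R_A \le |\mathbf v| \le R$, the annulus
  density $\rho_A = n/(\pi(R^2 - R_A^2))$ and the bin's annular area
  replace the disk quantities.
* **Angular metric.** Principal arguments $\arg \mathbf v$ are counted in
  $M$ equal sectors over $[-\pi, \pi)$ and divided by
  $\tfrac12 \rho\, \Delta_\theta R^2$. Its bin mean is exactly 1 by
  construction. On an annulus the same full-disk normalisation is kept
  (with $\rho$ recomputed from the retained sites), so sector values stay
  comparable across domains.
* **Angular pair-correlation metric.** For every unordered pair of
  occupied sites the pair angle
  $\Theta = \arccos(\mathbf v_1 \cdot \mathbf v_2 / |\mathbf v_1||\mathbf v_2|) \in [0, \pi]$
  is counted in $N$ equal bins and divided by
  $\tfrac12 \rho_s \Delta_\Theta R^2 (\pi \rho_s R^2 - 1)$ — the total
  pair count spread evenly over the bins. Because pairs grow as
  $O(n^2)$, a random subsample of $n_s$ sites (effective density
  $\rho_s = n_s/(\pi R^2)$) can be analysed instead; sampling is without
  replacement from the deterministic row-major site order under a user
  seed, so results are reproducible.

The radial and pair-correlation metrics are rotation invariant; the
angular metric is the one that knows orientation, which is what lets it
locate individual filaments.

## From signals to indices

A growing colony's radial signal is above 1 through its fully occupied
core and falls below 1 in the sparse filamentous margin. `find_r_csr()`
locates the crossover radius $R_\mathrm{csr}$: the last downward crossing
of 1 after which the signal stays below 1 for at least `persistence`
consecutive bins (or through the final bin), linearly interpolated between
the bracketing bin midpoints. Four scalar indices summarise a colony:

| index | definition | reads as |
|---|---|---|
| $I_r$ | $1 - R_\mathrm{csr}/R$ | radial extent of the margin relative to the colony |
| $I_\theta$ | $\sum_{k=1}^{M/2} |\hat f_k|^2$ | total angular spectral power at nonzero wavenumbers |
| $I_\Theta$ | $F_\Theta(1) - 1$ | excess of near-zero pair angles: sites sharing a filament |
| $I_a$ | $1 - \rho$ | unoccupied area fraction (no spatial information) |

$\hat f_k$ are the discrete Fourier coefficients of the angular metric,
$\hat f_k = \frac{1}{M c_k}\sum_j F_\theta(j) e^{-ikx_j}$ for
$k = 0, \pm1, \dots, \pm M/2$, evaluated at the bin edges
$x_j = -\pi + 2\pi j/M$, with half weight $c_k = 2$ on the endpoint modes
so that the inverse transform over all modes reconstructs the signal
exactly (verified to $10^{-9}$ in the tests). $\hat f_0 = 1$ always;
$I_\theta$ sums positive wavenumbers only. Two mode filters support
inspection of the angular signal: a low-pass filter $|k| < \alpha$ and a
dominant-mode filter $|\hat f_k|^2 > \beta$, which isolates the
characteristic angular wavelength of the filaments. Their defaults
($\alpha = 10$, $\beta = 0.03$) are midpoints of the ranges that are
useful at $M = 200$; both are ordinary user parameters.

`analyze_colony()` chains the whole per-colony workflow: full-disk radial
metric → $R_\mathrm{csr}$ → annulus $R_\mathrm{csr} \le |\mathbf v| \le R$
→ angular metric, spectrum and pair metric on the annulus → one tidy
record. The annulus restriction matters: over the full disk the angular
metrics are dominated by the fully occupied core and barely see the
margin. `summarize_sample()` averages records across colonies (mean ± SEM,
with the $(n-1)$-denominator standard deviation) and fits a degree-6
polynomial per trajectory for display; the fit never feeds back into any
index.

```{r worked}
g <- four_cluster_pattern(l = 21, R = 150)
density_summary(g)
rad <- radial_metric(g, L = 50)
rad[22:24, ]
```

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `L` | 180 (or $R/\Delta_r$ with $\Delta_r \approx 4.6$ µm for micron-scaled images) | bins | radial resolution; the bin width sets the precision of $R_\mathrm{csr}$ |
| `M` | 200 | bins | angular resolution; more bins admit higher wavenumbers and raise $I_\theta$ for the same pattern, so compare colonies only at fixed `M` |
| `N` | 200 | bins | pair-angle resolution; $I_\Theta$ uses only the first bin, so `N` sets the angular scale "local" refers to |
| `n_s` | 1000 (exhaustive when $n \le 5000$) | sites | pair subsample; exhaustive pairs are exact and still cheap below a few thousand sites |
| `persistence` | 3 | bins | how many consecutive below-unity bins confirm the CSR crossover; 1 reproduces the idealised single-crossing rule, 3 ignores single-bin noise |
| `length_scale` | 1 | physical units / pixel | applied to reported distances ($R$, $R_\mathrm{csr}$) only; every metric and index is dimensionless and unaffected |

All computation happens in lattice units. The micron-per-pixel factor of a
given imaging setup must be supplied by the user; none is assumed.

## Numerical choices

* **Binning.** All bins are half-open $[a, b)$ with a closed last bin:
  the site at exactly $R$ (which always exists, $R$ being the maximum
  occupied distance) and antipodal pairs at exactly $\Theta = \pi$ are
  counted rather than dropped.
* **Centre.** The centre of mass is kept real-valued; rounding it to a
  lattice site would bias the first radial bins by up to half a pixel.
* **Pair angles.** The cosine argument is clamped to $[-1, 1]$ before
  `acos`; floating-point dot products of near-parallel vectors can exceed
  1 by rounding.
* **Sites at the exact centre.** A zero-magnitude position vector has no
  direction: it is assigned $\theta = 0$ in the angular metric, excluded
  from pairs, and both events are reported.
* **Empty annulus.** A colony that is uniform out to its rim has
  $R_\mathrm{csr} = R$ and no annulus; $I_\theta$ and $I_\Theta$ are set
  to 0 and flagged (`annulus_empty`) rather than erroring, so time
  courses stay rectangular.
* **Degenerate radial signals.** Never above 1 → $R_\mathrm{csr} = 0$;
  never persistently below 1 → $R_\mathrm{csr} = R$ (so $I_r = 0$,
  matching the early-time regime where the colony is uniform).
* **Filtered reconstructions** are real by mode-set symmetry; imaginary
  residue above $10^{-9}$ of the signal scale signals a corrupted mode
  set instead of being silently discarded.

## The synthetic generators, and what passing tests show

The generators produce every validation input in code:

* `random_disk()` / `random_annulus()` place exactly
  $\mathrm{round}(\rho \pi R^2)$ (or the annular analogue) distinct sites
  uniformly at random — exact-$n$ sampling keeps the realised density on
  target, which makes the CSR calibration sharp; per-site Bernoulli
  occupation is available as an option.
* `four_cluster_pattern()` is the deterministic reference pattern: four
  fully occupied $l \times l$ squares (odd $l$, so each has a central
  lattice site and exactly $l^2$ sites) centred on the circle of radius
  $R/2$. Its four-fold symmetry drives the rotation-invariance tests.
* `filamentous_colony()` is a phenomenological filamentous colony: a
  fully occupied core disk, optionally a ragged rim whose occupancy
  tapers linearly over `core_taper` pixels, straight radial arms of given
  directions, angular half-width and occupancy, and a sparse background.
  Arm membership is decided by circular angular distance, so arms at the
  $\pm\pi$ branch cut behave like any other.
* `colony_time_course()` grows a colony through strictly increasing
  times: a uniformly expanding (tapered) disk until an onset time, then
  elongating arms. Per-site random draws are fixed once and every
  occupancy probability is nondecreasing in time, so colonies are nested
  — a site never empties. Arms can switch on one by one (`arm_stagger`)
  and densify gradually (`maturation`), which is what makes the angular
  and pair indices rise over the filamentation period rather than jump:
  real filaments emerge and fill in over tens of hours, they do not
  appear fully formed.

These generators emulate geometry and sampling noise, not biology: there
is no nutrient field, no cell-scale mechanics, no curvature or branching
of filaments, and arms are straight radial strips. A passing test
therefore shows that the metrics recover *planted* structure of the kind
the generator can express — known core/margin ratios, known arm
directions, monotone filamentation — at realistic sizes and densities. It
does not show that real micrographs are segmented correctly (the package
assumes an already-binary mask), nor that straight-arm recovery rates
transfer to strongly curved or branching filaments.

Generator conditions used by the validation suite, chosen once as
representative of late-stage colonies at the scale of the reference
patterns: domain radius $R = 150$ with core radius 75; thin arms
(half-width 0.008 rad, about 2 px at the rim) at occupancy 0.9–0.95 over
a background of 0.005–0.01; a 3 px rim taper; time courses over 20–240 h
with onset at 100 h, core growth 0.2 px/h, arm growth 0.5 px/h, arms
staggered 10 h apart and maturing over 60 h. The angle-recovery
experiment uses 50 replicates of 2–8 arms separated by at least 0.15 rad
at $M = 200$; the CSR calibration uses 10 domains at $\rho = 0.1$,
$R = 150$ with $L = M = N = 30$ and $n_s = 100$. These sizes keep each
experiment in the seconds-to-a-minute range on one core.

## Design choices where the design was open

* **$R_\mathrm{csr}$ rule.** For clean signals any crossing rule agrees;
  for noisy margins we take the *last* downward crossing that persists,
  because filamentous margins genuinely hover around 1 near the core
  boundary and the outermost persistent crossing is what separates core
  from margin. Interpolation between bin midpoints removes the half-bin
  quantisation.
* **Four-cluster radial maximum.** The reference pattern's radial counts
  are constant (252 sites per 3-unit bin) across the clusters' radial
  support $[64.5, 86.1]$, so after dividing by the growing annulus area
  the normalised signal is highest in the first fully covered bin,
  $[66, 69)$ — at the inner edge of the aggregation plateau that is
  centred on $R/2 = 75$. The worked example reports the bin actually
  attaining the maximum.
* **One-sided $I_\theta$.** The index sums positive wavenumbers only.
  Conjugate symmetry means the two-sided sum is simply twice this (plus
  the endpoint subtlety); the one-sided form is kept because its values
  are the ones meaningfully compared across colonies.
* **Parseval bookkeeping.** With the $1/(Mc_k)$ coefficient convention
  the exact identity is $M \sum_k c_k |\hat f_k|^2 = \sum_j F_\theta(j)^2$
  (endpoint modes at half weight counted twice); the test suite asserts
  this form.
* **Sextic trend fits** are display-only. Six is the lowest even degree
  that tracks the flat–rise–saturate shape of index trajectories over
  eight or more time points without ringing; with 8 points it leaves one
  residual degree of freedom, so the curve is a guide, not an estimate.
* **MAT container support.** Experimental stacks stored as MATLAB v5
  files are read by a purpose-built minimal reader (largest 4-D
  numeric/logical array wins, matching the loose internal naming of such
  files); v7.3/HDF5 files and big-endian files are rejected with clear
  errors. The package's own plain-text container is the lossless
  round-trip format.

## Known limitations

* Metrics are undefined for an empty domain, and the pair metric needs at
  least two off-centre sites; the contracts error early and explicitly.
* $R_\mathrm{csr}$ on a *perfectly* uniform colony is noise-driven — the
  signal hovers at 1 and the crossover can land anywhere. Real colonies
  (and the generator, via its rim taper) have margins that keep the core
  solidly above 1, which is what makes the estimate stable.
* $I_\theta$ depends on $M$ by construction; cross-study comparisons must
  fix the bin count.
* Averaging angular *signals* across differently oriented colonies
  washes out structure (the average approaches 1 as the sample grows);
  average the per-colony *indices* instead, which is what
  `summarize_sample()` does.
* The package does not segment raw micrographs; masks must be binary on
  input, and a more-than-two-level image is rejected rather than
  thresholded silently.
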