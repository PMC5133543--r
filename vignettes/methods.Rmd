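---
title: "Models and methods behind incellfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind incellfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

incellfold implements, at desk scale, the full computational path from
non-uniformly sampled (NUS) NMR time-domain data to a Bayesian posterior
ensemble of protein structures: maximum-entropy spectral reconstruction with
automatic regularization selection, NOESY peak assignment by chemical-shift
matching, NOE intensity-to-distance calibration, torsion-space simulated
annealing, replica-exchange Monte Carlo (REXMC) refinement with per-spectrum
nuisance parameters, and ensemble analytics. This vignette describes the
models, their assumptions, the tunable parameters, and what the synthetic
benchmarks do and do not demonstrate.

## Maximum-entropy reconstruction of undersampled planes

A 2D plane is reconstructed by estimating a nonnegative spectrum $h$ on the
full $n_1 \times n_2$ grid from the measured subset of time-domain points
$D_p$. We minimize

$$C(h) = L(h) - \lambda S(h), \qquad
  L(h) = \tfrac12 \sum_{p \in \text{schedule}} |\mathrm{IDFT}(h)_p - D_p|^2,
  \qquad
  S(h) = \sum_i \left[ h_i - A - h_i \log(h_i/A) \right],$$

with the Skilling entropy relative to a flat default level $A$ (by default
the estimated time-domain noise $\sigma$). Note that $L$ is the *raw*
residual: the noise does not scale the objective. It enters instead through
the evidence used to select $\lambda$, so that $\lambda$ itself carries the
error weighting of the data — a larger measurement error yields a larger
selected $\lambda$ and a smoother spectrum. (If $\sigma$ were folded into
$L$, the selected $\lambda$ would *shrink* with growing noise while the
effective smoothing $\lambda\sigma^2$ grew; the chosen parameterization
keeps the intuitive reading of $\lambda$ as the weight of prior
information against data error.)

$\lambda$ is chosen by maximizing a Laplace-approximated log-evidence
$$\log p(D \mid \lambda) \approx -\frac{C(h^*)}{\sigma^2}
  + \tfrac12 \log\det\!\big(2\pi H^{-1}\big),$$
where $h^*$ is the optimum for that $\lambda$ and $H$ is the Hessian of the
$\sigma^{-2}$-scaled objective at $h^*$, approximated by its diagonal
$n_s/(N^2\sigma^2) + \lambda/(\sigma^2 h^*_i)$. The search scans a
log-spaced grid (default $\sigma^2 \cdot [10^{-3}, 10^{3}]$, 9 points) and
refines the bracket around the argmax by golden-section search. Two
numerical choices matter here:

* **Optimizer.** The objective's curvature contains $\lambda/h$, which blows
  up near the nonnegativity bound and defeats plain projected gradient
  descent. We use the classic entropy-metric preconditioner: descent along
  $-h \odot \nabla C$ with a monotone backtracking line search (the
  objective never increases across iterations), stopping at a relative
  objective change below $10^{-9}$ (cap 4000 iterations). During the
  golden-section refinement the solves are tightened to $10^{-12}$, because
  the evidence surface is nearly flat within $\pm 15\%$ of the optimal
  $\lambda$ and solver noise would otherwise dominate the refinement.
* **Cold starts.** Every evidence evaluation starts from the flat spectrum
  $h = A$, so the evidence is a well-defined function of $\lambda$,
  independent of evaluation order. A fallback to the grid argmax is taken
  only when a competitive interior second mode appears (within 1% of the
  evidence range); edge bumps at extreme $\lambda$ are under-converged
  solves, not modes.

The time-domain noise is estimated as the median absolute deviation (scaled
to a Gaussian $\sigma$) of the real and imaginary parts in the late half of
the sampled increments, where decaying signals contribute least. Peak
picking reports 8-neighborhood local maxima above a threshold multiple of
the noise, in ppm via the axis metadata.

Only 2D planes are handled; 3D spectra would be processed plane by plane.
Quadrature/hypercomplex bookkeeping of real acquisition schemes is out of
scope; the synthetic data are complex grids with absorption-mode positive
peaks, so negative-lobe spectra are not covered by the tests.

## Polypeptide model

Conformations live in torsion space: bond lengths, bond angles, and the
peptide bond $\omega = 180^\circ$ are fixed at template values (an
ECEPP-like internal-coordinate table embedded in `R/geometry.R`), and the
degrees of freedom are $\phi$, $\psi$, $\chi_1$, $\chi_2$ per residue.
Cartesian coordinates are built by sequential internal-to-Cartesian (NeRF)
placement; the first residue sits in a canonical frame (N at the origin,
C$\alpha$ on $+x$, C' in the $xy$-plane). Side chains beyond $\chi_2$ are
frozen at anti conformations; aromatic rings are placed as rigid bodies;
proline's ring is frozen near a C$\gamma$-endo pucker and its $\phi$ remains
formally rotatable (the CD–N closure is not a template bond), which slightly
over-frees proline backbones. Torsion-to-coordinate-to-torsion round trips
are exact to $10^{-6}$ degrees and built residues satisfy the
L-amino-acid chirality test.

The physical prior replaces an atomistic force field with two terms:

$$E(X) = k_\text{rep} \sum_{\text{nonbonded } i<j}
  \max(0,\; r^\text{min}_{ij} - r_{ij})^2
  + k_\text{tor} \sum_\theta (1 + \cos 3\theta).$$

The repulsion runs over heavy-atom pairs more than four bonds apart
(protons ride their heavy atoms; the depth-4 exclusion covers rigid rings),
with $r^\text{min}_{ij} = 0.62\,(R_i + R_j)$ from per-element van der Waals
radii — the scaling keeps hydrogen-bonded O$\cdots$H backbone contacts at
~2.0 Å from counting as clashes. Defaults: $k_\text{rep} = 1$,
$k_\text{tor} = 0.05$, energies in units of $k_BT$ at the reference
temperature. The solvent dielectric constant 78.5 is recorded in
`prior_params()` for completeness but the surrogate has no electrostatic
term. This prior plays the same *role* as a force field plus implicit
solvent in the Bayesian scheme — the posterior is driven by the data — but
no equivalence with any published force field's energies is claimed.

## NOE interpretation

Peaks are matched against proton shifts with per-dimension tolerances
(defaults 0.04 ppm for ^1^H, 0.4 ppm for ^13^C/^15^N); a peak's assignment
options are the cross-product of matching protons, minus self-pairs. A
simplified network-support filter retains a long-range option ($|i-j| \ge
2$) only if at least `min_support` other candidate peaks link a neighboring
residue pair ($|i-i'| \le 1$, $|j-j'| \le 1$); this is a deliberate
simplification of network anchoring, not a reproduction of it.

Calibration uses the isolated-spin-pair relation $I = C/r^6$: the upper
bound is $\mathrm{clip}((C/I)^{1/6},\, 2.4,\, 6.0)$ Å (van der Waals
contact to NOE detection limit), and auto-calibration solves
$C = \mathrm{median}(I) \cdot 4^6$ so the median derived distance is 4.0 Å,
the midrange of observable NOEs. Sequence-range classes follow
$|i-j| = 0/1/2\text{–}4/\ge 5$ for intra/sequential/medium/long. Ambiguous
candidates become one restraint whose effective distance is the
$r^{-6}$-summed $r_\text{eff} = (\sum_\text{options} r^{-6})^{-1/6}$; the
target function is the sum of squared bound violations plus weighted
squared dihedral-interval violations (default weight 0.0025 Å²/deg²).
Hydrogen-bond restraints are never generated.

## Conventional calculation and Bayesian refinement

The conventional stage is multi-start Metropolis annealing in torsion space
on `target + 0.05 * prior`, a surrogate for torsion-angle dynamics filling
the same role (global minimization from random starts). Schedules are
geometric: temperature 50 → 0.1 in target-function units, single-torsion
move width 30° → 2°; defaults 100 starts × 10,000 steps (tests and the
pipeline scale these down). The lowest-target conformer seeds the
refinement.

The refinement samples the joint posterior over the conformation $X$ and,
per spectrum $s$, a log-calibration $c_s = \ln C_s$ and noise scale
$\sigma_s$:

$$\log \pi \;=\; \sum_s \sum_{k \in s}
  \left[-\frac{(\ln I_k - c_s + 6 \ln r_{\text{eff},k}(X))^2}{2\sigma_s^2}
        - \ln \sigma_s\right]
  + \sum_s \log N(c_s;\, \mu_0, \tau_0^2)
  + \sum_s \log \mathrm{IG}(\sigma_s^2;\, \alpha_0, \beta_0)
  - E(X).$$

The likelihood is normal on log intensities. That choice makes the normal
prior on $c_s$ and the inverse-gamma prior on $\sigma_s^2$ *exactly*
conjugate, respects intensity positivity, and matches the multiplicative
intensity noise of the generator. Both nuisance parameters are Gibbs-updated
(every 10 steps by default); under tempering by $\beta$, the normal
conditional's precision scales by $\beta$ and
$\mathrm{IG}(a, b) \mapsto \mathrm{IG}(\beta(a{+}1){-}1,\, \beta b)$.
Hyperparameter defaults: $\mu_0$ from auto-calibration, $\tau_0 = 2$ (log
units), $\alpha_0 = 2$, $\beta_0 = 0.5$.

Conformations move by a mixture proposal: with probability 0.8 a Gaussian
perturbation of one torsion (sd 10°), otherwise a small correlated Gaussian
kick of all torsions (sd 1.5°) — a symmetric surrogate for the
molecular-dynamics leg of a hybrid scheme, exactly detailed-balance correct.
$K$ replicas temper the *full* log-posterior by $\beta_k = T_1/T_k$ on a
geometric ladder (the production setting, 10 replicas over 300–400 K, is
available; the desk-scale default is 4 replicas, $2 \times 10^5$ steps).
Adjacent replicas attempt swaps every 100 steps with probability
$\min(1, \exp((\beta_i - \beta_j)(U_i - U_j)))$, $U = -\log\pi$. Snapshots
are recorded from the coldest chain every `stride` steps;
`burn_and_thin()` keeps post-burn stride multiples (a production-scale
bookkeeping — $10^7$ steps, burn $10^6$, one conformer every 5000 —
yields 1800 states by this rule). The MAP state is the recorded maximum;
all randomness flows from one R RNG seed (a single stream rather than
per-replica streams — determinism per seed is what reproducibility here
needs).

## Ensemble analytics

Superposition is Kabsch via SVD with a reflection guard. The mean structure
is iterative (superpose all members on the current mean, re-average, repeat
to $10^{-6}$ Å); it is defined up to a global rigid motion fixed by the
first member's frame. Per-residue RMSD profiles superpose globally on the
backbone (N, C$\alpha$, C') first, then report per-residue means and
standard deviations across members; the side-chain selection is the
$\beta$–$\epsilon$ carbons plus side-chain nitrogens, deliberately omitting
$\zeta$ atoms. PCA operates on flattened selected-atom coordinates after
superposition, without mass weighting. Subsampling keeps
$\lfloor fN \rfloor$ members uniformly without replacement, preserving
order.

## Synthetic data and what the tests show

The generators provide complete ground truth: three clash-free presets with
frozen torsion tables (a 12-mer β-hairpin, a 16-mer helix-turn-helix whose
helical residues sit exactly at $(\phi,\psi) = (-60°, -45°)$, and a 20-mer
two-strand fold), shift tables drawn from per-proton-class normal ranges
with controllable degeneracy (non-degenerate tables are resampled until all
proton pairs separate by > 0.045 ppm, widening the class ranges when the
packing is too tight), NOE peak lists with $I = C_s/r^6 \cdot \varepsilon$,
$\ln\varepsilon \sim N(0, \sigma_s^2)$, for all proton pairs within 5.5 Å
(classed into amide- and carbon-bound 2D ^1^H–^1^H lists as the desk-scale
stand-in for the three 3D NOESY types), and NUS time-domain data as
decaying complex sinusoids on a schedule plus complex Gaussian noise.

Because every proton pair under the cutoff yields a peak, the presets carry
a denser restraint net (roughly 25 per residue) than real spectra provide;
recovery under these conditions demonstrates the correctness of the
machinery — exact restraint recovery at zero noise, sub-Ångström fold
recovery, calibration constants recovered within posterior uncertainty —
not the performance to be expected from sparse, artifact-laden in-cell
data. Likewise the generators contain no spin diffusion, no background
signals, and no assignment errors beyond shift degeneracy, so passing tests
bound the algorithmic, not the experimental, error.

Problem sizes in the shipped tests were chosen for a laptop-class single
core: reconstructions on 32×32 and 48×22 grids, annealing at 8–20 starts ×
4000–5000 steps, refinement at 4 replicas × $2\times10^5$ steps, and a
10-seed repetition of the end-to-end benchmark.

## Known limitations

No stereospecific assignment or pseudo-atom handling; `HN` is accepted as
an alias of `H` in restraint files but pseudo-atoms (`QB` etc.) are not
expanded. Side chains stop at $\chi_2$; cis-proline and non-standard
residues are unsupported. The MaxEnt stage assumes positive
absorption-mode spectra. The network filter and the hybrid move are
documented simplifications of network anchoring and of hybrid Monte Carlo
respectively. The evidence for $\lambda$ uses a diagonal Laplace
approximation; it implements the selection principle, not any specific
published implementation of it.
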