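# incellfold

Protein structure determination from in-cell NMR data, at desk scale.

In-cell NMR observes isotope-labeled proteins inside living cells, but the
data are sparse and noisy: measurement time forces non-uniform sampling
(NUS) of the indirect dimensions, strong background signals bury weak NOESY
cross peaks, and few distance restraints survive to the structure
calculation. `incellfold` implements the computational chain that copes
with this regime:

1. **Maximum-entropy reconstruction** of undersampled 2D planes by
   minimizing `C(h) = L(h) - lambda * S(h)` (Skilling entropy `S`, residual
   `L`), with `lambda` selected automatically by maximizing a
   Laplace-approximated evidence `log p(D | lambda)` — noisier data yield a
   larger `lambda` and a smoother spectrum.
2. **NOESY interpretation**: chemical-shift matching of peaks (tolerances
   0.04 ppm for 1H, 0.4 ppm for 13C/15N) with ambiguity, a network-support
   filter, and NOE calibration by `I = C / r^6` with clipping to
   [2.4, 6.0] Å.
3. **Torsion-space simulated annealing** against the restraint target
   function (sum of squared bound violations) from many random starts.
4. **Bayesian refinement** by replica-exchange Monte Carlo over the joint
   posterior of the conformation and per-spectrum nuisance parameters
   (log-calibration `c_s = ln C_s`, noise `sigma_s`): a normal likelihood
   on log intensities, a normal prior on `c_s`, an inverse-gamma prior on
   `sigma_s^2` (both exactly conjugate, so Gibbs-updated), and a
   soft-sphere + torsion physical prior on the conformation.
5. **Posterior-ensemble analytics**: burn-in/thinning, MAP extraction,
   Kabsch superposition, mean structure, global and per-residue RMSD, PCA,
   and display subsampling.

A synthetic-data module generates ground-truth structures, shift tables,
NOE peak lists, and NUS time-domain data with known parameters, so every
stage is testable end to end without experimental data.

## Worked example

The whole pipeline on a synthetic 12-mer beta-hairpin scenario — simulate
NOESY peak lists with 10% multiplicative intensity noise, assign and
calibrate them, anneal, refine with 4 replicas, and analyze the posterior
ensemble:

```r
library(incellfold)
cfg <- pipeline_config(outdir = "run1", seed = 5,
                       n_starts = 8, n_steps = 4000,
                       rexmc_steps = 5e4, noe_sigma = 0.1)
res <- run_pipeline(cfg)
str(res$report)
#> List of 4
#>  $ n_conformers         : int 400
#>  $ rmsd_to_mean         : num 0.0356
#>  $ map_log_posterior    : num 1725
#>  $ pc1_variance_fraction: num 0.481

# how close is the maximum-a-posteriori structure to the generating truth?
smap <- read_pdb_model(file.path("run1", "map.pdb"))[[1]]
truth <- read_pdb_model(file.path("run1", "reference.pdb"))[[1]]
kabsch_superpose(smap, truth, select_atoms(smap, "backbone"))$rmsd
#> [1] 0.0679
```

`n_conformers` is the size of the thinned posterior ensemble sampled at
300 K; `rmsd_to_mean` (Å) measures how tightly the ensemble clusters
around its mean coordinates; `map_log_posterior` is the log-density of the
best sampled state; and `pc1_variance_fraction` is the share of coordinate
variance captured by the first principal component of the ensemble. The
final line shows that the refined maximum-a-posteriori structure lands
within 0.07 Å backbone RMSD of the structure that generated the data.

The run directory also holds the fixtures (`shifts.prot`, `*.peaks`),
calibrated restraints (`restraints.upl`), the annealing seed (`seed.pdb`),
the full ensemble and a 20% display subsample (multi-model PDB), per-residue
RMSD and PCA tables (TSV), and a resolved `config.yaml` that reproduces the
run exactly.

A thin command-line front end wraps the same functions:

```sh
exec/incellfold simulate --preset hairpin12 --seed 1 --outdir run2
exec/incellfold assign --peaks run2/noesyN.peaks,run2/noesyC.peaks \
    --shifts run2/shifts.prot --out run2/restraints.upl
exec/incellfold anneal --seq KTFTVNGKTYTE --upl run2/restraints.upl \
    --n-starts 20 --n-steps 5000 --seed 1 --out run2/seed.pdb
```

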