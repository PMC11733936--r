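---
title: "Estimating ligand off-rates from temperature-scaled unbinding simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ligand off-rates from temperature-scaled unbinding simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offrate)
```

## The problem

The dissociation rate constant $k_\mathrm{off}$ — equivalently the
residence time $1/k_\mathrm{off}$ — of a protein–ligand complex is a
pharmacodynamic driver in its own right: a drug that stays bound keeps
acting after free concentration drops. Measured residence times span
milliseconds to hours, far beyond what equilibrium molecular dynamics can
reach. This package implements a temperature-scaling strategy: run many
short replicas hot enough that every ligand unbinds within a few
nanoseconds, measure *when* each replica unbinds, and map the resulting
rate back to room temperature.

## Model and assumptions

**Population scaling.** At equilibrium the population of a microstate $x$
is $P(x) \propto e^{-\beta V(x)}$ with $\beta = (k_B T)^{-1}$. Simulating
at an elevated temperature $T_\mathrm{sim} = \lambda T_\mathrm{ref}$ is
equivalent to scaling the potential by $1/\lambda$, so the scaled-run
populations $P^*(x)$ relate to the reference ones by an element-wise power:
$P(x) \propto P^*(x)^{\lambda}$, renormalized. `reweight_population()`
implements exactly this.

**Rate scaling.** For rates we assume an Arrhenius law with a
barrier-independent prefactor, $k \propto e^{-\beta \Delta V^\ddagger}$.
Raising the temperature by $\lambda$ divides the exponent by $\lambda$, so
on the log scale

$$\log_{10} k(T_\mathrm{ref}) = \lambda \, \log_{10} k(T_\mathrm{sim}) + c,$$

which is `reweight_log_rate()`. The additive constant $c$ collects the
prefactor and the unit convention; it cancels in differences between
ligands and is otherwise absorbed when predictions are min–max normalized
onto an experimental range (`normalize_to_reference()`). This log-linear
form is the unique one consistent with the population relation above under
the common-prefactor assumption. Predictions are therefore *relative*:
rank orders and differences are meaningful, absolute placement requires
normalization against a few known ligands.

**Median first-passage estimator.** Each replica contributes the time at
which its ligand first leaves the bound state. If unbinding is a
single-barrier escape, these times are exponentially distributed and the
population median is $\ln(2)/k$; `rate_from_median_time()` inverts that.
The median (rather than the mean) is robust to the handful of replicas
that dawdle or never unbind. Replicas still bound at `t_max` are
*censored*: under the default policy they enter the order statistics at
`t_max`, which can only push the median up, never down — dropping them
would bias the rate fast. The estimate is flagged `RELIABLE` only when
strictly more than half the replicas unbound, so the sample median cannot
sit on a censored value; otherwise it is a `LOWER_BOUND` and
`estimate_koff()` refuses it unless explicitly overridden (the remedy is a
hotter or longer protocol, see `temperature_scan()`).

**Thermodynamic side-car.** $\Delta G = RT\ln K_d$ (with
$R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, 1 M standard state) and
$K_d = k_\mathrm{off}/k_\mathrm{on}$ connect off-rates to affinities.
Free-energy conversions default to 298 K — the convention under which a
10 nM binder is $-10.9$ kcal/mol — while kinetic reweighting defaults to
$T_\mathrm{ref} = 300$ K. A $k_\mathrm{off}$–$K_d$ correlation is only
expected when $k_\mathrm{on}$ is roughly constant across the series, which
empirically holds within series of similar binding modes; the
`filter_rules()`/`per_target_range_normalize()` helpers exist to restrict
benchmark sets to that regime (dropping, e.g., kinase inhibitors whose
type-1/type-2 classification changes the protein conformation, and
targets with a single data point, which cannot be range-normalized).

## The unbinding protocol and its parameters

`build_simulation_spec()` assembles the production protocol:

| parameter | default | meaning |
|---|---|---|
| `temperature_K` | required (600–1000 typical) | scaled simulation temperature |
| `total_time_ns` | required (1–5 typical) | per-replica simulation length |
| `time_step_fs` | 2 | NVT Langevin integration step |
| `n_replicas` | 32 | independent replicas per ligand |
| `sigma_A` | 3.0 | backbone restraint width (Å) |
| `site_cutoff_A` | 6.0 | binding-site residues left unrestrained |
| `frame_interval_ps` | 10 | trajectory save interval |

Backbone restraints prevent the protein from unfolding before the ligand
leaves at these temperatures. `sigma_A` is interpreted as the standard
deviation of a harmonic positional restraint, giving the
Boltzmann-consistent force constant $k = k_B T_\mathrm{ref}/\sigma^2$ per
coordinate (≈ 0.066 kcal mol$^{-1}$ Å$^{-2}$ at the defaults). This
interpretation is a design choice — restraint conventions vary between
engines — and both `sigma` and the derived constant are recorded on the
spec so a backend can apply whatever it natively supports. Residues with
any heavy atom within `site_cutoff_A` (inclusive) of any ligand heavy atom
in the *initial* pose are freed whole; the site is not recomputed per
frame. The thermostat friction (default 1 ps$^{-1}$) is configurable
because no single value is canonical.

Replica $i$ receives seed `base_seed + i - 1` and identical physics
(`plan_replicas()`), so runs parallelize trivially and results cannot
depend on execution order.

## Analysis chain

Trajectory frames are superposed protein-to-protein onto the **first
frame of each trajectory** (Kabsch fit; `superpose_to_first_frame()`) —
not onto the input pose, a deliberate convention since the first saved
frame already reflects the heated ensemble. Ligand RMSD
(`ligand_rmsd_series()`) uses heavy atoms only, with no ligand fitting,
and frame $f$ carries time $f \times$ `frame_interval` (the first frame is
one save interval into the run). A ligand is unbound past a 5.0 Å RMSD
cutoff; `detect_unbinding()` additionally requires the excursion to
persist for `persistence` frames (default 5, i.e. 50 ps at the default
interval) before calling the unbinding time, reported as the *first* frame
of the sustained excursion (earliest-evidence convention). `persistence =
1` recovers the bare single-cutoff rule; an excursion truncated by the end
of the trajectory never qualifies. Both the persistence window and the
censoring policy are exposed as options because reasonable protocols
differ on them.

`temperature_scan()` encodes protocol calibration: among candidate
temperatures, pick the lowest at which every reference ligand has a
`RELIABLE` median inside the target window (e.g. medians within ≤ 4 ns per
replica) — lowest, because less scaling means less distortion of the
landscape.

## The toy layer: what it emulates and what it does not

`toy_potential()` + `simulate_escape()` provide a desk-scale stand-in for
the expensive MD stage: overdamped (Euler–Maruyama) Langevin dynamics in a
one-dimensional metastable well, in reduced units ($k_B = 1$, energies in
$k_B T_\mathrm{ref}$). The well is a harmonic basin joined
$C^1$-continuously to an inverted parabola of height
$\Delta V^\ddagger$; the join point and barrier position follow from the
curvatures and height, so varying the height at fixed curvatures leaves
the Kramers prefactor untouched and rate ratios are purely Arrhenius —
the property the reweighting step assumes, here by construction. The
closed-form oracle is

$$k = \frac{\omega_a \omega_b}{2\pi\gamma} e^{-\Delta V^\ddagger / k_B T},$$

exact for overdamped dynamics in the high-barrier limit; below
$\Delta V^\ddagger / k_B T = 3$ the saddle-point approximation degrades
and `kramers_rate()` warns. Escape is absorbed one reduced length beyond
the barrier top with no re-entry, mirroring the irreversible reading of
the 5 Å cutoff. The stability bound `dt < 0.1/γ` is enforced at
construction.

The scripted-trajectory generator (`make_scripted_trajectory()`) covers
the other half of the pipeline: coordinate trajectories with a known
departure frame, optional single-frame recrossing excursions, rigid-body
motion of the whole complex, and Gaussian coordinate noise. On noise-free
scripts the analysis chain recovers the departure time exactly, which the
tests assert.

What the toy layer does **not** emulate: solvent, force fields,
multi-dimensional exit pathways, protein flexibility, rebinding kinetics,
or any chemistry. Passing toy-level tests validates the *statistics* of
the estimator — censoring behaviour, Arrhenius recovery, rank fidelity —
not predictive accuracy on real complexes, which requires a production MD
backend and experimental benchmarks.

## Numerical choices and problem sizes

- Escape simulations use `dt = 0.005` reduced time; the first-passage
  discretization error at this step is far below the sampling noise of a
  64-replica median.
- Paired base seeds (common random numbers) are used when two barriers are
  compared, the standard variance-reduction device for relative rates;
  with 64 replicas it roughly halves the spread of the reweighted
  difference.
- Verification sizes were chosen to make sampling noise a small fraction
  of the quantity under test while keeping the whole suite interactive:
  64 replicas for rate differences and rank checks (matching the
  production default of up to 32 per ligand, doubled for tighter
  medians), 128 per temperature for the Arrhenius-linearity fit over
  $T \in [0.7, 1.5]$ with $\Delta V^\ddagger = 5$, and 256 for the
  absolute Kramers-rate comparison.
- Arrhenius-recovery checks use barriers of 9 and 11 $k_B T_\mathrm{ref}$
  at $\lambda = 3$ so that $\Delta V^\ddagger / k_B T_\mathrm{sim} \ge 3$
  on both sides of the comparison, inside the Kramers validity domain;
  lower barriers acquire a visible non-Arrhenius bias (the escape stops
  being a rare event), which is a property of the physics, not of the
  estimator.
- Ties in screening ranks are broken by stable input order and counted;
  ROC AUC gives ties half credit (midrank/Mann–Whitney convention).
- $R^2$ is the squared Pearson correlation of observed vs predicted (the
  scatter-plot convention, invariant to the affine freedom of relative
  predictions), not $1 - SS_\mathrm{res}/SS_\mathrm{tot}$; error bands
  are boundary-inclusive.

## A minimal end-to-end run

```{r pipeline}
cfg <- tempfile(fileext = ".yaml")
yaml::write_yaml(list(
  backend = "toy", t_sim = 3, t_ref = 1,
  n_replicas = 32, base_seed = 1, dt = 0.005, t_max = 1000,
  ligands = list(list(id = "slow", barrier_height = 7),
                 list(id = "fast", barrier_height = 5)),
  output_dir = tempfile("run")), cfg)
res <- suppressMessages(run_pipeline(cfg))
res$results[, c("ligand_id", "tau_median", "quality", "log10_koff_ref")]
```

The slower dissociater (higher barrier) ends up with the smaller
reweighted $\log_{10} k_\mathrm{off}$, and rerunning the same config
reproduces the table bit for bit: all randomness flows from `base_seed`,
and the audit JSON records the config hash, seeds and package version.

## Known limitations

- The reweighting assumes a common prefactor and a temperature-independent
  barrier; entropic barriers or unbinding mechanisms that change with
  temperature violate it, and nothing in the statistics will flag that.
- Absolute rates are not predicted; the offset $c$ must come from
  normalization against known ligands.
- Censoring-heavy runs (`LOWER_BOUND`) indicate the protocol, not the
  estimator, is inadequate — raise the temperature or lengthen replicas.
- The trajectory readers cover DCD and multi-model PDB; XTC input is not
  supported.
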