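---
title: "Modular Kuramoto networks: methods and design notes"
author: "kuranet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular Kuramoto networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kuranet)
```

# The model

kuranet studies synchronization on *two-scale* oscillator networks. Each
of $n$ nodes is a population of $N$ Kuramoto phase oscillators, all-to-all
coupled at intrinsic strength $K_i$; nodes interact through a directed,
weighted adjacency matrix $A$ scaled by a global coupling $\kappa$:

$$
\dot\theta_{ik} \;=\; \omega_{ik}
  \;+\; K_i\, r_i \sin(\psi_i - \theta_{ik})
  \;+\; \kappa \sum_j A_{ij}\, r_j \sin(\psi_j - \theta_{ik}),
$$

where $r_i e^{i\psi_i} = \frac1N \sum_k e^{i\theta_{ik}}$ is node $i$'s
complex order parameter. The intra-node term is the exact mean-field
identity of the all-to-all sine coupling; for the inter-node term we use
the driving node's mean field directly (the form the thermodynamic-limit
reduction assumes; the microscopic per-oscillator double sum divided by
$N$ is equivalent as $N \to \infty$). Natural frequencies are i.i.d.
normal with mean $\Omega$ and standard deviation 1 for every node; order
parameters are invariant under shifts of $\Omega$ (co-rotating frame), so
the default is $\Omega = 0$.

**Orientation convention.** `A[i, j]` couples node $j$'s mean field into
node $i$ — row = receiver. Every reader, writer, solver and generator in
the package uses this convention.

The motivation is electrophysiology: a scalp electrode sums the activity
of a locally dense cortical patch (one node of strongly coupled
oscillators), and electrodes/regions interact through a sparse directed
large-scale network. Emergent high-amplitude collective oscillation is
the model's proxy for seizure-like hypersynchrony, while the incoherent
state produces low-amplitude irregular signals (`node_signal()` sums
$\sin\theta$ over a node's oscillators to emulate the recorded trace).

# Mean-field theory

In the limit $N \to \infty$, oscillators with $|\omega| \le X_i$ lock to
the mean field, where
$X_i = K_i r_i + \kappa \sum_j A_{ij} r_j$
(`effective_drive()`) is the node's total locking field. Integrating the
frequency density $g(\omega)$ against the cosine of the locked phase
offsets over that window gives the self-consistency relation
$r_i = F(X_i)$ with

$$
F(X) \;=\; \int_{-\pi/2}^{\pi/2} g(X \sin\varphi)\, X \cos^2\!\varphi
  \; d\varphi .
$$

For the standard normal density this evaluates in closed form through
modified Bessel functions,

$$
F(X) \;=\; X \sqrt{\tfrac{\pi}{8}}\; e^{-X^2/4}
  \left[ I_0\!\left(\tfrac{X^2}{4}\right)
       + I_1\!\left(\tfrac{X^2}{4}\right) \right],
$$

which `self_consistency_map()` uses by default; adaptive quadrature of
the integral form is available for any symmetric unimodal density and
must agree with the Bessel route to $10^{-8}$ (a standing test). The
quadrature works in the phase variable $\omega = X\sin\varphi$, splitting
the integration at the density's support edges so that discontinuous
densities (e.g. uniform) pose no difficulty. Asymmetric densities are
rejected: the phase-alignment argument that makes all nodes lock in
phase — and makes the global order parameter equal $\frac1n \sum_i r_i$
beyond onset (`global_order_parameter()`) — relies on symmetry and
non-negative weights. Below onset we define the analytic global order
parameter as 0 by the same formula.

`solve_mean_field()` iterates the map with damping 0.5 from the all-ones
vector. The map is monotone for non-negative weights, so iteration from
an upper seed descends onto the largest fixed point: the locked branch
when it exists, otherwise the zero branch (always a fixed point). The
residual tolerance is $10^{-10}$ with a cap of $10^4$ iterations;
convergence slows within about 0.1% of a critical point, where the cap
triggers a diagnostic error rather than a silent bad answer. Converged
components below $10^{-6}$ are reported as exactly 0; branch selection
(`"zero"` vs `"locked"`) follows.

## Critical couplings

An isolated node synchronizes at $K_c = 2 / (\pi g(0))$
($\sqrt{8/\pi} \approx 1.5958$ for the standard normal). The package
computes this two independent ways (`single_node_critical_coupling()`):
the linearized slope condition in closed form, and bisection on $K$ with
a nonlinear existence test (a positive crossing of $K F(X) - X$ on a
fine logarithmic grid of drive values, which avoids the critical slowing
down that plagues fixed-point iteration near the onset).

When every node is individually sub-critical ($K_i < K_c$), linearizing
$r_i = F(X_i)$ around the incoherent state gives $D r = \kappa A r$ with
$D = \mathrm{diag}(K_c - K_i)$ positive definite. Non-trivial solutions
appear where $\det(D - \kappa A) = 0$; equivalently
$\kappa_c = 1/\lambda_{\max}(D^{-1} A)$ with $\lambda_{\max}$ the largest
real positive eigenvalue (`kappa_c_eigen()`). Because $D^{-1}A$ is
non-negative, the spectral radius is attained by a real non-negative
eigenvalue (Perron–Frobenius), which the solver uses as an internal
cross-check. A second, independent route scans the determinant on a
400-point logarithmic grid spanning $[10^{-3}, 10^3] \cdot (K_c - \max_i
K_i)$ and bisects the first sign change (`kappa_c_determinant()`); the
determinant is evaluated on the max-normalized matrix so rounding noise
does not grow like $\kappa^n$ on nilpotent adjacencies. Both routes agree
to $10^{-6}$ on random strongly connected test graphs.

Closed forms for elementary motifs (`motif_kappa_c()`): the general
two-node pair gives
$\kappa_c = \sqrt{(K_c - K_1)(K_c - K_2)/(a_{12} a_{21})}$, the
symmetric unit pair $\kappa_c = K_c - K$, and the $n$-cycle the
geometric mean of $(K_c - K_i)/a_i$ — equal to the two-node value for
unit weights and uniform $K$.

**Network-driven vs node-driven synchronization.** A finite $\kappa_c$
requires a cycle: a strongly connected component of size $\ge 2$ in the
positive-weight digraph (`classify_scenario()`). Hierarchical (DAG)
networks have nilpotent adjacency, all eigenvalues zero, and
$\kappa_c = \infty$: collective synchrony can then only be *node-driven*
— seeded by a node whose own $K_i$ exceeds $K_c$ and propagated
downstream (`node_driven_scan()`).

# Numerical simulation

`simulate_network()` integrates the phase equations with fixed-step RK4
(compiled), default $dt = 0.01$ time units; the dynamics are non-stiff
and a fixed step keeps runs exactly reproducible. Phases are stored
wrapped to $[0, 2\pi)$, optionally thinned (`store_every`) to bound
memory. Initial phases are i.i.d. uniform from the seed. Reported
coherence values discard the first half of a run as transient and
time-average the rest (`simulated_mean_r()`).

Test and verification scales: $N = 10^3$ oscillators per node for
routine tests, $N = 10^4$ for single-node oracle comparisons, and
$N = 5000$ for the two-node onset study; sweeps run 80 time units per
coupling value, extended to 200 within ~25% above the predicted onset,
where critical slowing down stretches the locking transient well past
the usual equilibration time. These sizes make the finite-size
fluctuation floor
($\sim N^{-1/2}$) small against the locked-branch values being checked.

**Onset detection at finite N.** Below $\kappa_c$ the time-averaged
order parameter is not flat: the $N^{-1/2}$ incoherent floor is
amplified by the linear-response susceptibility
$1/\sqrt{1 - \text{gain}}$, with gain
$(K + \kappa\lambda_{\max})/K_c$, and measurably so at $N = 5000$ (the
sub-critical value roughly quadruples between $\kappa = 0$ and
$0.9\,\kappa_c$). `empirical_onset()` therefore tests each sweep point
against the susceptibility-scaled finite-size baseline (calibrated off
the lowest-coupling point, saturated at its largest finite value beyond
the linear regime) plus three standard deviations, rather than against a
flat floor that would fire on sub-critical fluctuation growth well
before the transition. Detection then lands on the first sweep point
with macroscopic coherence, within one grid step above the analytic
$\kappa_c$.

# Functional network inference

The inference pipeline (`infer_functional_network()`) mirrors standard
resting-state EEG practice: zero-phase 4th-order Butterworth filtering
(band-pass 1–70 Hz, 48–52 Hz notch in `preprocess_recording()`; band
table delta 1–3, theta 3–6, low alpha 6–9, high alpha 9–12, beta 12–25,
gamma 25–70 Hz in `band_split()` — the two physiologically printed bands
plus a conventional subdivision of the rest, fully overridable).
Forward–backward filtering is essential here: phase distortion would
corrupt the lag estimates that carry all directionality information.

Edge weights are maximum time-lagged cross-correlations: for each
channel pair, the Pearson correlation of the overlapping segments at
every lag in $\pm$`max_lag` (default 200 ms — physiological conduction
delays), taking the maximum absolute value and its lag
(`lagged_crosscorr()`). Overlap normalization keeps every lag's value in
$[-1, 1]$. Ties in $|corr|$ break toward the smallest $|$lag$|$, then
the negative lag, making output deterministic. `best_lag > 0` means the
first channel leads and is assigned the source role.

**Significance.** Finite segments of autocorrelated signals produce
spurious lagged correlations. The null is built per pair from IAAFT
surrogates (`iaaft_surrogate()`): iterative alternation between imposing
the original amplitude spectrum and restoring the original value
multiset, stopping early once the rank ordering is stationary. The
surrogates preserve each channel's spectrum (hence autocorrelation)
while destroying cross-channel correlation; a pair is kept iff its
observed statistic beats the surrogate ensemble at the rank-test level
$\alpha$ (`significance_mask()`).

Defaults: 99 surrogates, 100 IAAFT iterations, $\alpha = 0.01$. The
level is the strictest a 99-surrogate rank test supports, and the choice
is deliberate: with 171 channel pairs in a 19-channel montage, a 5%
per-pair level would admit roughly eight false pairs per recording —
overwhelming the handful of true edges a sparse directed structure
carries, and indirect-path pruning cannot remove unstructured false
edges. At 1% the expected false count is below two while genuinely
coupled pairs (correlations several times the null scale) are retained;
the surrogate test's calibration is itself verified at both levels by
the test suite.

**Directionalization and pruning.** Each retained pair becomes one
directed edge, leader as source; pairs with best lag exactly 0 are
dropped entirely, since instantaneous correlation is the signature of
volume conduction from a common source rather than directed interaction
(`directionalize()`). Finally `prune_indirect()` removes a direct edge
when a stronger 2-edge path exists (evaluated on the original weights,
removals applied together), then repeats for 3-edge paths on what
remains. Path strength is the bottleneck — the minimum edge weight along
the path — a scale-free weakest-link reading; a product rule is
available by configuration. Pruning is idempotent and never adds edges.

# Synthetic data

The package generates every input it needs.

*Linear lagged recordings* (`make_lagged_truth()`,
`gen_lagged_recording()`) are the primary inference test bed, matching
the predominantly linear character of resting-state EEG that motivates a
correlation-based method in the first place. Each channel is a
band-limited AR(1) innovation (coefficient 0.95 — a 1/f-like background
that gives the surrogate test real autocorrelation to control for) plus
gain-weighted lag-delayed parent channels plus white measurement noise
(sd 0.1 against unit-variance innovations). Default scale mirrors a
routine clinical segment: 19 channels (10–20 montage labels), 20 s at
256 Hz, 10 planted edges of gain 0.8 with distinct lags of 4–40 samples.
Planted edges form *disjoint chains* of at most three edges: chains
emulate propagating activity, their indirect (skip) correlations are
exactly what the pruning stage is built to remove, and they avoid
common-driver fan-outs with unequal lags — a structure whose
inter-sibling correlations no chain-pruning rule can attribute, and
which a correlation-based method cannot disambiguate even in principle.
Passing recovery tests on this generator therefore demonstrates correct
mechanics of the pipeline, not robustness to every confound of real EEG
(volume conduction beyond zero-lag mixing, nonstationarity, and common
drivers remain outside its scope).

*Kuramoto recordings* (`gen_kuramoto_recording()`) run the full
oscillator model and emit per-node summed-sine signals, optionally
splicing a sub-critical and a super-critical coupling regime mid-run to
emulate a background-to-seizure transition; they exercise the nonlinear
path qualitatively.

*Cohorts* (`gen_cohort()`): control subjects get sparse random
DAG-dominant digraphs — forward edges along a random hierarchy with
probability 0.165 (about 28 edges per 19-node network, sparse like
pruned functional networks), each gaining a reciprocal partner with
probability 0.1. Case subjects use the same generator with reciprocal
probability 0.1 + 0.55·effect: more reciprocal edges mean more strongly
connected components and stochastically lower $\kappa_c$. Effect 0 makes
the groups exchangeable by construction. These rates were fixed once at
design time so that the full-effect cohort at the study's group sizes
(35 vs 40) separates decisively while effect 0 stays at the nominal
type-I level.

# Cohort analysis

Per subject, two model-based measures: the critical global coupling of
the subject's network with all intrinsic couplings fixed at $0.5 K_c$
(`subject_kappa_c()`; lower = closer to synchronization = more
seizure-prone; $\infty$ is legal and means purely hierarchical flow),
and the node-driven scan (`node_driven_scan()`), which seeds each node
in turn at $2 K_c$ (the others at $0.5 K_c$), solves the mean-field
system at a scan coupling of $\kappa = 0.4$, and records the global
order parameter. The sub-/super-critical factors bracket $K_c$
comfortably on either side; the scan coupling sits below the global
onset of the control generator's networks (their median $\kappa_c$ is
near 1), so any synchrony the scan finds is attributable to the seeded
node. All three are configuration, not constants.

Group comparison uses the two-sided Wilcoxon rank-sum test (exact for
small tie-free samples, normal approximation with tie and continuity
corrections otherwise). Scores are rank-transformed before the call so
that infinite critical couplings keep their extreme rank instead of
being dropped — a rank test is invariant under this. Multiplicity is
handled by Bonferroni only (`bonferroni()`), with the node-driven family
corrected by the number of electrodes. Significant measures get ROC
analysis (`roc_analysis()`): full threshold sweep, trapezoid AUC,
operating point closest to perfect classification (ties toward higher
sensitivity), PPV / FDR / sensitivity / specificity at that point. For
the critical coupling, *lower* is case-like and $+\infty$ sorts as most
control-like; for node-driven synchrony, *higher* is case-like; the
direction is explicit per measure.

# Known limitations

- The mean-field solver reports existence of the locked branch, not its
  stability, and uses the single locked-cluster ansatz throughout (no
  drifting-cluster corrections).
- No time-delayed coupling, no noise term in the phase equation, no
  amplitude dynamics.
- Inference assumes the dependence structure is visible to lagged
  correlation; common drivers with unequal lags and genuinely nonlinear
  coupling are out of reach by design.
- Recordings are read and written as CSV; EDF files should be converted
  upstream.
- Within about 0.1% of a critical coupling the damped fixed-point
  iteration hits its iteration cap and raises an error instead of
  returning a half-converged value.
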