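---
title: "Methods: PRE-driven reweighting and analysis of a fuzzy IDP-receptor ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRE-driven ensemble reweighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical numbers beyond those the test
suite and `scripts/acceptance.R` themselves compute.

## The scientific problem

A long intrinsically disordered protein (IDP) chain binds a folded
four-helix-bundle receptor through several short helical motifs, each able
to occupy either of two binding faces. The bound chain remains largely
disordered — a *fuzzy complex* interconverting between a small number of
anchored configurations (here four, with the central motif always bound).
No single structure represents such a system; the analysis target is a
weighted conformational ensemble whose frame weights are refined against
intermolecular PRE data and then propagated into every derived quantity:
state populations, contact statistics, a clustered conformational
landscape, and residue-wise conformational entropy.

## PRE forward model

Transverse PRE rates are computed per frame from the Solomon–Bloembergen
equation with the spectral density
$J(\omega) = \langle r^{-6}\rangle\,[S^2\tau_c/(1+\omega^2\tau_c^2) +
(1-S^2)\tau_t/(1+\omega^2\tau_t^2)]$ and intensity ratios from the
exponential INEPT attenuation $R_{2,\mathrm{red}}e^{-\Gamma_2 t_d}/
(R_{2,\mathrm{red}}+\Gamma_2)$.

Parameters (see `physicalConstants()`):

* `field` — spectrometer ¹H frequency, MHz; default 600 (the data this
  workflow targets were acquired at 600/900 MHz; ω_I enters only through
  the $J(\omega_I)$ term).
* `tauc` — rotational correlation time of the complex, default 29 ns.
  This is the empirical molecular-weight estimate ≈ 0.6 ns/kDa applied to
  a 47.8 kDa complex (`rotationalCorrelationTime()`); the temperature
  dependence of that rule is not modelled — τ_c is taken as configured.
* `taui` — spin-label correlation time, default 500 ps. The combined time
  is formed as $1/\tau_t = 1/\tau_c + 1/\tau_i$; the standard total
  correlation-time rule. This combination is a package decision: the
  spectral density needs a τ_t, and the Lipari–Szabo-style decomposition
  is the conventional closure.
* `td` — total INEPT time, default 10 ms; `r2red` — diamagnetic R₂,
  default 40 s⁻¹ (molecular-weight based); `cap` — Γ₂ ceiling, default
  450 s⁻¹, beyond which the intensity ratio is numerically flat, so the
  inverse map truncates there.

**Spin-label model.** Instead of shipping a published MTSL rotamer
library, the label is modelled as a pseudo-rotamer cloud: `nRotamers`
(default 16) candidate electron positions on a deterministic Fibonacci
grid over a spherical cap (half-angle 75°) oriented away from the host
chain, at a tether length of 8 Å (a three-bond MTSL arm), Boltzmann
weighted by a soft-sphere clash energy (σ = 3.5 Å, ε = 2 kT) against all
other particles. Fully buried candidates receive negligible weight. The
order parameter factorizes as $S^2 = S^2_{radial}S^2_{angular}$ with
$S^2_{radial}=\langle r^{-3}\rangle^2/\langle r^{-6}\rangle$ and the
angular part computed as the second-rank tensor order parameter of the
electron–proton unit vectors under $p_k r_k^{-3}$ weighting, which makes
the factorization exact. The cloud construction is deliberately simple
and pluggable: anything that produces positions and probabilities can
replace it. With coarse one-bead models the "amide proton" is the residue
bead itself; this costs ~1 Å of fidelity, far below the r⁻⁶ contrast that
drives the analysis.

## BME reweighting

Experimental intensity profiles are smoothed per label site by LOESS
(span 0.2 over residue number, local quadratic; constants and straight
lines are reproduced exactly, so the smoother cannot bias flat or linear
stretches). Smoothing is on by default with a raw-data switch. Ratios are
converted to Γ₂ by bracketed bisection of the strictly decreasing forward
map (unique root; ratios ≥ 1 map to 0) and truncated at the 450 s⁻¹ cap.
The error model is $\sigma_i^2 = \mathrm{scale}/\max(\mathrm{ratio}_i,
\mathrm{floor})$ with scale 1 (Γ₂² units) and floor 0.05 — variances that
grow as peaks vanish; a constant-σ mode is retained for comparison.

Weights follow the maximum-entropy form
$w_j \propto w_j^0\exp(-\sum_i\lambda_i\Gamma_{2,i,j})$ with λ from
minimizing the convex dual
$C(\lambda)=\log Z+\sum_i\lambda_i\Gamma^{exp}_{2,i}+
\tfrac{\theta}{2}\sum_i\lambda_i^2\sigma_i^2$.

Numerical choices that matter:

* **Preconditioning.** The dual is invariant under shifting each
  observable row and its target by a constant, and reparametrizing
  λ rescales the quadratic penalty exactly. The solver therefore centres
  every row by its prior mean and scales it to unit prior standard
  deviation, carrying the transformed diagonal penalty. Without this the
  Hessian spans the square of the Γ₂ dynamic range (~10⁵) and L-BFGS
  stalls; with it the same problems converge in seconds.
* **No cap on the calculated matrix.** The truncation applies to the
  *experimental* conversion only. Capping the per-frame predictions as
  well was tried and rejected: it silently lowers ensemble means below
  otherwise attainable targets, making a perfectly consistent zero-noise
  problem infeasible and collapsing the effective sample size.
* **Optimization.** L-BFGS-B with the analytic gradient, deterministic
  λ = 0 start, warm starts along the θ grid, gradient-norm target 1e-8
  (configurable) with warn-don't-fail semantics below a relative
  1e-3 guard; `strict = TRUE` restores hard failure.
* **θ selection.** The verbal "χ² changes minimally" rule is quantified:
  the selected θ is the largest grid value for which a further ten-fold
  decrease (interpolated on log θ) improves χ² by less than 5% relative.
  On a curve that is flat from the start this returns the largest θ
  (the prior is already adequate); on a descending curve with a plateau
  it returns the knee.

State contributions are weight sums over the per-frame state labels; all
states are pooled into a single reweighting problem with one
normalization, matching the one-weight-set-over-all-frames design.

## Conformational landscape

Features are minimum Cα–Cα distances between consecutive 4-residue
windows (final partial window retained — for 311 residues, 78 segments)
for all window pairs with more than two segments strictly between
(b − a ≥ 4), giving n(n−1)/2 − (3n−6) = 2775 features. PCA is centred and
unscaled (distances share units); the top 50 components feed both the
2-D embedding and clustering. UMAP is trained on a seeded random 10%
subsample and the remaining frames are projected into the trained space —
this breaks the temporal autocorrelation a trajectory would otherwise
imprint on the embedding; training frames keep their fitted coordinates.
Clustering is Louvain community detection on a K-nearest-neighbour graph
built in PC space (k = 15, resolution 1; neither is dictated by the
workflow's sources, both are exposed). The validation partition is
K-means on the embedding with k equal to the number of communities;
agreement is scored by ARI and by AMI with the hypergeometric
expected-MI correction (implemented in-package; no installed R package
provides it), and significance by shuffling labels 10,000 times — the
chance-corrected indices have zero expectation under permutation, which
the suite verifies. Cluster representatives are the frames nearest their
cluster centroid in embedding coordinates.

## Contacts

Two segments are in contact when their minimum inter-particle distance is
at or below a cutoff — 8 Å for Cα-only coarse models (4.5 Å would be the
heavy-atom convention). The contact definition is a package choice, as
the upstream workflow never states one; it is configurable and recorded
in the run summary. Intra-chain maps omit pairs two or fewer segments
apart. Per-state maps restrict and renormalize the weights within each
state. A contact is state-specific when its frequency is ≥ 0.6 in one
state and ≤ 0.2 in all others, matching the low/high thresholds used in
the entropy comparison for consistency.

## Conformational entropy

Backbone torsions (φ, ψ; ω excluded as rigid) — or, for coarse Cα-only
chains, one pseudo-dihedral per residue — are histogrammed into 35 equal
bins of [−π, π) with BME-reweighted probabilities, and
$S=-[\sum_iP_i\ln(P_ih)+(n-1)/(2N)]$. Choices:

* n = 35 is honoured over an exact 10° width (35 × 10° ≠ 360°; the two
  stated conventions are inconsistent, and the bin count is the one that
  enters the estimator). Since h only shifts S by a constant, differences
  between residues and states are unaffected.
* The finite-sampling term is applied exactly as written — subtracted
  inside the bracket. The conventional Miller–Madow correction *adds*
  (n−1)/(2N) to the plug-in entropy; both forms are available
  (`correction = "printed"`/`"additive"`), the printed form is default,
  and the uniform-distribution tests pin each form's closed-form value.
* N in the correction is the raw frame count by default; an effective
  sample size can be supplied through `nEff` when weights are far from
  uniform.

Residue entropy is the sum over that residue's torsions; the energy form
multiplies by RT at 310 K. Low (<20%) versus high (>60%) contact-class
entropy distributions are compared with a two-sided Wilcoxon rank-sum
test; groups under 3 members are flagged and skipped.

## Titration

Binding is quantified from intensity decay: f_b = 1 − I/I₀ (clipped to
[0, 1], zero-ligand point forced to 0), fitted per residue with the
single-site *depletion* isotherm rather than the L ≫ P hyperbola, because
the fixed receptor concentration (100 μM) is comparable to the fitted
constants. Kd is optimized on a log scale within (10⁻³, 10⁶)
concentration units; an optional saturation amplitude can be co-fitted.
Motif summaries are mean ± sample (n−1) SD over residues — the SD
convention is a package choice. Units are carried as entered; the
workflow's concentrations are in μM and the package treats the reference
constants (17, 7, 13) in those units, noting that a mM reading would be
inconsistent with saturation inside a 300 μM titration.

## The synthetic generator: what it emulates, and what it does not

The generator replaces two out-of-scope simulation engines with a
desk-scale stand-in whose *ground truth is known*:

* **Chain.** One bead per residue, bond length 3.8 Å, hard-sphere
  excluded volume (non-bonded minimum 4 Å), grown as a biased
  self-avoiding walk. Helical LD motifs (defaults LD1 3–14, LD2 144–155,
  LD4 263–274 — estimates from label/mutation sites, configurable) are
  emitted as rigid ideal Cα helices (rise 1.5 Å, radius 2.3 Å,
  100°/residue).
* **Receptor proxy.** A rigid bundle of four ideal-helix rods numbered
  916–1040, so the four standard label sites (984, 1006 / 1018, 1040)
  resolve on it, with one anchor point per binding face just outside the
  bundle surface.
* **States.** Each bound state anchors exactly two motifs on distinct
  faces (the central motif always bound); frames carry state labels and
  ground-truth weights (state weight spread uniformly within the state).
* **Calibration (set once).** The apo walk carries a mild
  centroid-repulsion bias (−0.07) putting the mean Rg in the
  experimentally plausible 52–59 Å band; the complex walk a weak
  attraction (+0.025) putting the weighted complex Rg near the 35 Å
  scattering estimate. Anchored growth uses staged waypoints (over the
  bundle pole, then outside the target face) because a plain Euclidean
  reachability bound cannot see that the receptor blocks direct paths;
  soft biases fade over retries so hard constraints remain the only
  rejections.
* **Observables.** PRE tables are the package's own forward model under
  the ground-truth weights with multiplicative Gaussian noise clipped to
  [0, 1.2] (experimental ratios can slightly exceed 1); titrations are
  the depletion isotherm plus noise.

What passing tests on these data show: that the inference machinery —
forward model, preparation, reweighting, landscape, contacts, entropy,
titration — is internally consistent and recovers planted truth at
realistic dimensions (311 residues, 4 sites, ~1250 observables, 8000
frames). What they do not show: force-field realism, convergence of real
MD sampling, or the behaviour of experimental noise that is neither
multiplicative nor independent across residues. Real spin labels also
have chemistry (rotamer preferences, partial labelling) the pseudo-cloud
does not capture.

## Problem sizes and budgets

The test suite and the acceptance script run at the sizes a laptop
handles in minutes: 2,000 frames per state (8,000 total) for the
population-recovery and Rg checks, 150-frame-per-blob landscapes with
10,000 permutation shuffles, 60 apo frames for the compaction band, and
closed-form or ≤100-frame toys everywhere else. The compiled growth,
Γ₂ and segment-distance kernels keep the full recovery run under a few
minutes on one CPU.

## Known limitations

* The pseudo-rotamer label model is geometric, not chemical; absolute Γ₂
  scales are faithful to the equations but not to MTSL rotamer
  statistics.
* Louvain/UMAP hyperparameters are conventions, not fitted quantities;
  cluster counts depend on them (no automatic resolution selection is
  attempted, by design).
* The entropy estimator ignores torsion–torsion correlations
  (mutual-information corrections are out of scope), so residue sums are
  upper bounds on the correlated entropy.
* The coarse chain has no side chains, so heavy-atom contact definitions
  and side-chain χ entropies activate only when all-atom frames are
  supplied.
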