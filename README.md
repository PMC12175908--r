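# PREnsemble

Integrative analysis of "fuzzy" complexes between an intrinsically
disordered protein (IDP) and a folded receptor domain, driven by
paramagnetic relaxation enhancement (PRE) NMR data.

The motivating system is a ~311-residue disordered chain carrying short
amphipathic helical motifs (LD motifs) that bind the two faces of a
four-helix-bundle receptor domain, interconverting between several bound
configurations while the rest of the chain stays disordered.  For such a
system no single structure exists; the deliverable is a *weighted
conformational ensemble*.  PREnsemble provides every stage of that
analysis for R users:

- **PRE back-calculation.** Transverse PRE rates from coordinates via the
  Solomon-Bloembergen equations,

  Γ₂ = (1/15)(μ₀/4π)² γ_I² g² μ_B² S_e(S_e+1) [4J(0) + 3J(ω_I)],
  J(ω) = ⟨r⁻⁶⟩ [S²τ_c/(1+ω²τ_c²) + (1−S²)τ_t/(1+ω²τ_t²)],

  with rotamer-averaged order parameters S² = S²_radial · S²_angular,
  S²_radial = ⟨r⁻³⟩²/⟨r⁻⁶⟩, and HSQC intensity ratios
  I_para/I_dia = R₂,red · exp(−Γ₂ t_d)/(R₂,red + Γ₂).
- **Bayesian maximum-entropy (BME) reweighting.** Frame weights
  w_j ∝ w_j⁰ exp(−Σᵢ λᵢ Γ₂,ᵢⱼ) obtained by minimizing the convex dual
  C(λ) = log Z(λ) + Σᵢ λᵢ Γ₂,ᵢ^exp + (θ/2) Σᵢ λᵢ²σᵢ², with LOESS
  smoothing of the experimental intensity profiles, conversion to Γ₂
  truncated at 450 s⁻¹, an inverse-intensity error model, a θ scan with an
  elbow rule, and per-state aggregate contributions.
- **Conformational landscape.** Minimum Cα distances between 4-residue
  segment pairs (2775 features for a 311-residue chain), top-50 PCA, UMAP
  trained on a 10% subsample, Louvain communities on a KNN graph, weighted
  cluster contributions, and ARI/AMI permutation validation.
- **Contacts.** Weighted intra-/inter-chain segment contact maps,
  interaction-probability profiles, and state-specific contacts.
- **Conformational entropy.** Residue-wise torsion entropy
  S = −[Σᵢ Pᵢ ln(Pᵢh) + (n−1)/(2N)] over 35 bins under the refined
  weights, its RT energy form at 310 K, and low/high contact-class
  comparisons (Wilcoxon).
- **Titration Kd fitting.** Per-residue dissociation constants from
  intensity-decay titrations using the single-site depletion isotherm
  f_b = [(P+L+K_d) − √((P+L+K_d)² − 4PL)]/(2P), summarized per motif.
- **Synthetic ground truth.** A self-avoiding coarse-chain generator with
  rigid helical motifs, a rigid receptor proxy with two binding faces, and
  four interconverting anchored states with known state weights, plus
  synthetic PRE and titration observables produced by the package's own
  forward models — so every stage is testable without molecular-dynamics
  trajectories or spectrometer data.

## Worked example

```r
library(PREnsemble)

truth <- groundTruth(stateWeights = c(I = .4, II = .3, III = .2, IV = .1),
                     noiseSd = 0, seed = 11)
cx  <- sampleComplexEnsemble(truth = truth, nFramesPerState = 2000)
pre <- synthesizePRE(cx, truth = truth)          # 4 label sites x 311 residues
tab <- preparePRETable(pre$table, smooth = FALSE)
rw  <- bmeReweight(cx, pre$profiles, tab, theta = 0.1)
rw$fit
#> BMEResult: theta = 0.1, chi2 = 4.801e-08 (prior 50.76), Neff = 6495.9
#>   state contributions: I = 0.369, II = 0.321, III = 0.187, IV = 0.124

radiusOfGyration(cx, weights = refinedWeights(rw$fit))$summary$mean[1]
#> [1] 35.13662
```

Starting from uniform priors (0.25 per state), reweighting against the
zero-noise synthetic PREs recovers the planted state populations
(0.4, 0.3, 0.2, 0.1) to within 0.03, drives the variance-scaled χ² from
50.8 to ~5e-8 while keeping an effective sample size of ~6500 of 8000
frames, and the reweighted complex is compact (Rg ≈ 35 Å).

The full flow — generation, forward PRE, preparation, reweighting,
landscape, contacts, entropy, titration — is orchestrated by
`runPipeline()` (see `?validatePipelineConfig` for every tunable and
`inst/scripts/run-pipeline.R` for a shell entry point).

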