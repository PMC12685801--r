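# lobenet

Anatomically constrained representation learning for volumetric lung
imaging, exercised end to end on synthetic lung phantoms.

## The problem

Models for lung disease should respect what is known about the lungs:
pathology sits in specific lobes, severity grows with lesion burden, the
two lungs are approximately mirror symmetric, and diseases co-occur in
predictable patterns. `lobenet` implements a representation-learning
framework that encodes these priors in both the architecture and the
training objective, for researchers who want to study how such constraints
behave at desk scale with fully known ground truth.

The architecture, for a study `x = (I, c, m)` with volume `I`, clinical
vector `c`, metadata `m`, and binary lobe masks `M^(k)`:

* **Region decomposition** `I^(k) = I ⊙ M^(k)`, each lobe encoded by a
  shared residual 3D CNN into features `F^(k)`.
* **Gated region attention** `α^(k) = σ(wᵀ tanh(W_g · GAP(F^(k))))` with
  the attended summary `r = Σ_k α^(k) h_k` over pooled lobe descriptors
  `h_k` (normalized, convex-combination variant by default).
* **Graph attention** over the lobe adjacency (RUL–RML–RLL and LUL–LLL
  chains plus upper–upper and lower–lower inter-lung edges): additive
  attention `η(j,k) = softmax_j aᵀ LeakyReLU([W_q h_j ; W_k h_k])`,
  residual GELU update, multi-head averaging, concatenated descriptor
  `g = [h'_1; …; h'_K]`.
* **Multi-modal fusion** `z = [v_img ; MLP₁(c) ; MLP₂(m)]` with zero-fill
  for missing modalities; linear heads for lesion-lobe classification,
  ordinal severity `ŝ = ψ(z)`, and multi-label prediction.
* **Structural and knowledge-guided penalties**: hierarchical consistency
  `‖z − Σ α_k z_k‖²`, class-center loss, linear MMD between cohorts,
  mask-guided total variation, severity MSE, attention entropy, graph
  smoothness `Σ_(i,j)∈E ‖h'_i − h'_j‖²`, ordinal ranking hinge
  `max(0, ŝ_j − ŝ_i + δ)`, bilateral symmetry `‖f_L − T f_R‖²`, label
  co-occurrence `‖ŷ − Cŷ‖²`, zone attention `‖H⊙Z − H‖²`, and cross-view
  consistency (plain, contrastive, affine-aligned).
* **Two-stage curriculum**: masked block reconstruction plus an instance
  contrastive loss with momentum-encoder targets, then supervised
  fine-tuning under the weighted composite objective.

Since the clinical datasets this class of model targets are
access-restricted, the package ships a seeded **synthetic lung phantom
generator** (ellipsoidal lungs carved into 5 lobes, one lesion per study
whose size is a deterministic monotone function of the ordinal severity
grade, correlated clinical covariates, two cohorts with an intensity
shift, paired acquisition views) so that every component is testable as a
parameter-recovery problem: the ground-truth lesioned lobe is known, and
evaluation asks whether the trained gated attention finds it.

Gradients come from a compact reverse-mode automatic differentiation
engine included in the package (R tape over arrays, compiled im2col 3D
convolution kernels), validated operator-by-operator and end-to-end
against finite differences.

## A worked example

```r
library(lobenet)

pc  <- phantom_config(grid_size = 16, n_samples = 200, seed = 7)
coh <- generate_cohort(pc)

cfg <- train_config(stage1_epochs = 1, stage2_epochs = 12, lr = 2e-3, seed = 11)
res <- run_curriculum(coh, pc, cfg)

res$evaluation$metrics$accuracy        # 0.9   (chance is 0.2 for 5 lobes)
res$evaluation$attention_localization  # 1.0
```

On this 200-study cohort the held-out lesion-lobe accuracy reaches 0.9
(chance 0.2) and the lesioned lobe receives the maximal attention weight in
every held-out study: the attention mechanism recovers the known lesion
location rather than merely correlating with the label. `res$history`
holds per-epoch loss terms and validation accuracy; `write_cohort()` /
`read_cohort()` persist cohorts as NIfTI volumes with CSV tables and a
JSON manifest, and `inst/cli/lobenet.R` exposes `simulate`, `pretrain`,
`train`, `evaluate`, and `selftest-losses` verbs for shell use.

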