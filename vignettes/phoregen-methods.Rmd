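---
title: "phoregen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phoregen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phoregen is a hierarchical framework for structure-based molecular design
that uses the pharmacophore point cloud — a ligand reduced to a handful of
labeled 3D points — as the common currency between three learned or
geometric stages: (1) a pocket-conditioned diffusion model samples clouds
inside a protein pocket; (2) repeated samples are consensus-clustered into
one hypothesis; (3) a property-gated sequence model decodes the hypothesis
into molecules, which are then embedded in 3D and posed back into the cloud
by rigid alignment. A registration/differencing path compares the clouds of
two related pockets to propose selectivity-driving features. This vignette
documents the models, their assumptions, the tunable parameters, and the
choices made where the design was genuinely open.

## The pharmacophore data model

Every ligand-side object is a `pharm_cloud`: points with 3D coordinates
(Angstrom), one of eight feature categories (Aromatic, Hydrophobic,
PosIonizable, NegIonizable, Acceptor, Donor, LumpedHydrophobe, Other), and
a support count. The label/index bijection is fixed and serialized into
every JSON artifact, so one-hot encodings are portable across models and
files. The historical spellings "Localizable" and "Negativable" are read as
PosIonizable/NegIonizable on input; the PosIonizable reading matches how
positively ionizable features are described in pocket case studies of this
family of methods.

Feature detection is implemented as explicit graph rules rather than a
SMARTS engine: aromatic rings (one point per ring at its centroid), N/O–H
donors, N/O acceptors with a free lone pair (aromatic N–H and amide N
excluded), aliphatic amines plus amidine/guanidine groups and formal
cations as PosIonizable, carboxylic/sulfonic/phosphonic acids and formal
anions as NegIonizable, connected aliphatic carbon components (1–3 atoms as
Hydrophobic, 4+ as LumpedHydrophobe, halogens included), and sulfur
environments as the Other catch-all. Feature positions are unweighted
centroids of the member atoms — the natural coarse-grained reading; nothing
deduplicates a group matching two definitions, since the categories are
modeled as distinct. These rules are deliberately compact; they are not a
re-implementation of any particular commercial perception model, and the
test suite pins their output on reference molecules (benzene, methane,
phenol) so changes are visible.

Pockets are point clouds too: all non-hydrogen, non-water atoms within a
radius of a center (features = element symbols), or one C-alpha per residue
(features = residue types). The default radius is 10 Angstrom around a
reference-ligand centroid — wide enough to give the 6 Angstrom
message-passing cutoff margin on real structures.

## Pocket-conditioned diffusion over clouds

The generative model is a variance-preserving denoising diffusion process
over the cloud's coordinates and a continuous relaxation of its one-hot
categories, with the pocket as fixed, noise-free context:

* forward: `q(z_t | z_0) = N(alpha_t z_0, sigma_t^2 I)` with
  `alpha_t^2 + sigma_t^2 = 1`;
* reverse, via a noise predictor `phi(z_t, pocket, t)`:
  `z0_hat = z_t / alpha_t - (sigma_t / alpha_t) eps_hat`, followed by the
  exact Gaussian posterior step from `t` to `s < t` with mean
  `(alpha_{t|s} sigma_s^2 / sigma_t^2) z_t +
  (alpha_s sigma_{t|s}^2 / sigma_t^2) z0_hat` and variance
  `sigma_{t|s}^2 sigma_s^2 / sigma_t^2`, where
  `alpha_{t|s} = alpha_t / alpha_s` and
  `sigma_{t|s}^2 = sigma_t^2 - alpha_{t|s}^2 sigma_s^2`.

Two closed-form schedules are provided (`polynomial`, the default of the
equivariant-diffusion lineage, and a squared-cosine alternative), both
floored so `alpha_T` stays strictly positive; T defaults to 500 steps.
Training minimizes the simplified objective
`1/2 ||eps - phi(z_t, pocket, t)||^2` at uniformly drawn timesteps with
Adam, gradient clipping at global norm 1, and a cosine learning-rate decay
to 10%.

The noise predictor is an E(3)-equivariant graph network written directly
in R with analytic gradients (verified against numerical differentiation in
the tests). Its coordinate head predicts each cloud node's noise as a sum
of difference vectors to its neighbors weighted by rotation-invariant
scalars (functions of squared distances, node features and `t/T`); its
feature head is invariant. Equivariance is therefore exact by construction,
not approximate. Two choices are worth noting:

* **Frame handling.** All coordinates are expressed relative to the pocket
  centroid, and the ligand latent is noised with full (unprojected) 3D
  Gaussians. An alternative is to project ligand noise onto the
  zero-center-of-mass subspace; with a fixed pocket, however, that pins the
  sampled cloud's centroid to its initialization and makes pocket-relative
  placement unlearnable, so pocket-frame centering is used instead —
  translations are absorbed by the frame, rotations by the network.
* **Static message geometry.** Within one forward pass the network reuses
  the input geometry for all message layers and accumulates coordinate
  updates into the output head, rather than moving coordinates layer by
  layer. This keeps the hand-derived backward pass compact; the sampler
  still rebuilds the radius graph at every one of the 500 denoising steps.

During sampling the denoised estimate `z0_hat` is clamped to the plausible
data range before the posterior step — radially for coordinates (per-point
norm capped at 6 standard units; a per-axis box would not commute with
rotations and would silently break equivariance exactly when the clamp is
active) and per channel in the features. This is the standard guard
against the `1/alpha_t` amplification of prediction error at large `t`;
without it, early-chain errors feed back through the radius graph and blow
up the trajectory.

Full-scale defaults follow the reference protocol (hidden width 256, 5
layers, 6 Angstrom cutoff, learning rate 1e-4, batch 16); they are
impractical to *train* on one CPU, so the package's study configuration for
tests and the acceptance script is hidden width 48, 3 layers, learning rate
3e-3 with 220 epochs on 200 synthetic pairs, and a 16 Angstrom cutoff. The
wider cutoff matters for the synthetic geometry: fixture pockets are
shells of radius ~8 Angstrom, and at early reverse steps the latent points
sit near the pocket center, farther than 6 Angstrom from every pocket
node — a 6 Angstrom graph would give the model no directional signal
exactly when it must decide where the cloud belongs. Real pockets surround
the ligand at contact distance, so the tight cutoff of the full-scale
protocol does not have this problem. Pocket edges additionally carry a
smooth switching envelope over the outer quarter of the cutoff radius, so
the predictor is a continuous function of geometry: without it, an edge
entering or leaving the radius graph under an infinitesimal rotation
changes the output discontinuously, and the sampler's exact equivariance
(which the tests verify to ~1e-14 Angstrom over the full 500-step chain)
would be lost at the graph boundary.

## Consensus clustering and the feature vote

Sampling is repeated (5 times by default) and the pooled points are
clustered by a Gaussian mixture on coordinates, fitted with mclust; k is
chosen by BIC over 1..min(8, n/3) when `k = "auto"`, and BIC selects the
covariance family as well. The full-covariance model is among the
candidates, but with the few points per component typical of pooled
diffusion samples a forced full-covariance fit is overparameterized and
falls into degenerate local optima (observed directly on clean
two-cluster data), so the family is chosen from the data. Each
cluster's category is the argmax of summed per-point category indicators —
a majority vote, because the diffusion model outputs hard labels, so the
per-sample feature probability reduces to an indicator. The overall
category frequency of the pooled cloud breaks ties, and remaining ties fall
back to the pinned alphabet order; the tests check the vote against
exhaustive enumeration over all eight categories. The consensus cloud has
one point per component at the component mean, with the cluster size as its
support.

## Registration and selective differencing

Rigid registration uses the closed-form Kabsch solution (SVD of the
cross-covariance, with the determinant correction for proper rotations);
since diffusion clouds from two pockets are unpaired, the default mode
iterates nearest-neighbor assignment and refitting (ICP) to convergence.
Degenerate (collinear) configurations warn but still return a solution.
Tests compare against an independent quaternion-based (Horn) solver.

Selective features between a target and a homolog pocket are defined by a
nearest-neighbor distance test rather than a convex-hull membership test:
a target point is "outside the homolog's sampled space" when its nearest
transformed homolog point is farther than `delta` (default 2 Angstrom —
the scale of residue-level clashes). Hull tests were rejected because they
mislabel interior cavities. Survivors are DBSCAN-clustered (eps 1.5, min
3); noise points are dropped and each retained cluster is relabeled by the
same majority vote. Dual-target analysis is the same machinery composed
the other way: register, pool, cluster — shared features appear as
high-support clusters.

## The gated sequence generator

The molecule generator is a latent-variable conditional sequence model over
SMILES tokens. The combined condition has two parts:

* a pharmacophore-graph summary: per-node embeddings of (category one-hot,
  distance statistics to the other nodes) passed through a small MLP and
  mean-pooled;
* a gating vector: seven property channels (MW, LogP, QED, SAS, RotBonds,
  TPSA, DockScore). An open channel contributes a linear embedding of its
  standardized value; a closed channel contributes a learned null vector.
  Closed channels never read their stored value, so the closed-gate null
  effect is exact by construction (the tests still verify it
  behaviorally).

A recognition network (token-bag + length + condition) parameterizes a
Gaussian posterior over a latent z with N(0, I) prior; the decoder predicts
each next token from a sliding window of previous-token embeddings
(default 8) concatenated with z and the condition, through a stack of
residual feedforward blocks; a mapping head scores which decoder position
realizes each pharmacophore node against the node embeddings. The loss is
KL + token cross-entropy + mapping cross-entropy with weights 1:1:1 and a
linear KL warm-up over the first 10% of steps (guarding against posterior
collapse). Training opens each gate independently with probability 0.5 per
example, so conditional and unconditional channels are both learned; the
pharmacophore hypothesis for each example is a random feature subset of
the molecule (the infilling noise), with pairwise distances taken as
shortest bond-path length times 1.5 Angstrom per bond — the mean
single-bond length — as a metric surrogate available without conformers.
Feature-to-feature path length is the minimum over member-atom pairs. At
inference the hypothesis distances are Euclidean distances of the sampled
3D cloud; this train/inference distance-domain mismatch is inherited from
the surrogate and is a documented caveat, softened by the 1.5 Angstrom
match tolerance downstream.

This architecture is deliberately lighter than a full transformer
encoder-decoder: with no GPU autodiff stack available, all gradients are
hand-derived, and a windowed-context decoder with residual blocks is the
strongest architecture that keeps the analytic backward pass tractable and
CPU training inside minutes. The configuration surface keeps the reference
protocol's knobs (hidden width 384, 8 blocks, lr 3e-4, weight decay 1e-6,
cyclic cosine annealing with a 4-epoch period); the desk-scale study
configuration is hidden 96, 2 blocks, embedding 32, latent 8, lr 2e-3, 20
epochs on a 500-molecule corpus. At that scale the model reaches ~40%
chemical validity and a statistically strong molecular-weight gate
response; teacher-forced token accuracy exceeds 15 times chance.

Score-based fine-tuning (`finetune_with_scores`) continues training with
only the DockScore gate open on an externally supplied (SMILES, score)
table — docking itself is out of scope — after which generation can fix the
score channel (e.g. at -13 kcal/mol). The documented pre-filter ranges for
that protocol (MW 325–425, LogP 1–4, QED 0.4–0.8, SAS 1–5, RotBonds 4–6)
are exposed as `r1_prefilter_ranges()`.

## Conformers and pose alignment

Generated molecules are embedded deterministically: the base conformer is
the molecule's rule-based structure diagram (which handles fused ring
systems consistently) scaled to a 1.52 Angstrom mean bond length, and
additional conformers resample torsions around rotatable bonds, taking
the geometry out of plane. The backend's force-field conformer searches
are not seed-reproducible, and exact reproducibility of the whole
pipeline was judged more valuable at pharmacophore-centroid resolution
than energy-minimized local geometry; conformers are not re-minimized —
alignment treats them as rigid anyway, and the posing step is an overlay,
not a refinement. Poses come from an exact branch-and-bound over injective,
category-consistent assignments of cloud points to the conformer's feature
centroids, allowing up to `tolerance` cloud points to remain unmatched
(surplus molecule features are free, mirroring pharmacophore-screening
convention: the molecule may exceed the hypothesis). Each assignment is
solved by Kabsch on the matched centroids; poses with fit RMSD at most
`fit_cutoff` (default 1.5 Angstrom per matched pair) are kept and ranked
by (unmatched count, RMSD). The search is exact because clouds are small
(<= ~10 points); a search-space guard errors rather than silently
truncating. Pose-to-pose RMSD is symmetry-corrected by enumerating graph
automorphisms (element-colored, capped at 1e4 mappings).

## Evaluation suite

`generation_metrics` reports validity (parseable and passing a valence
sanity check — the underlying parser accepts hypervalent atoms a
generative model may emit, so parseability alone overcounts), uniqueness
(distinct canonical SMILES among valid), novelty (unique molecules absent
from the reference corpus; computed over unique molecules, the standard
benchmark convention), and the available ratio (valid, unique and novel
over all generated strings). `match_score` is the fraction of hypothesis
nodes satisfiable by an exact assignment search under category and
pairwise-distance consistency (tolerance 1.5 Angstrom, one bond unit).
The property panel uses OpenBabel's molecular weight, Wildman–Crippen LogP
and Ertl TPSA; QED is implemented from its published desirability functions
and structural-alert list; the rotatable-bond count is the acyclic
non-terminal single-bond definition. The synthetic-accessibility score is a
self-contained Ertl-style heuristic: it keeps the published
complexity-penalty structure (size, ring, stereo, macrocycle) and the 1–10
scale, but replaces the original database-derived fragment-contribution
term with a compact atom-environment familiarity term — absolute values
are therefore comparable in spirit but not numerically identical to the
reference implementation. SAS is treated as living on 1–10 (the published
range), not 0–10. Ligand efficiency is `-score / heavy atoms`, oriented so
larger is better.

## Synthetic fixtures: what they emulate and what they do not

`make_complex_fixtures` emulates pocket–ligand pharmacophore training
pairs: each pocket is a noisy spherical shell (radius ~8 Angstrom) of
residue-labeled points with a tight five-residue "anchor" cap on one face
(real binding sites are anisotropic; the cap plays the role of the
recognition face), and the paired cloud is drawn i.i.d. Gaussian (sigma 1
Angstrom) around the pocket center displaced 3 Angstrom toward the anchor
face. Every pair is randomly oriented, as deposited complexes are; the
realized displacement and rotation are stored as attributes, which is what
makes "did the sampler put the cloud in the right place" a measurable
question. An optional corruption mode displaces a known fraction of clouds
by 4–8 Angstrom, and `filter_fixture_pairs` screens pairs whose centroid
deviates more than 2 Angstrom from the anchor-implied position — the
desk-scale analogue of discarding poses that deviate beyond 2 Angstrom
RMSD during training-data curation.

What passing these tests shows: the diffusion machinery is algebraically
exact, exactly equivariant, and able to learn a pocket-determined placement
and a category distribution at toy scale. What it does not show: anything
about real pocket geometry, chemistry-conditioned feature placement, or
performance at CrossDocked/ChEMBL scale — fixture pockets have no residue
chemistry beyond the anchor marker, and cloud positions are unimodal
Gaussians. The corpus generator enumerates scaffold-times-substituent
templates (disubstituted benzenes/pyridines, piperazines, anilides,
sulfonamides, benzoates); it spans a wide property range (needed for
detectable gate effects) but has none of the scaffold diversity of a real
library, and molecular weight stays far below the 800 Da corpus cap used
for real-library preprocessing.

## Numerical choices

* Schedule floor 1e-7 on `alpha_t^2` keeps `predict_clean` finite at t = T.
* The GMM falls back to a regularizing prior when the full-covariance fit
  is singular, with a warning.
* The `z0_hat` clamp during sampling is radial for coordinates (per-point
  norm capped at 6 standard units — a per-axis box would not commute with
  rotations) and [-3, 3] per feature channel.
* Mixture fitting, DBSCAN, the assignment searches and the consensus vote
  are deterministic given their seeds; ties in the vote break by global
  frequency, then pinned alphabet order.
* All training loops are bitwise seed-deterministic; fixture generation
  restores the caller's RNG state.

## Desk-scale problem sizes

The test suite and the acceptance script train the denoiser on 200 fixture
pairs (220 epochs, ~4 minutes on one CPU) and the generator on a
500-molecule corpus (20 epochs, ~2.5 minutes), sample 200 clouds for the
recovery checks, and run the full pipeline (5 samples -> consensus -> 100
molecules -> poses -> report) end to end. These sizes were chosen as the
smallest at which the statistical checks (total-variation 0.15 on
marginals, 1 Angstrom centroid bias, one-sided gate-shift tests at alpha =
0.05 with n = 200) have comfortable power.

## Known limitations

* The feature-perception rules are compact approximations; molecules
  dominated by exotic chemistry fall into Other or are skipped.
* The generator's windowed context limits long-range SMILES consistency
  (unclosed rings are the main validity failure mode) and its validity
  (~40% at toy scale) is well below what a full transformer reaches after
  GPU-scale training.
* Inference feeds Euclidean cloud distances to a model trained on
  bond-path distances; the mismatch is tolerated, not resolved.
* The SAS term is a heuristic stand-in calibrated to the published scale,
  not the database-derived original.
* Docking, in-situ rescoring and molecular dynamics are intentionally out
  of scope; score-gated fine-tuning consumes external score tables only.
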