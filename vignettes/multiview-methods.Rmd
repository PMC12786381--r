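---
title: "Multi-view molecular representation learning and interaction prediction with molviews"
author: "molviews authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view molecular representation learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`molviews` predicts drug–target (DTI), drug–drug (DDI) and drug–microRNA
(DMI) interactions from three complementary molecular representations,
fused adaptively and propagated over the known interaction graph. The
pipeline has four stages.

**1. Three drug modalities.** For each molecule (from SMILES) we compute

* $x_1$ — a binary fingerprint (default: extended-connectivity,
  radius 2, folded to 1024 bits; MACCS structural keys and a hashed
  topological-torsion fingerprint are available). Fingerprints are
  computed from the canonical SMILES, so every spelling of a molecule
  maps to the same bits.
* $x_2$ — a graph-convolutional embedding of the heavy-atom graph: atom
  features (element, degree one-hots) and bond-order features are
  linearly embedded, updated for 2 message-passing rounds with tanh
  units and summed neighbour/bond aggregation, then pooled with a
  symmetric sum readout and projected to $d_2 = 64$ dimensions. Sums
  make the map invariant to atom-index permutation.
* $x_3$ — a direction-aware 3D spatial feature, described next.

**2. Six-view rendering and the spatial autoencoder.** A single
conformer per molecule is built by seeded distance-geometry embedding
(ETKDG) followed by MMFF94s force-field minimization; identical seeds
give bitwise-identical coordinates. The conformer is canonically
oriented (centroid at the origin, principal axes on $x,y,z$, signs fixed
by the furthest atom, right-handedness enforced so enantiomers are never
reflected onto each other) and rasterized orthographically into six
ball-and-stick views — front, right, back, bottom, top, left — as a
$4\times6\times H\times W$ tensor (CPK RGB + an alpha/occupancy
channel), with the molecule's bounding sphere scaled to 90% of the image
half-width in every view.

The tensor $y_i$ feeds a 3D convolutional autoencoder. The global
branch applies $n$ convolution layers
$h_k = W_k * h_{k-1} + b_k$ (LeakyReLU between layers) and takes the
latent $v$ as a linear projection of the final feature map; a mirrored
stack of transposed convolutions with a sigmoid output reconstructs
$\hat y_i$, trained on the mean per-sample sum of squared errors
$L = \frac1N\sum_i \lVert y_i - \hat y_i\rVert_2^2$. The local branch
groups the views into three fixed directional pairs
$g_1 = (\text{front}, \text{right})$, $g_2 = (\text{back},
\text{bottom})$, $g_3 = (\text{top}, \text{left})$ and passes each pair
through its own (non-weight-shared) convolutional path; pooled maps are
concatenated into $x_3 = \mathrm{concat}(a_1, a_2, a_3)$, $d_3 = 192$.

**3. SCRN fusion.** The self-controlled gated residual network projects
each modality into a shared space ($z_i = W_i x_i + b_i$), reduces each
$z_i$ to a scalar logit and applies a softmax across the three logits to
obtain gate weights $w_1 + w_2 + w_3 = 1$; the *original* modality
vectors, scaled by their gates, are concatenated,
$X = [w_1 x_1; w_2 x_2; w_3 x_3]$, and refined by two same-padding 1D
convolutions with a residual connection, $y = h_2 + X$. With zeroed
refinement kernels the block is exactly the gated concatenation.

**4. GCN link prediction.** Drug embeddings $y$ and partner features
(k-mer vectors for miRNAs, a pluggable protein language-model embedding
or its deterministic composition fallback for proteins) occupy
complementary blocks of the node feature matrix $H^{(0)}$. Propagation
follows the self-loop symmetric normalization
$H^{(l+1)} = \sigma(\tilde D^{-1/2}\tilde A\tilde D^{-1/2} H^{(l)}
W^{(l)})$ with $\tilde A = A + I$ and $\sigma$ = LeakyReLU, and pair
scores are $\hat Y_{ij} = \mathrm{sigmoid}(\langle x_i, t_j\rangle)$
over the final representations (symmetric by construction for DDI).
Training minimizes binary cross-entropy over the known positives plus
uniformly sampled unobserved pairs at a 1:1 ratio, redrawn each epoch
under the run seed. A two-layer feed-forward head on $y$, trained with
MSE and ridge regularization, serves scalar endpoints (acute-toxicity
LD50-style regression).

# Parameters that matter

| parameter | default | notes |
|---|---|---|
| fingerprint | morgan, radius 2, 1024 bits | best-performing kind in fingerprint comparisons; MACCS (166 fixed keys) and topological torsion available |
| render resolution $H\times W$ | 64 × 64 | configurable; bounding-sphere scaling keeps relative size comparable across molecules |
| encoder | 3 conv layers, 16/32/64 channels, 3³ kernels, spatial stride 2 | view axis unstrided; latent 128 |
| directional paths | 2 conv layers (8/32 channels) each | pooled to $d_3 = 192$ |
| encoder bias | off | a bias-free encoder maps empty background to exactly zero activations, anchoring Grad-CAM saliency on geometry (cf. bias-free CNNs); decoder and latent maps keep biases |
| SCRN | $d_z = 64$, kernel 3, LeakyReLU | second refinement kernel zero-initialized (exact residual pass-through at init); gate projections zero-initialized (uniform 1/3 gates at init) |
| GCN | 1 layer, width 16, linear output, weight decay $10^{-3}$, Adam lr $10^{-2}$, 600 epochs | see "Design choices" for why the default stack is shallow |
| negatives | 1:1, redrawn per epoch, seeded | fixed-once available via `neg_resample = FALSE`; held-out positives can be excluded from the pool (`exclude_pairs`) |
| property head | width 64, ridge (weight decay 0.2) | strong shrinkage because embeddings are much wider than desk-scale sample counts |
| miRNA k-mers | k = 3 (64 dims), U→T mapped | frequencies by default |
| protein fallback | 420 dims (20 composition + 400 2-mer) | deterministic, download-free; an external transformer model can be registered as `esm2_plugin` |

# What the synthetic fixtures emulate

The generator produces everything needed to exercise the pipeline
without downloads:

* **Molecules** from a seeded template grammar — heteroatom chains,
  substituted benzenes, fused bicyclics and stereocenter templates,
  including R/S enantiomer pairs. All are small, neutral, parseable and
  embeddable organics.
* **Planted interaction graphs**: latent factors $u_i, v_j \sim
  N(0, I_8)$, edge labels Bernoulli with
  $P(\text{edge}) = \mathrm{sigmoid}(3\,\langle u_i, v_j\rangle)$. The
  drug factors are injected linearly into the graph-embedding channel
  of the featurized molecules, and partner feature vectors are a seeded
  linear image of $v_j$ — without this leakage the labels would be
  statistically independent of molecule identity and end-to-end
  recovery would be untestable. The Bayes-optimal AUC (true logits
  scored against sampled labels) is stored in the manifest and bounds
  any model's achievable AUC.
* **Scalar endpoints**: a fixed linear function of interpretable
  descriptors (heavy atoms, rings, heteroatom fraction) plus optional
  Gaussian noise, with the coefficients stored for recovery checks.

These fixtures do not mimic real pharmacology: real interaction graphs
are sparse and scale-free rather than dense near 50%, real chemistry is
far more diverse, and real labels are noisy and biased. Passing tests
demonstrate that the machinery recovers structure it provably contains,
not that the defaults transfer to any particular benchmark.

# Numerical and design choices

* **Determinism.** Every stochastic step (initialization, negative
  sampling, splits, conformers) runs under an explicit seed, and
  training loops are free of hidden RNG, so trajectories reproduce
  bitwise. Conformer generation uses seeded distance geometry for the
  same reason.
* **Decoder input.** The architecture descriptions of the global latent
  and the directional feature conflict over which tensor seeds the
  decoder; here the autoencoder reconstructs from the global latent $v$
  (that is the pretraining objective) while $x_3$ is the representation
  exported to fusion. The literal variant (decoder seeded by the
  directional feature) sits behind `spatialConfig(decoder_input =
  "directional")`.
* **Scalar gates.** A softmax over vector-valued $z_i$ is ill-defined
  as a modality weight; since fused models report a single contribution
  percentage per modality, the default reduces each $z_i$ to a scalar
  logit. (`gate_mode = "elementwise"` keeps the per-coordinate variant.)
* **Shallow GCN by default.** On desk-scale graphs (tens of nodes per
  side) a 2-layer, width-128 LeakyReLU stack memorizes the training
  edges (training AUC ≈ 0.99) and loses held-out AUC by 0.02–0.05
  relative to a single propagation layer of width 16 with a linear
  output; the linear output also lets final embeddings carry signed
  coordinates into the inner product. The deeper stack is one argument
  away (`gcnConfig(hidden = c(128L, 128L), final_linear = FALSE)`).
* **Frozen features during link training.** The spatial encoder is
  pretrained on reconstruction and then frozen while the GCN trains;
  joint fine-tuning of the fusion block is available
  (`trainLinkPredictor(..., scrn = list(model, bundles))`) but is not
  the default — on fixture-sized data it is slower and measurably less
  stable than training the GCN alone on frozen fused features.
* **Negative pools.** "Unobserved" means unobserved anywhere in the
  labelled data: held-out test positives can be excluded from the
  training negative pool (standard benchmark practice); at the planted
  graph's ~50% density this matters, because otherwise about one in
  seven sampled "negatives" is actually a held-out positive. If a pool
  is smaller than the requested 1:1 draw, the draw is capped with a
  message.
* **Murcko scaffolds.** Terminal heavy atoms are stripped iteratively;
  the surviving core (ring systems + linkers) is re-canonicalized so
  equal frameworks compare equal. Acyclic molecules form one shared
  "empty scaffold" group. Scaffold entropy uses the natural logarithm.
* **Occlusion check.** Because the canvas is mostly empty and masking
  an already-zero pixel is a no-op, the Grad-CAM occlusion sanity check
  ranks saliency over occupied pixels only, and targets the first
  encoder layer (least blurred by striding). The heatmaps themselves
  are standard rectified, gradient-weighted activation maps.
* **Degenerate inputs.** Single-atom molecules render six identical
  centered discs; molecules with one scaffold make a scaffold split
  impossible (warned, all assigned to train); single-class label
  vectors leave rank metrics undefined (NA with a warning) while
  threshold metrics are still computed.

# Problem sizes

The test-suite and acceptance runs use 20 rendered molecules at
64 × 64 for autoencoder training (50 epochs), a 50 × 40 planted
bipartite graph with latent dimension 8 and logit scale 3 for link
recovery (five 80/20 splits), 100 seeded scaffold splits, five orphaned
drugs, and 50 molecules for endpoint recovery. These sizes were chosen
so a complete run is a desk-scale exercise on a single CPU.

# Known limitations

* The renderer is a flat orthographic rasterizer (painter's algorithm,
  no lighting); front/back views are mirror images only up to genuine
  occlusion-order flips, which is why the mirror-symmetry property is
  stated with a pixel tolerance.
* One conformer per molecule: conformational ensembles, tautomers and
  protonation states are out of scope.
* The protein fallback encoder is a composition statistic, not a
  language model; it exists so the full pipeline runs without
  downloads, and a real pretrained model can be plugged in.
* Held-out generalization of the property head at fixture scale
  (p ≫ n) is noise-dominated; the recovery check therefore measures
  goodness of fit of the noiseless map, with a held-out check kept at
  unit-test scale where the geometry is favourable.
* Gate-weight reports on untrained fusion are uniform by construction;
  trained gate percentages depend on the task data and no particular
  values are claimed.
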