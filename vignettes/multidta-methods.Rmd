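---
title: "Multigranular binding affinity and binding region prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multigranular binding affinity and binding region prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given a small-molecule ligand (a SMILES string) and a protein target (an
amino-acid sequence), `multidta` predicts two quantities jointly:

* a continuous **binding affinity** on the pKd scale
  (pKd = −log10(Kd / 10⁹) for Kd in nM), and
* a **binding region**: a contiguous window of R protein positions where the
  ligand is predicted to bind.

The model belongs to the sequence-based drug–target affinity (DTA) family:
no 3-D structure is used, only the two strings. Its distinguishing features
are (i) a *multigranular* ligand representation — the same molecule is
encoded three ways in parallel — and (ii) an explicit binding-region head,
trained with position-wise supervision when region labels exist.

## Model

### Ligand encoders (three granularities)

1. **Graph attention network (GAT).** The SMILES string is parsed into an
   undirected molecular graph. Each atom carries a 78-dimensional
   descriptor: a one-hot element over a fixed 44-symbol list, one-hot degree
   (0–10), one-hot total hydrogen count (0–10), one-hot implicit valence
   (0–10), and an aromaticity flag. After a linear transform to E_g
   dimensions, attention scores e_ij = LeakyReLU(aᵀ[h_i‖h_j]) are
   softmax-normalized over each atom's bonded neighborhood and used to
   aggregate neighbor features (ELU output nonlinearity). The first layer is
   multi-headed with concatenated heads, the second single-headed. Global
   max pooling over real atoms yields x_g.

   Neighborhoods contain *only bonded atoms*; a self-loop is added solely
   for atoms with no bonds (single-atom molecules, truncation orphans) so
   the softmax is always well defined. A universal self-loop is a common
   alternative, but the bonded-only reading keeps a single-edge graph's
   attention equal to 1 on the unique neighbor, which is the behaviour the
   surrounding contracts assume.

2. **Residual character CNN.** Characters are mapped through a fixed
   64-letter vocabulary (codes 1–64, 0 = padding; the table is shipped in
   `inst/extdata/smiles_vocab.tsv` and anchored at C→42, O→48, '1'→35,
   ')'→31, 'l'→25), embedded, and passed through three 1-D convolution
   blocks (conv → channel normalization → ReLU). The embedding is added
   back (a residual connection in embedding space — the skip must land
   before the projection for the dimensions to match), followed by a
   position-wise projection and max pooling, giving x_c.

   The "batch normalization" inside each block is implemented as
   **per-channel normalization over the real sequence positions of the
   sample** (instance-norm flavour) with learned gain and shift. This makes
   evaluation deterministic, keeps padding exactly neutral, and needs no
   running-statistics plumbing; with batch-size-one graphs it is the
   batch-norm limit anyway.

3. **Sub-structure transformer.** A vocabulary of the most frequent
   consecutive sub-strings (length ≤ l, default 3) is built from a ligand
   corpus; single characters are always included so tokenization is total.
   Greedy longest-match tokenization, token + learned positional embeddings,
   then three transformer blocks: multi-head self-attention → FC → residual
   → layer norm, position-wise FC → residual → layer norm. A final
   position-wise MLP and max pooling give x_t.

All three encoders also retain their **pre-pooling position-wise maps**
(per atom, per character, per token), which the interaction module consumes.
The maps are stored with real rows only — padding rows after bias and
normalization would not be zero, so keeping them would poison the fusion
softmax; the fusion step pads back to fixed capacities with masked softmax
instead.

### Protein encoder (gated-convolution VAE)

The protein is read as overlapping 3-mers (MTVKTE → MTV, TVK, VKT, KTE),
each embedded through a learnable table (hashable to fewer rows for
desk-scale work; the full table has 21³ rows). Three 1-D gated convolution
layers (output = conv_A(x) ⊙ sigmoid(conv_B(x)); channels W_en, 2W_en,
3W_en) encode the sequence; the third layer's output is the position-wise
protein feature map used downstream. The latent path applies temporal max
pooling and a global average pool — this is what lets proteins of any
length map to a fixed-size latent — then two FC heads emit μ and log σ²,
and z = μ + exp(½ log σ²) ⊙ ε by reparameterization (z = μ in evaluation).

The decoder resizes z with an FC layer, applies three stride-2 transposed
convolutions (zero-interleave upsampling + convolution, each with ReLU),
and a final position-wise FC produces a scalar reconstruction profile of
exactly ϑ_p positions. Because the reconstruction is 1-D, the
reconstruction *target* is the 1-D profile obtained by averaging the input
3-mer embedding across channels.

From the reconstruction, the **original binding area** s marks the top
fraction (default 0.1) of positions by min–max-normalized reconstruction
magnitude. The literature this design follows never specifies the
mechanism linking reconstruction to sites; magnitude-based top-k is the
simplest monotone choice and is isolated behind one function
(`reconstruction_binding_profile`) so alternatives can be swapped in.

### Interaction module

* **Ligand kernel.** K_l = W[x_g‖x_c‖x_t] + b, a short vector (default
  length 9) used as a 1-D correlation filter.
* **Response vector.** The protein feature map is projected to a scalar per
  position and correlated with K_l (zero-padded, centred):
  r_i = Σ_m K_l(m)·f(i + m − ⌊L_s/2⌋). The printed index-free form
  r_i = Σ_m K_l(m)·f(i) is available behind
  `interaction_config(response_mode = "literal")` for comparison; the
  correlation reading is the default because it is the only one in which
  the kernel actually *filters* the protein profile.
* **Binding region.** BR combines the min–max-normalized r and s
  elementwise; whether the "public space" of r and s means union or
  intersection is genuinely ambiguous, so both are implemented
  (`br_mode = "max"` default, `"min"` alternative). The predicted interval
  has width R with its midpoint at the argmax of BR, clipped at the
  sequence ends with width preserved. Exact ties in BR (frequent, because
  both normalized profiles peak at 1) are resolved by the response
  evidence r; the argmax is restricted to real (non-padding) protein
  positions.
* **Bilinear maps.** For each granularity,
  I[i,j] = Σ_c q_c · ReLU(PU)[i,c] · ReLU(GV)[j,c] over protein positions i
  and ligand positions j — the per-position resolution of the bilinear
  attention form, which is the only reading consistent with the printed
  matrix shapes.
* **Fusion.** I = [I_pg‖I_pc‖I_pt] along the ligand axis at fixed
  capacities (shorter maps zero-padded, padding masked out of the softmax);
  f_a = row-wise softmax of I·W_m; X_out = (I·W_a) ⊙ f_a; v_out =
  FC(column means of X_out). The affinity head is a two-layer FC with ReLU.

### Losses and training regimes

* Affinity: mean squared error.
* VAE: reconstruction MSE (weight γ default 0.1) and KL term (β default
  1e-3), trained jointly — the upstream description states the VAE is not
  pre-trained, so its objectives enter the main loss.
* Region: the **rectified wing loss** on (r − label vector), where the
  label vector is 0 outside the annotated region and equal to the pair's
  affinity inside it. The penalty is 0 for |x| < r_thresh,
  w·ln(1 + (|x| − r_thresh)/ε) for r_thresh ≤ |x| < w, and |x| − C beyond,
  with C chosen for continuity. Defaults (r_thresh = 0.1, w = 2.0, ε = 0.5)
  are configurable; the exact constants are not recoverable from the
  source material. The dead zone is what makes the many-zeros label
  vectors tolerable.
* Joint objective: Loss = ψ·L_BA + (1 − ψ)·L_BR with ψ = 0.4 (the reported
  grid-search optimum). Records without a region label contribute an
  all-zero label vector — "no binding region" is informative supervision —
  while `encode_region_labels` itself refuses records without regions.

Optimization is Adam (lr 1e-3 default, batch 32), fully seeded; early
stopping on validation MSE with patience 10 when a validation set is given.

## Why a hand-rolled autodiff engine

No deep-learning framework is available in the supported R environment, so
the package implements a small reverse-mode automatic differentiation tape
over dense matrices (`R/autodiff.R`). Operations are mixed-mode: with
plain-matrix inputs they are ordinary fast matrix code (used for
evaluation), with node inputs they record backward closures. Every op is
verified against central finite differences in the test suite, and a
whole-model gradient check during development agreed to ~1e-8 relative
error. This is slower than a framework (~30 ms per forward+backward on the
desk-scale configuration) but exact, dependency-free, and sufficient for
the scaled-down protocols below.

## The synthetic world

`generate_dataset()` draws ligands and proteins and labels pairs by a
stated rule, so both heads have recoverable ground truth:

* **Ligands**: branched chains over C/O with an optional ring, in the
  supported SMILES dialect; k pharmacophore atoms (default symbol N) are
  planted and recorded.
* **Proteins**: uniform random sequences over the 20 amino acids,
  length 80–120; half carry the motif HWKH at a uniform random position,
  recorded as the true region.
* **Affinity** = 4.0 + 2.0 · 1[motif] · min(k, 3) + N(0, 0.3²), i.e. a
  baseline pKd of 4 (weak/non-binder), up to 10 for a saturated binder,
  with noise far below the effect size so the signal is identifiable
  (between-group separation ≫ 4σ).

Lengths 80–120 keep desk-scale runtimes sane while leaving the motif a
small target (~4% of the sequence); ligand sizes 10–24 atoms are typical
of fragment-to-lead chemistry. These constants are the package's stated
world: tests and acceptance criteria are computed against them, not tuned.

What the generator does **not** emulate: real chemistry (ring systems,
stereochemistry, charge states), binding thermodynamics, correlated label
noise, assay-specific biases, or the long-tailed affinity distributions of
public benchmarks. A green end-to-end test therefore establishes that the
architecture can extract a planted, identifiable signal through the full
pipeline — not that it reproduces published benchmark performance.

## Numerical choices

* Softmax is computed with row-max subtraction; masked entries use an
  additive −1e30 before normalization.
* Min–max normalization of a constant vector returns zeros (degenerate
  inputs never divide by zero).
* Binding-area ties are broken by position (smallest index first);
  BR argmax ties by response value.
* Channel/layer normalizations use ε = 1e-5 inside the square root.
* The correlation filter zero-pads; with even kernel lengths the extra tap
  falls on the right.
* Weight initialization is Glorot-uniform throughout, seeded once per
  `mg_init()` call; whole training runs are bit-reproducible given
  (records, config, seed).

## Scaled-down evaluation protocol

The acceptance suite trains `mg_config_small()` (all encoder widths ≤ 64,
protein capacity 120, hashed 1024-row 3-mer table) on 2000 synthetic pairs
(defaults above, seed 0, 4:1:1 split), joint regime, 8 epochs, Adam
lr 2e-3 — about 7 minutes on one CPU. It then checks held-out concordance
index and MSE, and region accuracy at R ∈ {5, 10, 15} against the planted
motifs, including monotonicity in R and the analytic random-placement
baseline (R + motif length − 1) / protein length. The same run backs the
README's worked example.

## Known limitations

* The SMILES dialect covers the organic subset, brackets, branches, ring
  closures and aromatic atoms — no stereochemistry or isotopes; there is no
  canonicalization, so the same molecule written two ways encodes
  differently.
* Training is single-threaded and per-sample (no batched linear algebra);
  production-capacity configurations (ϑ_p = 1000, dims 128) evaluate fine
  but are slow to train in R.
* The 64-letter character table is anchored at five documented codes; the
  remaining 59 assignments are a frozen package convention.
* Region supervision assumes one contiguous binding region per pair.
* The VAE's link from reconstruction to binding sites is an explicit
  design choice (magnitude top-k), not an established mechanism.
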