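# multidta

Joint prediction of protein–ligand **binding affinity** (pKd scale) and the
**binding region** on the protein sequence, from nothing but a SMILES string
and an amino-acid sequence.

## Who this is for

Computational chemists and method developers working on sequence-based
drug–target affinity (DTA) models who want a fully inspectable, tested,
dependency-light implementation of a multigranular affinity + region
architecture — including a seeded synthetic benchmark with planted ground
truth, the standard DTA metrics, and cold-split evaluation protocols — that
runs end-to-end on a laptop CPU with no external downloads.

## The model

A ligand is encoded at three granularities in parallel:

* **atoms** — a graph attention network (GAT) over the molecular graph;
  each atom carries a 78-dimensional descriptor (element, degree, hydrogen
  count, implicit valence, aromaticity); attention
  e<sub>ij</sub> = ζ(aᵀ[h<sub>i</sub>‖h<sub>j</sub>]) is softmax-normalized
  over bonded neighborhoods,
* **characters** — a residual 1-D CNN over the 64-letter integer encoding
  of the SMILES string,
* **sub-structures** — a transformer over frequent consecutive
  sub-sequence tokens (greedy longest-match tokenization).

The protein is read as overlapping 3-mers and encoded by a
gated-convolution **variational autoencoder**: three layers of
conv<sub>A</sub>(x) ⊙ σ(conv<sub>B</sub>(x)), reparameterized latent
z = μ + exp(½ log σ²) ⊙ ε, and a deconvolutional decoder whose
reconstruction highlights the "original binding area" s.

The interaction module concatenates the pooled ligand features into a
short **ligand kernel** K<sub>l</sub>, correlates it along the protein to
produce the **response vector** r (peaks = candidate binding sites), forms
the binding-region profile BR from r and s (window of width R centred at
the argmax), and computes per-position **bilinear attention maps**
I[i,j] = Σ<sub>c</sub> q<sub>c</sub>·σ(PU)[i,c]·σ(GV)[j,c] for each
granularity, fused with a softmax attention into the affinity head.

Training minimizes `Loss = ψ·L_BA + (1−ψ)·L_BR` with ψ = 0.4, where L_BA
is the MSE on affinities and L_BR a rectified wing loss on the
position-wise region labels (0 outside the region, the affinity value
inside). Everything — including backpropagation — is implemented in plain R
on a small reverse-mode autodiff engine (`R/autodiff.R`), gradient-checked
against finite differences.

See `vignettes/multidta-methods.Rmd` for assumptions, parameter meanings,
numerical choices, and what the synthetic benchmark does and does not
establish.

## Worked example

```r
library(multidta)

# 1. simulate a labelled world: proteins with planted HWKH motifs, ligand
#    affinity driven by the pharmacophore (N) count
ds <- generate_dataset(sim_config(n_pairs = 2000, seed = 0))
sp <- split_dataset(ds$records, split_spec("random", seed = 0))

# 2. train the desk-scale model jointly on affinity + region
cfg <- mg_config_small(dim = 24, max_protein = 120)
fit <- train_model(sp$train, cfg, regime = "joint",
                   tc = train_config(epochs = 8, lr = 2e-3, patience = Inf),
                   seed = 0)

# 3. evaluate on the held-out split
pred  <- mg_predict(fit$weights, sp$test, cfg, fit$subvocab, region_scale = 15)
truth <- vapply(sp$test, `[[`, 0, "affinity")
m <- evaluate_affinity(pred$affinity, truth)
cat(sprintf("held-out CI  : %.3f\n", m$ci))
cat(sprintf("held-out MSE : %.3f  (label variance %.3f)\n", m$mse, var(truth)))

has  <- vapply(sp$test, function(r) !is.null(r$region), FALSE)
regs <- lapply(which(has), function(i) c(pred$region_start[i], pred$region_end[i]))
acc  <- region_accuracy(regs, lapply(sp$test[has], `[[`, "region"), R = 15)
cat(sprintf("region accuracy (R = 15): %.3f on %d motif pairs\n", acc, sum(has)))
```

Output from this exact script (seed 0, one CPU, ~7 minutes):

```
held-out CI  : 0.808
held-out MSE : 0.190  (label variance 6.232)
region accuracy (R = 15): 0.972 on 177 motif pairs
```

Reading the numbers: a concordance index of 0.81 means a randomly chosen
better-binding pair is ranked above a worse one 81% of the time (0.5 is
chance); the MSE sits near the generator's noise floor (σ² = 0.09) and far
below the label variance; and 97% of planted motifs on held-out proteins
fall inside the predicted width-15 window (random placement would score
≈ 0.18).

## Command line

```sh
exec/multidta simulate --n-pairs 500 --seed 0 --out-dir data/
exec/multidta train --pairs data/pairs.tsv --regime joint --epochs 8 --out-dir run/
exec/multidta predict --pairs data/pairs.tsv --model run/fit.rds --out predictions.tsv
exec/multidta evaluate --predictions predictions.tsv
```

Subcommands: `simulate`, `featurize`, `train`, `predict`, `evaluate`.
Formats: TSV/CSV pairs tables (optionally with `protein_id` + FASTA),
BED-like region TSV (0-based half-open intervals), JSON run configs,
JSON-lines training history.

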