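---
title: "Tri-modal contrastive alignment of protein sequence, structure and text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-modal contrastive alignment of protein sequence, structure and text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`trimodalign` learns a shared latent space for three views of a protein: its
amino-acid sequence $S$, its backbone 3D structure $R$ (N, CA, C coordinates
per residue), and a free-text description of its function $T$. Three
modality-specific encoders produce pooled embeddings
$\mathbf{s} = E_s(S)$, $\mathbf{r} = E_r(R)$, $\mathbf{t} = E_t(T)$, each
passed through a per-modality projection head (LayerNorm followed by one
affine map) into a common $d$-dimensional space.

Alignment is contrastive and anchored on the sequence. For a batch of $N$
sequence–structure pairs, the InfoNCE loss

$$
\mathcal{L}_{s,r} \;=\; -\frac{1}{N}\sum_{i=1}^{N}
\log \frac{\exp(\mathbf{s}_i^\top \mathbf{r}_i / \tau)}
          {\sum_{j=1}^{N} \exp(\mathbf{s}_i^\top \mathbf{r}_j / \tau)}
$$

treats the matching structure as the positive and every other structure in
the batch as a negative; $\mathcal{L}_{s,t}$ is defined identically over
sequence–text pairs. The temperature is $\tau = 0.07$ and the training
objective is the equal-weight sum $\mathcal{L}_{s,r} + \mathcal{L}_{s,t}$.
Each optimization step draws the two pair subsets independently and
uniformly at random from the available paired records, so a record lacking
one modality still contributes through the channels it has. Because both
losses share the sequence side, structure and text become *indirectly*
coupled: the package's retrieval evaluation measures this anchor coupling
explicitly, as structure–text agreement is never trained directly.

Design choices worth knowing about:

* **Loss direction.** The losses place the sequence embedding in the query
  position, exactly as written above; a symmetric bidirectional variant
  exists behind `alignment_config(symmetric = TRUE)`, off by default.
* **Sum versus average.** The combined loss is the equal-weight *sum* of the
  two terms. Averaging instead would change nothing but an effective factor
  of two on the learning rate; the default is the sum, and the weights are
  explicit in `alignment_config(loss_weights = )`.
* **Normalization.** Projected embeddings are L2-normalized before the dot
  products. At $\tau = 0.07$ unnormalized inner products are numerically
  fragile (the exponent scale is unbounded); the literal unnormalized
  reading remains available via `build_alignment_model(normalize = FALSE)`.
* **Negatives** come only from within the same pair-type subset of the
  batch; there is no memory bank and no cross-subset negative.
* **Shared encoding.** A record drawn into both subsets in one step is
  encoded once and its sequence embedding shared by both loss terms.

## Encoders

**Sequence.** A token transformer over the 20 standard residues plus `X`
(non-standard residues map to `X`). Tokenization brackets the residue tokens
with BOS/EOS; the pooled embedding is the *BOS output*, which attends to all
positions. Pre-norm residual blocks, learned absolute positional embeddings
(the simplest scheme consistent with a transformer when none is otherwise
specified), and a fused-QKV attention implementation.

**Structure.** Backbone coordinates become a residue graph: nodes carry
sin/cos of the backbone dihedrals $(\phi, \psi, \omega)$ as scalar features
and three unit vectors (forward CA→CA, backward CA→CA, and an imputed
side-chain direction) as geometric features; each residue connects to its
$k$ nearest neighbours by CA distance, with 16 Gaussian radial-basis
features of the distance (centers evenly spanning 0–20 Å, width equal to
the center spacing) and the unit displacement on each edge. Geometric
vector perceptron (GVP) message-passing layers update scalars from
rotation-invariant quantities only (scalars and vector norms) and vectors
through channel-mixing linear maps gated by scalars — so scalars are exactly
invariant and vectors exactly equivariant under global rotations, and
everything is translation-free by construction from displacements. The GVP
scalar track then feeds a transformer, and the pooled embedding is the mean
over unmasked residues; it is therefore invariant to rigid motions of the
input up to floating-point error (the test suite bounds it at $10^{-3}$
relative over repeated random motions; in double precision the observed
error is near machine epsilon). Chain termini lacking a neighbour get
zeroed direction vectors and dihedral features; residues missing any of
N/CA/C are masked out of the graph entirely.

**Text.** A word-level transformer over a corpus-built lowercase whitespace
vocabulary with `<pad>/<bos>/<eos>/<unk>` specials; the pooled embedding is
the *EOS output*. The tokenizer interface is pluggable so a pretrained
subword tokenizer can be substituted at larger scales.

**Scale.** The package's defaults are desk scale — 2 transformer layers of
width 64 (2 heads, feed-forward ratio 2) per token encoder and 1 GVP layer
with 32 scalar / 4 vector channels, $k = 16$ neighbours — chosen so the full
pretraining study runs on one CPU in minutes. The documented full-scale
configuration (33 layers × width 1280 for sequences; 4 GVP + 8 transformer
layers for structures; 8 text layers; $k=30$) is expressible through
`encoder_config()` but is not instantiated anywhere in the tests.

## Optimization

AdamW with decoupled weight decay, betas (0.9, 0.95), cosine-annealed
learning rate. Desk-scale defaults: peak learning rate `1e-3`, weight decay
`1e-4`, 16 + 16 pairs per step, 1,500 steps. The documented full-scale
recipe (peak `5e-6`, batches of 80 + 80, 20 epochs) is available as
`alignment_config(scale = "full")`. Training is a pure function of the seed:
sampling, initialization and (where used) dropout all draw from the seeded
R RNG, and a paused run resumed from captured optimizer + RNG state
reproduces the uninterrupted trajectory exactly.

Weights initialize from truncated normals with fan-in-scaled standard
deviation (`1/sqrt(d_in)`) in the transformer blocks, embeddings and
projection heads. The fixed-0.02 convention of large-width transformer
stacks starves early feature learning at width 64 — with it, desk-scale
pretraining learns only class-level alignment within its step budget —
so the width-aware scaling is the default and the fixed variant remains
selectable in the layer constructors.

All numerics run on a small reverse-mode automatic-differentiation engine
written for this package (dense-matrix tape, C++ kernels for layer
normalization, attention and GELU). Every backward rule is validated
against finite differences in the test suite. GELU uses the sigmoid
approximation $x\,\sigma(1.702x)$.

## The synthetic corpus: what it emulates and what it does not

`generate_corpus()` produces records in which the three modalities share
controlled information, standing in for a curated sequence/structure/text
corpus:

* a latent **class** $c \in \{1..K\}$ (default $K = 8$) drawn uniformly;
* an **instance code** of 4 residues placed at a fixed N-terminal window of
  the sequence and spelled letter-by-letter in the text;
* a class **motif** of 5 residues at the next fixed window, over an i.i.d.
  random background (default length 30–50);
* for a `structure_coverage` fraction of records (exactly
  `round(coverage * n)`), an ideal α-helix-like backbone whose geometry
  (rise per residue) is class-specific, with 0.1 Å coordinate noise and a
  random rigid pose;
* a text naming the class keyword and spelling the code.

Consequently sequence↔text share class *and* instance information, while
sequence↔structure share class information only — so instance-level
retrieval isolates the text channel, class-level retrieval isolates the
structure channel, and structure↔text agreement can only arise through the
anchor. The fixed positions of code and motif are deliberate: a code placed
at a random position within an i.i.d. background is not identifiable by any
encoder (the code letters are distributionally indistinguishable from
background), and an instance code exposed as a single opaque token could
never generalize to held-out records whose token was unseen in training.
Fixed windows make both signals learnable by position-aware encoders while
keeping the corpus trivially generatable at any size.

What the generator does **not** emulate: realistic secondary-structure
mixtures, disorder, domain architecture, homology structure between
records, or natural-language variation in the texts. Passing the recovery
tests therefore demonstrates that the alignment mechanics work — losses,
batching, pooling, projection, anchor coupling, frozen-encoder transfer —
not that desk-scale encoders learn biologically meaningful representations.

## Recovery study and numerical choices

The standing evaluation pretrains on 480 of 600 records and evaluates on
the 120 held out: sequence→text instance recall@1, sequence↔structure
class-level top-1, and structure↔text class-level top-1 (the anchor-coupling
probe, chance $1/K$). Problem sizes (600 records, 1,500 steps, batches of
16 + 16) were fixed once as the desk-scale study design.

Numerical conventions: masked softmax uses $-\infty$ logits and a row-max
shift; InfoNCE and cross-entropy use log-sum-exp; L2 normalization guards
with $10^{-12}$; vector norms in GVP layers carry an $10^{-8}$ floor inside
the square root (so the gradient is defined at zero vectors); degenerate
classification ratios (0/0) are reported as 0 and AUC on single-class truth
is an explicit error rather than NaN; ties in AUC use midranks. Zero-length
sequences, empty texts, and structures with no unmasked residue are
rejected at the boundary with named errors.

## Downstream heads

Six frozen-encoder heads mirror the documented task architectures: a
(wild-type, mutant) concatenation MLP with dropout 0.5 and leaky ReLU for
missense-variant pathogenicity; a 128-hidden LayerNorm MLP over structure
embeddings for 5-class thermostability; a channelized 1-D CNN (d→4→4,
kernel 7) with batch norm over zero-padded protein sets for anti-CRISPR
detection; a two-block conv/pool CNN with dropout 0.15 and a 64-wide dense
layer for peptide bioactivity; a 256-hidden MLP regressor for MIC; and a
per-position convolution (kernel 7, same padding) with masked mean pooling
for fitness regression. Optimizer recipes follow the documented settings
per task (Adam/SGD/AdamW, early-stopping rules, schedules); where a recipe
leaves a rule open, the package default is recorded in the head's help page
(the MIC per-epoch multiplier defaults to constant 1; the peptide step
decay to ×0.5 every 50 epochs; hidden sizes quoted at full scale either
scale with the embedding width where proportional — the variant head's
hidden equals the width — or keep their literal values: 128, 256, 64, 4).
Validation splits for early stopping carve 10% of the training set by seed.
Two desk-scale findings are worth noting. First, contrastive pretraining
makes the sequence encoder close to invariant to background residues (they
carry no alignment signal), so downstream tasks must read features the
encoder actually represents: the fitness task plants copies of a single
reference motif, and benign variants substitute inside the represented
instance-code window. Second, single-residue discrimination sits near an
information ceiling for the frozen desk encoder — one substitution barely
moves the pooled embedding — so variant classification recovers the signal
well above chance (F1 around 0.75) but not near-perfectly; at full scale,
with encoders pretrained on real corpora, the same head architecture is the
documented configuration.
Every run digests the encoder weights before and after training and fails
hard if they changed; per-seed metrics are reported with mean ± SD and a
two-sided paired t-test when two variants are compared, with a
zero-variance pair flagged as undefined rather than given a p value.

## Known limitations

* Desk-scale encoders trained from scratch cannot reproduce benchmark
  numbers that depend on large pretrained weights and external datasets;
  the package's claims are mechanistic, and real-data mode (FASTA + PDB +
  manifest input) is functional but exercised only on synthetic files.
* The text tokenizer is whitespace-based; subword models must be plugged in
  for realistic corpora.
* Single-process, CPU-only by design; no distributed training.
* mmCIF, full-atom side chains and live ID-mapping services are out of
  scope; PDB parsing covers standard ATOM records with altloc and
  insertion-code handling (first conformer; insertion codes ordered after
  their base number).
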