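# trimodalign

Contrastive pretraining of protein representations across three modalities
— amino-acid sequence, backbone 3D structure, and free-text functional
description — with the **sequence as the anchor**. A sequence transformer
(BOS pooling), a GVP-GNN + transformer structure encoder (masked mean
pooling over residues), and a text transformer (EOS pooling) are projected
by per-modality heads (LayerNorm + one affine map) into a shared latent
space, where two InfoNCE losses align sequence–structure and sequence–text
pairs:

```
L_{s,r} = -(1/N) Σ_i log[ exp(s_i·r_i/τ) / Σ_j exp(s_i·r_j/τ) ],   τ = 0.07
```

and likewise `L_{s,t}`; training minimizes their equal-weight sum with AdamW
under a cosine schedule, drawing both pair subsets uniformly at random each
step, so records missing a modality still contribute through the channels
they have. Because both losses share the sequence side, structure and text
become aligned **indirectly** — the package measures this anchor coupling as
structure↔text retrieval that is never trained directly.

The package is aimed at method developers who want the full mechanics of
tri-modal anchored alignment — encoders, losses, batching, retrieval
evaluation, frozen-encoder fine-tuning heads, and a controlled synthetic
corpus — runnable and testable on one CPU. Everything trains on a compact
reverse-mode autodiff engine included in the package (R tape + C++ kernels);
no deep-learning framework is required. Desk-scale encoder defaults (2
layers, width 64, 1 GVP layer) pretrain in minutes; the documented
full-scale configuration (33×1280 sequence encoder, 4 GVP + 8 transformer
structure encoder, 8-layer text encoder, batches of 80+80 at learning rate
5e-6 over 20 epochs) is expressible through the same configuration objects.

## A worked example

Generate a seeded tri-modal corpus, pretrain, and evaluate held-out
cross-modal retrieval:

```r
library(trimodalign)

corpus <- generate_corpus(
  synthetic_spec(n = 600, K = 8, structure_coverage = 0.5, seed = 0))
corpus$manifest
#> <corpus_manifest> 600 records: 600 sequence-text pairs, 300 sequence-structure pairs

set.seed(100)
held_out <- sort(sample.int(600, 120))
model <- build_alignment_model(
  text_vocab = build_text_vocab(vapply(corpus$records, `[[`, "", "text")),
  seed = 1)

fit <- pretrain(corpus$records[-held_out],
                alignment_config(steps = 1500, seed = 1), model = model)
fit
#> <alignment_fit> 1500 steps: loss 5.8554 -> 0.0285

evaluate_alignment(fit$model, corpus$records[held_out])
#> # A tibble: 1 x 5
#>   seq_text_recall1 seq_struct_top1 struct_text_top1 n_text_queries n_struct_queries
#>              <dbl>           <dbl>            <dbl>          <int>            <int>
#> 1            0.833           0.881            0.847            120               59
```

Pretraining takes about six minutes on one CPU. On the 120 held-out
records, 83% of sequences rank their own text first among all 120 texts
(instance-level retrieval through the trained sequence-text channel), 88%
of sequences agree with their structure's class, and — although no loss
ever compared structures with texts — 85% of structures retrieve a text of
the correct class, far above the 12.5% chance level: the anchor does the
coupling.

The three retrieval numbers probe three different information channels the
generator builds in: instance-level sequence→text recall@1 (texts spell a
per-record code), class-level sequence↔structure agreement (backbone
geometry is class-specific), and class-level structure↔text agreement —
the anchor-coupling effect, since that pair is never aligned directly
(chance is 1/8).

Downstream, encoders are frozen (enforced by a weight digest) and small
task heads are trained on their embeddings:

```r
ds <- make_task_dataset(corpus, "regression_mic", seed = 0)
res <- run_task(task_spec("regression_mic", seeds = 0:2), ds, fit$model,
                corpus = corpus)
glance(res)
```

`autoplot(fit)` draws the loss trajectory; `tidy()`/`glance()` methods
return tibbles throughout. A thin CLI wrapper
(`inst/cli/trimodalign.R`) exposes `simulate`, `pretrain`, `embed`,
`finetune` and `report` commands over YAML run configs whose digest is
embedded in every output.

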