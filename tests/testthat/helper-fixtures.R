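# Shared fixtures. Everything is generated in code; the expensive desk-scale
# pretraining run is computed once per session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

# Small tri-modal corpus for fast unit tests.
fixture_small_corpus <- function(n = 60, seed = 0) {
  key <- sprintf("corpus_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_corpus(
      synthetic_spec(n = n, K = 8, structure_coverage = 0.5, seed = seed))
  }
  .fixtures[[key]]
}

# The recovery-study conditions: corpus of 600 records (8 classes, structure
# coverage 0.5, generator seed 0), an 80:20 held-out split, desk encoders
# (2 transformer layers of width 64, 1 GVP layer), 1,500 steps of batches of
# 16 + 16 pairs. Pretrained once and shared by the alignment-recovery and
# downstream-recovery tests.
fixture_recovery <- function(seed = 0) {
  key <- sprintf("recovery_%d", seed)
  if (is.null(.fixtures[[key]])) {
    corpus <- generate_corpus(
      synthetic_spec(n = 600, K = 8, structure_coverage = 0.5, seed = 0))
    set.seed(100)
    test_idx <- sort(sample.int(600, 120))
    texts <- vapply(corpus$records, `[[`, "", "text")
    model <- build_alignment_model(text_vocab = build_text_vocab(texts),
                                   seed = seed)
    fit <- pretrain(corpus$records[-test_idx],
                    alignment_config(steps = 1500L, seed = seed),
                    model = model)
    .fixtures[[key]] <- list(corpus = corpus, test_idx = test_idx, fit = fit,
                             model = fit$model)
  }
  .fixtures[[key]]
}

# A small untrained model over the small corpus's vocabulary.
fixture_model <- function(seed = 0) {
  key <- sprintf("model_%d", seed)
  if (is.null(.fixtures[[key]])) {
    corpus <- fixture_small_corpus()
    texts <- vapply(corpus$records, `[[`, "", "text")
    .fixtures[[key]] <- build_alignment_model(
      text_vocab = build_text_vocab(texts), seed = seed)
  }
  .fixtures[[key]]
}

# Finite-difference gradient of a scalar-valued function.
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Evaluate a scalar loss built by `make_loss` (node-in, node-out) and its
# analytic gradient at x0; compare against finite differences.
expect_gradient <- function(make_loss, x0, tol = 1e-5) {
  ns <- asNamespace("trimodalign")
  f <- function(x) {
    p <- ns$ad_param(x)
    ns$ad_tape_start()
    v <- ns$ad_value(make_loss(p))[1, 1]
    ns$ad_tape_clear()
    v
  }
  p <- ns$ad_param(x0)
  ns$ad_tape_start()
  loss <- make_loss(p)
  ns$ad_backward(loss)
  gn <- numeric_gradient(f, x0)
  err <- max(abs(p$grad - gn)) / max(1, max(abs(gn)))
  expect_lt(err, tol)
}

random_rigid_motion <- function(coords) {
  Q <- random_rotation()
  tr <- stats::runif(3, -20, 20)
  for (a in c("N", "CA", "C")) {
    coords[, a, ] <- sweep(matrix(coords[, a, ], ncol = 3) %*% t(Q), 2, tr, "+")
  }
  coords
}

apply_rigid <- function(structure, Q = NULL, tr = c(0, 0, 0)) {
  co <- structure$coords
  n <- structure$n
  take <- function(atom) {
    m <- matrix(co[, atom, ], n, 3)
    if (!is.null(Q)) m <- m %*% t(Q)
    sweep(m, 2, tr, "+")
  }
  suppressWarnings(backbone_structure(take("N"), take("CA"), take("C"),
                                      resno = structure$resno))
}
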