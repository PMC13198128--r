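ns <- asNamespace("trimodalign")

test_that("residue graph degrees, RBF features and termini follow the contract", {
  st <- helix_backbone(10, 1.5, 100, 2.3)
  g <- build_residue_graph(st, k = 30)
  expect_equal(as.integer(table(g$edge_dst)), rep(9L, 10))  # k capped at n - 1

  # RBF feature by direct formula at the observed distance
  centers <- seq(0, 20, length.out = 16)
  sigma <- centers[2] - centers[1]
  e <- 1L
  d <- g$edge_dist[e]
  expect_equal(g$edge_s[e, ], exp(-(d - centers)^2 / (2 * sigma^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a distance exactly at a center peaks at 1
  expect_equal(max(ns$rbf_expand(centers[4])[1, ]), 1.0)

  # zero unmasked residues is an error
  bad <- suppressWarnings(backbone_structure(
    matrix(NA_real_, 2, 3), matrix(NA_real_, 2, 3), matrix(NA_real_, 2, 3)))
  expect_error(build_residue_graph(bad), "unmasked")

  # terminal nodes carry zero forward/backward vectors
  fwd_first <- g$node_v[(10 - 1) * 3 + 1:3, 1]  # forward channel of last residue
  expect_equal(fwd_first, c(0, 0, 0))
  expect_equal(g$node_v[1:3, 2], c(0, 0, 0))    # backward channel of first
})

test_that("GVP layer: identity on identity transform, zero vectors stay zero, equivariance", {
  model <- fixture_model()
  layer <- model$struct$gvp[[1]]
  set.seed(21)
  for (rep in 1:5) {
    st <- helix_backbone(sample(8:20, 1), runif(1, 1.2, 2), 100, 2.3,
                         noise_sd = 0.2)
    g0 <- build_residue_graph(st, k = 8)
    feats <- list(s = matrix(rnorm(g0$n * 32), g0$n, 32),
                  v = g0$node_v %*% matrix(rnorm(12), 3, 4))
    base <- gvp_layer(g0, feats, layer)

    # identical inputs give identical outputs
    again <- gvp_layer(g0, feats, layer)
    expect_identical(base, again)

    # all-zero vector channels in -> all-zero vector channels out
    z <- gvp_layer(build_residue_graph(st, k = 8),
                   list(s = feats$s, v = feats$v * 0), layer)
    # the graph's own edge vectors still feed the layer; zero them too
    gz <- g0; gz$edge_v <- gz$edge_v * 0
    z <- gvp_layer(gz, list(s = feats$s, v = feats$v * 0), layer)
    expect_equal(max(abs(z$v)), 0)

    # rotations: scalars invariant, vectors equivariant
    for (k in 1:4) {
      Q <- random_rotation()
      st_rot <- apply_rigid(st, Q, runif(3, -5, 5))
      g1 <- build_residue_graph(st_rot, k = 8)
      rot3 <- function(V) {
        out <- V
        for (i in seq_len(nrow(V) / 3)) {
          rows <- (i - 1) * 3 + 1:3
          out[rows, ] <- Q %*% V[rows, ]
        }
        out
      }
      feats_rot <- list(s = feats$s, v = rot3(feats$v))
      out_rot <- gvp_layer(g1, feats_rot, layer)
      expect_equal(out_rot$s, base$s, tolerance = 1e-5)
      expect_equal(out_rot$v, rot3(base$v), tolerance = 1e-5)
    }
  }
})

test_that("non-finite GVP features are rejected", {
  model <- fixture_model()
  st <- helix_backbone(6, 1.5, 100, 2.3)
  g <- build_residue_graph(st, k = 5)
  feats <- list(s = matrix(NaN, 6, 32), v = matrix(0, 18, 4))
  expect_error(gvp_layer(g, feats, model$struct$gvp[[1]]), "non-finite")
})

test_that("BOS pooling is the position-0 output and ignores padding", {
  model <- fixture_model()
  r <- fixture_small_corpus()$records[[1]]
  out <- encode_sequence(model, r$sequence)
  expect_equal(out$pooled, unname(out$per_position[1, ]))

  # batched forward pads the shorter record; pooled outputs must not change
  toks1 <- tokenize_sequence(r$sequence)
  toks2 <- tokenize_sequence(strrep("A", nchar(r$sequence) + 17))
  both <- ns$fw_tokens(model$seq, model$meta$seq_cfg, list(toks1, toks2), "bos")
  expect_lt(max(abs(ns$ad_value(both$pooled)[1, ] - out$pooled)), 1e-6)

  # repeated evaluation is bit-identical
  out2 <- encode_sequence(model, r$sequence)
  expect_identical(out$pooled, out2$pooled)
})

test_that("EOS pooling is the EOS-position output and ignores padding", {
  model <- fixture_model()
  r <- fixture_small_corpus()$records[[1]]
  toks <- tokenize_text(r$text, model$meta$text_vocab)
  out <- encode_text(model, toks)
  expect_equal(out$pooled, unname(out$per_position[toks$eos, ]))

  longer <- tokenize_text(paste(r$text, "with further words appended here"),
                          model$meta$text_vocab)
  both <- ns$fw_tokens(model$text, model$meta$text_cfg, list(toks, longer), "eos")
  expect_lt(max(abs(ns$ad_value(both$pooled)[1, ] - out$pooled)), 1e-6)
})

test_that("structure pooling averages per-residue embeddings and handles n = 1", {
  model <- fixture_model()
  st <- helix_backbone(12, 1.5, 100, 2.3, noise_sd = 0.1)
  out <- encode_structure(model, st)
  expect_equal(out$pooled, unname(colMeans(out$per_residue)), tolerance = 1e-12)

  one <- helix_backbone(1, 1.5, 100, 2.3)
  out1 <- encode_structure(model, one)
  expect_equal(out1$pooled, unname(out1$per_residue[1, ]))
})

test_that("pooled structure embeddings are invariant to rigid motions", {
  model <- fixture_model()
  set.seed(22)
  for (rep in 1:5) {
    st <- helix_backbone(sample(10:30, 1), runif(1, 1, 2.5), 100, 2.3,
                         noise_sd = 0.1)
    base <- encode_structure(model, st)$pooled
    for (k in 1:5) {
      moved <- apply_rigid(st, random_rotation(), runif(3, -50, 50))
      p <- encode_structure(model, moved)$pooled
      expect_lt(max(abs(p - base)) / max(abs(base)), 1e-3)
    }
  }
})

test_that("projection outputs are unit-norm, dimension-homogeneous and shift-invariant", {
  model <- fixture_model()
  corpus <- fixture_small_corpus()
  r <- corpus$records[[which(vapply(corpus$records, function(x) !is.null(x$structure), TRUE))[1]]]
  ps <- project(model, encode_sequence(model, r$sequence)$pooled, "sequence")
  pr <- project(model, encode_structure(model, r$structure)$pooled, "structure")
  pt <- project(model, encode_text(model, r$text)$pooled, "text")
  expect_equal(ncol(ps), model$meta$shared_dim)
  expect_equal(ncol(pr), ncol(ps))
  expect_equal(ncol(pt), ncol(ps))
  for (p in list(ps, pr, pt)) expect_equal(sqrt(sum(p^2)), 1, tolerance = 1e-6)

  # layer normalization inside the head removes constant shifts of the input
  emb <- encode_sequence(model, r$sequence)$pooled
  expect_lt(max(abs(project(model, emb + 3.7, "sequence") - ps)), 1e-6)

  expect_error(project(model, emb[1:10], "sequence"), "width")
})

test_that("checkpoints round-trip weights and configuration", {
  model <- fixture_model()
  # perturb a transformer-layer weight so restore is distinguishable from a
  # same-seed re-initialization
  w <- model$seq$tr$layers[[1]]$wqkv$W
  w$value <- w$value + 0.01
  r <- fixture_small_corpus()$records[[1]]
  before <- encode_sequence(model, r$sequence)$pooled
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f, extra = list(note = "unit"))
  back <- load_checkpoint(f)
  expect_identical(encode_sequence(back, r$sequence)$pooled, before)
  expect_equal(attr(back, "checkpoint_extra")$note, "unit")
})
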