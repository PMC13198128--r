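brute_info_nce <- function(q, k, tau) {
  # independent oracle: per-row softmax written out directly
  n <- nrow(q)
  losses <- numeric(n)
  for (i in seq_len(n)) {
    sims <- exp(as.numeric(q[i, ] %*% t(k)) / tau)
    losses[i] <- -log(sims[i] / sum(sims))
  }
  mean(losses)
}

test_that("info_nce matches the brute-force softmax oracle on random instances", {
  set.seed(31)
  for (i in 1:100) {
    q <- matrix(rnorm(64), 8, 8)
    k <- matrix(rnorm(64), 8, 8)
    tau <- runif(1, 0.05, 2)
    expect_equal(info_nce(q, k, tau), brute_info_nce(q, k, tau),
                 tolerance = 1e-6)
  }
})

test_that("info_nce closed forms hold for uniform and orthogonal similarities", {
  for (N in c(2L, 16L, 80L)) {
    q <- matrix(1, N, 4) / 2
    expect_equal(info_nce(q, q, 0.07), log(N), tolerance = 1e-6)
  }
  # N = 2, tau = 1, q_i.k_i = 1 and cross similarities 0
  q <- diag(2)
  expect_equal(info_nce(q, q, 1), log(1 + exp(-1)), tolerance = 1e-6)
})

test_that("info_nce rejects degenerate inputs", {
  expect_error(info_nce(matrix(1, 1, 4), matrix(1, 1, 4)), "N >= 2")
  expect_error(info_nce(matrix(c(1, NA), 2, 2), matrix(1, 2, 2)), "non-finite")
  expect_error(info_nce(matrix(1, 3, 4), matrix(1, 4, 4)), "dimensions")
})

test_that("loss moves monotonically toward log(N) as temperature grows", {
  set.seed(32)
  q <- matrix(rnorm(64), 8, 8); k <- matrix(rnorm(64), 8, 8)
  losses <- vapply(c(0.07, 0.7, 7, 700), function(tau) info_nce(q, k, tau), 1)
  gaps <- abs(losses - log(8))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-3)
})

test_that("combined loss respects weights, missing subsets and row permutations", {
  set.seed(33)
  d <- 16
  unit <- function(n) {
    m <- matrix(rnorm(n * d), n, d)
    m / sqrt(rowSums(m^2))
  }
  s1 <- unit(8); r1 <- unit(8); s2 <- unit(10); t2 <- unit(10)
  cfg <- alignment_config()
  b <- tri_modal_batch(s1, r1, s2, t2, struct_ids = paste0("a", 1:8),
                       text_ids = paste0("b", 1:10))
  out <- combined_loss(b, cfg)
  expect_equal(out$total,
               info_nce(s1, r1, cfg$temperature) + info_nce(s2, t2, cfg$temperature),
               tolerance = 1e-12)

  # missing structure subset contributes zero and is flagged
  b2 <- tri_modal_batch(seq_text = s2, text = t2, text_ids = paste0("b", 1:10))
  out2 <- combined_loss(b2, cfg)
  expect_equal(out2$total, info_nce(s2, t2, cfg$temperature))
  expect_false(out2$terms$present[out2$terms$term == "seq_struct"])

  expect_error(combined_loss(tri_modal_batch(), cfg), "empty")

  # permuting rows within each subset leaves the total unchanged
  p1 <- sample(8); p2 <- sample(10)
  b3 <- tri_modal_batch(s1[p1, ], r1[p1, ], s2[p2, ], t2[p2, ],
                        struct_ids = paste0("a", p1), text_ids = paste0("b", p2))
  expect_equal(combined_loss(b3, cfg)$total, out$total, tolerance = 1e-6)
})

test_that("the optional structure-text term uses records shared by both subsets", {
  set.seed(34)
  d <- 8
  unit <- function(n) { m <- matrix(rnorm(n * d), n, d); m / sqrt(rowSums(m^2)) }
  ids <- paste0("r", 1:6)
  s <- unit(6); r <- unit(6); t <- unit(6)
  cfg <- alignment_config(sta_weight = 0.5)
  b <- tri_modal_batch(s, r, s, t, struct_ids = ids, text_ids = ids)
  out <- combined_loss(b, cfg)
  expect_equal(nrow(out$terms), 3L)
  expect_equal(out$total,
               info_nce(s, r, cfg$temperature) + info_nce(s, t, cfg$temperature) +
                 0.5 * info_nce(r, t, cfg$temperature),
               tolerance = 1e-12)
})

test_that("batch sampling is uniform, exhaustive at the boundary, and seeded", {
  corpus <- fixture_small_corpus(n = 20, seed = 4)
  m <- build_manifest(corpus$records)
  n_struct <- m$n_seq_struct
  cfg <- alignment_config(batch_struct = n_struct, batch_text = 2L)
  set.seed(1)
  plan <- sample_batch(m, cfg)
  expect_setequal(plan$struct_ids, m$seq_struct_pairs)  # exhaustive draw

  set.seed(9); a <- sample_batch(m, cfg)
  set.seed(9); b <- sample_batch(m, cfg)
  expect_identical(a, b)

  cfg_big <- alignment_config(batch_struct = n_struct + 1L, batch_text = 2L)
  expect_error(sample_batch(m, cfg_big), "with_replacement")
  cfg_rep <- alignment_config(batch_struct = n_struct + 1L, batch_text = 2L,
                              sample_with_replacement = TRUE)
  expect_length(sample_batch(m, cfg_rep)$struct_ids, n_struct + 1L)

  # selection frequencies within 3 sigma of uniform over 10,000 draws
  pool <- m$seq_struct_pairs[1:10]
  m10 <- trimodalign:::manifest_from_ids(character(0), pool, 10L)
  cfg2 <- alignment_config(batch_struct = 2L, batch_text = 0L)
  set.seed(2)
  counts <- table(unlist(replicate(10000, sample_batch(m10, cfg2)$struct_ids)))
  p <- 0.2
  sigma <- sqrt(p * (1 - p) * 10000)
  expect_true(all(abs(counts - 2000) < 3 * sigma))
})

test_that("pretraining overfits a single repeated batch and is seed-reproducible", {
  corpus <- fixture_small_corpus(n = 8, seed = 6)
  cfg <- alignment_config(batch_struct = 0L, batch_text = 8L, steps = 200L,
                          seed = 1, schedule = "constant")
  fit <- pretrain(corpus$records, cfg, shared_dim = 16L)
  expect_lt(fit$trajectory$total[200], 0.1 * fit$trajectory$total[1])

  cfg2 <- alignment_config(batch_struct = 0L, batch_text = 8L, steps = 20L, seed = 1)
  f1 <- pretrain(corpus$records, cfg2, shared_dim = 16L)
  f2 <- pretrain(corpus$records, cfg2, shared_dim = 16L)
  expect_identical(f1$trajectory$total, f2$trajectory$total)
})

test_that("a paused run resumed from captured state matches the uninterrupted one", {
  corpus <- fixture_small_corpus(n = 16, seed = 8)
  cfg <- alignment_config(batch_struct = 4L, batch_text = 4L, steps = 40L, seed = 3)
  full <- pretrain(corpus$records, cfg, shared_dim = 16L)
  part <- pretrain(corpus$records, cfg, shared_dim = 16L, stop_after = 20L,
                   keep_state = TRUE)
  rest <- pretrain(corpus$records, cfg, shared_dim = 16L, resume = part$state)
  got <- c(part$trajectory$total, rest$trajectory$total)
  expect_equal(got, full$trajectory$total, tolerance = 1e-12)
})

test_that("missing-modality configs train text-only and divergence is caught", {
  recs <- lapply(1:6, function(i) {
    protein_record(paste0("t", i),
                   paste(sample(AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                20, replace = TRUE), collapse = ""),
                   text = paste("protein number", i))
  })
  cfg <- alignment_config(batch_struct = 0L, batch_text = 4L, steps = 5L, seed = 0)
  fit <- pretrain(recs, cfg, shared_dim = 8L)
  expect_true(all(is.na(fit$trajectory$loss_seq_struct)))
  expect_true(all(is.finite(fit$trajectory$loss_seq_text)))

  cfg_bad <- alignment_config(batch_struct = 4L, batch_text = 4L, steps = 5L)
  expect_error(pretrain(recs, cfg_bad, shared_dim = 8L), "no sequence-structure|none")
})

test_that("retrieval ranks, recall and class-level top-1 behave at the extremes", {
  set.seed(35)
  q <- matrix(rnorm(200), 20, 10)
  self <- retrieve(q, q, k = 1L)
  expect_equal(unname(self$recall_at_k[1]), 1.0)

  labs <- rep(1L, 20)
  expect_equal(retrieve(q, matrix(rnorm(200), 20, 10), labels = labs)$class_top1, 1.0)

  expect_error(retrieve(q, q, k = 21L), "gallery")

  # chance level for random unit vectors: recall@1 near 1/N over 50 seeds
  r1 <- vapply(1:50, function(s) {
    set.seed(s)
    a <- matrix(rnorm(100 * 16), 100, 16)
    b <- matrix(rnorm(100 * 16), 100, 16)
    unname(retrieve(a, b, k = 1L)$recall_at_k[1])
  }, 1)
  p <- 1 / 100
  se <- sqrt(p * (1 - p) / 100) / sqrt(50)
  expect_lt(abs(mean(r1) - p), 3 * se + 1e-9)
})
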