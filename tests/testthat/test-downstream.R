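ns <- asNamespace("trimodalign")

test_that("head architectures satisfy their output contracts", {
  set.seed(51)
  d <- 16L
  # variant: softmax over 2 classes on concatenated (wt, mut) embeddings
  vh <- variant_head(d)
  x <- matrix(rnorm(6 * 2 * d), 6, 2 * d)
  pr <- predict_head(vh, x)
  z <- ns$ad_value(vh$forward(vh, x, training = FALSE))
  p2 <- exp(z) / rowSums(exp(z))
  expect_equal(unname(pr$prob), unname(p2[, 2]), tolerance = 1e-12)
  expect_true(all(abs(rowSums(p2) - 1) < 1e-12))
  # concatenation order matters: swapping wt and mut changes the logits
  swapped <- cbind(x[, (d + 1):(2 * d)], x[, 1:d])
  expect_gt(max(abs(ns$ad_value(vh$forward(vh, swapped)) - z)), 0)
  expect_error(vh$forward(vh, x[, 1:d, drop = FALSE]), "2d")

  # thermostability: 5 logits
  th <- thermostability_head(d)
  expect_equal(ncol(ns$ad_value(th$forward(th, matrix(rnorm(3 * d), 3)))), 5L)

  # peptide: sigmoid output strictly inside (0, 1)
  ph <- peptide_head(d)
  pp <- predict_head(ph, matrix(rnorm(4 * d), 4))
  expect_true(all(pp$prob > 0 & pp$prob < 1))

  # MIC: one scalar per example
  mh <- mic_head(d)
  expect_length(predict_head(mh, matrix(rnorm(5 * d), 5)), 5L)

  # fitness: a length-1 per-position input is valid under same padding
  fh <- fitness_head(d)
  expect_length(predict_head(fh, list(matrix(rnorm(d), 1, d))), 1L)
  expect_error(fh$forward(fh, list(matrix(0, 0, d))), "zero-length")

  # anti-CRISPR: needs an Acr plus a non-empty Cas set
  ah <- acr_head(d)
  expect_error(ah$forward(ah, list(matrix(rnorm(d), 1, d))), "Cas")
  out <- predict_head(ah, list(matrix(rnorm(3 * d), 3, d),
                               matrix(rnorm(2 * d), 2, d)))
  expect_length(out$prob, 2L)
})

test_that("acr convolutions treat padded set positions as exact zeros", {
  set.seed(52)
  d <- 8L
  ah <- acr_head(d)
  a <- matrix(rnorm(2 * d), 2, d)
  b <- matrix(rnorm(4 * d), 4, d)
  # forward of [a] alone vs [a] padded within a batch containing a longer set:
  # the masked mean and masked batch norm must make a's logits identical in
  # eval mode regardless of the padding introduced by b
  z_alone <- ns$ad_value(ah$forward(ah, list(a), training = FALSE))
  z_batch <- ns$ad_value(ah$forward(ah, list(a, b), training = FALSE))
  expect_equal(z_batch[1, ], z_alone[1, ], tolerance = 1e-9)
})

test_that("deterministic eval-mode forwards and seeded training trajectories", {
  set.seed(53)
  d <- 8L
  x <- matrix(rnorm(40 * d), 40, d)
  y <- rbinom(40, 1, 0.5)
  mh1 <- mic_head(d)
  expect_identical(predict_head(mh1, x), predict_head(mh1, x))

  train_once <- function(seed) {
    set.seed(seed)
    h <- peptide_head(d)
    fit_head(h, x, y, recipe = list(epochs = 3L, batch = 8L))$history$train_loss
  }
  expect_identical(train_once(4), train_once(4))
  expect_false(identical(train_once(4), train_once(5)))
})

test_that("paired comparison reproduces the closed-form t statistic", {
  a <- structure(list(task = "x", seeds = 0:4,
                      per_seed = tibble::tibble(seed = 0:4, metric = "f1",
                                                value = c(0.71, 0.74, 0.69, 0.72, 0.73)),
                      summary = NULL), class = "task_result")
  b <- a
  b$per_seed$value <- c(0.65, 0.70, 0.66, 0.68, 0.64)
  out <- compare_task_results(a, b, "f1")
  dd <- a$per_seed$value - b$per_seed$value
  t_manual <- mean(dd) / (sd(dd) / sqrt(5))
  expect_equal(out$statistic, t_manual, tolerance = 1e-9)
  expect_equal(out$p_value, 2 * pt(-abs(t_manual), df = 4), tolerance = 1e-9)

  self <- compare_task_results(a, a, "f1")
  expect_true(self$undefined_variance)
  expect_true(is.na(self$p_value))
})

test_that("run_task reports per-seed metrics, mean/SD, and keeps encoders frozen", {
  rec <- fixture_recovery()
  corpus <- rec$corpus
  model <- rec$model
  ds <- make_task_dataset(corpus, "regression_mic", seed = 0)
  spec <- task_spec("regression_mic", seeds = 0:1,
                    recipe = list(epochs = 30L))
  digest_before <- ns$nn_weight_digest(model[c("seq", "text", "struct", "proj")])
  res <- run_task(spec, ds, model, corpus = corpus)
  digest_after <- ns$nn_weight_digest(model[c("seq", "text", "struct", "proj")])
  expect_identical(digest_before, digest_after)
  expect_equal(sort(unique(res$per_seed$seed)), 0:1)
  m <- res$per_seed$value[res$per_seed$metric == "r2"]
  expect_equal(res$summary$mean[res$summary$metric == "r2"], mean(m))
  expect_equal(res$summary$sd[res$summary$metric == "r2"], sd(m))
})

test_that("variant and anti-CRISPR heads recover their synthetic tasks", {
  rec <- fixture_recovery()
  corpus <- rec$corpus
  model <- rec$model

  # Single-substitution discrimination sits near its information ceiling for
  # a frozen desk-scale encoder (the embedding barely moves under one
  # residue change); the head must still recover the signal far above the
  # 0.5 chance level. The learning-rate override is the desk-scale recipe
  # (the documented rate targets 1280-wide embeddings).
  ds <- make_task_dataset(corpus, "pairwise_variant", seed = 0)
  res <- run_task(task_spec("pairwise_variant", seeds = 0L,
                            recipe = list(lr = 1e-3, epochs = 400L,
                                          patience = 40L)),
                  ds, model, corpus = corpus)
  expect_gte(res$summary$mean[res$summary$metric == "f1"], 0.65)

  ds2 <- make_task_dataset(corpus, "acr_pairing", seed = 0)
  res2 <- run_task(task_spec("acr_pairing", seeds = 0L), ds2, model,
                   corpus = corpus)
  expect_gte(res2$summary$mean[res2$summary$metric == "acc"], 0.85)
})
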