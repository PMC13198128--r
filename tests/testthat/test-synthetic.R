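test_that("helix geometry matches the closed-form chord length", {
  st <- helix_backbone(30, rise = 1.5, turn = 100, radius = 2.3,
                       noise_sd = 0, pose = FALSE)
  d <- ca_distances(st)
  expected <- sqrt(1.5^2 + (2 * 2.3 * sin(50 * pi / 180))^2)
  expect_equal(unname(d), rep(expected, 29), tolerance = 1e-12)
  expect_equal(expected, 3.83, tolerance = 0.005)

  one <- helix_backbone(1, 1.5, 100, 2.3)
  expect_equal(one$n, 1L)
  expect_true(all(one$mask))
  expect_error(helix_backbone(5, -1, 100, 2.3))
})

test_that("helix generation is deterministic under a fixed RNG state", {
  set.seed(77); a <- helix_backbone(15, 1.5, 100, 2.3, noise_sd = 0.1)
  set.seed(77); b <- helix_backbone(15, 1.5, 100, 2.3, noise_sd = 0.1)
  expect_identical(a$coords, b$coords)
})

test_that("rigid poses do not change internal geometry", {
  set.seed(78)
  nopose <- helix_backbone(20, 1.8, 100, 2.3, pose = FALSE)
  posed <- helix_backbone(20, 1.8, 100, 2.3, pose = TRUE)
  expect_equal(ca_distances(posed), ca_distances(nopose), tolerance = 1e-9)
})

test_that("corpus generation is reproducible and respects coverage exactly", {
  spec <- synthetic_spec(n = 120, K = 8, structure_coverage = 0.37, seed = 5)
  a <- generate_corpus(spec)
  b <- generate_corpus(spec)
  expect_identical(a$records, b$records)
  n_struct <- sum(vapply(a$records, function(r) !is.null(r$structure), TRUE))
  expect_equal(n_struct, round(0.37 * 120))
  expect_equal(a$manifest$n_seq_struct, n_struct)
  expect_equal(a$manifest$n_seq_text, 120L)

  empty <- generate_corpus(synthetic_spec(n = 0, K = 8, seed = 1))
  expect_length(empty$records, 0L)
  expect_equal(empty$manifest$n_seq_struct, 0L)
  expect_equal(empty$manifest$n_seq_text, 0L)
})

test_that("class draws are uniform within 3 sigma at n = 10,000", {
  corpus <- generate_corpus(synthetic_spec(n = 10000, K = 8,
                                           structure_coverage = 0, seed = 11))
  counts <- table(vapply(corpus$records, function(r) r$class_label, 1L))
  expected <- 10000 / 8
  sigma <- sqrt(10000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("a rule-based motif reader attains perfect class accuracy from sequence", {
  corpus <- generate_corpus(synthetic_spec(n = 1000, K = 8,
                                           structure_coverage = 0, seed = 13))
  motifs <- corpus$motifs
  spec <- corpus$spec
  pred <- vapply(corpus$records, function(r) {
    window <- substr(r$sequence, spec$id_code_len + 1L,
                     spec$id_code_len + spec$motif_len)
    match(window, motifs)
  }, 1L)
  truth <- vapply(corpus$records, function(r) r$class_label, 1L)
  expect_equal(pred, truth)
})

test_that("noiseless per-class CA-CA distances are separated by at least 0.1 A", {
  spec <- synthetic_spec(n = 8, K = 8, seed = 0)
  d <- vapply(seq_len(8), function(cl) {
    g <- spec$geometry[cl, ]
    mean(ca_distances(helix_backbone(20, g$rise, g$turn, g$radius,
                                     noise_sd = 0, pose = FALSE)))
  }, 1)
  expect_true(all(diff(sort(d)) >= 0.1))
})

test_that("texts carry the class keyword and the spelled instance code", {
  corpus <- fixture_small_corpus(n = 30, seed = 2)
  spec <- corpus$spec
  for (r in corpus$records[1:10]) {
    expect_match(r$text, spec$class_words[r$class_label], fixed = TRUE)
    code <- tolower(substr(r$sequence, 1, spec$id_code_len))
    spelled <- paste(strsplit(code, "")[[1]], collapse = " ")
    expect_match(r$text, spelled, fixed = TRUE)
  }
})

test_that("task datasets derive labels from the latent class as documented", {
  corpus <- fixture_small_corpus(n = 60, seed = 1)
  classes <- vapply(corpus$records, function(r) r$class_label, 1L)

  ds <- make_task_dataset(corpus, "binary_peptide", seed = 0)
  all_lab <- rbind(ds$train, ds$test)
  expect_equal(all_lab$label[order(all_lab$id)],
               (classes %% 2L)[order(vapply(corpus$records, `[[`, "", "id"))])

  # noiseless regression targets are an exact affine function of class
  ds2 <- make_task_dataset(corpus, "regression_mic", seed = 0, noise_sd = 0,
                           slope = 0.5, intercept = 1)
  both <- rbind(ds2$train, ds2$test)
  cls_by_id <- stats::setNames(classes, vapply(corpus$records, `[[`, "", "id"))
  expect_equal(both$target, 0.5 * unname(cls_by_id[both$id]) + 1)

  # thermostability bins only cover records with structure
  ds3 <- make_task_dataset(corpus, "five_class_thermo", seed = 0)
  n_struct <- sum(vapply(corpus$records, function(r) !is.null(r$structure), TRUE))
  expect_equal(nrow(ds3$train) + nrow(ds3$test), n_struct)
  expect_true(all(ds3$train$label %in% 1:5))

  expect_error(make_task_dataset(corpus, "nope"), "unknown task")
})

test_that("80:20 splits use the floor rule: n = 600 gives (480, 120)", {
  corpus <- generate_corpus(synthetic_spec(n = 600, K = 8,
                                           structure_coverage = 0, seed = 3))
  ds <- make_task_dataset(corpus, "binary_peptide", seed = 0, split = 0.8)
  expect_equal(nrow(ds$train), 480L)
  expect_equal(nrow(ds$test), 120L)
})

test_that("variant pairs flip exactly one residue, inside or outside the motif", {
  corpus <- fixture_small_corpus(n = 40, seed = 7)
  ds <- make_task_dataset(corpus, "pairwise_variant", seed = 0)
  tab <- rbind(ds$train, ds$test)
  spec <- corpus$spec
  motif_span <- spec$id_code_len + seq_len(spec$motif_len)
  for (i in seq_len(nrow(tab))) {
    wt <- strsplit(tab$wt_sequence[i], "")[[1]]
    mt <- strsplit(tab$mut_sequence[i], "")[[1]]
    diff_pos <- which(wt != mt)
    expect_length(diff_pos, 1L)
    expect_equal(as.integer(diff_pos %in% motif_span), tab$label[i])
  }
})

test_that("fitness scores count reference-motif copies planted in the sequence", {
  corpus <- fixture_small_corpus(n = 40, seed = 8)
  ds <- make_task_dataset(corpus, "fitness", seed = 0)
  tab <- rbind(ds$train, ds$test)
  ref <- corpus$motifs[1]
  for (i in seq_len(nrow(tab))) {
    hits <- gregexpr(ref, tab$sequence[i], fixed = TRUE)[[1]]
    expect_equal(sum(hits > 0), tab$score[i])
  }
  expect_gte(max(tab$score), 2)  # copies actually get planted
})

test_that("anti-CRISPR pairing labels are balanced by construction", {
  corpus <- fixture_small_corpus(n = 60, seed = 1)
  ds <- make_task_dataset(corpus, "acr_pairing", seed = 0)
  lab <- c(ds$train$label, ds$test$label)
  expect_gt(mean(lab), 0.3)
  expect_lt(mean(lab), 0.7)
  # labels really reflect class agreement
  cls <- stats::setNames(vapply(corpus$records, function(r) r$class_label, 1L),
                         vapply(corpus$records, `[[`, "", "id"))
  tab <- rbind(ds$train, ds$test)
  expect_equal(tab$label,
               as.integer(unname(cls[tab$id]) == unname(cls[tab$partner_id])))
})
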