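test_that("FASTA reading handles empty files, single entries and errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_identical(read_fasta(f), list())

  writeLines(c(">P1 some description", "MKV"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "P1")
  expect_equal(recs[[1]]$sequence, "MKV")

  writeLines(c("MKV", ">P1"), f)
  expect_error(read_fasta(f), "line 1")

  writeLines(c(">P1", "MKV", ">P2", "", ">P3", "ACD"), f)
  expect_error(read_fasta(f), "P2")
})

test_that("FASTA normalization uppercases and maps non-standard residues to X", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "mkvBzuoj"), f)
  recs <- read_fasta(f)
  expect_equal(recs[[1]]$sequence, "MKVXXXXX")
})

test_that("FASTA write -> read round-trips random records identically", {
  set.seed(42)
  recs <- lapply(1:50, function(i) {
    protein_record(sprintf("R%02d", i),
                   paste(sample(aa_alphabet(), sample(5:120, 1), replace = TRUE),
                         collapse = ""))
  })
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f, width = 60L)
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, "", "id"), vapply(recs, `[[`, "", "id"))
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
})

test_that("backbone reading parses minimal files and masks incomplete residues", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), f)
  st <- read_backbone(f, "A")
  expect_equal(st$n, 1L)
  expect_true(all(st$mask))
  expect_equal(unname(st$coords[1, "CA", ]), c(1.458, 0, 0))

  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   ALA A   2       3.000   2.000   0.000  1.00  0.00           N",
    "ATOM      5  C   ALA A   2       4.500   3.400   0.000  1.00  0.00           C",
    "END"), f)
  st <- suppressWarnings(read_backbone(f, "A"))
  expect_equal(st$n, 2L)
  expect_equal(st$mask, c(TRUE, FALSE))

  expect_error(read_backbone(f, "B"), "chain 'B'")
})

test_that("backbone write -> read round-trips helical structures to 1e-3 A", {
  set.seed(7)
  for (i in 1:20) {
    st <- helix_backbone(sample(5:40, 1), rise = runif(1, 1, 2),
                         turn = runif(1, 80, 120), radius = runif(1, 1.8, 2.6),
                         noise_sd = 0.05)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_backbone(st, f)
    back <- read_backbone(f, "A")
    expect_equal(back$n, st$n)
    expect_lt(max(abs(back$coords - st$coords)), 1e-3)
  }
})

test_that("length filtering keeps 300, drops 301, preserves order, is idempotent", {
  mk <- function(id, len) protein_record(id, strrep("A", len))
  recs <- list(mk("a", 300), mk("b", 301), mk("c", 10), mk("d", 300))
  out <- filter_by_length(recs)
  expect_equal(vapply(out, `[[`, "", "id"), c("a", "c", "d"))
  expect_identical(filter_by_length(out), out)
  expect_identical(filter_by_length(list()), list())
})

test_that("manifest counts match brute-force enumeration and flag duplicates", {
  corpus <- fixture_small_corpus(n = 100, seed = 3)
  m <- build_manifest(corpus$records)
  n_text <- sum(vapply(corpus$records, function(r) !is.null(r$text), TRUE))
  n_struct <- sum(vapply(corpus$records, function(r) !is.null(r$structure), TRUE))
  expect_equal(m$n_seq_text, n_text)
  expect_equal(m$n_seq_struct, n_struct)
  expect_setequal(m$seq_struct_pairs,
                  vapply(Filter(function(r) !is.null(r$structure), corpus$records),
                         `[[`, "", "id"))

  dup <- c(corpus$records[1], corpus$records[1])
  expect_error(build_manifest(dup), "duplicate")

  none <- lapply(1:5, function(i) protein_record(paste0("x", i), "MKV"))
  expect_equal(build_manifest(none)$n_seq_struct, 0L)
})

test_that("record invariants: structure length must match sequence length", {
  st <- helix_backbone(10, 1.5, 100, 2.3)
  expect_error(protein_record("x", strrep("A", 9), structure = st), "9")
  expect_silent(protein_record("x", strrep("A", 10), structure = st))
})

test_that("sequence tokenizer emits BOS/EOS and inverts exactly", {
  t1 <- tokenize_sequence("M")
  expect_length(t1$token_ids, 3L)
  expect_equal(t1$bos, 1L)
  expect_equal(t1$eos, 3L)
  expect_equal(tokenize_sequence("mkv")$token_ids, tokenize_sequence("MKV")$token_ids)
  expect_error(tokenize_sequence("MK1"), "non-letter")

  set.seed(5)
  for (i in 1:100) {
    s <- paste(sample(aa_alphabet(), sample(1:80, 1), replace = TRUE), collapse = "")
    expect_identical(detokenize_sequence(tokenize_sequence(s)), s)
  }
})

test_that("text tokenizer folds case, appends EOS, and builds exact vocabularies", {
  docs <- c("Kinase binds ATP", "a viral Protease", "kinase again")
  vocab <- build_text_vocab(docs)
  words <- setdiff(vocab, c("<pad>", "<bos>", "<eos>", "<unk>"))
  expect_setequal(words, c("kinase", "binds", "atp", "a", "viral", "protease", "again"))

  expect_identical(tokenize_text("Kinase", vocab)$token_ids,
                   tokenize_text("kinase", vocab)$token_ids)
  one <- tokenize_text("kinase", vocab)
  expect_length(one$token_ids, 2L)
  expect_equal(one$eos, 2L)
  oov <- tokenize_text("unseen", vocab)
  expect_equal(oov$token_ids[1], match("<unk>", vocab))
  expect_error(tokenize_text("   ", vocab), "empty")
})

test_that("corpus write -> read round-trips records including structures and labels", {
  corpus <- fixture_small_corpus(n = 20, seed = 9)
  dir <- withr::local_tempdir()
  mp <- write_corpus(corpus$records, dir)
  back <- suppressWarnings(read_corpus(mp))  # CA-CA validation warnings ok
  expect_equal(length(back), 20L)
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(corpus$records, `[[`, "", "sequence"))
  expect_equal(vapply(back, function(r) r$class_label, 1L),
               vapply(corpus$records, function(r) r$class_label, 1L))
  has_st <- vapply(corpus$records, function(r) !is.null(r$structure), TRUE)
  expect_equal(vapply(back, function(r) !is.null(r$structure), TRUE), has_st)
  i <- which(has_st)[1]
  expect_lt(max(abs(back[[i]]$structure$coords - corpus$records[[i]]$structure$coords)),
            1e-3)
})
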