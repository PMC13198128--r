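# Corpus input/output: protein records, FASTA and PDB backbone parsing,
# length filtering, pairing manifest, and sequence/text tokenizers.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALPHABET <- c(AA20, "X")
SEQ_SPECIALS <- c("<pad>", "<bos>", "<eos>")
SEQ_VOCAB <- c(SEQ_SPECIALS, AA_ALPHABET)
TEXT_SPECIALS <- c("<pad>", "<bos>", "<eos>", "<unk>")

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues plus `X`, the catch-all for non-standard residues
#' (`B`, `Z`, `U`, `O`, `J` and anything else outside the standard 20).
#'
#' @return character vector of 21 single-letter codes
#' @export
aa_alphabet <- function() AA_ALPHABET

#' Normalize an amino-acid sequence
#'
#' Uppercases and maps non-standard residue letters to `X`. Non-letter
#' characters raise an error.
#'
#' @param sequence character scalar
#' @return normalized sequence string
#' @export
normalize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  bad <- !grepl("^[A-Z]$", chars)
  if (any(bad)) {
    stop("sequence contains non-letter characters: ",
         paste(unique(chars[bad]), collapse = " "))
  }
  chars[!(chars %in% AA20)] <- "X"
  paste(chars, collapse = "")
}

# ---- domain types ------------------------------------------------------------

#' Backbone structure (N, CA, C coordinates per residue)
#'
#' @param n_xyz,ca_xyz,c_xyz numeric n x 3 matrices of coordinates in Angstrom;
#'   rows with any missing (NA) atom are masked out
#' @param resno optional residue numbering kept as metadata only
#' @return an object of class `backbone_structure` with fields `coords`
#'   (n x 3 atoms x 3 xyz array), `mask` (TRUE iff all three atoms present)
#'   and `resno`
#' @details Consecutive unmasked CA-CA distances outside (2, 5) Angstrom raise
#'   a warning (chain breaks and clashes are tolerated, but flagged).
#' @export
backbone_structure <- function(n_xyz, ca_xyz, c_xyz, resno = NULL) {
  n_xyz <- as_xyz(n_xyz); ca_xyz <- as_xyz(ca_xyz); c_xyz <- as_xyz(c_xyz)
  n <- nrow(ca_xyz)
  stopifnot(nrow(n_xyz) == n, nrow(c_xyz) == n)
  coords <- array(NA_real_, dim = c(n, 3L, 3L),
                  dimnames = list(NULL, c("N", "CA", "C"), c("x", "y", "z")))
  coords[, "N", ] <- n_xyz
  coords[, "CA", ] <- ca_xyz
  coords[, "C", ] <- c_xyz
  mask <- apply(coords, 1L, function(r) all(is.finite(r)))
  bad_inf <- apply(coords, 1L, function(r) any(is.infinite(r) | is.nan(r)))
  if (any(bad_inf)) stop("backbone coordinates must be finite or NA")
  if (is.null(resno)) resno <- seq_len(n)
  obj <- structure(list(coords = coords, mask = mask, resno = resno, n = n),
                   class = "backbone_structure")
  dd <- ca_distances(obj)
  if (length(dd) && any(dd <= 2.0 | dd >= 5.0)) {
    warning(sprintf("%d consecutive CA-CA distance(s) outside (2, 5) Angstrom",
                    sum(dd <= 2.0 | dd >= 5.0)))
  }
  obj
}

as_xyz <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == 3L)
  storage.mode(m) <- "double"
  m
}

# Distances between consecutive *unmasked* CA atoms.
ca_distances <- function(structure) {
  ca <- structure$coords[structure$mask, "CA", , drop = FALSE]
  k <- dim(ca)[1]
  if (k < 2L) return(numeric(0))
  ca <- matrix(ca, k, 3L)
  sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-k, , drop = FALSE])^2))
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("<backbone_structure> %d residues (%d masked)\n",
              x$n, sum(!x$mask)))
  invisible(x)
}

#' One protein record: sequence plus optional structure, text and class label
#'
#' @param id record identifier
#' @param sequence amino-acid sequence (normalized on construction)
#' @param structure optional [backbone_structure()]; if present its residue
#'   count must equal the sequence length
#' @param text optional free-text functional description
#' @param class_label optional integer label (synthetic provenance only)
#' @return an object of class `protein_record`
#' @export
protein_record <- function(id, sequence, structure = NULL, text = NULL,
                           class_label = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_sequence(sequence)
  if (!nzchar(sequence)) stop("record '", id, "': empty sequence")
  if (!is.null(structure)) {
    stopifnot(inherits(structure, "backbone_structure"))
    if (structure$n != nchar(sequence)) {
      stop(sprintf(
        "record '%s': structure has %d residues but sequence has %d; crop the sequence to the structurally resolved span before pairing",
        id, structure$n, nchar(sequence)))
    }
  }
  if (!is.null(text)) {
    stopifnot(is.character(text), length(text) == 1L)
    if (!nzchar(trimws(text))) stop("record '", id, "': empty text")
  }
  structure(list(id = id, sequence = sequence, structure = structure,
                 text = text, class_label = class_label),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa%s%s\n", x$id, nchar(x$sequence),
              if (!is.null(x$structure)) " +structure" else "",
              if (!is.null(x$text)) " +text" else ""))
  invisible(x)
}

# ---- FASTA -------------------------------------------------------------------

#' Read protein sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are uppercased and non-standard residues mapped to `X`.
#'
#' @param path FASTA file (wrapped or unwrapped lines)
#' @return list of sequence-only [protein_record()]s (empty file gives an
#'   empty list)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) return(list())
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA header at line %d of %s: expected '>'",
                 first, path))
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) return(list())
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA record(s) with empty sequence body: ",
         paste(ids[empty], collapse = ", "))
  }
  unname(Map(function(id, s) protein_record(id, s), ids, seqs))
}

#' Write protein records to a FASTA file
#'
#' @param records list of [protein_record()]
#' @param path output file
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 60L) {
  seqs <- Biostrings::BStringSet(vapply(records, function(r) r$sequence, ""))
  names(seqs) <- vapply(records, function(r) r$id, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# ---- PDB backbone ------------------------------------------------------------

#' Read backbone N/CA/C coordinates from a PDB file
#'
#' Residues are ordered by residue sequence number (insertion codes
#' lexicographically after their base number); alternate locations resolve to
#' the first-listed conformer; a residue missing any of N, CA or C is masked.
#'
#' @param path PDB-format file with ATOM records
#' @param chain chain identifier (default `"A"`)
#' @return a [backbone_structure()]
#' @export
read_backbone <- function(path, chain = "A") {
  stopifnot(file.exists(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain &
             at$elety %in% c("N", "CA", "C"), , drop = FALSE]
  if (!nrow(at)) {
    stop(sprintf("no ATOM records for chain '%s' in %s", chain, path))
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  key <- paste(at$resno, ins, sep = "|")
  # first-listed conformer wins for duplicated (residue, atom) entries
  dup <- duplicated(paste(key, at$elety))
  at <- at[!dup, , drop = FALSE]
  key <- key[!dup]; ins <- ins[!dup]
  ord_keys <- unique(key[order(at$resno, ins)])
  n <- length(ord_keys)
  get_atom <- function(elety) {
    m <- matrix(NA_real_, n, 3L)
    sel <- at$elety == elety
    idx <- match(key[sel], ord_keys)
    m[idx, ] <- cbind(at$x[sel], at$y[sel], at$z[sel])
    m
  }
  resno <- at$resno[match(ord_keys, key)]
  backbone_structure(get_atom("N"), get_atom("CA"), get_atom("C"),
                     resno = resno)
}

#' Write a backbone structure as PDB ATOM records
#'
#' @param structure a [backbone_structure()]
#' @param path output file
#' @param chain chain identifier
#' @return `path`, invisibly
#' @export
write_backbone <- function(structure, path, chain = "A") {
  keep <- which(structure$mask)
  if (!length(keep)) stop("cannot write a structure with no unmasked residue")
  atoms <- c("N", "CA", "C")
  xyz <- do.call(rbind, lapply(keep, function(i) structure$coords[i, atoms, ]))
  n_at <- 3L * length(keep)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("ATOM", n_at),
    resno = rep(structure$resno[keep], each = 3L),
    resid = rep("ALA", n_at),
    chain = rep(chain, n_at),
    elety = rep(atoms, length(keep)),
    eleno = seq_len(n_at),
    o = rep(1, n_at), b = rep(0, n_at)
  )
  invisible(path)
}

# ---- filtering and manifest --------------------------------------------------

#' Drop records whose sequence exceeds a maximum length
#'
#' Records strictly longer than `max_len` residues are removed (a record of
#' exactly `max_len` is retained); order is preserved.
#'
#' @param records list of [protein_record()]
#' @param max_len maximum retained length (default 300)
#' @return filtered list
#' @export
filter_by_length <- function(records, max_len = 300L) {
  Filter(function(r) nchar(r$sequence) <= max_len, records)
}

#' Build the pairing manifest of a corpus
#'
#' @param records list of validated [protein_record()]s with unique ids
#' @return an object of class `corpus_manifest` with fields `seq_text_pairs`,
#'   `seq_struct_pairs` (record ids), their counts and the total record count
#' @export
build_manifest <- function(records) {
  ids <- vapply(records, function(r) r$id, "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate record ids: ", paste(dup, collapse = ", "))
  }
  has_text <- vapply(records, function(r) !is.null(r$text), TRUE)
  has_struct <- vapply(records, function(r) !is.null(r$structure), TRUE)
  manifest_from_ids(ids[has_text], ids[has_struct], length(records))
}

#' Build a manifest from pairing metadata alone
#'
#' For corpus-scale bookkeeping where the records themselves are not loaded:
#' takes the id lists of the two pair types and the total record count.
#'
#' @param seq_text_ids ids of records with a text description
#' @param seq_struct_ids ids of records with a structure
#' @param n_records total record count
#' @return a `corpus_manifest`
#' @export
manifest_from_metadata <- function(seq_text_ids, seq_struct_ids, n_records) {
  stopifnot(!anyDuplicated(seq_text_ids), !anyDuplicated(seq_struct_ids),
            n_records >= length(seq_text_ids),
            n_records >= length(seq_struct_ids))
  manifest_from_ids(seq_text_ids, seq_struct_ids, as.integer(n_records))
}

manifest_from_ids <- function(seq_text_ids, seq_struct_ids, n_records) {
  structure(list(
    seq_text_pairs = as.character(seq_text_ids),
    seq_struct_pairs = as.character(seq_struct_ids),
    n_seq_text = length(seq_text_ids),
    n_seq_struct = length(seq_struct_ids),
    n_records = n_records
  ), class = "corpus_manifest")
}

#' @export
print.corpus_manifest <- function(x, ...) {
  cat(sprintf("<corpus_manifest> %d records: %d sequence-text pairs, %d sequence-structure pairs\n",
              x$n_records, x$n_seq_text, x$n_seq_struct))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble corpus_manifest
#' @export
as_tibble.corpus_manifest <- function(x, ...) {
  ids <- union(x$seq_text_pairs, x$seq_struct_pairs)
  tibble::tibble(
    id = ids,
    has_text = ids %in% x$seq_text_pairs,
    has_structure = ids %in% x$seq_struct_pairs
  )
}

#' Write / read a corpus manifest table
#'
#' The on-disk manifest is a tab-separated table with columns `id`,
#' `fasta_path`, `pdb_path` (empty when no structure), `text` (empty when no
#' text) and optionally `class_label`.
#'
#' @param records list of [protein_record()]
#' @param dir output directory; FASTA and PDB files are written under it
#' @param name base name for the corpus files
#' @return path of the manifest file, invisibly
#' @export
write_corpus <- function(records, dir, name = "corpus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(name, ".fasta"))
  write_fasta(records, fasta)
  pdb_dir <- file.path(dir, "pdb")
  rows <- lapply(records, function(r) {
    pdb_path <- ""
    if (!is.null(r$structure)) {
      dir.create(pdb_dir, showWarnings = FALSE)
      pdb_path <- file.path(pdb_dir, paste0(r$id, ".pdb"))
      write_backbone(r$structure, pdb_path)
    }
    tibble::tibble(
      id = r$id, fasta_path = fasta, pdb_path = pdb_path,
      text = if (is.null(r$text)) "" else r$text,
      class_label = if (is.null(r$class_label)) NA_integer_ else r$class_label
    )
  })
  manifest_path <- file.path(dir, paste0(name, "_manifest.tsv"))
  readr::write_tsv(dplyr::bind_rows(rows), manifest_path)
  invisible(manifest_path)
}

#' @rdname write_corpus
#' @param manifest_path manifest file written by [write_corpus()]
#' @return `read_corpus()`: list of [protein_record()]
#' @export
read_corpus <- function(manifest_path) {
  tab <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           fasta_path = readr::col_character(),
                           pdb_path = readr::col_character(),
                           text = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  fasta_cache <- list()
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    fp <- tab$fasta_path[i]
    if (is.null(fasta_cache[[fp]])) {
      recs <- read_fasta(fp)
      fasta_cache[[fp]] <- stats::setNames(recs, vapply(recs, `[[`, "", "id"))
    }
    base <- fasta_cache[[fp]][[tab$id[i]]]
    if (is.null(base)) stop("id '", tab$id[i], "' not found in ", fp)
    st <- NULL
    if (!is.na(tab$pdb_path[i]) && nzchar(tab$pdb_path[i])) {
      st <- read_backbone(tab$pdb_path[i])
    }
    tx <- if (!is.na(tab$text[i]) && nzchar(tab$text[i])) tab$text[i] else NULL
    cl <- if ("class_label" %in% names(tab) && !is.na(tab$class_label[i])) {
      as.integer(tab$class_label[i])
    } else NULL
    out[[i]] <- protein_record(tab$id[i], base$sequence, structure = st,
                               text = tx, class_label = cl)
  }
  out
}

# ---- tokenizers --------------------------------------------------------------

#' Tokenize an amino-acid sequence
#'
#' Emits `[BOS, residue tokens..., EOS]` over the fixed 21-letter alphabet
#' (20 standard residues plus `X`), so the output always has
#' `nchar(sequence) + 2` tokens.
#'
#' @param sequence amino-acid string (normalized first)
#' @return an object of class `tokenized_input` with fields `token_ids`,
#'   `bos` / `eos` positions, `pad_id` and `modality`
#' @export
tokenize_sequence <- function(sequence) {
  s <- normalize_sequence(sequence)
  chars <- strsplit(s, "")[[1]]
  ids <- match(chars, SEQ_VOCAB)
  if (anyNA(ids)) {
    stop("characters outside the amino-acid alphabet after X-mapping: ",
         paste(unique(chars[is.na(ids)]), collapse = " "))
  }
  ids <- c(match("<bos>", SEQ_VOCAB), ids, match("<eos>", SEQ_VOCAB))
  structure(list(token_ids = as.integer(ids), bos = 1L, eos = length(ids),
                 pad_id = match("<pad>", SEQ_VOCAB), modality = "sequence",
                 vocab_size = length(SEQ_VOCAB)),
            class = "tokenized_input")
}

#' Invert [tokenize_sequence()]
#'
#' @param tokens a `tokenized_input` produced by [tokenize_sequence()]
#' @return the amino-acid string
#' @export
detokenize_sequence <- function(tokens) {
  stopifnot(inherits(tokens, "tokenized_input"), tokens$modality == "sequence")
  ids <- tokens$token_ids
  core <- ids[ids > length(SEQ_SPECIALS)]
  paste(SEQ_VOCAB[core], collapse = "")
}

#' Build a whitespace word vocabulary from a text corpus
#'
#' Lowercased, whitespace-split word types plus the specials
#' `<pad>`, `<bos>`, `<eos>`, `<unk>`. The tokenizer is deliberately
#' self-contained (no pretrained subword model is required); the interface is
#' pluggable, so any vocabulary vector with the same specials can be supplied
#' to [tokenize_text()].
#'
#' @param texts character vector of documents
#' @return character vector: specials followed by sorted word types
#' @export
build_text_vocab <- function(texts) {
  words <- unlist(strsplit(tolower(texts), "\\s+"))
  words <- words[nzchar(words)]
  c(TEXT_SPECIALS, sort(unique(words)))
}

#' Tokenize a text description
#'
#' Lowercases, splits on whitespace, maps out-of-vocabulary words to `<unk>`,
#' and appends `<eos>` (whose output embedding is the pooled text
#' representation).
#'
#' @param text non-empty character scalar
#' @param vocab vocabulary from [build_text_vocab()]
#' @return a `tokenized_input`
#' @export
tokenize_text <- function(text, vocab) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty text")
  words <- strsplit(tolower(text), "\\s+")[[1]]
  words <- words[nzchar(words)]
  ids <- match(words, vocab)
  ids[is.na(ids)] <- match("<unk>", vocab)
  ids <- c(ids, match("<eos>", vocab))
  structure(list(token_ids = as.integer(ids), bos = NA_integer_,
                 eos = length(ids), pad_id = match("<pad>", vocab),
                 modality = "text", vocab_size = length(vocab)),
            class = "tokenized_input")
}

#' @export
print.tokenized_input <- function(x, ...) {
  cat(sprintf("<tokenized_input> %s, %d tokens\n", x$modality,
              length(x$token_ids)))
  invisible(x)
}
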