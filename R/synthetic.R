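# Seeded synthetic tri-modal corpus with controlled cross-modal information.
#
# Each record carries a latent class c and an instance code u. The sequence
# exposes both (instance code at a fixed N-terminal window, class motif right
# after it); the text spells the code letter-by-letter and names the class
# keyword; the structure is a class-specific helix and therefore carries class
# information only. Sequence-text pairs thus share instance- and class-level
# information while sequence-structure pairs share class-level information
# only, so each retrieval criterion probes a specific information channel.

SYN_CLASS_WORDS <- c("kinase", "protease", "chaperone", "transporter",
                     "isomerase", "ligase", "oxidoreductase", "hydrolase",
                     "phosphatase", "synthase", "receptor", "regulator",
                     "polymerase", "nuclease", "permease", "reductase")

#' Synthetic corpus specification
#'
#' @param n record count
#' @param K class count (>= 2)
#' @param motif_len class-motif length (default 5)
#' @param id_code_len instance-code length in residues (default 4; base-20
#'   digits over the amino-acid alphabet)
#' @param structure_coverage fraction of records that also get a backbone
#'   structure; the realized count is exactly `round(structure_coverage * n)`
#' @param helix_rise,helix_turn,helix_radius per-class helix geometry: vectors
#'   recycled over classes (rise in Angstrom per residue, turn in degrees,
#'   radius in Angstrom). The default grid varies rise by 0.35 Angstrom per
#'   class so that noiseless consecutive CA-CA distances differ between
#'   classes by at least 0.1 Angstrom while staying inside the 2-5 Angstrom
#'   plausibility band
#' @param coord_noise coordinate noise sd in Angstrom (default 0.1)
#' @param length_range background sequence length range (default 30-50)
#' @param class_words class keyword vocabulary for the texts
#' @param seed integer seed; identical spec + seed gives byte-identical output
#' @return a `synthetic_spec`
#' @export
synthetic_spec <- function(n, K = 8L, motif_len = 5L, id_code_len = 4L,
                           structure_coverage = 0.5,
                           helix_rise = 0.9 + 0.35 * (seq_len(K) - 1L),
                           helix_turn = 100, helix_radius = 2.2,
                           coord_noise = 0.1, length_range = c(30L, 50L),
                           class_words = SYN_CLASS_WORDS, seed = 0L) {
  stopifnot(n >= 0L, K >= 2L, motif_len >= 1L, id_code_len >= 0L,
            structure_coverage >= 0, structure_coverage <= 1,
            all(helix_rise > 0), all(helix_turn > 0), all(helix_radius > 0),
            length_range[1] >= motif_len + id_code_len,
            length_range[2] >= length_range[1],
            length(class_words) >= K)
  geom <- tibble::tibble(
    class = seq_len(K),
    rise = rep_len(helix_rise, K),
    turn = rep_len(helix_turn, K),
    radius = rep_len(helix_radius, K)
  )
  structure(list(n = as.integer(n), K = as.integer(K),
                 motif_len = as.integer(motif_len),
                 id_code_len = as.integer(id_code_len),
                 structure_coverage = structure_coverage,
                 geometry = geom, coord_noise = coord_noise,
                 length_range = as.integer(length_range),
                 class_words = class_words[seq_len(K)],
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Pairwise-distinct class motifs; regenerated (with a diagnostic) in the
# unlikely event of a collision at small alphabets.
make_class_motifs <- function(K, motif_len) {
  for (attempt in 1:20) {
    motifs <- vapply(seq_len(K), function(i) {
      paste(sample(AA20, motif_len, replace = TRUE), collapse = "")
    }, "")
    if (!anyDuplicated(motifs)) return(motifs)
    message("class motif collision; regenerating (attempt ", attempt, ")")
  }
  stop("could not draw ", K, " distinct motifs of length ", motif_len)
}

#' Generate an ideal-helix backbone
#'
#' CA atoms follow `(radius cos(i turn), radius sin(i turn), i rise)`; N and C
#' are placed at fixed offsets from each CA along the local helix tangent;
#' Gaussian coordinate noise (if any) and a random global rigid pose are
#' applied last, drawn from the current R random-number state. The noiseless
#' consecutive CA-CA distance has the closed form
#' `sqrt(rise^2 + (2 radius sin(turn/2))^2)`.
#'
#' @param L residue count (>= 1)
#' @param rise rise per residue (Angstrom)
#' @param turn turn per residue (degrees)
#' @param radius helix radius (Angstrom)
#' @param noise_sd coordinate noise sd (Angstrom)
#' @param pose apply a random global rotation + translation (default TRUE)
#' @return a [backbone_structure()]
#' @export
helix_backbone <- function(L, rise, turn, radius, noise_sd = 0, pose = TRUE) {
  stopifnot(L >= 1L, rise > 0, turn > 0, radius > 0, noise_sd >= 0)
  th <- (seq_len(L) - 1L) * turn * pi / 180
  ca <- cbind(radius * cos(th), radius * sin(th), (seq_len(L) - 1L) * rise)
  # local tangent of the helix curve, analytic
  tang <- unit_rows(cbind(-radius * sin(th) * turn * pi / 180,
                          radius * cos(th) * turn * pi / 180,
                          rep(rise, L)))
  # radial direction gives the frame a second axis so N/C sit off the curve
  radial <- unit_rows(cbind(cos(th), sin(th), rep(0, L)))
  n_xyz <- ca - 1.2 * tang + 0.4 * radial
  c_xyz <- ca + 1.2 * tang + 0.4 * radial
  if (noise_sd > 0) {
    n_xyz <- n_xyz + matrix(stats::rnorm(3L * L, 0, noise_sd), L)
    ca <- ca + matrix(stats::rnorm(3L * L, 0, noise_sd), L)
    c_xyz <- c_xyz + matrix(stats::rnorm(3L * L, 0, noise_sd), L)
  }
  if (pose) {
    Q <- random_rotation()
    tr <- stats::runif(3, -10, 10)
    n_xyz <- sweep(n_xyz %*% t(Q), 2L, tr, "+")
    ca <- sweep(ca %*% t(Q), 2L, tr, "+")
    c_xyz <- sweep(c_xyz %*% t(Q), 2L, tr, "+")
  }
  suppressWarnings(backbone_structure(n_xyz, ca, c_xyz))
}

#' Draw a uniformly random rotation matrix
#'
#' QR-based with determinant fixed to +1 (a proper rotation).
#'
#' @return 3 x 3 rotation matrix
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a synthetic tri-modal corpus
#'
#' Every record gets a class drawn uniformly from `1..K` and an instance code;
#' the sequence places the code at positions 1..`id_code_len` and the class
#' motif immediately after, over a random background; the text spells the code
#' letters and names the class keyword; a `round(coverage * n)`-sized random
#' subset of records additionally gets a class-geometry helix backbone of
#' matching length. Output is byte-identical under identical spec + seed.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `records` (list of [protein_record()]), `manifest`
#'   (a [build_manifest()] result), `motifs` (per-class), and `spec`
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  if (spec$n == 0L) {
    return(list(records = list(), manifest = manifest_from_ids(character(0), character(0), 0L),
                motifs = character(0), spec = spec))
  }
  motifs <- make_class_motifs(spec$K, spec$motif_len)
  classes <- sample.int(spec$K, spec$n, replace = TRUE)
  n_struct <- round(spec$structure_coverage * spec$n)
  struct_set <- if (n_struct > 0L) sample.int(spec$n, n_struct) else integer(0)
  has_struct <- seq_len(spec$n) %in% struct_set

  records <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    cl <- classes[i]
    L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
    code <- sample(AA20, spec$id_code_len, replace = TRUE)
    chars <- sample(AA20, L, replace = TRUE)
    if (spec$id_code_len > 0L) chars[seq_len(spec$id_code_len)] <- code
    chars[spec$id_code_len + seq_len(spec$motif_len)] <- strsplit(motifs[cl], "")[[1]]
    sequence <- paste(chars, collapse = "")
    text <- paste("protein", paste(tolower(code), collapse = " "),
                  "functions as a", spec$class_words[cl], "enzyme")
    st <- NULL
    if (has_struct[i]) {
      g <- spec$geometry[cl, ]
      st <- helix_backbone(L, g$rise, g$turn, g$radius,
                           noise_sd = spec$coord_noise, pose = TRUE)
    }
    records[[i]] <- protein_record(sprintf("SYN%05d", i), sequence,
                                   structure = st, text = text,
                                   class_label = cl)
  }
  list(records = records, manifest = build_manifest(records),
       motifs = motifs, spec = spec)
}

#' Build a labeled downstream task dataset from a synthetic corpus
#'
#' Labels derive from the latent class (or motif content):
#' * `binary_peptide` -- class parity;
#' * `regression_mic` -- `target = slope * class + intercept + noise`;
#' * `five_class_thermo` -- `class mod 5` over records with structure (the
#'   five thermostability bins);
#' * `pairwise_variant` -- one single-residue substitution per record: inside
#'   the class motif (label 1, disruptive) or inside the instance-code window
#'   (label 0, identity-changing but function-preserving). Both windows are
#'   represented by the pretrained encoder, so the head must distinguish
#'   *which* kind of feature moved -- substitutions in the unrepresented
#'   background would be near-invisible to a frozen desk encoder;
#' * `fitness` -- extra copies of a fixed reference motif (class 1's motif)
#'   planted in the background; score = total occurrences of that motif;
#' * `acr_pairing` -- pairs of records, balanced by construction: half the
#'   partners are drawn from the same class (label 1), half from a different
#'   class (label 0).
#'
#' An 80:20 split (train size `floor(split * n)`) is drawn with `seed`.
#'
#' @param corpus a [generate_corpus()] result
#' @param task task identifier (above)
#' @param seed split/noise seed
#' @param split training fraction
#' @param noise_sd regression noise sd
#' @param slope,intercept regression target parameters
#' @return a `task_dataset`: list with `task`, `train`, `test` tibbles, `seed`
#' @export
make_task_dataset <- function(corpus, task, seed = 0L, split = 0.8,
                              noise_sd = 0.1, slope = 0.5, intercept = 1.0) {
  tasks <- c("binary_peptide", "regression_mic", "five_class_thermo",
             "pairwise_variant", "fitness", "acr_pairing")
  if (!task %in% tasks) {
    stop("unknown task '", task, "'; expected one of: ", paste(tasks, collapse = ", "))
  }
  records <- corpus$records
  motifs <- corpus$motifs
  set.seed(seed)
  ids <- vapply(records, `[[`, "", "id")
  classes <- vapply(records, function(r) r$class_label %||% NA_integer_, 1L)
  spec <- corpus$spec

  tab <- switch(task,
    binary_peptide = tibble::tibble(id = ids, label = classes %% 2L),
    regression_mic = tibble::tibble(
      id = ids,
      target = slope * classes + intercept + stats::rnorm(length(ids), 0, noise_sd)
    ),
    five_class_thermo = {
      keep <- vapply(records, function(r) !is.null(r$structure), TRUE)
      tibble::tibble(id = ids[keep], label = (classes[keep] %% 5L) + 1L)
    },
    pairwise_variant = {
      rows <- lapply(seq_along(records), function(i) {
        r <- records[[i]]
        chars <- strsplit(r$sequence, "")[[1]]
        in_motif <- stats::runif(1) < 0.5
        motif_span <- spec$id_code_len + seq_len(spec$motif_len)
        pos <- if (in_motif) sample(motif_span, 1L) else
          sample(seq_len(spec$id_code_len), 1L)
        chars[pos] <- sample(setdiff(AA20, chars[pos]), 1L)
        tibble::tibble(id = r$id, wt_sequence = r$sequence,
                       mut_sequence = paste(chars, collapse = ""),
                       label = as.integer(in_motif))
      })
      dplyr::bind_rows(rows)
    },
    fitness = {
      ref <- strsplit(motifs[1L], "")[[1]]
      m <- spec$motif_len
      rows <- lapply(seq_along(records), function(i) {
        r <- records[[i]]
        chars <- strsplit(r$sequence, "")[[1]]
        L <- length(chars)
        head_end <- spec$id_code_len + m
        extra <- sample(0:4, 1L)
        # non-overlapping slots in the background
        slots <- seq(head_end + 1L, L - m + 1L, by = m)
        extra <- min(extra, length(slots))
        if (extra > 0L) {
          for (s in sample(slots, extra)) chars[s:(s + m - 1L)] <- ref
        }
        seqn <- paste(chars, collapse = "")
        hits <- gregexpr(motifs[1L], seqn, fixed = TRUE)[[1]]
        tibble::tibble(id = r$id, sequence = seqn,
                       score = sum(hits > 0L))
      })
      dplyr::bind_rows(rows)
    },
    acr_pairing = {
      partner <- vapply(seq_along(records), function(i) {
        same <- stats::runif(1) < 0.5
        pool <- if (same) setdiff(which(classes == classes[i]), i)
                else which(classes != classes[i])
        if (!length(pool)) pool <- setdiff(seq_along(records), i)
        if (length(pool) == 1L) pool else sample(pool, 1L)
      }, 1L)
      tibble::tibble(id = ids, partner_id = ids[partner],
                     label = as.integer(classes == classes[partner]))
    }
  )
  n <- nrow(tab)
  n_train <- floor(split * n)
  train_idx <- sample.int(n, n_train)
  structure(list(task = task,
                 train = tab[sort(train_idx), , drop = FALSE],
                 test = tab[-sort(train_idx), , drop = FALSE],
                 seed = as.integer(seed), split = split),
            class = "task_dataset")
}

#' @export
print.task_dataset <- function(x, ...) {
  cat(sprintf("<task_dataset> %s: %d train / %d test\n", x$task,
              nrow(x$train), nrow(x$test)))
  invisible(x)
}
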