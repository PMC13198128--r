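# Sequence-anchored contrastive alignment: InfoNCE losses over in-batch
# negatives, mixed-modality batch sampling, the pretraining loop, and
# cross-modal retrieval evaluation.

#' Alignment (pretraining) configuration
#'
#' Defaults are the desk-scale settings used throughout the package's tests:
#' 16 sequence-structure and 16 sequence-text pairs per step and a peak
#' learning rate suited to small encoders trained from scratch. The full-scale
#' recipe documented by the method -- 80 + 80 pairs per step, AdamW at
#' 5e-6 peak learning rate, weight decay 1e-4, betas (0.9, 0.95), cosine
#' annealing over 20 epochs -- is available via `scale = "full"`.
#'
#' @param temperature softmax temperature of the InfoNCE losses (default 0.07)
#' @param loss_weights weights of the sequence-structure and sequence-text
#'   terms (default equal weights 1, 1; the combined loss is their weighted sum)
#' @param sta_weight weight of the optional direct structure-text alignment
#'   term (default 0 = off)
#' @param batch_struct,batch_text pairs sampled per step from each pair type
#' @param lr,weight_decay,betas AdamW hyperparameters
#' @param schedule `"cosine"` (annealed to 0 over the run) or `"constant"`
#' @param steps total optimization steps (overrides `epochs` when given)
#' @param epochs passes over the larger pair list (used when `steps` is NULL)
#' @param seed seed controlling initialization order, sampling and dropout
#' @param symmetric also average the reversed-direction InfoNCE terms
#'   (default FALSE: sequence embeddings are the queries, as the anchor role
#'   prescribes)
#' @param sample_with_replacement fall back to sampling with replacement when
#'   a pair list is smaller than its batch size
#' @param scale `"desk"` or `"full"` preset
#' @return an `alignment_config`
#' @export
alignment_config <- function(temperature = 0.07, loss_weights = c(1, 1),
                             sta_weight = 0, batch_struct = 16L,
                             batch_text = 16L, lr = 1e-3,
                             weight_decay = 1e-4, betas = c(0.9, 0.95),
                             schedule = c("cosine", "constant"),
                             steps = 1500L, epochs = NULL, seed = 0L,
                             symmetric = FALSE,
                             sample_with_replacement = FALSE,
                             scale = c("desk", "full")) {
  scale <- match.arg(scale)
  schedule <- match.arg(schedule)
  if (scale == "full") {
    if (missing(batch_struct)) batch_struct <- 80L
    if (missing(batch_text)) batch_text <- 80L
    if (missing(lr)) lr <- 5e-6
    if (missing(epochs)) epochs <- 20L
    if (missing(steps)) steps <- NULL
  }
  stopifnot(temperature > 0, all(loss_weights >= 0), sta_weight >= 0,
            batch_struct >= 2L || batch_struct == 0L,
            batch_text >= 2L || batch_text == 0L,
            batch_struct + batch_text > 0L)
  structure(list(temperature = temperature, loss_weights = loss_weights,
                 sta_weight = sta_weight,
                 batch_struct = as.integer(batch_struct),
                 batch_text = as.integer(batch_text),
                 lr = lr, weight_decay = weight_decay, betas = betas,
                 schedule = schedule,
                 steps = if (is.null(steps)) NULL else as.integer(steps),
                 epochs = if (is.null(epochs)) NULL else as.integer(epochs),
                 seed = as.integer(seed), symmetric = symmetric,
                 sample_with_replacement = sample_with_replacement,
                 scale = scale),
            class = "alignment_config")
}

#' InfoNCE loss
#'
#' For queries and keys paired row-by-row, each row's loss is the negative
#' log-probability of its true key under a temperature-scaled softmax over all
#' keys in the batch (the positive plus every other row as negative):
#' `loss_i = -log( exp(q_i . k_i / tau) / sum_j exp(q_i . k_j / tau) )`.
#' Returns the mean over rows, computed with a numerically stable
#' log-sum-exp. With all pairwise similarities equal it reduces to `log(N)`.
#'
#' @param queries,keys N x D matrices, row i of each from the same record
#' @param temperature softmax temperature `tau > 0`
#' @return mean loss (scalar)
#' @export
info_nce <- function(queries, keys, temperature = 0.07) {
  queries <- as.matrix(queries); keys <- as.matrix(keys)
  if (nrow(queries) < 2L) stop("InfoNCE needs N >= 2 rows (no negatives otherwise)")
  if (!identical(dim(queries), dim(keys))) stop("queries and keys must have matching dimensions")
  if (any(!is.finite(queries)) || any(!is.finite(keys))) stop("non-finite input to info_nce")
  stopifnot(temperature > 0)
  S <- tcrossprod(queries, keys) / temperature
  m <- apply(S, 1L, max)
  lse <- m + log(rowSums(exp(S - m)))
  mean(lse - diag(S))
}

#' Tri-modal projected batch
#'
#' Bundles the projected embeddings of one pretraining step: the
#' sequence/structure pair subset and the sequence/text pair subset, each
#' matched row-by-row.
#'
#' @param seq_struct,struct projected sequence and structure matrices for the
#'   sequence-structure subset (same row order); NULL when the subset is empty
#' @param seq_text,text projected sequence and text matrices for the
#'   sequence-text subset; NULL when empty
#' @param struct_ids,text_ids record ids per row
#' @return a `tri_modal_batch`
#' @export
tri_modal_batch <- function(seq_struct = NULL, struct = NULL,
                            seq_text = NULL, text = NULL,
                            struct_ids = NULL, text_ids = NULL) {
  if (!is.null(seq_struct)) stopifnot(identical(dim(seq_struct), dim(struct)))
  if (!is.null(seq_text)) stopifnot(identical(dim(seq_text), dim(text)))
  structure(list(seq_struct = seq_struct, struct = struct,
                 seq_text = seq_text, text = text,
                 struct_ids = struct_ids, text_ids = text_ids),
            class = "tri_modal_batch")
}

#' Combined alignment loss with per-term breakdown
#'
#' `w1 * L_seq_struct + w2 * L_seq_text` (+ `w3 * L_struct_text` when the
#' structure-text term is enabled); a missing pair subset contributes zero and
#' is flagged in the breakdown.
#'
#' @param batch a [tri_modal_batch()]
#' @param cfg an [alignment_config()]
#' @return list with `total` and a `terms` tibble (term, value, weight,
#'   present)
#' @export
combined_loss <- function(batch, cfg = alignment_config()) {
  stopifnot(inherits(batch, "tri_modal_batch"))
  has_sr <- !is.null(batch$seq_struct) && nrow(batch$seq_struct) >= 2L
  has_st <- !is.null(batch$seq_text) && nrow(batch$seq_text) >= 2L
  if (!has_sr && !has_st) stop("both pair subsets are empty")
  l_sr <- if (has_sr) info_nce(batch$seq_struct, batch$struct, cfg$temperature) else 0
  l_st <- if (has_st) info_nce(batch$seq_text, batch$text, cfg$temperature) else 0
  terms <- tibble::tibble(
    term = c("seq_struct", "seq_text"),
    value = c(l_sr, l_st),
    weight = cfg$loss_weights,
    present = c(has_sr, has_st)
  )
  total <- sum(terms$value * terms$weight)
  if (cfg$sta_weight > 0) {
    shared <- intersect(batch$struct_ids, batch$text_ids)
    has_sta <- length(shared) >= 2L
    l_sta <- if (has_sta) {
      r <- batch$struct[match(shared, batch$struct_ids), , drop = FALSE]
      t <- batch$text[match(shared, batch$text_ids), , drop = FALSE]
      info_nce(r, t, cfg$temperature)
    } else 0
    terms <- dplyr::bind_rows(terms, tibble::tibble(
      term = "struct_text", value = l_sta, weight = cfg$sta_weight,
      present = has_sta))
    total <- total + cfg$sta_weight * l_sta
  }
  list(total = total, terms = terms)
}

#' Sample one batch plan of record ids
#'
#' Draws `batch_struct` ids uniformly without replacement from the
#' sequence-structure pair list and `batch_text` from the sequence-text list,
#' using the current R random-number state (seed it for reproducibility).
#'
#' @param manifest a [build_manifest()] result
#' @param cfg an [alignment_config()]
#' @return list with `struct_ids` and `text_ids`
#' @export
sample_batch <- function(manifest, cfg = alignment_config()) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  draw <- function(pool, m, what) {
    if (m == 0L) return(character(0))
    if (!length(pool)) stop("no ", what, " pairs available in the manifest")
    if (m > length(pool)) {
      if (!cfg$sample_with_replacement) {
        stop(sprintf("requested %d %s pairs but only %d available (set sample_with_replacement = TRUE to allow reuse)",
                     m, what, length(pool)))
      }
      return(sample(pool, m, replace = TRUE))
    }
    sample(pool, m)
  }
  list(struct_ids = draw(manifest$seq_struct_pairs, cfg$batch_struct, "sequence-structure"),
       text_ids = draw(manifest$seq_text_pairs, cfg$batch_text, "sequence-text"))
}

# ---- pretraining -------------------------------------------------------------

#' Contrastive pretraining of the three encoders
#'
#' Runs `sample_batch -> encode -> project -> combined loss -> AdamW` steps
#' under a cosine-annealed learning rate. All encoders and projection heads
#' receive gradient (joint pretraining; no frozen anchor). A record appearing
#' in both pair subsets of one step is encoded once and its sequence
#' embedding shared. Fully reproducible given `cfg$seed`.
#'
#' @param corpus list of [protein_record()] (or the list returned by
#'   [generate_corpus()])
#' @param cfg an [alignment_config()]
#' @param model optionally a pre-built [build_alignment_model()]; by default a
#'   desk-scale model is initialized from `cfg$seed`
#' @param shared_dim shared latent dimension when building the default model
#' @param checkpoint_dir if non-NULL, write `checkpoint_final.rds` and
#'   `checkpoint_best.rds` (lowest-loss step) plus an epoch-end checkpoint
#' @param verbose print a progress line every `print_every` steps
#' @param print_every progress cadence
#' @param resume a previous fit's `$state` to continue from (restores model
#'   weights, optimizer moments and the random-number state, so the resumed
#'   trajectory matches an uninterrupted run step for step)
#' @param keep_state retain the training state in the returned fit for
#'   later resumption
#' @param stop_after pause after this step of the schedule (the remaining
#'   steps can be completed later via `resume` without changing the
#'   trajectory)
#' @return an `alignment_fit`: the trained model, a per-step `trajectory`
#'   tibble (step, loss_seq_struct, loss_seq_text, total, lr), a
#'   `pair_counts` tibble of how often each record was drawn into each
#'   pair-type subset, and the config
#' @export
pretrain <- function(corpus, cfg = alignment_config(), model = NULL,
                     shared_dim = 64L, checkpoint_dir = NULL,
                     verbose = FALSE, print_every = 100L,
                     resume = NULL, keep_state = FALSE, stop_after = NULL) {
  records <- if (!is.null(corpus$records)) corpus$records else corpus
  manifest <- build_manifest(records)
  if (cfg$batch_struct > 0L && manifest$n_seq_struct == 0L) {
    stop("config requests sequence-structure pairs but the corpus has none")
  }
  if (cfg$batch_text > 0L && manifest$n_seq_text == 0L) {
    stop("config requests sequence-text pairs but the corpus has none")
  }
  set.seed(cfg$seed)
  by_id <- stats::setNames(records, vapply(records, `[[`, "", "id"))

  texts <- unlist(lapply(records, function(r) r$text %||% character(0)))
  if (is.null(model)) {
    vocab <- build_text_vocab(texts)
    model <- build_alignment_model(shared_dim = shared_dim, text_vocab = vocab,
                                   seed = cfg$seed)
  }
  seq_tok <- lapply(by_id, function(r) tokenize_sequence(r$sequence))
  text_tok <- lapply(by_id, function(r) {
    if (is.null(r$text)) NULL else tokenize_text(r$text, model$meta$text_vocab)
  })
  graphs <- lapply(by_id, function(r) {
    if (is.null(r$structure)) NULL else
      build_residue_graph(r$structure, k = model$meta$struct_cfg$k_neighbors)
  })

  n_steps <- cfg$steps
  if (is.null(n_steps)) {
    per_epoch <- ceiling(max(manifest$n_seq_struct, manifest$n_seq_text) /
                           max(cfg$batch_struct, cfg$batch_text))
    n_steps <- as.integer(cfg$epochs * per_epoch)
  }
  steps_per_epoch <- if (!is.null(cfg$epochs)) ceiling(n_steps / cfg$epochs) else n_steps

  params <- nn_params(model[c("seq", "text", "struct", "proj")])
  opt <- adamw_init(params)
  start_step <- 1L
  if (!is.null(resume)) {
    nn_load_state(model[c("seq", "text", "struct", "proj")], resume$weights)
    opt <- resume$opt
    start_step <- resume$step + 1L
    assign(".Random.seed", resume$rng, envir = globalenv())
  }
  traj <- matrix(NA_real_, n_steps, 4L)
  ids_all <- vapply(records, `[[`, "", "id")
  draw_struct <- stats::setNames(integer(length(ids_all)), ids_all)
  draw_text <- draw_struct
  best <- Inf
  if (!is.null(checkpoint_dir)) dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)

  last_step <- min(n_steps, stop_after %||% n_steps)
  for (step in start_step:last_step) {
    plan <- sample_batch(manifest, cfg)
    draw_struct[plan$struct_ids] <- draw_struct[plan$struct_ids] + 1L
    draw_text[plan$text_ids] <- draw_text[plan$text_ids] + 1L
    uids <- union(plan$struct_ids, plan$text_ids)

    ad_tape_start()
    s_pool <- fw_tokens(model$seq, model$meta$seq_cfg, seq_tok[uids], "bos")$pooled
    s_proj <- fw_project(model, s_pool, "sequence")
    losses <- list()
    weights <- numeric(0)
    l_sr_val <- NA_real_; l_st_val <- NA_real_
    if (cfg$batch_struct > 0L) {
      r_pool <- fw_structs(model, graphs[plan$struct_ids])$pooled
      r_proj <- fw_project(model, r_pool, "structure")
      q <- ad_rows(s_proj, match(plan$struct_ids, uids))
      l_sr <- ad_info_nce(q, r_proj, cfg$temperature)
      if (isTRUE(cfg$symmetric)) {
        l_sr <- ad_weighted_sum(list(l_sr, ad_info_nce(r_proj, q, cfg$temperature)),
                                c(0.5, 0.5))
      }
      losses <- c(losses, list(l_sr)); weights <- c(weights, cfg$loss_weights[1])
      l_sr_val <- ad_value(l_sr)[1, 1]
    }
    if (cfg$batch_text > 0L) {
      t_pool <- fw_tokens(model$text, model$meta$text_cfg,
                          text_tok[plan$text_ids], "eos")$pooled
      t_proj <- fw_project(model, t_pool, "text")
      q <- ad_rows(s_proj, match(plan$text_ids, uids))
      l_st <- ad_info_nce(q, t_proj, cfg$temperature)
      if (isTRUE(cfg$symmetric)) {
        l_st <- ad_weighted_sum(list(l_st, ad_info_nce(t_proj, q, cfg$temperature)),
                                c(0.5, 0.5))
      }
      losses <- c(losses, list(l_st)); weights <- c(weights, cfg$loss_weights[2])
      l_st_val <- ad_value(l_st)[1, 1]
    }
    loss <- ad_weighted_sum(losses, weights)
    total <- ad_value(loss)[1, 1]
    if (!is.finite(total)) {
      ad_tape_clear()
      stop(sprintf("non-finite loss at step %d: training diverged", step))
    }
    nn_zero_grads(params)
    ad_backward(loss)
    lr_t <- if (cfg$schedule == "cosine") cosine_lr(step, n_steps, cfg$lr) else cfg$lr
    opt <- adamw_step(opt, params, lr_t, cfg$betas, weight_decay = cfg$weight_decay)

    traj[step, ] <- c(l_sr_val, l_st_val, total, lr_t)
    if (verbose && (step %% print_every == 0L || step == 1L)) {
      message(sprintf("step %5d  L_sr=%.4f  L_st=%.4f  total=%.4f  lr=%.2e",
                      step, l_sr_val, l_st_val, total, lr_t))
    }
    if (!is.null(checkpoint_dir)) {
      if (total < best) {
        best <- total
        save_checkpoint(model, file.path(checkpoint_dir, "checkpoint_best.rds"),
                        extra = list(step = step, loss = total))
      }
      if (step %% steps_per_epoch == 0L) {
        save_checkpoint(model, file.path(checkpoint_dir, "checkpoint_epoch.rds"),
                        extra = list(step = step, loss = total))
      }
    }
  }

  trajectory <- tibble::tibble(
    step = seq_len(n_steps),
    loss_seq_struct = traj[, 1], loss_seq_text = traj[, 2],
    total = traj[, 3], lr = traj[, 4]
  )[start_step:last_step, , drop = FALSE]
  if (!is.null(checkpoint_dir)) {
    save_checkpoint(model, file.path(checkpoint_dir, "checkpoint_final.rds"),
                    extra = list(step = last_step, loss = traj[last_step, 3]))
  }
  state <- NULL
  if (keep_state) {
    state <- list(weights = nn_state(model[c("seq", "text", "struct", "proj")]),
                  opt = opt, step = last_step,
                  rng = get(".Random.seed", envir = globalenv()))
  }
  pair_counts <- tibble::tibble(id = ids_all,
                                struct_draws = unname(draw_struct),
                                text_draws = unname(draw_text))
  structure(list(model = model, trajectory = trajectory, config = cfg,
                 manifest = manifest, pair_counts = pair_counts,
                 state = state),
            class = "alignment_fit")
}

#' @export
print.alignment_fit <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat(sprintf("<alignment_fit> %d steps: loss %.4f -> %.4f\n",
              n, x$trajectory$total[1], x$trajectory$total[n]))
  invisible(x)
}

# ---- retrieval ---------------------------------------------------------------

#' Cross-modal retrieval evaluation
#'
#' Ranks every gallery row against each query by cosine similarity (dot
#' product on unit-norm rows). Row i of the gallery is taken as the true
#' counterpart of query i; `recall_at_k` is the fraction of queries whose
#' counterpart ranks in the top k, and, when labels are given,
#' `class_top1` is the fraction whose best hit shares the query's label.
#'
#' @param queries,gallery matrices with matching dimensions, matched
#'   row-by-row; rows are normalized internally if needed
#' @param labels optional per-row class labels (shared by queries and gallery)
#' @param k recall cut-off(s)
#' @return a `retrieval_result`: tibble `ranks` (query, rank_of_true,
#'   top_hit, top_label_match) plus `recall_at_k` and `class_top1`
#' @export
retrieve <- function(queries, gallery, labels = NULL, k = 1L) {
  queries <- as.matrix(queries); gallery <- as.matrix(gallery)
  stopifnot(ncol(queries) == ncol(gallery))
  if (any(k > nrow(gallery))) stop("k exceeds the gallery size")
  qn <- queries / pmax(sqrt(rowSums(queries^2)), 1e-12)
  gn <- gallery / pmax(sqrt(rowSums(gallery^2)), 1e-12)
  S <- tcrossprod(qn, gn)
  n <- nrow(S)
  rank_true <- integer(n)
  top_hit <- integer(n)
  for (i in seq_len(n)) {
    ord <- order(S[i, ], decreasing = TRUE)
    rank_true[i] <- which(ord == i)
    top_hit[i] <- ord[1]
  }
  ranks <- tibble::tibble(query = seq_len(n), rank_of_true = rank_true,
                          top_hit = top_hit)
  recall <- vapply(k, function(kk) mean(rank_true <= kk), 1)
  names(recall) <- paste0("recall_at_", k)
  class_top1 <- NA_real_
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    ranks$top_label_match <- labels[top_hit] == labels
    class_top1 <- mean(ranks$top_label_match)
  }
  structure(list(ranks = ranks, recall_at_k = recall, class_top1 = class_top1,
                 n = n, k = k),
            class = "retrieval_result")
}

#' Cross-modal retrieval evaluation over a record set
#'
#' Projects the held-out records with each encoder and measures: instance
#' retrieval of the matching text per sequence (recall at 1); class-level
#' top-1 agreement between sequence and structure embeddings; and class-level
#' top-1 between structure and text embeddings, which are never directly
#' aligned during pretraining and are coupled only through the sequence
#' anchor.
#'
#' @param model a pretrained alignment model
#' @param records held-out [protein_record()]s with class labels
#' @return tibble with `seq_text_recall1`, `seq_struct_top1`,
#'   `struct_text_top1` and the query counts behind each
#' @export
evaluate_alignment <- function(model, records) {
  labels <- vapply(records, function(r) r$class_label %||% NA_integer_, 1L)
  s_emb <- embed_records(model, records, "sequence", project = TRUE)
  t_emb <- embed_records(model, records, "text", project = TRUE)
  has_st <- vapply(records, function(r) !is.null(r$structure), TRUE)
  r_emb <- embed_records(model, records[has_st], "structure", project = TRUE)
  st <- retrieve(s_emb, t_emb, labels = labels, k = 1L)
  sr <- retrieve(s_emb[has_st, , drop = FALSE], r_emb,
                 labels = labels[has_st], k = 1L)
  rt <- retrieve(r_emb, t_emb[has_st, , drop = FALSE],
                 labels = labels[has_st], k = 1L)
  tibble::tibble(
    seq_text_recall1 = unname(st$recall_at_k[1]),
    seq_struct_top1 = sr$class_top1,
    struct_text_top1 = rt$class_top1,
    n_text_queries = st$n,
    n_struct_queries = sr$n
  )
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result> n=%d; %s%s\n", x$n,
              paste(names(x$recall_at_k), sprintf("%.3f", x$recall_at_k),
                    sep = "=", collapse = ", "),
              if (!is.na(x$class_top1)) sprintf("; class_top1=%.3f", x$class_top1) else ""))
  invisible(x)
}
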