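# Frozen-encoder fine-tuning heads and their training recipes.
#
# Heads consume embeddings from a frozen alignment model; the frozen contract
# is enforced by comparing an MD5 digest of the encoder weights before and
# after every run. Hidden sizes quoted for full-scale (1280-wide) embeddings
# scale with the embedding width where they are proportional by design
# (variant head); literal hidden sizes (128, 256, 64, 4) are kept as the
# documented defaults.

new_head <- function(type, d, module, forward, out, recipe) {
  structure(list(type = type, d = d, module = module, forward = forward,
                 out = out, recipe = recipe),
            class = "task_head")
}

#' @export
print.task_head <- function(x, ...) {
  cat(sprintf("<task_head> %s (d=%d, %s parameters)\n", x$type, x$d,
              format(nn_n_params(x$module), big.mark = ",")))
  invisible(x)
}

# Flatten a record-major (B*L) x C signal into B x (L*C) feature rows.
ad_flatten_signal <- function(x, B, L) {
  x <- ad_wrap(x)
  C <- ncol(x$value)
  y <- matrix(0, B, L * C)
  for (b in seq_len(B)) {
    y[b, ] <- as.vector(t(x$value[((b - 1L) * L + 1L):(b * L), , drop = FALSE]))
  }
  ad_op(y, list(x), function(g) {
    dX <- matrix(0, B * L, C)
    for (b in seq_len(B)) {
      dX[((b - 1L) * L + 1L):(b * L), ] <- matrix(g[b, ], L, C, byrow = TRUE)
    }
    list(dX)
  })
}

# ---- head constructors -------------------------------------------------------

#' Missense-variant pathogenicity head
#'
#' Binary classifier over the concatenated (wild-type, mutant) pooled sequence
#' embeddings: `2d -> hidden d -> dropout 0.5 -> leaky ReLU -> linear ->
#' softmax`. At the full-scale width 1280 the hidden layer is the documented
#' 1280. Trained with Adam (lr 1e-4, weight decay 1e-3), early stopping after
#' 10 stagnant validation epochs.
#'
#' @param d embedding width of the frozen sequence encoder
#' @param hidden hidden width (defaults to `d`)
#' @return a `task_head` whose inputs are N x 2d matrices
#' @export
variant_head <- function(d, hidden = d) {
  module <- list(fc1 = nn_linear_init(2L * d, hidden, sd = 0.05),
                 fc2 = nn_linear_init(hidden, 2L, sd = 0.05))
  fwd <- function(head, x, training = FALSE) {
    x <- ad_wrap(x)
    if (ncol(ad_value(x)) != 2L * head$d) {
      stop("variant head expects concatenated (wild-type, mutant) embeddings of width 2d")
    }
    h <- nn_linear(x, head$module$fc1)
    h <- ad_dropout(h, 0.5, training)
    h <- ad_leaky_relu(h)
    nn_linear(h, head$module$fc2)
  }
  recipe <- list(optimizer = "adam", lr = 1e-4, weight_decay = 1e-3,
                 epochs = 200L, batch = 32L, patience = 10L)
  new_head("variant", d, module, fwd, "softmax2", recipe)
}

#' Thermostability head (5 classes over structure embeddings)
#'
#' `d -> 128 -> LayerNorm -> ReLU -> linear logits` over the five
#' thermostability bins (hyperthermophilic down to cryophilic).
#'
#' @param d embedding width of the frozen structure encoder
#' @param hidden hidden width (documented default 128)
#' @return a `task_head` over N x d matrices
#' @export
thermostability_head <- function(d, hidden = 128L) {
  module <- list(fc1 = nn_linear_init(d, hidden, sd = 0.05),
                 ln = nn_layernorm_init(hidden),
                 fc2 = nn_linear_init(hidden, 5L, sd = 0.05))
  fwd <- function(head, x, training = FALSE) {
    h <- nn_linear(ad_wrap(x), head$module$fc1)
    h <- ad_relu(nn_layernorm(h, head$module$ln))
    nn_linear(h, head$module$fc2)
  }
  recipe <- list(optimizer = "adam", lr = 1e-3, weight_decay = 0,
                 epochs = 200L, batch = 32L, patience = 10L)
  new_head("thermostability", d, module, fwd, "logits5", recipe)
}

#' Anti-CRISPR activity head
#'
#' The per-protein embeddings of one example (Acr first, then the Cas set)
#' are stacked along a length axis as a (set size x d) channelized signal,
#' zero-padded to the batch maximum; two 1-D convolutions (d -> 4 -> 4,
#' kernel 7, stride 1, same padding) each followed by batch normalization and
#' ReLU; masked mean over set positions; two hidden-size-4 linear layers to a
#' 2-class output. Padding rows are masked from the normalization statistics
#' and the pooling, so they contribute nothing.
#'
#' @param d embedding width
#' @return a `task_head` whose inputs are lists of (set size x d) matrices
#' @export
acr_head <- function(d) {
  module <- list(conv1 = nn_linear_init(7L * d, 4L, sd = 0.05),
                 bn1 = nn_batchnorm_init(4L),
                 conv2 = nn_linear_init(7L * 4L, 4L, sd = 0.2),
                 bn2 = nn_batchnorm_init(4L),
                 fc1 = nn_linear_init(4L, 4L, sd = 0.2),
                 fc2 = nn_linear_init(4L, 2L, sd = 0.2))
  fwd <- function(head, x, training = FALSE) {
    stopifnot(is.list(x))
    sizes <- vapply(x, nrow, 1L)
    if (any(sizes < 2L)) stop("each example needs an Acr embedding plus a non-empty Cas set")
    lay <- pad_layout(sizes)
    X <- matrix(0, lay$B * lay$L, head$d)
    X[lay$target, ] <- do.call(rbind, x)
    h <- ad_conv1d(ad_const(X), head$module$conv1$W, head$module$conv1$b,
                   lay$B, lay$L, 7L, 3L, 3L)
    h <- ad_relu(ad_batchnorm(h, head$module$bn1$gamma, head$module$bn1$beta,
                              head$module$bn1$state, training, lay$valid))
    h <- ad_conv1d(h, head$module$conv2$W, head$module$conv2$b,
                   lay$B, lay$L, 7L, 3L, 3L)
    h <- ad_relu(ad_batchnorm(h, head$module$bn2$gamma, head$module$bn2$beta,
                              head$module$bn2$state, training, lay$valid))
    h <- ad_group_mean(h, lay$groups, lay$B)
    h <- ad_relu(nn_linear(h, head$module$fc1))
    nn_linear(h, head$module$fc2)
  }
  recipe <- list(optimizer = "adam", lr = 3e-3, weight_decay = 0.01,
                 weight_decay_final = 0.001, epochs = 250L, batch = 32L,
                 train_delta = 0.005, plateau_factor = 0.9, plateau_patience = 10L)
  new_head("acr", d, module, fwd, "softmax2", recipe)
}

#' Bioactive-peptide head
#'
#' The pooled sequence embedding is reshaped to a length-d one-channel
#' signal: two blocks of conv (kernel 3, stride 1, padding 2) + batch norm +
#' ReLU + max pooling (kernel 2, padding 1) + dropout 0.15, then a dense
#' hidden layer of 64 with ReLU and dropout, and a sigmoid output. Trained
#' with SGD (lr 1e-2, momentum 0.5), step decay, early stopping after 40
#' stagnant validation epochs.
#'
#' @param d embedding width
#' @param channels convolution channels (package default 16)
#' @return a `task_head` over N x d matrices
#' @export
peptide_head <- function(d, channels = 16L) {
  l1 <- d + 4L - 3L + 1L
  p1 <- (l1 + 2L - 2L) %/% 2L + 1L
  l2 <- p1 + 4L - 3L + 1L
  p2 <- (l2 + 2L - 2L) %/% 2L + 1L
  module <- list(conv1 = nn_linear_init(3L, channels, sd = 0.2),
                 bn1 = nn_batchnorm_init(channels),
                 conv2 = nn_linear_init(3L * channels, channels, sd = 0.1),
                 bn2 = nn_batchnorm_init(channels),
                 fc1 = nn_linear_init(p2 * channels, 64L, sd = 0.05),
                 fc2 = nn_linear_init(64L, 1L, sd = 0.1))
  fwd <- function(head, x, training = FALSE) {
    x <- as_ad_matrix(ad_value(ad_wrap(x)))
    B <- nrow(x); L <- ncol(x)
    sig <- ad_const(matrix(as.vector(t(x)), ncol = 1L))  # (B*L) x 1
    h <- ad_conv1d(sig, head$module$conv1$W, head$module$conv1$b, B, L, 3L, 2L, 2L)
    h <- ad_relu(ad_batchnorm(h, head$module$bn1$gamma, head$module$bn1$beta,
                              head$module$bn1$state, training))
    L1 <- L + 4L - 3L + 1L
    h <- ad_maxpool1d(h, B, L1, 2L, 1L)
    h <- ad_dropout(h, 0.15, training)
    P1 <- (L1 + 2L - 2L) %/% 2L + 1L
    h <- ad_conv1d(h, head$module$conv2$W, head$module$conv2$b, B, P1, 3L, 2L, 2L)
    h <- ad_relu(ad_batchnorm(h, head$module$bn2$gamma, head$module$bn2$beta,
                              head$module$bn2$state, training))
    L2 <- P1 + 4L - 3L + 1L
    h <- ad_maxpool1d(h, B, L2, 2L, 1L)
    h <- ad_dropout(h, 0.15, training)
    P2 <- (L2 + 2L - 2L) %/% 2L + 1L
    h <- ad_flatten_signal(h, B, P2)
    h <- ad_dropout(ad_relu(nn_linear(h, head$module$fc1)), 0.15, training)
    nn_linear(h, head$module$fc2)
  }
  recipe <- list(optimizer = "sgd", lr = 1e-2, momentum = 0.5,
                 weight_decay = 0, epochs = 200L, batch = 32L,
                 patience = 40L, step_decay = 0.5, step_every = 50L)
  new_head("peptide", d, module, fwd, "sigmoid", recipe)
}

#' MIC regression head
#'
#' `d -> 256 -> ReLU -> 1`, trained with Adam (lr 1e-4) under mean squared
#' error; the per-epoch multiplicative learning-rate rule defaults to a
#' constant 1 (no decay) and is pluggable via the recipe.
#'
#' @param d embedding width
#' @param hidden hidden width (documented default 256)
#' @return a `task_head` over N x d matrices
#' @export
mic_head <- function(d, hidden = 256L) {
  module <- list(fc1 = nn_linear_init(d, hidden, sd = 0.05),
                 fc2 = nn_linear_init(hidden, 1L, sd = 0.05))
  fwd <- function(head, x, training = FALSE) {
    nn_linear(ad_relu(nn_linear(ad_wrap(x), head$module$fc1)), head$module$fc2)
  }
  recipe <- list(optimizer = "adam", lr = 1e-4, weight_decay = 0,
                 epochs = 200L, batch = 32L, lr_lambda = function(epoch) 1)
  new_head("mic", d, module, fwd, "scalar", recipe)
}

#' Fitness regression head
#'
#' Per-position sequence embeddings pass a 1-D convolution over the length
#' axis (kernel 7, stride 1, same padding), dropout 0.1, ReLU, a masked mean
#' over positions, and a single-layer perceptron to a scalar. Trained with
#' AdamW (lr 3e-4, weight decay 5e-2) under a cosine schedule with 100
#' warm-up steps.
#'
#' @param d embedding width
#' @param channels convolution output channels (package default 32)
#' @param steps total training steps (desk default 1500; the full-scale
#'   recipe uses 10,000)
#' @return a `task_head` whose inputs are lists of (length x d) matrices
#' @export
fitness_head <- function(d, channels = 32L, steps = 1500L) {
  module <- list(conv = nn_linear_init(7L * d, channels, sd = 0.05),
                 fc = nn_linear_init(channels, 1L, sd = 0.1))
  fwd <- function(head, x, training = FALSE) {
    stopifnot(is.list(x))
    lens <- vapply(x, nrow, 1L)
    if (any(lens < 1L)) stop("zero-length input to the fitness head")
    lay <- pad_layout(lens)
    X <- matrix(0, lay$B * lay$L, head$d)
    X[lay$target, ] <- do.call(rbind, x)
    h <- ad_conv1d(ad_const(X), head$module$conv$W, head$module$conv$b,
                   lay$B, lay$L, 7L, 3L, 3L)
    h <- ad_relu(ad_dropout(h, 0.1, training))
    h <- ad_group_mean(h, lay$groups, lay$B)
    nn_linear(h, head$module$fc)
  }
  recipe <- list(optimizer = "adamw", lr = 3e-4, weight_decay = 5e-2,
                 betas = c(0.9, 0.999), batch = 64L, steps = as.integer(steps),
                 warmup = 100L)
  new_head("fitness", d, module, fwd, "scalar", recipe)
}

# ---- generic head training ---------------------------------------------------

head_loss <- function(head, logits, y) {
  switch(head$out,
    softmax2 = ad_softmax_xent(logits, as.integer(y) + 1L),
    logits5 = ad_softmax_xent(logits, as.integer(y)),
    sigmoid = ad_bce_logits(logits, as.numeric(y)),
    scalar = ad_mse(logits, matrix(as.numeric(y), ncol = 1L))
  )
}

take_rows <- function(x, idx) {
  if (is.list(x)) x[idx] else x[idx, , drop = FALSE]
}

n_examples <- function(x) if (is.list(x)) length(x) else nrow(x)

#' Predict with a trained head (evaluation mode)
#'
#' @param head a `task_head`
#' @param x inputs in the head's format
#' @return for classifiers, a list with `prob` (positive-class or per-class
#'   probabilities) and `class`; for regressors, a numeric vector
#' @export
predict_head <- function(head, x) {
  z <- ad_value(head$forward(head, x, training = FALSE))
  switch(head$out,
    softmax2 = {
      p <- exp(z - apply(z, 1L, max))
      p <- p / rowSums(p)
      list(prob = p[, 2L], class = as.integer(p[, 2L] > 0.5))
    },
    logits5 = {
      p <- exp(z - apply(z, 1L, max))
      p <- p / rowSums(p)
      list(prob = p, class = max.col(p))
    },
    sigmoid = {
      p <- 1 / (1 + exp(-z[, 1L]))
      list(prob = p, class = as.integer(p > 0.5))
    },
    scalar = z[, 1L]
  )
}

val_loss_of <- function(head, x, y) {
  ad_value(head_loss(head, head$forward(head, x, training = FALSE), y))[1, 1]
}

#' Train a task head on frozen embeddings
#'
#' Mini-batch training under the head's recipe (optimizer, schedule,
#' early-stopping rule). Epoch-based recipes monitor validation loss and
#' restore the best weights; the anti-CRISPR rule stops when the decrease in
#' training loss falls below its threshold; step-based recipes (fitness) run
#' a fixed number of steps under cosine annealing with warm-up.
#'
#' @param head a `task_head`
#' @param x_train,y_train training inputs / targets
#' @param x_val,y_val validation split (used by the stopping rules)
#' @param recipe optionally override `head$recipe`
#' @param verbose print one line per 25 epochs
#' @return list with the trained `head` and a per-epoch `history` tibble
#' @export
fit_head <- function(head, x_train, y_train, x_val = NULL, y_val = NULL,
                     recipe = NULL, verbose = FALSE) {
  rc <- utils::modifyList(head$recipe, recipe %||% list())
  params <- nn_params(head$module)
  opt <- switch(rc$optimizer,
    adam = , adamw = adamw_init(params),
    sgd = sgd_momentum_init(params))
  n <- n_examples(x_train)
  batch <- min(rc$batch, n)
  has_val <- !is.null(x_val) && n_examples(x_val) > 0L

  if (!is.null(rc$steps)) {
    # step-based recipe (fitness): cosine schedule with warm-up
    hist <- numeric(rc$steps)
    for (step in seq_len(rc$steps)) {
      idx <- sample.int(n, batch, replace = batch > n)
      ad_tape_start()
      loss <- head_loss(head, head$forward(head, take_rows(x_train, idx), TRUE),
                        y_train[idx])
      hist[step] <- ad_value(loss)[1, 1]
      nn_zero_grads(params)
      ad_backward(loss)
      lr_t <- cosine_lr(step, rc$steps, rc$lr, warmup = rc$warmup %||% 0L)
      opt <- adamw_step(opt, params, lr_t, rc$betas %||% c(0.9, 0.999),
                        weight_decay = rc$weight_decay)
    }
    return(list(head = head,
                history = tibble::tibble(epoch = seq_len(rc$steps),
                                         train_loss = hist)))
  }

  best_val <- Inf
  best_state <- NULL
  stagnant <- 0L
  prev_train <- Inf
  lr <- rc$lr
  hist <- list()
  for (epoch in seq_len(rc$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    wd <- rc$weight_decay
    if (!is.null(rc$weight_decay_final)) {
      frac <- (epoch - 1L) / max(rc$epochs - 1L, 1L)
      wd <- rc$weight_decay + frac * (rc$weight_decay_final - rc$weight_decay)
    }
    if (!is.null(rc$step_decay)) {
      lr <- rc$lr * rc$step_decay^((epoch - 1L) %/% rc$step_every)
    }
    if (!is.null(rc$lr_lambda)) lr <- rc$lr * rc$lr_lambda(epoch)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      if (length(idx) < 2L) next  # batch-norm statistics need >= 2 rows
      ad_tape_start()
      loss <- head_loss(head, head$forward(head, take_rows(x_train, idx), TRUE),
                        y_train[idx])
      ep_loss <- ep_loss + ad_value(loss)[1, 1] * length(idx)
      nn_zero_grads(params)
      ad_backward(loss)
      if (rc$optimizer == "sgd") {
        opt <- sgd_momentum_step(opt, params, lr, rc$momentum %||% 0, wd)
      } else if (rc$optimizer == "adamw") {
        opt <- adamw_step(opt, params, lr, rc$betas %||% c(0.9, 0.999),
                          weight_decay = wd)
      } else {
        # Adam with L2 regularization folded into the gradient
        if (wd > 0) for (p in params) if (!is.null(p$grad)) p$grad <- p$grad + wd * p$value
        opt <- adamw_step(opt, params, lr, rc$betas %||% c(0.9, 0.999),
                          weight_decay = 0)
      }
    }
    ep_loss <- ep_loss / n
    vl <- if (has_val) val_loss_of(head, x_val, y_val) else NA_real_
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = ep_loss,
                                    val_loss = vl, lr = lr)
    if (verbose && epoch %% 25L == 0L) {
      message(sprintf("epoch %3d  train=%.4f  val=%.4f  lr=%.2e", epoch, ep_loss, vl, lr))
    }
    if (!is.null(rc$train_delta)) {
      if (is.finite(prev_train) && prev_train - ep_loss < rc$train_delta && ep_loss <= prev_train) break
      if (has_val) {
        if (vl < best_val - 1e-9) { best_val <- vl; stagnant <- 0L }
        else {
          stagnant <- stagnant + 1L
          if (!is.null(rc$plateau_patience) && stagnant >= rc$plateau_patience) {
            lr <- lr * (rc$plateau_factor %||% 0.9)
            rc$lr <- lr
            stagnant <- 0L
          }
        }
      }
      prev_train <- ep_loss
    } else if (has_val && !is.null(rc$patience)) {
      if (vl < best_val - 1e-9) {
        best_val <- vl
        best_state <- nn_state(head$module)
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= rc$patience) break
      }
    }
  }
  if (!is.null(best_state)) nn_load_state(head$module, best_state)
  list(head = head, history = dplyr::bind_rows(hist))
}

# ---- running a full task -----------------------------------------------------

#' Downstream task specification
#'
#' @param task task identifier (matching [make_task_dataset()])
#' @param metrics metric names for [compute_metrics()] (defaults per task)
#' @param seeds head-initialization seeds (the protocol repeats each task
#'   over independent seeded runs and reports mean and SD)
#' @param recipe recipe overrides for [fit_head()]
#' @return a `task_spec`
#' @export
task_spec <- function(task, metrics = NULL, seeds = 0:4, recipe = list()) {
  if (is.null(metrics)) {
    metrics <- switch(task,
      binary_peptide = c("acc", "bacc", "sn", "sp", "mcc", "f1", "auc"),
      pairwise_variant = c("f1", "precision", "recall"),
      acr_pairing = c("acc", "f1", "auc"),
      five_class_thermo = "acc",
      regression_mic = c("mse", "r2"),
      fitness = c("spearman", "pearson", "r2"),
      stop("no default metrics for task '", task, "'")
    )
  }
  structure(list(task = task, metrics = metrics, seeds = as.integer(seeds),
                 recipe = recipe),
            class = "task_spec")
}

# Per-position embeddings for a set of sequences (BOS/EOS rows included).
embed_positions <- function(model, sequences, batch_size = 16L) {
  chunks <- split(seq_along(sequences), ceiling(seq_along(sequences) / batch_size))
  out <- vector("list", length(sequences))
  for (ix in chunks) {
    toks <- lapply(sequences[ix], tokenize_sequence)
    fw <- fw_tokens(model$seq, model$meta$seq_cfg, toks, "bos")
    H <- ad_value(fw$h)
    for (j in seq_along(ix)) {
      rows <- (j - 1L) * fw$layout$L + seq_len(length(toks[[j]]$token_ids))
      out[[ix[j]]] <- H[rows, , drop = FALSE]
    }
  }
  out
}

task_inputs <- function(task, split_tab, model, corpus_by_id) {
  d <- model$meta$seq_cfg$width
  recs <- function(col = "id") lapply(split_tab[[col]], function(i) corpus_by_id[[i]])
  switch(task,
    binary_peptide = ,
    regression_mic = embed_records(model, recs(), "sequence", project = FALSE),
    five_class_thermo = embed_records(model, recs(), "structure", project = FALSE),
    pairwise_variant = {
      wt <- embed_sequences(model, split_tab$wt_sequence)
      mt <- embed_sequences(model, split_tab$mut_sequence)
      cbind(wt, mt)
    },
    fitness = embed_positions(model, split_tab$sequence),
    acr_pairing = {
      e1 <- embed_records(model, recs("id"), "sequence", project = FALSE)
      e2 <- embed_records(model, recs("partner_id"), "sequence", project = FALSE)
      lapply(seq_len(nrow(split_tab)), function(i) rbind(e1[i, ], e2[i, ]))
    }
  )
}

# Pooled embeddings for raw sequences (not corpus records).
embed_sequences <- function(model, sequences, batch_size = 32L) {
  chunks <- split(seq_along(sequences), ceiling(seq_along(sequences) / batch_size))
  rows <- lapply(chunks, function(ix) {
    toks <- lapply(sequences[ix], tokenize_sequence)
    ad_value(fw_tokens(model$seq, model$meta$seq_cfg, toks, "bos")$pooled)
  })
  do.call(rbind, rows)
}

task_targets <- function(task, split_tab) {
  switch(task,
    binary_peptide = , pairwise_variant = , acr_pairing = split_tab$label,
    five_class_thermo = split_tab$label,
    regression_mic = split_tab$target,
    fitness = split_tab$score
  )
}

build_task_head <- function(task, d, recipe = list()) {
  head <- switch(task,
    binary_peptide = peptide_head(d),
    regression_mic = mic_head(d),
    five_class_thermo = thermostability_head(d),
    pairwise_variant = variant_head(d),
    fitness = fitness_head(d),
    acr_pairing = acr_head(d)
  )
  if (length(recipe)) head$recipe <- utils::modifyList(head$recipe, recipe)
  head
}

#' Run a downstream task on a frozen alignment model
#'
#' For each seed: carve a 10% validation split from the training set, build a
#' fresh head, train it per its recipe on embeddings from the frozen
#' encoders, and evaluate on the test split. The encoder-weight digest is
#' verified unchanged after every run (frozen contract); a mutation is a hard
#' failure.
#'
#' @param spec a [task_spec()]
#' @param dataset a [make_task_dataset()] result
#' @param model a pretrained [build_alignment_model()] (or checkpoint path)
#' @param corpus the corpus the dataset ids refer to (needed by tasks that
#'   embed corpus records)
#' @param verbose forwarded to [fit_head()]
#' @return a `task_result`: `per_seed` tibble (seed x metric), `summary`
#'   tibble (metric, mean, sd), and run metadata
#' @export
run_task <- function(spec, dataset, model, corpus = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "task_spec"), inherits(dataset, "task_dataset"),
            spec$task == dataset$task)
  if (is.character(model)) model <- load_checkpoint(model)
  corpus_by_id <- NULL
  if (!is.null(corpus)) {
    records <- if (!is.null(corpus$records)) corpus$records else corpus
    corpus_by_id <- stats::setNames(records, vapply(records, `[[`, "", "id"))
  }
  enc <- model[c("seq", "text", "struct", "proj")]
  digest_before <- nn_weight_digest(enc)

  x_train_all <- task_inputs(spec$task, dataset$train, model, corpus_by_id)
  x_test <- task_inputs(spec$task, dataset$test, model, corpus_by_id)
  y_train_all <- task_targets(spec$task, dataset$train)
  y_test <- task_targets(spec$task, dataset$test)
  d <- model$meta$seq_cfg$width

  per_seed <- list()
  for (seed in spec$seeds) {
    set.seed(seed)
    n <- n_examples(x_train_all)
    val_idx <- sample.int(n, max(2L, floor(0.1 * n)))
    tr_idx <- setdiff(seq_len(n), val_idx)
    head <- build_task_head(spec$task, d, spec$recipe)
    fit <- fit_head(head, take_rows(x_train_all, tr_idx), y_train_all[tr_idx],
                    take_rows(x_train_all, val_idx), y_train_all[val_idx],
                    verbose = verbose)
    pred <- predict_head(fit$head, x_test)
    mt <- if (fit$head$out == "scalar") {
      compute_metrics(y_test, pred, metrics = spec$metrics)
    } else if (fit$head$out == "logits5") {
      tibble::tibble(metric = "acc", value = multiclass_accuracy(y_test, pred$class))
    } else {
      compute_metrics(y_test, pred$class, scores = pred$prob,
                      metrics = spec$metrics)
    }
    per_seed[[length(per_seed) + 1L]] <- dplyr::mutate(mt, seed = seed, .before = 1L)
  }
  digest_after <- nn_weight_digest(enc)
  if (!identical(digest_before, digest_after)) {
    stop("frozen-encoder contract violated: encoder weights changed during fine-tuning")
  }
  per_seed <- dplyr::bind_rows(per_seed)
  summary <- dplyr::summarise(dplyr::group_by(per_seed, .data$metric),
                              mean = mean(.data$value),
                              sd = stats::sd(.data$value),
                              .groups = "drop")
  structure(list(task = spec$task, per_seed = per_seed, summary = summary,
                 seeds = spec$seeds, digest = digest_before),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("<task_result> %s over %d seed(s)\n", x$task, length(x$seeds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s %.4f +/- %.4f\n", s$metric[i], s$mean[i],
                ifelse(is.na(s$sd[i]), 0, s$sd[i])))
  }
  invisible(x)
}

#' Paired comparison of two task results
#'
#' Two-sided paired t-test on per-seed metric values (paired by seed,
#' significance threshold 0.05). Zero variance of the differences (e.g. a
#' method compared against itself) is reported as an undefined-variance flag
#' rather than a p value.
#'
#' @param a,b `task_result`s over identical seed sets
#' @param metric metric to compare
#' @return tibble with the mean difference, t statistic, p value and flags
#' @export
compare_task_results <- function(a, b, metric) {
  stopifnot(inherits(a, "task_result"), inherits(b, "task_result"),
            identical(a$seeds, b$seeds))
  va <- a$per_seed$value[a$per_seed$metric == metric]
  vb <- b$per_seed$value[b$per_seed$metric == metric]
  stopifnot(length(va) == length(vb), length(va) >= 2L)
  d <- va - vb
  if (stats::sd(d) == 0) {
    return(tibble::tibble(metric = metric, mean_diff = mean(d),
                          statistic = NA_real_, p_value = NA_real_,
                          undefined_variance = TRUE, significant = FALSE))
  }
  tt <- stats::t.test(va, vb, paired = TRUE)
  tibble::tibble(metric = metric, mean_diff = mean(d),
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 undefined_variance = FALSE, significant = tt$p.value < 0.05)
}
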