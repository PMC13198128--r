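# Parameter containers and layers built on the autodiff engine.
#
# A "module" is a nested named list whose leaves are ad_param nodes (plus a few
# non-trainable state environments for batch-norm running statistics). Weights
# draw from a truncated normal clipped at 2 sd; transformer blocks use
# fan-in-scaled sd (1/sqrt(d_in)) so activation variance is width-independent
# at the small widths this package trains from scratch.

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

nn_linear_init <- function(d_in, d_out, sd = 0.02, zero_bias = TRUE) {
  list(
    W = ad_param(matrix(trunc_normal(d_in * d_out, sd), d_in, d_out)),
    b = ad_param(matrix(if (zero_bias) 0 else trunc_normal(d_out, sd), 1, d_out))
  )
}

nn_linear <- function(x, lin) ad_add_bias(ad_matmul(x, lin$W), lin$b)

nn_layernorm_init <- function(d) {
  list(gamma = ad_param(matrix(1, 1, d)), beta = ad_param(matrix(0, 1, d)))
}

nn_layernorm <- function(x, ln) ad_layernorm(x, ln$gamma, ln$beta)

nn_embedding_init <- function(n_vocab, d, sd = NULL) {
  # fan-in-style scaling by default, matching the transformer blocks
  if (is.null(sd)) sd <- 1 / sqrt(d)
  ad_param(matrix(trunc_normal(n_vocab * d, sd), n_vocab, d))
}

nn_batchnorm_init <- function(d) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- rep(0, d)
  state$running_var <- rep(1, d)
  list(gamma = ad_param(matrix(1, 1, d)), beta = ad_param(matrix(0, 1, d)),
       state = state)
}

# ---- transformer encoder stack -----------------------------------------------

nn_transformer_init <- function(n_layers, d, n_heads, d_ff = 2L * d,
                                init = c("scaled", "fixed")) {
  stopifnot(d %% n_heads == 0L)
  init <- match.arg(init)
  # fan-in-scaled init keeps activation variance width-independent; the
  # fixed 0.02 alternative matches large-width transformer convention
  sd_of <- function(d_in) if (init == "scaled") 1 / sqrt(d_in) else 0.02
  layers <- lapply(seq_len(n_layers), function(i) {
    list(
      ln1 = nn_layernorm_init(d),
      wqkv = nn_linear_init(d, 3L * d, sd = sd_of(d)),  # fused Q/K/V
      wo = nn_linear_init(d, d, sd = sd_of(d)),
      ln2 = nn_layernorm_init(d),
      ff1 = nn_linear_init(d, d_ff, sd = sd_of(d)),
      ff2 = nn_linear_init(d_ff, d, sd = sd_of(d_ff))
    )
  })
  list(layers = layers, ln_final = nn_layernorm_init(d),
       n_heads = n_heads, d = d)
}

# x: (B*L) x d record-major; valid: logical mask over rows (PAD = FALSE).
# Pre-norm residual blocks; PAD keys are masked out of attention so padded
# positions never influence valid ones.
nn_transformer <- function(x, tr, B, L, valid) {
  h <- x
  d <- tr$d
  for (ly in tr$layers) {
    a <- nn_layernorm(h, ly$ln1)
    qkv <- nn_linear(a, ly$wqkv)
    att <- ad_attention_qkv(qkv, B, L, tr$n_heads, valid)
    h <- ad_add(h, nn_linear(att, ly$wo))
    f <- nn_layernorm(h, ly$ln2)
    f <- nn_linear(ad_gelu(nn_linear(f, ly$ff1)), ly$ff2)
    h <- ad_add(h, f)
  }
  nn_layernorm(h, tr$ln_final)
}

# ---- parameter traversal -----------------------------------------------------

nn_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is_ad_node(x)) {
      if (isTRUE(x$is_param)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(module)
  out
}

nn_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

nn_n_params <- function(module) {
  sum(vapply(nn_params(module), function(p) length(p$value), 1))
}

# Extract plain numeric weights from a module (for checkpointing / digests);
# batch-norm running statistics are carried along so eval-mode forwards are
# reproducible from a checkpoint.
nn_state <- function(module) {
  if (is_ad_node(module)) return(module$value)
  if (is.environment(module) && !is_ad_node(module)) {
    return(list(running_mean = module$running_mean, running_var = module$running_var))
  }
  if (is.list(module)) return(lapply(module, nn_state))
  module
}

nn_load_state <- function(module, state) {
  if (is_ad_node(module)) {
    stopifnot(identical(dim(module$value), dim(as_ad_matrix(state))))
    module$value <- as_ad_matrix(state)
    return(invisible(module))
  }
  if (is.environment(module)) {
    module$running_mean <- state$running_mean
    module$running_var <- state$running_var
    return(invisible(module))
  }
  if (is.list(module)) {
    # positional traversal: layer lists are unnamed
    for (i in seq_along(module)) {
      el <- module[[i]]
      if (is.list(el) || is_ad_node(el) || is.environment(el)) {
        nn_load_state(el, state[[i]])
      }
    }
  }
  invisible(module)
}

# MD5 digest of a module's weights, used to enforce the frozen-encoder
# contract during downstream fine-tuning.
nn_weight_digest <- function(module) {
  tf <- tempfile()
  on.exit(unlink(tf))
  vals <- lapply(nn_params(module), function(p) p$value)
  saveRDS(vals, tf, compress = FALSE)
  unname(tools::md5sum(tf))
}

# ---- optimizers and schedules ------------------------------------------------

adamw_init <- function(params) {
  list(t = 0L, m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0))
}

# Decoupled weight decay as in AdamW: decay is applied to the weights directly,
# not through the gradient moments.
adamw_step <- function(opt, params, lr, betas = c(0.9, 0.95), eps = 1e-8,
                       weight_decay = 0) {
  opt$t <- opt$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g^2
    mhat <- opt$m[[i]] / c1
    vhat <- opt$v[[i]] / c2
    p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$value)
  }
  opt
}

sgd_momentum_init <- function(params) {
  list(v = lapply(params, function(p) p$value * 0))
}

sgd_momentum_step <- function(opt, params, lr, momentum = 0, weight_decay = 0) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    opt$v[[i]] <- momentum * opt$v[[i]] + g
    p$value <- p$value - lr * opt$v[[i]]
  }
  opt
}

#' Cosine-annealed learning rate with optional linear warm-up
#'
#' @param step current step (1-based)
#' @param total total number of steps in the schedule
#' @param lr_max peak learning rate
#' @param lr_min floor of the schedule
#' @param warmup number of linear warm-up steps
#' @return the learning rate for `step`
#' @keywords internal
cosine_lr <- function(step, total, lr_max, lr_min = 0, warmup = 0L) {
  if (warmup > 0L && step <= warmup) return(lr_max * step / warmup)
  prog <- (step - warmup) / max(total - warmup, 1L)
  prog <- min(max(prog, 0), 1)
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * prog))
}
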