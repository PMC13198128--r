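# Modality encoders: sequence transformer (BOS pooling), GVP-GNN + transformer
# structure encoder (masked mean pooling), text transformer (EOS pooling), and
# the per-modality projection heads into the shared latent space.

#' Encoder configuration
#'
#' Desk-scale defaults are small enough to pretrain on one CPU: 2 transformer
#' layers of width 64 with 4 heads, and a single GVP-GNN layer for the
#' structure branch. The full-scale configuration documented by the method is
#' a 33-layer, width-1280 sequence transformer; a structure encoder of 4
#' GVP-GNN layers followed by 8 transformer layers; and an 8-layer text
#' transformer -- reachable by passing those values here, not instantiated by
#' default.
#'
#' @param modality one of `"sequence"`, `"structure"`, `"text"`
#' @param layers transformer layer count
#' @param width embedding dimension (divisible by `heads`)
#' @param heads attention heads
#' @param ff_mult feed-forward width as a multiple of `width`
#' @param gvp_layers GVP-GNN layers (structure only)
#' @param scalar_channels,vector_channels GVP feature channels (structure only)
#' @param k_neighbors residue-graph neighbours (structure only)
#' @param max_len maximum token/residue positions supported
#' @return an `encoder_config`
#' @export
encoder_config <- function(modality = c("sequence", "structure", "text"),
                           layers = 2L, width = 64L, heads = 2L,
                           ff_mult = 2L, gvp_layers = 1L, scalar_channels = 32L,
                           vector_channels = 4L, k_neighbors = 16L,
                           max_len = 512L) {
  modality <- match.arg(modality)
  stopifnot(width %% heads == 0L, layers >= 1L, width >= heads)
  structure(list(modality = modality, layers = as.integer(layers),
                 width = as.integer(width), heads = as.integer(heads),
                 ff_mult = as.integer(ff_mult),
                 gvp_layers = as.integer(gvp_layers),
                 scalar_channels = as.integer(scalar_channels),
                 vector_channels = as.integer(vector_channels),
                 k_neighbors = as.integer(k_neighbors),
                 max_len = as.integer(max_len)),
            class = "encoder_config")
}

# ---- geometric vector perceptron ---------------------------------------------

gvp_init <- function(si, vi, so, vo) {
  h <- max(vi, vo)
  list(
    wh = ad_param(matrix(trunc_normal(vi * h, 0.2), vi, h)),
    wmu = ad_param(matrix(trunc_normal(h * vo, 0.2), h, vo)),
    ws = nn_linear_init(si + h, so, sd = 0.1),
    wg = nn_linear_init(so, vo, sd = 0.1)
  )
}

# Core GVP: scalars are built from rotation-invariant inputs (existing scalars
# and vector-channel norms); vectors pass through channel-mixing linear maps
# and a sigmoid gate computed from the scalar path. No vector bias exists, so
# zero vector inputs give zero vector outputs.
gvp_apply <- function(p, s, V, activate = TRUE) {
  Vh <- ad_matmul(V, p$wh)
  vn <- ad_vec_norm(Vh)
  s_out <- nn_linear(ad_cbind(s, vn), p$ws)
  if (activate) s_out <- ad_relu(s_out)
  gate <- ad_sigmoid(nn_linear(s_out, p$wg))
  V_out <- ad_vec_gate(ad_matmul(Vh, p$wmu), gate)
  list(s = s_out, v = V_out)
}

gvp_gnn_layer_init <- function(ns, nv) {
  list(
    msg = gvp_init(2L * ns + RBF_N, nv + 1L, ns, nv),
    ln1 = nn_layernorm_init(ns),
    ff = gvp_init(ns, nv, ns, nv),
    ln2 = nn_layernorm_init(ns),
    ns = ns, nv = nv
  )
}

# One message-passing layer over a (possibly batched) residue graph given as
# src/dst index vectors into the node rows. Mean aggregation over incoming
# edges; residual updates; layer normalization on the scalar track only (a
# vector-track normalization would break equivariance).
gvp_gnn_layer_forward <- function(layer, s, V, src, dst, edge_s, edge_v, n) {
  if (length(src)) {
    s_src <- ad_rows(s, src)
    s_dst <- ad_rows(s, dst)
    V_src <- ad_rows(V, vec_row_index(src))
    msg <- gvp_apply(layer$msg,
                     ad_cbind(s_src, s_dst, ad_const(edge_s)),
                     ad_cbind(V_src, ad_const(edge_v)))
    cnt <- tabulate(dst, nbins = n)
    inv <- 1 / pmax(cnt, 1L)
    s_agg <- ad_mul(ad_colsum_groups(msg$s, dst, n),
                    ad_const(matrix(inv, n, layer$ns)))
    inv3 <- inv[rep(seq_len(n), each = 3L)]
    V_agg <- ad_mul(ad_colsum_groups(msg$v, vec_row_index(dst), 3L * n),
                    ad_const(matrix(inv3, 3L * n, layer$nv)))
    s <- ad_add(s, s_agg)
    V <- ad_add(V, V_agg)
  }
  s <- nn_layernorm(s, layer$ln1)
  ff <- gvp_apply(layer$ff, s, V)
  s <- nn_layernorm(ad_add(s, ff$s), layer$ln2)
  V <- ad_add(V, ff$v)
  list(s = s, v = V)
}

#' Apply one GVP-GNN layer to residue-graph features
#'
#' Exposed mainly for property testing: scalars are invariant and vectors
#' equivariant under any global rotation of the input coordinates, and
#' all-zero vector channels stay zero.
#'
#' @param graph a [build_residue_graph()] result
#' @param features list with `s` (n x ns scalars) and `v` (3n x nv vectors)
#' @param weights layer weights from an alignment model
#'   (`model$struct$gvp[[i]]`)
#' @return updated `list(s, v)` of plain matrices
#' @export
gvp_layer <- function(graph, features, weights) {
  stopifnot(inherits(graph, "residue_graph"))
  if (any(!is.finite(features$s)) || any(!is.finite(features$v))) {
    stop("non-finite values in GVP features")
  }
  out <- gvp_gnn_layer_forward(weights, ad_const(features$s),
                               ad_const(features$v),
                               graph$edge_src, graph$edge_dst,
                               graph$edge_s, graph$edge_v, graph$n)
  list(s = ad_value(out$s), v = ad_value(out$v))
}

# ---- model construction ------------------------------------------------------

#' Build a tri-modal alignment model
#'
#' Initializes the three encoders and the per-modality projection heads
#' (LayerNorm + one affine map) with truncated-normal weights under `seed`.
#'
#' @param seq_cfg,struct_cfg,text_cfg [encoder_config()]s
#' @param shared_dim dimension of the shared latent space
#' @param text_vocab text vocabulary from [build_text_vocab()]
#' @param seed integer seed for weight initialization
#' @param normalize L2-normalize projected embeddings (default TRUE; when
#'   FALSE the raw affine outputs enter the contrastive dot products)
#' @return an object of class `alignment_model`
#' @export
build_alignment_model <- function(seq_cfg = encoder_config("sequence"),
                                  struct_cfg = encoder_config("structure"),
                                  text_cfg = encoder_config("text"),
                                  shared_dim = 64L, text_vocab,
                                  seed = 0L, normalize = TRUE) {
  stopifnot(inherits(seq_cfg, "encoder_config"),
            seq_cfg$modality == "sequence",
            struct_cfg$modality == "structure",
            text_cfg$modality == "text")
  set.seed(seed)
  ds <- seq_cfg$width; dr <- struct_cfg$width; dt <- text_cfg$width
  ns <- struct_cfg$scalar_channels; nv <- struct_cfg$vector_channels
  model <- list(
    seq = list(
      emb = nn_embedding_init(length(SEQ_VOCAB), ds),
      pos = nn_embedding_init(seq_cfg$max_len, ds),
      tr = nn_transformer_init(seq_cfg$layers, ds, seq_cfg$heads,
                               d_ff = (seq_cfg$ff_mult %||% 2L) * ds)
    ),
    text = list(
      emb = nn_embedding_init(length(text_vocab), dt),
      pos = nn_embedding_init(text_cfg$max_len, dt),
      tr = nn_transformer_init(text_cfg$layers, dt, text_cfg$heads,
                               d_ff = (text_cfg$ff_mult %||% 2L) * dt)
    ),
    struct = list(
      s_embed = nn_linear_init(6L, ns, sd = 0.1),
      v_embed = ad_param(matrix(trunc_normal(3L * nv, 0.2), 3L, nv)),
      gvp = lapply(seq_len(struct_cfg$gvp_layers),
                   function(i) gvp_gnn_layer_init(ns, nv)),
      s_proj = nn_linear_init(ns, dr, sd = 0.05),
      pos = nn_embedding_init(struct_cfg$max_len, dr),
      tr = nn_transformer_init(struct_cfg$transformer_layers %||% struct_cfg$layers,
                               dr, struct_cfg$heads,
                               d_ff = (struct_cfg$ff_mult %||% 2L) * dr)
    ),
    proj = list(
      sequence = list(ln = nn_layernorm_init(ds),
                      lin = nn_linear_init(ds, shared_dim, sd = 1 / sqrt(ds))),
      structure = list(ln = nn_layernorm_init(dr),
                       lin = nn_linear_init(dr, shared_dim, sd = 1 / sqrt(dr))),
      text = list(ln = nn_layernorm_init(dt),
                  lin = nn_linear_init(dt, shared_dim, sd = 1 / sqrt(dt)))
    ),
    meta = list(seq_cfg = seq_cfg, struct_cfg = struct_cfg, text_cfg = text_cfg,
                shared_dim = as.integer(shared_dim), text_vocab = text_vocab,
                normalize = normalize, seed = as.integer(seed),
                format_version = 1L)
  )
  class(model) <- "alignment_model"
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf("<alignment_model> shared_dim=%d, %s parameters\n",
              x$meta$shared_dim,
              format(nn_n_params(x[c("seq", "text", "struct", "proj")]),
                     big.mark = ",")))
  invisible(x)
}

# ---- batched forward passes (node mode) --------------------------------------

pad_layout <- function(lengths) {
  B <- length(lengths)
  L <- max(lengths)
  valid <- rep(FALSE, B * L)
  src_of <- integer(0)
  target <- integer(sum(lengths))
  off <- 0L
  for (b in seq_len(B)) {
    rows <- (b - 1L) * L + seq_len(lengths[b])
    valid[rows] <- TRUE
    target[(off + 1L):(off + lengths[b])] <- rows
    off <- off + lengths[b]
  }
  groups <- ifelse(valid, rep(seq_len(B), each = L), NA_integer_)
  list(B = B, L = L, valid = valid, target = target, groups = groups,
       pos = rep(seq_len(L), times = B))
}

# Forward a list of tokenized inputs through a token transformer.
fw_tokens <- function(enc, cfg, tokens_list, pool) {
  lens <- vapply(tokens_list, function(t) length(t$token_ids), 1L)
  lay <- pad_layout(lens)
  if (lay$L > cfg$max_len) {
    stop(sprintf("input of %d tokens exceeds max_len %d", lay$L, cfg$max_len))
  }
  pad_id <- tokens_list[[1]]$pad_id
  ids <- rep(pad_id, lay$B * lay$L)
  ids[lay$target] <- unlist(lapply(tokens_list, `[[`, "token_ids"))
  if (any(ids > nrow(ad_value(enc$emb)) | ids < 1L)) {
    stop("token id outside the embedding vocabulary")
  }
  h <- ad_add(ad_rows(enc$emb, ids), ad_rows(enc$pos, lay$pos))
  h <- nn_transformer(h, enc$tr, lay$B, lay$L, lay$valid)
  pooled <- switch(pool,
    bos = ad_rows(h, (seq_len(lay$B) - 1L) * lay$L + 1L),
    eos = {
      eos_pos <- vapply(tokens_list, `[[`, 1L, "eos")
      ad_rows(h, (seq_len(lay$B) - 1L) * lay$L + eos_pos)
    },
    mean = ad_group_mean(h, lay$groups, lay$B)
  )
  list(h = h, pooled = pooled, layout = lay)
}

# Forward a list of residue graphs through the GVP stack + transformer.
fw_structs <- function(model, graphs) {
  cfg <- model$meta$struct_cfg
  ns_list <- lapply(graphs, `[[`, "node_s")
  nv_list <- lapply(graphs, `[[`, "node_v")
  lens <- vapply(graphs, `[[`, 1L, "n")
  n_tot <- sum(lens)
  off <- cumsum(c(0L, lens[-length(lens)]))
  src <- unlist(lapply(seq_along(graphs), function(i) graphs[[i]]$edge_src + off[i]))
  dst <- unlist(lapply(seq_along(graphs), function(i) graphs[[i]]$edge_dst + off[i]))
  edge_s <- do.call(rbind, lapply(graphs, `[[`, "edge_s"))
  edge_v <- do.call(rbind, lapply(graphs, `[[`, "edge_v"))

  s <- nn_linear(ad_const(do.call(rbind, ns_list)), model$struct$s_embed)
  V <- ad_matmul(ad_const(do.call(rbind, nv_list)), model$struct$v_embed)
  for (layer in model$struct$gvp) {
    out <- gvp_gnn_layer_forward(layer, s, V, src, dst, edge_s, edge_v, n_tot)
    s <- out$s; V <- out$v
  }
  h <- nn_linear(s, model$struct$s_proj)

  lay <- pad_layout(lens)
  if (lay$L > cfg$max_len) {
    stop(sprintf("structure of %d residues exceeds max_len %d", lay$L, cfg$max_len))
  }
  # scatter union rows into padded record-major layout (zero row for PAD)
  d <- cfg$width
  idx <- rep(n_tot + 1L, lay$B * lay$L)
  idx[lay$target] <- seq_len(n_tot)
  hp <- ad_rows(ad_rbind(h, ad_const(matrix(0, 1L, d))), idx)
  hp <- ad_add(hp, ad_rows(model$struct$pos, lay$pos))
  hp <- nn_transformer(hp, model$struct$tr, lay$B, lay$L, lay$valid)
  pooled <- ad_group_mean(hp, lay$groups, lay$B)
  list(h = hp, pooled = pooled, layout = lay)
}

fw_project <- function(model, pooled, modality) {
  head <- model$proj[[modality]]
  z <- nn_linear(nn_layernorm(pooled, head$ln), head$lin)
  if (isTRUE(model$meta$normalize)) z <- ad_l2norm_rows(z) else z
}

# ---- user-facing encoding ----------------------------------------------------

#' Encode an amino-acid sequence
#'
#' The pooled representation is the output embedding at the BOS position,
#' which attends to every residue and serves as the whole-sequence summary.
#'
#' @param model an [build_alignment_model()] result
#' @param tokens a `tokenized_input` from [tokenize_sequence()] (or a raw
#'   sequence string, tokenized on the fly)
#' @return list with `per_position` ((L+2) x width matrix) and `pooled`
#'   (width vector)
#' @export
encode_sequence <- function(model, tokens) {
  if (is.character(tokens)) tokens <- tokenize_sequence(tokens)
  stopifnot(inherits(tokens, "tokenized_input"), tokens$modality == "sequence")
  out <- fw_tokens(model$seq, model$meta$seq_cfg, list(tokens), "bos")
  list(per_position = ad_value(out$h), pooled = as.numeric(ad_value(out$pooled)))
}

#' Encode a backbone structure
#'
#' GVP-GNN layers extract rotation-invariant scalar features which a
#' transformer then contextualizes; the pooled representation is the mean of
#' per-residue embeddings over unmasked positions, and is invariant to global
#' rigid motions of the input coordinates.
#'
#' @param model an alignment model
#' @param structure a [backbone_structure()] or prebuilt [build_residue_graph()]
#' @return list with `per_residue` (n x width) and `pooled` (width vector)
#' @export
encode_structure <- function(model, structure) {
  g <- if (inherits(structure, "residue_graph")) structure else
    build_residue_graph(structure, k = model$meta$struct_cfg$k_neighbors)
  out <- fw_structs(model, list(g))
  per <- ad_value(out$h)[out$layout$valid, , drop = FALSE]
  list(per_residue = per, pooled = as.numeric(ad_value(out$pooled)))
}

#' Encode a text description
#'
#' The pooled representation is the output embedding at the appended EOS
#' position.
#'
#' @param model an alignment model
#' @param tokens a `tokenized_input` from [tokenize_text()] (or a raw string,
#'   tokenized with the model's vocabulary)
#' @return list with `per_position` and `pooled`
#' @export
encode_text <- function(model, tokens) {
  if (is.character(tokens)) tokens <- tokenize_text(tokens, model$meta$text_vocab)
  stopifnot(inherits(tokens, "tokenized_input"), tokens$modality == "text")
  if (is.na(tokens$eos)) stop("text tokens lack an EOS position")
  out <- fw_tokens(model$text, model$meta$text_cfg, list(tokens), "eos")
  list(per_position = ad_value(out$h), pooled = as.numeric(ad_value(out$pooled)))
}

#' Project a pooled embedding into the shared latent space
#'
#' LayerNorm followed by one affine map; outputs have dimension
#' `model$meta$shared_dim` for every modality and unit L2 norm when the model
#' was built with `normalize = TRUE`.
#'
#' @param model an alignment model
#' @param pooled pooled embedding vector or matrix (rows = items)
#' @param modality `"sequence"`, `"structure"` or `"text"`
#' @return projected matrix (rows = items)
#' @export
project <- function(model, pooled, modality) {
  pooled <- if (is.matrix(pooled)) pooled else matrix(pooled, nrow = 1L)
  d <- ncol(ad_value(model$proj[[modality]]$lin$W))
  din <- nrow(ad_value(model$proj[[modality]]$lin$W))
  if (ncol(pooled) != din) {
    stop(sprintf("embedding width %d does not match projection input width %d",
                 ncol(pooled), din))
  }
  ad_value(fw_project(model, ad_const(pooled), modality))
}

# ---- batch embedding of records ---------------------------------------------

#' Embed corpus records with a (frozen) model
#'
#' @param model an alignment model
#' @param records list of [protein_record()]
#' @param modality which encoder to use
#' @param project map into the shared latent space (TRUE) or return raw pooled
#'   encoder embeddings (FALSE)
#' @param batch_size records per forward pass
#' @return numeric matrix with one row per record (rownames = ids)
#' @export
embed_records <- function(model, records, modality = c("sequence", "structure", "text"),
                          project = TRUE, batch_size = 32L) {
  modality <- match.arg(modality)
  ids <- vapply(records, `[[`, "", "id")
  chunks <- split(seq_along(records), ceiling(seq_along(records) / batch_size))
  rows <- lapply(chunks, function(ix) {
    recs <- records[ix]
    pooled <- switch(modality,
      sequence = fw_tokens(model$seq, model$meta$seq_cfg,
                           lapply(recs, function(r) tokenize_sequence(r$sequence)),
                           "bos")$pooled,
      text = fw_tokens(model$text, model$meta$text_cfg,
                       lapply(recs, function(r) {
                         if (is.null(r$text)) stop("record '", r$id, "' has no text")
                         tokenize_text(r$text, model$meta$text_vocab)
                       }), "eos")$pooled,
      structure = fw_structs(model, lapply(recs, function(r) {
        if (is.null(r$structure)) stop("record '", r$id, "' has no structure")
        build_residue_graph(r$structure, k = model$meta$struct_cfg$k_neighbors)
      }))$pooled
    )
    if (project) pooled <- fw_project(model, pooled, modality)
    ad_value(pooled)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}

# ---- checkpointing -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' Checkpoints store all encoder and projection weights together with the
#' configuration that produced them and a format-version field.
#'
#' @param model an alignment model
#' @param path checkpoint file
#' @param extra optional named list stored alongside (e.g. the config digest)
#' @return `path` invisibly; `load_checkpoint()` returns the restored model
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  obj <- list(
    format_version = 1L,
    meta = model$meta,
    weights = nn_state(model[c("seq", "text", "struct", "proj")]),
    extra = extra
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version)) stop("not a model checkpoint: ", path)
  m <- obj$meta
  model <- build_alignment_model(m$seq_cfg, m$struct_cfg, m$text_cfg,
                                 shared_dim = m$shared_dim,
                                 text_vocab = m$text_vocab,
                                 seed = m$seed, normalize = m$normalize)
  nn_load_state(model[c("seq", "text", "struct", "proj")], obj$weights)
  attr(model, "checkpoint_extra") <- obj$extra
  model
}
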