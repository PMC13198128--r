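# Reverse-mode automatic differentiation on dense matrices.
#
# A "node" is an environment holding a numeric matrix `value`, an optional
# accumulated `grad`, the parent nodes it was computed from, and a backward
# closure mapping the node's output gradient to a list of parent gradients.
# Ops append nodes to an active tape; ad_backward() walks the tape in reverse
# creation order (a valid reverse topological order). When no tape is active
# ops run value-only and keep no graph, so inference costs no memory.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$n <- 0L

ad_tape_active <- function() !is.null(.ad$tape)

#' @keywords internal
ad_tape_start <- function(capacity = 4096L) {
  .ad$tape <- vector("list", capacity)
  .ad$n <- 0L
  invisible(NULL)
}

#' @keywords internal
ad_tape_clear <- function() {
  .ad$tape <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

ad_tape_append <- function(node) {
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) {
    .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  }
  .ad$tape[[n]] <- node
  .ad$n <- n
  invisible(NULL)
}

row_max <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]

# column-broadcast helpers (sweep() pays an aperm; these don't)
bc_mul <- function(x, v) x * rep(v, each = nrow(x))
bc_add <- function(x, v) x + rep(v, each = nrow(x))

as_ad_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Wrap a constant matrix as a non-differentiable node
#' @keywords internal
ad_const <- function(x) {
  node <- new.env(parent = emptyenv())
  node$value <- as_ad_matrix(x)
  node$grad <- NULL
  node$requires <- FALSE
  class(node) <- "ad_node"
  node
}

#' Create a trainable parameter node
#' @keywords internal
ad_param <- function(x, name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- as_ad_matrix(x)
  node$grad <- NULL
  node$requires <- TRUE
  node$is_param <- TRUE
  node$name <- name
  class(node) <- "ad_node"
  node
}

is_ad_node <- function(x) inherits(x, "ad_node")

ad_wrap <- function(x) if (is_ad_node(x)) x else ad_const(x)

# Generic op constructor. `backward` is function(g) -> list of parent grads
# (NULL entries for parents that need none), evaluated lazily at backprop.
ad_op <- function(value, parents, backward) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires <- FALSE
  for (p in parents) if (isTRUE(p$requires)) { node$requires <- TRUE; break }
  if (node$requires && ad_tape_active()) {
    node$parents <- parents
    node$backward <- backward
    ad_tape_append(node)
  }
  class(node) <- "ad_node"
  node
}

ad_value <- function(x) if (is_ad_node(x)) x$value else x

#' Run backpropagation from a scalar loss node
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_ad_node(loss), length(loss$value) == 1L)
  if (!ad_tape_active()) stop("no active tape: call ad_tape_start() before the forward pass")
  loss$grad <- matrix(1, 1, 1)
  for (i in seq_len(.ad$n)) {
    node <- .ad$tape[[.ad$n - i + 1L]]
    if (is.null(node$grad)) next
    grads <- node$backward(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      g <- grads[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      if (!isTRUE(p$requires)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    # free intermediate gradients as we go
    if (!isTRUE(node$is_param)) node$grad <- NULL
  }
  ad_tape_clear()
  invisible(NULL)
}

# ---- elementwise / linear algebra ops ----------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_op(a$value %*% b$value, list(a, b), function(g) {
    list(tcrossprod(g, b$value), crossprod(a$value, g))
  })
}

ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

# bias: a 1 x d parameter broadcast over the rows of x
ad_add_bias <- function(x, b) {
  x <- ad_wrap(x); b <- ad_wrap(b)
  bv <- as.numeric(b$value)
  ad_op(bias_add(x$value, bv), list(x, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_op(a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

ad_scale <- function(x, s) {
  x <- ad_wrap(x)
  ad_op(x$value * s, list(x), function(g) list(g * s))
}

ad_relu <- function(x) {
  x <- ad_wrap(x)
  keep <- x$value > 0
  ad_op(x$value * keep, list(x), function(g) list(g * keep))
}

ad_leaky_relu <- function(x, alpha = 0.01) {
  x <- ad_wrap(x)
  pos <- x$value > 0
  slope <- ifelse(pos, 1, alpha)
  ad_op(x$value * slope, list(x), function(g) list(g * slope))
}

# Sigmoid-form GELU approximation: x * sigmoid(1.702 x). Cheap and smooth;
# the exact erf form is not worth its cost here.
ad_gelu <- function(x) {
  x <- ad_wrap(x)
  fw <- gelu_fwd(x$value)
  ad_op(fw$y, list(x), function(g) list(g * fw$dydx))
}

ad_sigmoid <- function(x) {
  x <- ad_wrap(x)
  s <- 1 / (1 + exp(-x$value))
  ad_op(s, list(x), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(x) {
  x <- ad_wrap(x)
  th <- tanh(x$value)
  ad_op(th, list(x), function(g) list(g * (1 - th^2)))
}

# Row-wise layer normalization with affine parameters (1 x d each).
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- ad_wrap(x); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  gv <- as.numeric(gamma$value)
  fw <- layernorm_fwd(x$value, gv, as.numeric(beta$value), eps)
  ad_op(fw$y, list(x, gamma, beta), function(g) {
    bw <- layernorm_bwd(g, fw$xhat, fw$inv, gv)
    list(bw$dx, matrix(bw$dgamma, 1L), matrix(bw$dbeta, 1L))
  })
}

# Select a contiguous column block [from, to].
ad_cols <- function(x, from, to) {
  x <- ad_wrap(x)
  ad_op(x$value[, from:to, drop = FALSE], list(x), function(g) {
    dX <- matrix(0, nrow(x$value), ncol(x$value))
    dX[, from:to] <- g
    list(dX)
  })
}

# Gather rows (duplicates allowed; used for embedding lookup).
ad_rows <- function(x, idx) {
  x <- ad_wrap(x)
  idx <- as.integer(idx)
  ad_op(x$value[idx, , drop = FALSE], list(x), function(g) {
    acc <- rowsum(g, group = idx, reorder = FALSE)
    dX <- matrix(0, nrow(x$value), ncol(x$value))
    dX[as.integer(rownames(acc)), ] <- acc
    list(dX)
  })
}

# Mean of selected rows per group: groups is an integer vector (1..G) over the
# rows of x; rows with group NA are excluded. Returns a G x d matrix.
ad_group_mean <- function(x, groups, n_groups) {
  x <- ad_wrap(x)
  keep <- !is.na(groups)
  gk <- as.integer(groups[keep])
  counts <- tabulate(gk, nbins = n_groups)
  if (any(counts == 0L)) stop("ad_group_mean: empty group")
  sums <- rowsum(x$value[keep, , drop = FALSE], group = gk, reorder = TRUE)
  out <- sums / counts[sort(unique(gk))]
  # rowsum with reorder sorts groups ascending; all groups present by check above
  ad_op(out, list(x), function(g) {
    dX <- matrix(0, nrow(x$value), ncol(x$value))
    dX[keep, ] <- g[gk, , drop = FALSE] / counts[gk]
    list(dX)
  })
}

ad_colsum_groups <- function(x, groups, n_groups) {
  # sum rows of x by group (all rows used), groups in 1..n_groups
  x <- ad_wrap(x)
  gk <- as.integer(groups)
  out <- matrix(0, n_groups, ncol(x$value))
  acc <- rowsum(x$value, group = gk, reorder = TRUE)
  out[sort(unique(gk)), ] <- acc
  ad_op(out, list(x), function(g) list(g[gk, , drop = FALSE]))
}

ad_cbind <- function(...) {
  parts <- lapply(list(...), ad_wrap)
  widths <- vapply(parts, function(p) ncol(p$value), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_op(do.call(cbind, lapply(parts, function(p) p$value)), parts, function(g) {
    lapply(seq_along(parts), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_rbind <- function(...) {
  parts <- lapply(list(...), ad_wrap)
  hts <- vapply(parts, function(p) nrow(p$value), 1L)
  ends <- cumsum(hts)
  starts <- ends - hts + 1L
  ad_op(do.call(rbind, lapply(parts, function(p) p$value)), parts, function(g) {
    lapply(seq_along(parts), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

# L2-normalize each row.
ad_l2norm_rows <- function(x, eps = 1e-12) {
  x <- ad_wrap(x)
  v <- x$value
  n <- sqrt(rowSums(v^2) + eps)
  y <- v / n
  ad_op(y, list(x), function(g) {
    list(g / n - v * (rowSums(g * v) / n^3))
  })
}

ad_dropout <- function(x, p, training) {
  x <- ad_wrap(x)
  if (!training || p <= 0) return(x)
  keep <- matrix(stats::rbinom(length(x$value), 1L, 1 - p), nrow(x$value)) / (1 - p)
  ad_op(x$value * keep, list(x), function(g) list(g * keep))
}

ad_mean_all <- function(x) {
  x <- ad_wrap(x)
  n <- length(x$value)
  ad_op(matrix(mean(x$value), 1, 1), list(x), function(g) {
    list(matrix(as.numeric(g) / n, nrow(x$value), ncol(x$value)))
  })
}

ad_sum_all <- function(x) {
  x <- ad_wrap(x)
  ad_op(matrix(sum(x$value), 1, 1), list(x), function(g) {
    list(matrix(as.numeric(g), nrow(x$value), ncol(x$value)))
  })
}

# weighted sum of scalar nodes: sum_i w_i * x_i
ad_weighted_sum <- function(nodes, weights) {
  nodes <- lapply(nodes, ad_wrap)
  val <- 0
  for (i in seq_along(nodes)) val <- val + weights[i] * nodes[[i]]$value
  ad_op(matrix(val, 1, 1), nodes, function(g) {
    lapply(seq_along(nodes), function(i) matrix(as.numeric(g) * weights[i], 1, 1))
  })
}

# ---- fused multi-head self-attention -----------------------------------------
#
# qkv: (B*L) x 3d matrix of fused query/key/value projections, record-major
# row layout (row (b-1)*L + l). valid: logical length B*L, FALSE on PAD key
# positions (masked out of the softmax). Slicing and backward assembly happen
# inside the op, so no intermediate full-size gradients are allocated.
ad_attention_qkv <- function(qkv, B, L, n_heads, valid) {
  qkv <- ad_wrap(qkv)
  d <- ncol(qkv$value) %/% 3L
  stopifnot(d %% n_heads == 0L)
  fw <- attn_qkv_fwd(qkv$value, B, L, n_heads, valid)
  ad_op(fw$out, list(qkv), function(g) {
    list(attn_qkv_bwd(g, qkv$value, fw$attn, B, L, n_heads))
  })
}

ad_attention <- function(q, k, v, B, L, n_heads, valid) {
  q <- ad_wrap(q); k <- ad_wrap(k); v <- ad_wrap(v)
  d <- ncol(q$value)
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  scl <- 1 / sqrt(dh)
  out <- matrix(0, B * L, d)
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    vb <- valid[rows]
    Qb <- q$value[rows, , drop = FALSE]
    Kb <- k$value[rows, , drop = FALSE]
    Vb <- v$value[rows, , drop = FALSE]
    Ab <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Qb[, cols, drop = FALSE], Kb[, cols, drop = FALSE]) * scl
      S[, !vb] <- -Inf
      S <- S - row_max(S)
      E <- exp(S)
      A <- E / rowSums(E)
      Ab[[h]] <- A
      out[rows, cols] <- A %*% Vb[, cols, drop = FALSE]
    }
    attn[[b]] <- Ab
  }
  ad_op(out, list(q, k, v), function(g) {
    dQ <- matrix(0, B * L, d); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- attn[[b]][[h]]
        Gb <- g[rows, cols, drop = FALSE]
        Vb <- v$value[rows, cols, drop = FALSE]
        dV[rows, cols] <- crossprod(A, Gb)
        dA <- tcrossprod(Gb, Vb)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- (dS %*% k$value[rows, cols, drop = FALSE]) * scl
        dK[rows, cols] <- (crossprod(dS, q$value[rows, cols, drop = FALSE])) * scl
      }
    }
    list(dQ, dK, dV)
  })
}

# ---- 1-D convolution / pooling / batch norm ----------------------------------
#
# Signals are stored as (B*L) x C matrices, record-major. Padding positions are
# realized through an explicit zero row appended to the im2col gather, so pads
# contribute exactly zero and receive no gradient.

conv1d_index <- function(B, Lin, kernel, pad_left, pad_right, stride = 1L) {
  Lout <- (Lin + pad_left + pad_right - kernel) %/% stride + 1L
  if (Lout < 1L) stop("conv1d: output length < 1")
  zero_row <- B * Lin + 1L
  idx <- matrix(zero_row, B * Lout, kernel)
  for (b in seq_len(B)) {
    for (t in seq_len(Lout)) {
      src <- (t - 1L) * stride - pad_left + seq_len(kernel)  # 1-based into padded-less signal
      ok <- src >= 1L & src <= Lin
      row <- (b - 1L) * Lout + t
      idx[row, ok] <- (b - 1L) * Lin + src[ok]
    }
  }
  list(idx = idx, Lout = Lout, zero_row = zero_row)
}

# w: (kernel*Cin) x Cout, columns of the im2col block ordered tap-major
# (tap 1 channels..., tap 2 channels..., ...). b: 1 x Cout.
ad_conv1d <- function(x, w, b, B, Lin, kernel, pad_left = 0L, pad_right = 0L, stride = 1L) {
  x <- ad_wrap(x); w <- ad_wrap(w); b <- ad_wrap(b)
  Cin <- ncol(x$value)
  ix <- conv1d_index(B, Lin, kernel, pad_left, pad_right, stride)
  xp <- rbind(x$value, matrix(0, 1L, Cin))
  Xcol <- matrix(0, nrow(ix$idx), kernel * Cin)
  for (tap in seq_len(kernel)) {
    Xcol[, ((tap - 1L) * Cin + 1L):(tap * Cin)] <- xp[ix$idx[, tap], , drop = FALSE]
  }
  y <- sweep(Xcol %*% w$value, 2L, as.numeric(b$value), "+")
  ad_op(y, list(x, w, b), function(g) {
    dW <- crossprod(Xcol, g)
    dXcol <- tcrossprod(g, w$value)
    dXp <- matrix(0, nrow(xp), Cin)
    for (tap in seq_len(kernel)) {
      blk <- dXcol[, ((tap - 1L) * Cin + 1L):(tap * Cin), drop = FALSE]
      acc <- rowsum(blk, group = ix$idx[, tap], reorder = FALSE)
      dXp[as.integer(rownames(acc)), ] <- dXp[as.integer(rownames(acc)), ] + acc
    }
    list(dXp[seq_len(B * Lin), , drop = FALSE], dW, matrix(colSums(g), 1L))
  })
}

ad_maxpool1d <- function(x, B, Lin, kernel, pad = 0L, stride = NULL) {
  x <- ad_wrap(x)
  if (is.null(stride)) stride <- kernel
  C <- ncol(x$value)
  ix <- conv1d_index(B, Lin, kernel, pad, pad, stride)
  xp <- rbind(x$value, matrix(-Inf, 1L, C))
  n_out <- nrow(ix$idx)
  y <- matrix(-Inf, n_out, C)
  arg <- matrix(ix$zero_row, n_out, C)
  for (tap in seq_len(kernel)) {
    cand <- xp[ix$idx[, tap], , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    arg[upd] <- matrix(ix$idx[, tap], n_out, C)[upd]
  }
  y[!is.finite(y)] <- 0  # windows made only of padding
  ad_op(y, list(x), function(g) {
    dXp <- matrix(0, nrow(xp), C)
    for (cc in seq_len(C)) {
      acc <- rowsum(g[, cc, drop = FALSE], group = arg[, cc], reorder = FALSE)
      rs <- as.integer(rownames(acc))
      dXp[rs, cc] <- dXp[rs, cc] + acc
    }
    list(dXp[seq_len(B * Lin), , drop = FALSE])
  })
}

# Batch norm over the rows of x (optionally restricted by `valid` mask);
# `state` is an environment carrying running_mean / running_var, updated in
# training mode.
ad_batchnorm <- function(x, gamma, beta, state, training, valid = NULL,
                         momentum = 0.1, eps = 1e-5) {
  x <- ad_wrap(x); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  v <- x$value
  if (is.null(valid)) valid <- rep(TRUE, nrow(v))
  gv <- as.numeric(gamma$value)
  if (training) {
    vv <- v[valid, , drop = FALSE]
    n <- nrow(vv)
    mu <- colMeans(vv)
    va <- colMeans(sweep(vv, 2L, mu)^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va * n / max(n - 1L, 1L)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- bc_mul(bc_add(v, -mu), inv)
  y <- bc_add(bc_mul(xhat, gv), as.numeric(beta$value))
  if (!training) {
    return(ad_op(y, list(x, gamma, beta), function(g) {
      list(bc_mul(bc_mul(g, gv), inv),
           matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
    }))
  }
  n <- sum(valid)
  ad_op(y, list(x, gamma, beta), function(g) {
    dxhat <- bc_mul(g, gv)
    # direct path for every row
    dx <- bc_mul(dxhat, inv)
    # statistics paths: mu and var are computed from the valid rows only, but
    # every output row depends on them
    xc <- bc_add(v, -mu)
    dmu <- colSums(bc_mul(dxhat, -inv))
    dva <- colSums(dxhat * xc) * (-0.5) * inv^3
    add <- bc_mul(matrix(1, nrow(v), ncol(v)), dmu / n) +
      bc_mul(xc, 2 * dva / n)
    dx[valid, ] <- dx[valid, ] + add[valid, , drop = FALSE]
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

# ---- losses ------------------------------------------------------------------

# InfoNCE with sequence-side queries; numerically stable log-sum-exp.
ad_info_nce <- function(q, k, tau) {
  q <- ad_wrap(q); k <- ad_wrap(k)
  N <- nrow(q$value)
  S <- tcrossprod(q$value, k$value) / tau
  m <- row_max(S)
  lse <- m + log(rowSums(exp(S - m)))
  loss <- mean(lse - diag(S))
  P <- exp(S - lse)  # row-wise softmax
  ad_op(matrix(loss, 1, 1), list(q, k), function(g) {
    dS <- (P - diag(N)) * (as.numeric(g) / (N * tau))
    list(dS %*% k$value, crossprod(dS, q$value))
  })
}

# Mean softmax cross-entropy; labels in 1..C.
ad_softmax_xent <- function(logits, labels) {
  logits <- ad_wrap(logits)
  Z <- logits$value
  N <- nrow(Z)
  m <- row_max(Z)
  lse <- m + log(rowSums(exp(Z - m)))
  picked <- Z[cbind(seq_len(N), labels)]
  loss <- mean(lse - picked)
  P <- exp(Z - lse)
  ad_op(matrix(loss, 1, 1), list(logits), function(g) {
    dZ <- P
    dZ[cbind(seq_len(N), labels)] <- dZ[cbind(seq_len(N), labels)] - 1
    list(dZ * (as.numeric(g) / N))
  })
}

# Mean binary cross-entropy on raw logits (fused sigmoid); y in {0,1}.
ad_bce_logits <- function(logits, y) {
  logits <- ad_wrap(logits)
  z <- logits$value
  n <- length(z)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  s <- 1 / (1 + exp(-z))
  ad_op(matrix(loss, 1, 1), list(logits), function(g) {
    list((s - y) * (as.numeric(g) / n))
  })
}

ad_mse <- function(pred, target) {
  pred <- ad_wrap(pred)
  r <- pred$value - target
  n <- length(r)
  ad_op(matrix(mean(r^2), 1, 1), list(pred), function(g) {
    list(r * (2 * as.numeric(g) / n))
  })
}

# ---- geometric vector feature ops --------------------------------------------
#
# Vector features over n items with c channels are stored as (3n) x c matrices,
# rows grouped per item: item i occupies rows 3i-2..3i (x, y, z).

ad_vec_norm <- function(V, eps = 1e-8) {
  V <- ad_wrap(V)
  n3 <- nrow(V$value)
  stopifnot(n3 %% 3L == 0L)
  n <- n3 %/% 3L
  sq <- V$value^2
  i1 <- seq(1L, n3, by = 3L)
  norms <- sqrt(sq[i1, , drop = FALSE] + sq[i1 + 1L, , drop = FALSE] +
                  sq[i1 + 2L, , drop = FALSE] + eps)
  ad_op(norms, list(V), function(g) {
    g3 <- g[rep(seq_len(n), each = 3L), , drop = FALSE]
    n3m <- norms[rep(seq_len(n), each = 3L), , drop = FALSE]
    list(g3 * V$value / n3m)
  })
}

# Multiply each item-channel 3-vector by a scalar gate (n x c).
ad_vec_gate <- function(V, s) {
  V <- ad_wrap(V); s <- ad_wrap(s)
  n <- nrow(s$value)
  rep3 <- rep(seq_len(n), each = 3L)
  s3 <- s$value[rep3, , drop = FALSE]
  ad_op(V$value * s3, list(V, s), function(g) {
    list(g * s3, rowsum(g * V$value, group = rep3, reorder = FALSE))
  })
}

# Gather vector features for item index vector idx: expands to 3x row gather.
vec_row_index <- function(idx) {
  as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
}
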