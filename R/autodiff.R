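# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The whole network (frontend, Conformer blocks, decoders, losses) is built
# from the ops below. A "tape" records every op; ad_backward() replays it in
# reverse, accumulating gradients into parameter stores. Values are plain
# base-R matrices so all heavy lifting lands in BLAS.

tape_new <- function(train = FALSE) {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  e$train <- isTRUE(train)
  e
}

# A node handle carries its value and id; structural info lives on the tape.
# Arguments are forced before the id is allocated: sub-expressions that build
# their own nodes (e.g. ad_add(x, f(x))) must land below this node on the
# tape, or the reverse sweep would visit them too early.
ad_node <- function(tape, val, parents = integer(), bk = NULL, param = NULL) {
  force(val); force(parents); force(bk); force(param)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$n <- n
  tape$nodes[[n]] <- list(parents = parents, bk = bk, param = param)
  structure(list(id = n, val = val, tape = tape), class = "adnode")
}

ad_const <- function(tape, val) ad_node(tape, val)

# `p` is an environment with $value and $grad (see param_store()).
ad_param <- function(tape, p) ad_node(tape, p$value, param = p)

ad_value <- function(x) if (inherits(x, "adnode")) x$val else x

ad_backward <- function(tape, root, seed = 1) {
  grads <- vector("list", tape$n)
  grads[[root$id]] <- seed
  for (id in seq.int(tape$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tape$nodes[[id]]
    if (!is.null(nd$param)) nd$param$grad <- nd$param$grad + g
    if (is.null(nd$bk)) next
    pg <- nd$bk(g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      pid <- ps[[k]]
      grads[[pid]] <- if (is.null(grads[[pid]])) gk else grads[[pid]] + gk
    }
  }
  invisible(NULL)
}

## ---- elementwise and linear-algebra ops ----

ad_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  A <- a$val; B <- b$val
  if (ta && tb) stop("ad_matmul: transposing both operands is not supported")
  val <- if (!ta && !tb) A %*% B
    else if (!ta && tb) tcrossprod(A, B)
    else crossprod(A, B)
  ad_node(a$tape, val, c(a$id, b$id), function(g) {
    if (!ta && !tb) list(tcrossprod(g, B), crossprod(A, g))
    else if (!ta && tb) list(g %*% B, crossprod(g, A))
    else list(tcrossprod(B, g), A %*% g)
  })
}

ad_add <- function(a, b) {
  ad_node(a$tape, a$val + b$val, c(a$id, b$id), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$tape, a$val - b$val, c(a$id, b$id), function(g) list(g, -g))
}

# Broadcast helpers: add/multiply a length-C vector across the rows of a
# T x C matrix (column-major recycling; much faster than sweep()).
.brow_add <- function(x, v) x + rep(v, each = nrow(x))
.brow_mul <- function(x, v) x * rep(v, each = nrow(x))

# Add a length-C bias vector to every row of a T x C matrix.
ad_add_rowvec <- function(a, b) {
  ad_node(a$tape, .brow_add(a$val, as.numeric(b$val)), c(a$id, b$id),
          function(g) list(g, matrix(colSums(g), 1L)))
}

# Fused linear layer: x %*% W + bias (one node instead of two).
ad_linear <- function(x, W, b) {
  X <- x$val; Wv <- W$val
  val <- .brow_add(X %*% Wv, as.numeric(b$val))
  ad_node(x$tape, val, c(x$id, W$id, b$id), function(g) {
    list(tcrossprod(g, Wv), crossprod(X, g), matrix(colSums(g), 1L))
  })
}

ad_mul <- function(a, b) {
  A <- a$val; B <- b$val
  ad_node(a$tape, A * B, c(a$id, b$id), function(g) list(g * B, g * A))
}

ad_scale <- function(a, s) {
  ad_node(a$tape, a$val * s, a$id, function(g) list(g * s))
}

ad_add_const <- function(a, m) {
  ad_node(a$tape, a$val + m, a$id, function(g) list(g))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(a$tape, s, a$id, function(g) list(g * s * (1 - s)))
}

ad_swish <- function(a) {
  x <- a$val
  s <- 1 / (1 + exp(-x))
  ad_node(a$tape, x * s, a$id, function(g) list(g * s * (1 + x * (1 - s))))
}

## ---- row-wise softmax / log-softmax ----

.row_logsumexp <- function(x) {
  m <- cpp_row_max(x)
  m + log(rowSums(exp(x - m)))
}

ad_log_softmax <- function(a) {
  y <- cpp_logsoftmax_rows(a$val)
  ad_node(a$tape, y, a$id, function(g) list(g - exp(y) * rowSums(g)))
}

ad_softmax <- function(a) {
  p <- cpp_softmax_rows(a$val)
  ad_node(a$tape, p, a$id, function(g) list(p * (g - rowSums(g * p))))
}

## ---- normalization layers ----

# Layer norm over the channel (column) dimension of a T x C matrix.
ad_layer_norm <- function(x, gamma, beta, eps = 1e-5) {
  X <- x$val
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$val)
  y <- .brow_add(.brow_mul(xhat, gv), as.numeric(beta$val))
  ad_node(x$tape, y, c(x$id, gamma$id, beta$id), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    dxh <- .brow_mul(g, gv)
    dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * inv
    list(dx, dgamma, dbeta)
  })
}

# Batch norm over the time (row) dimension, per channel. `bn` is an
# environment holding running_mean / running_var; updated in training mode.
ad_batch_norm <- function(x, gamma, beta, bn, train, momentum = 0.1, eps = 1e-5) {
  X <- x$val
  Tn <- nrow(X)
  gv <- as.numeric(gamma$val)
  if (train) {
    mu <- colMeans(X)
    xc <- .brow_add(X, -mu)
    v <- colMeans(xc * xc)
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    # unbiased estimate feeds the running variance, as is conventional
    vu <- if (Tn > 1) v * Tn / (Tn - 1) else v
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * vu
  } else {
    mu <- bn$running_mean
    xc <- .brow_add(X, -mu)
    v <- bn$running_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- .brow_mul(xc, inv)
  y <- .brow_add(.brow_mul(xhat, gv), as.numeric(beta$val))
  ad_node(x$tape, y, c(x$id, gamma$id, beta$id), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    if (train) {
      gi <- gv * inv
      dx <- .brow_mul(g - .brow_add(matrix(0, Tn, length(gi)), colMeans(g)) -
                        .brow_mul(xhat, colMeans(g * xhat)), gi)
    } else {
      dx <- .brow_mul(g, gv * inv)
    }
    list(dx, dgamma, dbeta)
  })
}

## ---- structural ops ----

ad_slice_cols <- function(a, idx) {
  nc <- ncol(a$val)
  ad_node(a$tape, a$val[, idx, drop = FALSE], a$id, function(g) {
    d <- matrix(0, nrow(g), nc)
    d[, idx] <- g
    list(d)
  })
}

ad_cbind <- function(xs) {
  tape <- xs[[1]]$tape
  widths <- vapply(xs, function(x) ncol(x$val), 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  val <- do.call(cbind, lapply(xs, ad_value))
  ad_node(tape, val, vapply(xs, function(x) x$id, 0L), function(g) {
    lapply(seq_along(xs), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_dropout <- function(a, rate) {
  if (!a$tape$train || rate <= 0) return(a)
  keep <- (matrix(stats::runif(length(a$val)), nrow(a$val)) >= rate) / (1 - rate)
  ad_node(a$tape, a$val * keep, a$id, function(g) list(g * keep))
}

# Token-embedding lookup: rows of E indexed by integer vector `tokens`.
ad_embed <- function(Ep, tokens) {
  E <- Ep$val
  ad_node(Ep$tape, E[tokens, , drop = FALSE], Ep$id, function(g) {
    d <- matrix(0, nrow(E), ncol(E))
    agg <- rowsum(g, group = tokens)
    d[as.integer(rownames(agg)), ] <- agg
    list(d)
  })
}

ad_mean_all <- function(a) {
  n <- length(a$val)
  ad_node(a$tape, matrix(mean(a$val), 1, 1), a$id, function(g) {
    list(matrix(as.numeric(g) / n, nrow(a$val), ncol(a$val)))
  })
}

## ---- convolutions ----

# 1-D convolution along time via im2col. x: T x Cin; W: (K*Cin) x Cout
# (kernel-position-major blocks of Cin); b: Cout. Same padding, so
# L_out = floor((T - 1)/stride) + 1; output position t (0-based) reads input
# rows t*stride - floor((K-1)/2) .. + K - 1, out-of-range rows are zero.
ad_conv1d <- function(x, W, b, kernel, stride = 1L) {
  X <- x$val
  Wv <- W$val
  val <- cpp_conv1d_fwd(X, Wv, as.numeric(b$val), as.integer(kernel),
                        as.integer(stride))
  ad_node(x$tape, val, c(x$id, W$id, b$id), function(g) {
    r <- cpp_conv1d_bwd(X, Wv, g, as.integer(kernel), as.integer(stride))
    list(r$dx, r$dW, matrix(r$db, 1L))
  })
}

# Depthwise 1-D convolution, stride 1, same padding. W: K x C (one filter
# column per channel), b: C. Channel c of the output depends only on
# channel c of the input.
ad_depthwise_conv <- function(x, W, b, kernel) {
  X <- x$val
  Wv <- W$val
  val <- cpp_dwconv_fwd(X, Wv, as.numeric(b$val))
  ad_node(x$tape, val, c(x$id, W$id, b$id), function(g) {
    r <- cpp_dwconv_bwd(X, Wv, g)
    list(r$dx, r$dW, matrix(r$db, 1L))
  })
}

## ---- relative shift ----

# Position scores x: T x (2T-1), column c (1-based) holding the score of each
# query against relative offset (T - c), i.e. offsets T-1 .. -(T-1) left to
# right. Output: T x T with out[i, j] = x[i, T - (i - j)] — the score of
# query i against offset i - j. Implemented by the flatten-drop-reshape-slice
# trick; the explicit gather is the test oracle.
.shift_idx_cache <- new.env(parent = emptyenv())

# Linear indices (column-major) implementing the shift as a gather:
# out[i, j] = x[i, T - (i - j)] on a T x (2T-1) input.
.shift_idx <- function(Tn) {
  key <- as.character(Tn)
  idx <- .shift_idx_cache[[key]]
  if (is.null(idx)) {
    i <- rep(seq_len(Tn), Tn)
    j <- rep(seq_len(Tn), each = Tn)
    idx <- i + (Tn - i + j - 1L) * Tn
    .shift_idx_cache[[key]] <- idx
  }
  idx
}

ad_relative_shift <- function(a) {
  X <- a$val
  Tn <- nrow(X)
  if (ncol(X) != 2L * Tn - 1L) {
    stop("relative_shift expects a T x (2T-1) position-score matrix")
  }
  if (Tn == 1L) return(ad_node(a$tape, X, a$id, function(g) list(g)))
  idx <- .shift_idx(Tn)
  val <- matrix(X[idx], Tn, Tn)
  ad_node(a$tape, val, a$id, function(g) {
    d <- numeric(Tn * (2L * Tn - 1L))
    d[idx] <- g
    list(matrix(d, Tn))
  })
}

# Fused multi-head self-attention (C++ kernels, see src/ops.cpp).
# posmode: 0 plain scaled dot-product, 1 relative position scores with the
# Transformer-XL shift, 2 absolute-position scores without shift.
ad_mhsa <- function(Q, K, V, Kp, bc, bp, mask, H, posmode) {
  tape <- Q$tape
  Qv <- Q$val; Kv <- K$val; Vv <- V$val
  Kpv <- if (is.null(Kp)) matrix(0, 0, 0) else Kp$val
  bcv <- if (is.null(bc)) numeric(0) else as.numeric(bc$val)
  bpv <- if (is.null(bp)) numeric(0) else as.numeric(bp$val)
  mk <- if (is.null(mask)) matrix(0, 0, 0) else mask
  r <- cpp_mhsa_fwd(Qv, Kv, Vv, Kpv, bcv, bpv, mk, H, posmode)
  P <- r$P
  parents <- c(Q$id, K$id, V$id,
               if (posmode > 0L) c(Kp$id, bc$id, bp$id))
  ad_node(tape, r$out, parents, function(g) {
    b <- cpp_mhsa_bwd(g, Qv, Kv, Vv, Kpv, bcv, bpv, P, H, posmode)
    c(list(b$dQ, b$dK, b$dV),
      if (posmode > 0L) list(b$dKp, matrix(b$dbc, 1L), matrix(b$dbp, 1L)))
  })
}

## ---- losses as tape ops ----

# CTC loss on a T x V matrix of log-probabilities (column 1 = blank),
# target: integer vector of label columns (values in 2..V). Forward-backward
# in log space; gradient w.r.t. the log-probability matrix.
ad_ctc <- function(lp, target) {
  res <- ctc_forward_backward(lp$val, target, want_grad = TRUE)
  ad_node(lp$tape, matrix(res$loss, 1, 1), lp$id, function(g) {
    list(as.numeric(g) * res$grad)
  })
}

# Mean over rows of KL(q || p) where p = exp(lp) row-distributions and q is a
# fixed row-stochastic matrix (e.g. label-smoothed one-hot targets).
ad_kl_rows <- function(lp, q) {
  Tn <- nrow(q)
  lq <- ifelse(q > 0, log(q), 0)
  val <- sum(q * (lq - lp$val)) / Tn
  ad_node(lp$tape, matrix(val, 1, 1), lp$id, function(g) {
    list(-as.numeric(g) * q / Tn)
  })
}
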