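# The basecaller network: three-layer convolutional frontend, a stack of
# Conformer blocks (relative-position multi-head self-attention + gated
# depthwise-separable convolution), a CTC projection, and a pair of
# training-only causal decoders (forward and reverse).

VOCAB <- c("-", "A", "C", "G", "U")  # column 1 is the CTC blank
SOS_ID <- 6L
EOS_ID <- 7L
DEC_VOCAB_SIZE <- 7L

base_to_id <- function(seq) {
  ids <- match(strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]], VOCAB)
  if (anyNA(ids) || any(ids == 1L)) {
    stop("sequence contains characters outside {A,C,G,U/T}")
  }
  ids
}

id_to_base <- function(ids) paste(VOCAB[ids], collapse = "")

#' Model configuration
#'
#' Collects every architectural hyperparameter of the basecaller, including
#' the ablation switches. Defaults are the full-size network: a frontend with
#' output channels (4, 6, d_model), kernels (5, 5, 19) and strides (1, 1, 10)
#' for 10x downsampling, followed by `n_blocks` Conformer blocks of width
#' `d_model` with `n_heads` attention heads, a feed-forward expansion of
#' `ff_expansion` and a depthwise kernel of `conv_kernel` inside the gated
#' convolution sub-block. At these defaults the inference network carries
#' roughly fifty million trainable parameters.
#'
#' @param d_model Width of the block representations.
#' @param n_heads Number of attention heads; must divide `d_model`.
#' @param n_blocks Number of encoder blocks.
#' @param ff_expansion Feed-forward hidden multiplier (macaron halves).
#' @param conv_kernel Depthwise kernel size inside the gated conv block.
#' @param dropout Dropout rate used during training.
#' @param frontend_channels,frontend_kernels,frontend_strides Integer
#'   triples describing the convolutional frontend. The last channel count
#'   must equal `d_model`.
#' @param use_relative_shift If `FALSE`, position scores are computed from
#'   absolute sinusoidal encodings with no relative shift (the "w/o RS"
#'   ablation).
#' @param block_type `"conformer"` or `"transformer"`; the latter swaps each
#'   Conformer block for a standard Transformer encoder layer with absolute
#'   positions (the convolution sub-block is removed).
#' @param n_decoder_layers Layers in each training-only causal decoder.
#' @param lambda_weight Mixing weight of the CTC term in the joint loss.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d_model = 512L,
                         n_heads = 8L,
                         n_blocks = 8L,
                         ff_expansion = 4L,
                         conv_kernel = 31L,
                         dropout = 0.1,
                         frontend_channels = c(4L, 6L, d_model),
                         frontend_kernels = c(5L, 5L, 19L),
                         frontend_strides = c(1L, 1L, 10L),
                         use_relative_shift = TRUE,
                         block_type = c("conformer", "transformer"),
                         n_decoder_layers = 2L,
                         lambda_weight = 0.5) {
  block_type <- match.arg(block_type)
  cfg <- list(
    d_model = as.integer(d_model),
    n_heads = as.integer(n_heads),
    n_blocks = as.integer(n_blocks),
    head_dim = as.integer(d_model) %/% as.integer(n_heads),
    ff_expansion = as.integer(ff_expansion),
    conv_kernel = as.integer(conv_kernel),
    dropout = dropout,
    frontend_channels = as.integer(frontend_channels),
    frontend_kernels = as.integer(frontend_kernels),
    frontend_strides = as.integer(frontend_strides),
    vocab = VOCAB,
    use_relative_shift = isTRUE(use_relative_shift),
    block_type = block_type,
    n_decoder_layers = as.integer(n_decoder_layers),
    lambda_weight = lambda_weight
  )
  validate_model_config(cfg)
  structure(cfg, class = "model_config")
}

validate_model_config <- function(cfg) {
  stopifnot(
    cfg$d_model >= 1L, cfg$n_heads >= 1L,
    cfg$d_model %% cfg$n_heads == 0L,
    cfg$d_model %% 2L == 0L,
    length(cfg$frontend_channels) == 3L,
    length(cfg$frontend_kernels) == 3L,
    length(cfg$frontend_strides) == 3L,
    length(cfg$vocab) == 5L,
    cfg$lambda_weight >= 0, cfg$lambda_weight <= 1,
    cfg$n_decoder_layers >= 1L
  )
  if (cfg$frontend_channels[3] != cfg$d_model) {
    stop("last frontend channel count must equal d_model")
  }
  invisible(cfg)
}

#' Ablation configurations
#'
#' Derives the two ablated architectures from a base configuration:
#' `"no_relative_shift"` removes the relative shift of position scores
#' (absolute sinusoidal position scores are used instead), and
#' `"transformer"` replaces the Conformer blocks with standard Transformer
#' encoder layers. All other fields are unchanged.
#'
#' @param config A [model_config()].
#' @param which One of `"none"`, `"no_relative_shift"`, `"transformer"`.
#' @return A `model_config`.
#' @export
make_ablation <- function(config, which = c("none", "no_relative_shift", "transformer")) {
  which <- match.arg(which)
  if (which == "no_relative_shift") config$use_relative_shift <- FALSE
  if (which == "transformer") config$block_type <- "transformer"
  config
}

## ---- parameter shapes ----

.attn_shapes <- function(d, pos = FALSE) {
  s <- list(
    Wq = c(d, d), Wq_b = c(1L, d),
    Wk = c(d, d), Wk_b = c(1L, d),
    Wv = c(d, d), Wv_b = c(1L, d),
    Wo = c(d, d), Wo_b = c(1L, d)
  )
  if (pos) {
    s$Wp <- c(d, d)
    s$bias_content <- c(1L, d)
    s$bias_pos <- c(1L, d)
  }
  s
}

.ff_shapes <- function(d, f) {
  list(ln_g = c(1L, d), ln_b = c(1L, d),
       W1 = c(d, f), W1_b = c(1L, f),
       W2 = c(f, d), W2_b = c(1L, d))
}

.prefix <- function(prefix, shapes) {
  names(shapes) <- paste0(prefix, names(shapes))
  shapes
}

param_shapes <- function(config, include_decoders = TRUE) {
  d <- config$d_model
  f <- config$ff_expansion * d
  ch <- config$frontend_channels
  ks <- config$frontend_kernels
  cin <- c(1L, ch[1], ch[2])
  shapes <- list()
  for (i in 1:3) {
    shapes[[sprintf("fe.conv%d", i)]] <- c(ks[i] * cin[i], ch[i])
    shapes[[sprintf("fe.conv%d_b", i)]] <- c(1L, ch[i])
  }
  for (j in seq_len(config$n_blocks)) {
    p <- sprintf("enc.b%d.", j)
    if (config$block_type == "conformer") {
      blk <- c(
        .prefix("ff1_", .ff_shapes(d, f)),
        list(att_ln_g = c(1L, d), att_ln_b = c(1L, d)),
        .prefix("att_", .attn_shapes(d, pos = TRUE)),
        list(conv_ln_g = c(1L, d), conv_ln_b = c(1L, d),
             conv_pw1 = c(d, 2L * d), conv_pw1_b = c(1L, 2L * d),
             conv_dw_W = c(config$conv_kernel, d), conv_dw_b = c(1L, d),
             conv_bn_g = c(1L, d), conv_bn_b = c(1L, d),
             conv_pw2 = c(d, d), conv_pw2_b = c(1L, d)),
        .prefix("ff2_", .ff_shapes(d, f)),
        list(final_ln_g = c(1L, d), final_ln_b = c(1L, d))
      )
    } else {
      blk <- c(
        list(att_ln_g = c(1L, d), att_ln_b = c(1L, d)),
        .prefix("att_", .attn_shapes(d, pos = FALSE)),
        .prefix("ff_", .ff_shapes(d, f))
      )
    }
    shapes <- c(shapes, .prefix(p, blk))
  }
  if (config$block_type == "transformer") {
    shapes[["enc.final_ln_g"]] <- c(1L, d)
    shapes[["enc.final_ln_b"]] <- c(1L, d)
  }
  shapes[["enc.head"]] <- c(d, 5L)
  shapes[["enc.head_b"]] <- c(1L, 5L)
  if (include_decoders) {
    for (dir in c("fwd", "rev")) {
      p <- sprintf("dec.%s.", dir)
      dec <- list(embed = c(DEC_VOCAB_SIZE, d))
      for (l in seq_len(config$n_decoder_layers)) {
        lp <- sprintf("l%d.", l)
        lay <- c(
          list(sa_ln_g = c(1L, d), sa_ln_b = c(1L, d)),
          .prefix("sa_", .attn_shapes(d)),
          list(ca_ln_g = c(1L, d), ca_ln_b = c(1L, d)),
          .prefix("ca_", .attn_shapes(d)),
          .prefix("ff_", .ff_shapes(d, f))
        )
        dec <- c(dec, .prefix(lp, lay))
      }
      dec <- c(dec, list(final_ln_g = c(1L, d), final_ln_b = c(1L, d),
                         out = c(d, DEC_VOCAB_SIZE),
                         out_b = c(1L, DEC_VOCAB_SIZE)))
      shapes <- c(shapes, .prefix(p, dec))
    }
  }
  shapes
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars implied by a configuration, summed over
#' the shapes of every weight, bias, normalization gain/offset and attention
#' position bias. Batch-norm running statistics are not trainable and are
#' not counted.
#'
#' @param config A [model_config()].
#' @param include_decoders Count the training-only decoders as well? The
#'   default `FALSE` counts the inference network only.
#' @return Integer-valued numeric scalar.
#' @export
count_parameters <- function(config, include_decoders = FALSE) {
  validate_model_config(config)
  sh <- param_shapes(config, include_decoders = include_decoders)
  sum(vapply(sh, prod, 0))
}

## ---- initialization ----

param_store <- function(shapes, seed = 1L) {
  set.seed(seed)
  env <- new.env(parent = emptyenv())
  for (nm in names(shapes)) {
    dm <- shapes[[nm]]
    val <- if (grepl("(_ln_g|_bn_g)$", nm)) {
      matrix(1, dm[1], dm[2])
    } else if (grepl("(_b|_ln_b|_bn_b|bias_content|bias_pos)$", nm)) {
      matrix(0, dm[1], dm[2])
    } else if (grepl("embed$", nm)) {
      matrix(stats::rnorm(prod(dm), sd = 0.02), dm[1], dm[2])
    } else {
      lim <- sqrt(6 / (dm[1] + dm[2]))
      matrix(stats::runif(prod(dm), -lim, lim), dm[1], dm[2])
    }
    p <- new.env(parent = emptyenv())
    p$value <- val
    p$grad <- 0
    env[[nm]] <- p
  }
  env
}

#' Instantiate a basecaller network
#'
#' Allocates and initializes every trainable parameter of the architecture
#' described by `config` (Xavier-uniform weights, zero biases, unit
#' normalization gains), plus per-block batch-norm running statistics.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialization.
#' @param include_decoders Allocate the training-only decoders as well.
#' @return An object of class `basecaller_net`.
#' @export
init_network <- function(config, seed = 1L, include_decoders = TRUE) {
  validate_model_config(config)
  shapes <- param_shapes(config, include_decoders = include_decoders)
  params <- param_store(shapes, seed = seed)
  bn <- list()
  if (config$block_type == "conformer") {
    for (j in seq_len(config$n_blocks)) {
      e <- new.env(parent = emptyenv())
      e$running_mean <- numeric(config$d_model)
      e$running_var <- rep(1, config$d_model)
      bn[[sprintf("b%d", j)]] <- e
    }
  }
  structure(list(config = config, params = params, bn = bn,
                 has_decoders = include_decoders),
            class = "basecaller_net")
}

zero_grads <- function(net) {
  for (nm in ls(net$params)) net$params[[nm]]$grad <- 0
  invisible(net)
}

## ---- sinusoidal encodings ----

sinusoid_encoding <- function(positions, d) {
  k <- seq_len(d %/% 2L)
  freq <- 10000^(-(2 * (k - 1)) / d)
  ang <- outer(positions, freq)
  pe <- matrix(0, length(positions), d)
  pe[, 2L * k - 1L] <- sin(ang)
  pe[, 2L * k] <- cos(ang)
  pe
}

## ---- numeric building blocks (shared with the tape ops) ----

rel_shift_matrix <- function(x) {
  Tn <- nrow(x)
  if (ncol(x) != 2L * Tn - 1L) {
    stop("relative_shift expects a T x (2T-1) position-score matrix")
  }
  if (Tn == 1L) return(x)
  W <- 2L * Tn - 2L
  v <- as.numeric(t(x))
  body <- v[Tn:(Tn + Tn * W - 1L)]
  t(matrix(body, nrow = W))[, seq_len(Tn), drop = FALSE]
}

#' Relative shift of position scores
#'
#' Converts a matrix of per-offset position scores into the query-by-key
#' attention layout of Transformer-XL. The input holds, for each of T
#' queries, its raw score against every relative offset T-1, T-2, ..., 0,
#' ..., -(T-1) (columns left to right, 2T-1 of them). The output is T x T
#' with entry (i, j) equal to the score of query i against relative offset
#' i - j, computed by the flatten-drop-reshape-slice trick rather than an
#' explicit gather.
#'
#' @param scores Numeric matrix, T rows and 2T-1 columns.
#' @return A T x T numeric matrix.
#' @export
relative_shift <- function(scores) {
  if (!is.matrix(scores)) stop("scores must be a matrix")
  rel_shift_matrix(scores)
}

#' Gated linear unit
#'
#' Splits the channel dimension in half and gates the first half by the
#' sigmoid of the second: `GLU(a, b) = a * sigmoid(b)`.
#'
#' @param x Numeric vector of even length, or matrix with an even number of
#'   columns (channels).
#' @return Vector or matrix with half the channels of the input.
#' @export
glu <- function(x) {
  if (is.matrix(x)) {
    m <- ncol(x)
    if (m %% 2L != 0L) stop("glu requires an even channel dimension")
    h <- m %/% 2L
    x[, 1:h, drop = FALSE] * stats::plogis(x[, (h + 1):m, drop = FALSE])
  } else {
    m <- length(x)
    if (m %% 2L != 0L) stop("glu requires an even channel dimension")
    h <- m %/% 2L
    x[1:h] * stats::plogis(x[(h + 1):m])
  }
}

## ---- tape-based forward passes ----

.gp <- function(tape, net, nm) {
  p <- net$params[[nm]]
  if (is.null(p)) stop("unknown parameter: ", nm)
  ad_param(tape, p)
}

.lin <- function(tape, net, x, nm) {
  ad_linear(x, .gp(tape, net, nm), .gp(tape, net, paste0(nm, "_b")))
}

.fwd_frontend <- function(net, tape, xnode) {
  cfg <- net$config
  x <- xnode
  for (i in 1:3) {
    x <- ad_conv1d(x,
                   .gp(tape, net, sprintf("fe.conv%d", i)),
                   .gp(tape, net, sprintf("fe.conv%d_b", i)),
                   kernel = cfg$frontend_kernels[i],
                   stride = cfg$frontend_strides[i])
    x <- ad_swish(x)
  }
  x
}

# Multi-head attention. posmode: "rel" (Transformer-XL relative scores with
# shift), "abs_scores" (position scores from absolute sinusoidal encodings,
# no shift; the w/o-RS ablation), or "none" (plain scaled dot-product).
# The score/softmax/context computation is a single fused kernel; dropout
# is applied to the projected output.
.fwd_attention <- function(net, tape, q_in, kv_in, prefix, mask = NULL,
                           posmode = "none") {
  cfg <- net$config
  Q <- .lin(tape, net, q_in, paste0(prefix, "Wq"))
  K <- .lin(tape, net, kv_in, paste0(prefix, "Wk"))
  V <- .lin(tape, net, kv_in, paste0(prefix, "Wv"))
  pm <- switch(posmode, none = 0L, rel = 1L, abs_scores = 2L)
  Kp <- bc <- bp <- NULL
  if (pm > 0L) {
    Tn <- nrow(Q$val)
    pos <- if (pm == 1L) seq.int(Tn - 1L, -(Tn - 1L)) else seq.int(0L, Tn - 1L)
    R <- ad_const(tape, sinusoid_encoding(pos, cfg$d_model))
    Kp <- ad_matmul(R, .gp(tape, net, paste0(prefix, "Wp")))
    bc <- .gp(tape, net, paste0(prefix, "bias_content"))
    bp <- .gp(tape, net, paste0(prefix, "bias_pos"))
  }
  ctx <- ad_mhsa(Q, K, V, Kp, bc, bp, mask, cfg$n_heads, pm)
  ad_dropout(.lin(tape, net, ctx, paste0(prefix, "Wo")), cfg$dropout)
}

.fwd_ff <- function(net, tape, x, prefix, half = FALSE) {
  cfg <- net$config
  xn <- ad_layer_norm(x, .gp(tape, net, paste0(prefix, "ln_g")),
                      .gp(tape, net, paste0(prefix, "ln_b")))
  h <- ad_dropout(ad_swish(.lin(tape, net, xn, paste0(prefix, "W1"))), cfg$dropout)
  y <- ad_dropout(.lin(tape, net, h, paste0(prefix, "W2")), cfg$dropout)
  if (half) ad_scale(y, 0.5) else y
}

.fwd_conv_block <- function(net, tape, x, j) {
  cfg <- net$config
  p <- sprintf("enc.b%d.conv_", j)
  xn <- ad_layer_norm(x, .gp(tape, net, paste0(p, "ln_g")),
                      .gp(tape, net, paste0(p, "ln_b")))
  y <- .lin(tape, net, xn, paste0(p, "pw1"))
  d <- cfg$d_model
  a <- ad_slice_cols(y, 1:d)
  b <- ad_slice_cols(y, (d + 1L):(2L * d))
  y <- ad_mul(a, ad_sigmoid(b))
  y <- ad_depthwise_conv(y, .gp(tape, net, paste0(p, "dw_W")),
                         .gp(tape, net, paste0(p, "dw_b")),
                         kernel = cfg$conv_kernel)
  y <- ad_batch_norm(y, .gp(tape, net, paste0(p, "bn_g")),
                     .gp(tape, net, paste0(p, "bn_b")),
                     bn = net$bn[[sprintf("b%d", j)]], train = tape$train)
  y <- ad_swish(y)
  ad_dropout(.lin(tape, net, y, paste0(p, "pw2")), cfg$dropout)
}

.fwd_conformer_block <- function(net, tape, x, j) {
  cfg <- net$config
  p <- sprintf("enc.b%d.", j)
  x <- ad_add(x, .fwd_ff(net, tape, x, paste0(p, "ff1_"), half = TRUE))
  xn <- ad_layer_norm(x, .gp(tape, net, paste0(p, "att_ln_g")),
                      .gp(tape, net, paste0(p, "att_ln_b")))
  posmode <- if (cfg$use_relative_shift) "rel" else "abs_scores"
  x <- ad_add(x, .fwd_attention(net, tape, xn, xn, paste0(p, "att_"),
                                posmode = posmode))
  x <- ad_add(x, .fwd_conv_block(net, tape, x, j))
  x <- ad_add(x, .fwd_ff(net, tape, x, paste0(p, "ff2_"), half = TRUE))
  ad_layer_norm(x, .gp(tape, net, paste0(p, "final_ln_g")),
                .gp(tape, net, paste0(p, "final_ln_b")))
}

.fwd_transformer_block <- function(net, tape, x, j) {
  p <- sprintf("enc.b%d.", j)
  xn <- ad_layer_norm(x, .gp(tape, net, paste0(p, "att_ln_g")),
                      .gp(tape, net, paste0(p, "att_ln_b")))
  x <- ad_add(x, .fwd_attention(net, tape, xn, xn, paste0(p, "att_"),
                                posmode = "none"))
  ad_add(x, .fwd_ff(net, tape, x, paste0(p, "ff_")))
}

.fwd_encoder <- function(net, tape, signal) {
  cfg <- net$config
  x <- ad_const(tape, matrix(as.numeric(signal), ncol = 1L))
  x <- .fwd_frontend(net, tape, x)
  if (cfg$block_type == "transformer") {
    x <- ad_add_const(x, sinusoid_encoding(seq.int(0L, nrow(x$val) - 1L),
                                           cfg$d_model))
  }
  for (j in seq_len(cfg$n_blocks)) {
    x <- if (cfg$block_type == "conformer") {
      .fwd_conformer_block(net, tape, x, j)
    } else {
      .fwd_transformer_block(net, tape, x, j)
    }
  }
  if (cfg$block_type == "transformer") {
    x <- ad_layer_norm(x, .gp(tape, net, "enc.final_ln_g"),
                       .gp(tape, net, "enc.final_ln_b"))
  }
  logp <- ad_log_softmax(.lin(tape, net, x, "enc.head"))
  list(memory = x, logp = logp)
}

.fwd_decoder <- function(net, tape, memory, label_ids, direction) {
  cfg <- net$config
  if (length(label_ids) == 0L) stop("decoder targets must be nonempty")
  ids <- if (direction == "reverse") rev(label_ids) else label_ids
  tokens_in <- c(SOS_ID, ids)
  targets_out <- c(ids, EOS_ID)
  p <- sprintf("dec.%s.", if (direction == "reverse") "rev" else "fwd")
  x <- ad_embed(.gp(tape, net, paste0(p, "embed")), tokens_in)
  x <- ad_add_const(x, sinusoid_encoding(seq.int(0L, length(tokens_in) - 1L),
                                         cfg$d_model))
  x <- ad_dropout(x, cfg$dropout)
  L <- length(tokens_in)
  causal <- matrix(-1e9, L, L)
  causal[lower.tri(causal, diag = TRUE)] <- 0
  for (l in seq_len(cfg$n_decoder_layers)) {
    lp <- sprintf("%sl%d.", p, l)
    xn <- ad_layer_norm(x, .gp(tape, net, paste0(lp, "sa_ln_g")),
                        .gp(tape, net, paste0(lp, "sa_ln_b")))
    x <- ad_add(x, .fwd_attention(net, tape, xn, xn, paste0(lp, "sa_"),
                                  mask = causal))
    xn <- ad_layer_norm(x, .gp(tape, net, paste0(lp, "ca_ln_g")),
                        .gp(tape, net, paste0(lp, "ca_ln_b")))
    x <- ad_add(x, .fwd_attention(net, tape, xn, memory, paste0(lp, "ca_")))
    x <- ad_add(x, .fwd_ff(net, tape, x, paste0(lp, "ff_")))
  }
  x <- ad_layer_norm(x, .gp(tape, net, paste0(p, "final_ln_g")),
                     .gp(tape, net, paste0(p, "final_ln_b")))
  logp <- ad_log_softmax(.lin(tape, net, x, paste0(p, "out")))
  list(logp = logp, targets_out = targets_out, tokens_in = tokens_in)
}

## ---- exported numeric wrappers (inference mode) ----

#' Convolutional frontend
#'
#' Runs the three-layer downsampling frontend on a normalized signal chunk.
#' With same-padding and strides (1, 1, 10) the output length is
#' `floor((L - 1)/10) + 1` frames.
#'
#' @param net A [init_network()] object.
#' @param chunk Numeric vector of normalized signal samples.
#' @return A `L_out x d_model` matrix of feature frames.
#' @export
conv_frontend <- function(net, chunk) {
  stopifnot(inherits(net, "basecaller_net"), length(chunk) >= 1L)
  tape <- tape_new(train = FALSE)
  x <- ad_const(tape, matrix(as.numeric(chunk), ncol = 1L))
  .fwd_frontend(net, tape, x)$val
}

#' Relative-position multi-head self-attention
#'
#' Applies one encoder block's attention sub-module (in isolation, in
#' inference mode) to a T x d_model input: per head, attention weights are
#' the softmax over keys of
#' `[(Q + b_content) K' + relative_shift((Q + b_pos) Kp')] / sqrt(d_k)`,
#' contexts are concatenated across heads and projected.
#'
#' @param net A [init_network()] object.
#' @param X Numeric T x d_model matrix.
#' @param block Which encoder block's parameters to use.
#' @return A T x d_model matrix.
#' @export
relative_mhsa <- function(net, X, block = 1L) {
  stopifnot(inherits(net, "basecaller_net"), is.matrix(X))
  cfg <- net$config
  tape <- tape_new(train = FALSE)
  xn <- ad_const(tape, X)
  posmode <- if (cfg$use_relative_shift) "rel" else "abs_scores"
  p <- sprintf("enc.b%d.att_", block)
  .fwd_attention(net, tape, xn, xn, p, posmode = posmode)$val
}

#' Gated depthwise-separable convolution block
#'
#' One encoder block's convolution sub-module in isolation (inference mode):
#' layer norm, pointwise convolution to 2*d_model channels, GLU gate back to
#' d_model, depthwise convolution (same padding), batch normalization using
#' running statistics, swish, and a final pointwise convolution. Sequence
#' length is preserved.
#'
#' @inheritParams relative_mhsa
#' @return A matrix of the same shape as `X`.
#' @export
gated_conv_block <- function(net, X, block = 1L) {
  stopifnot(inherits(net, "basecaller_net"), is.matrix(X))
  if (net$config$block_type != "conformer") {
    stop("transformer blocks have no gated convolution sub-block")
  }
  tape <- tape_new(train = FALSE)
  .fwd_conv_block(net, tape, ad_const(tape, X), block)$val
}

#' One encoder block
#'
#' Applies a full encoder block (inference mode): macaron half feed-forward,
#' relative-position attention, gated convolution, second half feed-forward,
#' then layer norm — or a standard Transformer encoder layer when
#' `block_type = "transformer"`.
#'
#' @inheritParams relative_mhsa
#' @return A matrix of the same shape as `X`.
#' @export
conformer_block <- function(net, X, block = 1L) {
  stopifnot(inherits(net, "basecaller_net"), is.matrix(X))
  tape <- tape_new(train = FALSE)
  x <- ad_const(tape, X)
  if (net$config$block_type == "conformer") {
    .fwd_conformer_block(net, tape, x, block)$val
  } else {
    .fwd_transformer_block(net, tape, x, block)$val
  }
}

#' Encoder forward pass
#'
#' Full inference pass: frontend, all encoder blocks, CTC projection and
#' row-wise log-softmax over the five symbols (blank, A, C, G, U).
#'
#' @param net A [init_network()] object.
#' @param chunk Numeric vector of normalized signal samples.
#' @return An object of class `frame_logprobs`: list with `frames`
#'   (T x 5 log-probability matrix), `valid_length`, and `memory`
#'   (T x d_model encoder states, used by the training decoders).
#' @export
encoder_forward <- function(net, chunk) {
  stopifnot(inherits(net, "basecaller_net"), length(chunk) >= 1L)
  tape <- tape_new(train = FALSE)
  out <- .fwd_encoder(net, tape, chunk)
  structure(list(frames = out$logp$val,
                 valid_length = nrow(out$logp$val),
                 memory = out$memory$val),
            class = "frame_logprobs")
}

#' Decoder forward pass (teacher-forced)
#'
#' Runs one training decoder over a target sequence with teacher forcing.
#' The forward decoder sees tokens left to right under a lower-triangular
#' causal mask; the reverse decoder consumes the reversed target under the
#' same mask, which is equivalent to an anti-lower-triangular causal mask on
#' the original order. Output rows are log-probabilities over the 7-symbol
#' decoder vocabulary (blank, A, C, G, U, start, end).
#'
#' @param net A [init_network()] object (with decoders).
#' @param memory T x d_model encoder states (or a `frame_logprobs` object).
#' @param target Target base string over A, C, G, U (T is accepted for U).
#' @param direction `"forward"` or `"reverse"`.
#' @return Object of class `decoder_output`: list with `frames`
#'   ((L+1) x 7 log-probabilities in decoding order), `targets_out`
#'   (token ids each row predicts), and `direction`.
#' @export
decoder_forward <- function(net, memory, target, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(net, "basecaller_net"))
  if (!isTRUE(net$has_decoders)) stop("network was built without decoders")
  if (inherits(memory, "frame_logprobs")) memory <- memory$memory
  if (!nzchar(target)) stop("decoder targets must be nonempty")
  ids <- base_to_id(target)
  tape <- tape_new(train = FALSE)
  mem <- ad_const(tape, memory)
  out <- .fwd_decoder(net, tape, mem, ids, direction)
  structure(list(frames = out$logp$val, targets_out = out$targets_out,
                 direction = direction),
            class = "decoder_output")
}
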