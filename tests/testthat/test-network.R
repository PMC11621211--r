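test_that("model configuration validates and ablations flip single fields", {
  cfg <- model_config()
  expect_identical(cfg$frontend_channels, c(4L, 6L, 512L))
  expect_identical(cfg$frontend_kernels, c(5L, 5L, 19L))
  expect_identical(cfg$frontend_strides, c(1L, 1L, 10L))
  expect_identical(cfg$head_dim, 64L)
  expect_error(model_config(d_model = 30L, n_heads = 4L), "d_model")
  expect_error(model_config(frontend_channels = c(4L, 6L, 100L)), "d_model")
  expect_error(model_config(lambda_weight = 1.2))

  base <- tiny_model_config()
  no_rs <- make_ablation(base, "no_relative_shift")
  tcall <- make_ablation(base, "transformer")
  expect_identical(make_ablation(base, "none"), base)
  d1 <- names(which(!mapply(identical, base, no_rs)))
  expect_identical(d1, "use_relative_shift")
  d2 <- names(which(!mapply(identical, base, tcall)))
  expect_identical(d2, "block_type")
  expect_error(make_ablation(base, "bogus"))
})

test_that("frontend downsampling follows floor((L-1)/10) + 1 with same padding", {
  net <- init_network(tiny_model_config(), seed = 1, include_decoders = FALSE)
  for (L in c(1L, 10L, 11L, 4000L, 4096L)) {
    out <- conv_frontend(net, rnorm(L))
    expect_identical(nrow(out), (L - 1L) %/% 10L + 1L)
    expect_identical(ncol(out), 16L)
  }
})

test_that("relative shift equals the explicit (i-j) gather and rejects bad shapes", {
  set.seed(42)
  expect_identical(relative_shift(matrix(3.5, 1, 1)), matrix(3.5, 1, 1))
  x <- matrix(rnorm(4 * 7), 4)
  expect_identical(relative_shift(x), gather_shift_oracle(x))
  for (Tn in 2:16) {
    x <- matrix(rnorm(Tn * (2 * Tn - 1)), Tn)
    expect_identical(relative_shift(x), gather_shift_oracle(x))
  }
  expect_error(relative_shift(matrix(0, 4, 4)), "2T-1")
})

test_that("glu gates the first half by the sigmoid of the second", {
  expect_equal(glu(c(1, 2, 0, 0)), c(0.5, 1.0))
  expect_equal(glu(c(1.5, -2, 20, 20)), c(1.5, -2), tolerance = 1e-8)
  expect_equal(glu(c(-1, 3, log(3), log(1 / 3))), c(-0.75, 0.75))
  m <- matrix(c(1, 2, 0, 0), 1)
  expect_equal(glu(m), matrix(c(0.5, 1.0), 1))
  expect_error(glu(c(1, 2, 3)), "even")
})

test_that("relative attention normalizes rows and reduces to plain attention", {
  cfg <- tiny_model_config()
  net <- init_network(cfg, seed = 7, include_decoders = FALSE)
  set.seed(3)
  X <- matrix(rnorm(9 * 16), 9, 16)
  out <- relative_mhsa(net, X)
  expect_identical(dim(out), dim(X))
  expect_true(all(is.finite(out)))
  # attention rows sum to 1 (per head) on the fused kernel's probabilities
  Q <- sweep(X %*% net$params[["enc.b1.att_Wq"]]$value, 2,
             as.numeric(net$params[["enc.b1.att_Wq_b"]]$value), "+")
  K <- sweep(X %*% net$params[["enc.b1.att_Wk"]]$value, 2,
             as.numeric(net$params[["enc.b1.att_Wk_b"]]$value), "+")
  V <- sweep(X %*% net$params[["enc.b1.att_Wv"]]$value, 2,
             as.numeric(net$params[["enc.b1.att_Wv_b"]]$value), "+")
  Kp <- squigglecall:::sinusoid_encoding(8:-8, 16) %*%
    net$params[["enc.b1.att_Wp"]]$value
  r <- squigglecall:::cpp_mhsa_fwd(
    Q, K, V, Kp,
    as.numeric(net$params[["enc.b1.att_bias_content"]]$value),
    as.numeric(net$params[["enc.b1.att_bias_pos"]]$value),
    matrix(0, 0, 0), 2L, 1L)
  for (h in 1:2) {
    expect_equal(rowSums(r$P[, ((h - 1) * 9 + 1):(h * 9)]), rep(1, 9),
                 tolerance = 1e-5)
  }
  # zeroing the position pathway and both biases leaves standard
  # scaled dot-product attention
  net$params[["enc.b1.att_Wp"]]$value[] <- 0
  net$params[["enc.b1.att_bias_content"]]$value[] <- 0
  net$params[["enc.b1.att_bias_pos"]]$value[] <- 0
  expect_equal(relative_mhsa(net, X), plain_mhsa_oracle(X, net),
               tolerance = 1e-10)
  # T = 1: the single-key softmax is 1, so the output is W_O applied to V
  x1 <- matrix(rnorm(16), 1)
  v1 <- sweep(x1 %*% net$params[["enc.b1.att_Wv"]]$value, 2,
              as.numeric(net$params[["enc.b1.att_Wv_b"]]$value), "+")
  o1 <- sweep(v1 %*% net$params[["enc.b1.att_Wo"]]$value, 2,
              as.numeric(net$params[["enc.b1.att_Wo_b"]]$value), "+")
  expect_equal(relative_mhsa(net, x1), o1, tolerance = 1e-10)
})

test_that("with the position projection zeroed, the relative-shift toggle is inert", {
  cfg <- tiny_model_config()
  net <- init_network(cfg, seed = 11, include_decoders = FALSE)
  for (j in 1:2) {
    net$params[[sprintf("enc.b%d.att_Wp", j)]]$value[] <- 0
    net$params[[sprintf("enc.b%d.att_bias_pos", j)]]$value[] <- 0
  }
  sig <- rnorm(200)
  a <- encoder_forward(net, sig)
  net$config$use_relative_shift <- FALSE
  b <- encoder_forward(net, sig)
  expect_equal(a$frames, b$frames, tolerance = 1e-12)
})

test_that("gated conv block preserves length and the depthwise stage isolates channels", {
  cfg <- tiny_model_config()
  net <- init_network(cfg, seed = 5, include_decoders = FALSE)
  set.seed(4)
  for (Tn in c(1L, 7L, 100L)) {
    X <- matrix(rnorm(Tn * 16), Tn, 16)
    out <- gated_conv_block(net, X)
    expect_identical(dim(out), dim(X))
  }
  # channel isolation of the depthwise convolution itself
  W <- net$params[["enc.b1.conv_dw_W"]]$value
  b <- net$params[["enc.b1.conv_dw_b"]]$value
  X <- matrix(rnorm(20 * 16), 20, 16)
  y0 <- squigglecall:::cpp_dwconv_fwd(X, W, as.numeric(b))
  Xp <- X
  Xp[, 3] <- Xp[, 3] + rnorm(20)
  y1 <- squigglecall:::cpp_dwconv_fwd(Xp, W, as.numeric(b))
  expect_identical(y0[, -3], y1[, -3])
  expect_false(isTRUE(all.equal(y0[, 3], y1[, 3])))
  # swish fixes zero exactly
  expect_identical(squigglecall:::ad_swish(
    squigglecall:::ad_const(squigglecall:::tape_new(), matrix(0, 2, 2)))$val,
    matrix(0, 2, 2))
})

test_that("encoder blocks keep shape; a zeroed block is the identity up to layer norm", {
  cfg <- tiny_model_config()
  net <- init_network(cfg, seed = 6, include_decoders = FALSE)
  set.seed(9)
  X <- matrix(rnorm(12 * 16), 12, 16)
  expect_identical(dim(conformer_block(net, X)), dim(X))
  tnet <- init_network(make_ablation(cfg, "transformer"), seed = 6,
                       include_decoders = FALSE)
  expect_identical(dim(conformer_block(tnet, X)), dim(X))
  expect_false(any(grepl("conv_", ls(tnet$params))))  # no gated conv sub-block

  # zero every weight in block 1: all residual branches vanish and the
  # block reduces to its final layer norm
  for (nm in grep("^enc\\.b1\\.", ls(net$params), value = TRUE)) {
    if (!grepl("final_ln", nm)) net$params[[nm]]$value[] <- 0
  }
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  expect_equal(conformer_block(net, X), (X - mu) / sqrt(v + 1e-5),
               tolerance = 1e-12)
})

test_that("encoder output is normalized, correctly sized, and deterministic", {
  net <- init_network(tiny_model_config(), seed = 2, include_decoders = FALSE)
  fr <- encoder_forward(net, rnorm(4096))
  expect_s3_class(fr, "frame_logprobs")
  expect_identical(nrow(fr$frames), 410L)
  expect_identical(ncol(fr$frames), 5L)
  lse <- apply(fr$frames, 1, function(r) max(r) + log(sum(exp(r - max(r)))))
  expect_lt(max(abs(lse)), 1e-5)
  sig <- rnorm(500)
  expect_identical(encoder_forward(net, sig)$frames,
                   encoder_forward(net, sig)$frames)
})

test_that("decoders are causal/anti-causal and normalized", {
  net <- init_network(tiny_model_config(), seed = 8)
  set.seed(10)
  mem <- matrix(rnorm(20 * 16), 20, 16)
  y <- "ACGUACGU"
  L <- nchar(y)
  fw <- decoder_forward(net, mem, y, "forward")
  expect_identical(dim(fw$frames), c(L + 1L, 7L))
  lse <- apply(fw$frames, 1, function(r) max(r) + log(sum(exp(r - max(r)))))
  expect_lt(max(abs(lse)), 1e-5)
  # forward causality: perturbing token j leaves rows 1..j unchanged
  for (j in 1:L) {
    yy <- strsplit(y, "")[[1]]
    yy[j] <- setdiff(c("A", "C", "G", "U"), yy[j])[1]
    fw2 <- decoder_forward(net, mem, paste(yy, collapse = ""), "forward")
    expect_equal(fw$frames[seq_len(j), , drop = FALSE],
                 fw2$frames[seq_len(j), , drop = FALSE], tolerance = 1e-12)
    if (j < L) {
      expect_false(isTRUE(all.equal(fw$frames[j + 1, ], fw2$frames[j + 1, ])))
    }
  }
  # reverse anti-causality: perturbing token j leaves the rows that only
  # depend on tokens >= j unchanged (rows 1..L-j+1 in decoding order)
  rv <- decoder_forward(net, mem, y, "reverse")
  for (j in 1:L) {
    yy <- strsplit(y, "")[[1]]
    yy[j] <- setdiff(c("A", "C", "G", "U"), yy[j])[1]
    rv2 <- decoder_forward(net, mem, paste(yy, collapse = ""), "reverse")
    keep <- seq_len(L - j + 1L)
    expect_equal(rv$frames[keep, , drop = FALSE],
                 rv2$frames[keep, , drop = FALSE], tolerance = 1e-12)
  }
  expect_error(decoder_forward(net, mem, "", "forward"), "nonempty")
})

test_that("parameter counting is exact, additive and monotone", {
  cfg <- tiny_model_config()
  sh <- squigglecall:::param_shapes(cfg, include_decoders = TRUE)
  expect_identical(count_parameters(cfg, include_decoders = TRUE),
                   sum(vapply(sh, prod, 0)))
  net <- init_network(cfg, seed = 1)
  inst <- sum(vapply(ls(net$params),
                     function(nm) length(net$params[[nm]]$value), 0))
  expect_identical(inst, count_parameters(cfg, include_decoders = TRUE))
  big <- model_config(d_model = 16L, n_heads = 2L, n_blocks = 4L,
                      ff_expansion = 2L, conv_kernel = 5L, dropout = 0)
  expect_gt(count_parameters(big), count_parameters(cfg))
  expect_gt(count_parameters(cfg, TRUE), count_parameters(cfg, FALSE))
})
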