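test_that("plateau scheduler halves the rate after patience+1 flat evaluations", {
  s <- squigglecall:::plateau_scheduler(0.002, factor = 0.5, patience = 1L,
                                        threshold = 0.1)
  expect_equal(squigglecall:::scheduler_step(s, 1.0), 0.002)   # first value
  expect_equal(squigglecall:::scheduler_step(s, 0.99), 0.002)  # 1st flat
  expect_equal(squigglecall:::scheduler_step(s, 0.98), 0.001)  # 2nd flat: halve
  # a >10% relative improvement resets the counter
  expect_equal(squigglecall:::scheduler_step(s, 0.5), 0.001)
  expect_equal(squigglecall:::scheduler_step(s, 0.49), 0.001)
  expect_equal(squigglecall:::scheduler_step(s, 0.48), 0.0005)
  # absolute threshold mode
  sa <- squigglecall:::plateau_scheduler(1, factor = 0.5, patience = 0L,
                                         threshold = 0.1,
                                         threshold_mode = "abs")
  squigglecall:::scheduler_step(sa, 2.0)
  expect_equal(squigglecall:::scheduler_step(sa, 1.95), 0.5)
})

test_that("optimizers update parameters and clipping bounds the global norm", {
  cfg <- tiny_model_config()
  for (optname in c("ranger", "adamw")) {
    net <- init_network(cfg, seed = 4, include_decoders = FALSE)
    before <- net$params[["enc.head"]]$value
    opt <- squigglecall:::optimizer_new(optname, lr = 1e-2)
    for (nm in ls(net$params)) {
      net$params[[nm]]$grad <- net$params[[nm]]$value * 0 + 1
    }
    squigglecall:::optimizer_step(opt, net)
    expect_false(isTRUE(all.equal(before, net$params[["enc.head"]]$value)))
  }
  net <- init_network(cfg, seed = 4, include_decoders = FALSE)
  for (nm in ls(net$params)) net$params[[nm]]$grad <- net$params[[nm]]$value * 0 + 10
  squigglecall:::clip_gradients(net, 5)
  total <- sum(vapply(ls(net$params),
                      function(nm) sum(net$params[[nm]]$grad^2), 0))
  expect_equal(sqrt(total), 5, tolerance = 1e-9)
})

test_that("short training runs reduce the joint loss substantially", {
  pm <- make_pore_model(3, seed = 31)
  cfg <- sim_config(noise_sd_scale = 0)
  h5 <- tempfile(fileext = ".h5")
  simulate_dataset(50, c(30, 60), pm, cfg, h5, seed = 32)
  mc <- model_config(d_model = 32L, n_heads = 4L, n_blocks = 2L,
                     conv_kernel = 15L, dropout = 0)
  tc <- train_config(seed = 33, epochs = 2)
  fit <- train_basecaller(h5, mc, tc, quiet = TRUE)
  st <- fit$history$steps
  first <- mean(head(st$joint, 5))
  last <- mean(tail(st$joint, 5))
  expect_lt(last, 0.5 * first)
  expect_true(all(is.finite(st$joint)))
  expect_identical(nrow(fit$history$epochs), 2L)
})

test_that("training is deterministic in the seed and logs loss components", {
  pm <- make_pore_model(2, seed = 41)
  cfg <- sim_config(noise_sd_scale = 0)
  reads <- simulate_dataset(10, c(20, 30), pm, cfg,
                            tempfile(fileext = ".h5"), seed = 42)
  mc <- tiny_model_config()
  log1 <- tempfile(fileext = ".jsonl")
  tc <- train_config(seed = 7, epochs = 1, batch_size = 4L,
                     chunk_len = 512L, chunk_stride = 512L, log_path = log1)
  f1 <- train_basecaller(reads, mc, tc, quiet = TRUE)
  tc$log_path <- NULL
  f2 <- train_basecaller(reads, mc, tc, quiet = TRUE)
  expect_equal(f1$history$steps$joint, f2$history$steps$joint)
  expect_equal(f1$history$epochs$val_loss, f2$history$epochs$val_loss)
  rows <- lapply(readLines(log1), jsonlite::fromJSON)
  expect_length(rows, nrow(f1$history$steps))
  expect_true(all(c("step", "lr", "ctc", "kl_fwd", "kl_rev", "joint") %in%
                    names(rows[[1]])))
  # joint decomposes into the logged components (lambda = 0.5)
  r <- rows[[1]]
  expect_equal(r$joint, 0.5 * r$ctc + 0.25 * (r$kl_fwd + r$kl_rev),
               tolerance = 1e-9)
  # with lambda = 1 the logged CTC trajectory at step 0 is unchanged
  mc1 <- tiny_model_config(lambda_weight = 1)
  f3 <- train_basecaller(reads, mc1, tc, quiet = TRUE)
  expect_equal(f3$history$steps$ctc[1], f1$history$steps$ctc[1],
               tolerance = 1e-9)
})

test_that("checkpoints round-trip with identical validation loss", {
  pm <- make_pore_model(2, seed = 51)
  reads <- simulate_dataset(10, c(20, 30), pm, sim_config(noise_sd_scale = 0),
                            tempfile(fileext = ".h5"), seed = 52)
  mc <- tiny_model_config()
  tc <- train_config(seed = 8, epochs = 1, batch_size = 4L,
                     chunk_len = 512L, chunk_stride = 512L)
  fit <- train_basecaller(reads, mc, tc, quiet = TRUE)
  exs <- squigglecall:::.prepare_examples(reads, tc)$examples
  # inference-only checkpoint: CTC part of the loss must match exactly
  ck <- tempfile(fileext = ".rds")
  save_basecaller(fit, ck)
  back <- load_basecaller(ck)
  expect_false(back$net$has_decoders)
  fit$net$has_decoders <- FALSE
  v1 <- squigglecall:::validation_loss(fit$net, exs)
  v2 <- squigglecall:::validation_loss(back$net, exs)
  expect_equal(v1, v2, tolerance = 1e-6)
  # a full checkpoint preserves the joint validation loss too
  fit$net$has_decoders <- TRUE
  ck2 <- tempfile(fileext = ".rds")
  save_basecaller(fit, ck2, include_decoders = TRUE)
  back2 <- load_basecaller(ck2)
  expect_equal(squigglecall:::validation_loss(fit$net, exs),
               squigglecall:::validation_loss(back2$net, exs),
               tolerance = 1e-6)
})

test_that("configs serialize to YAML and back", {
  mc <- tiny_model_config()
  f <- tempfile(fileext = ".yaml")
  config_to_yaml(mc, f)
  mc2 <- config_from_yaml(f)
  expect_equal(unclass(mc), unclass(mc2))
  tc <- train_config(seed = 5)
  f2 <- tempfile(fileext = ".yaml")
  config_to_yaml(tc, f2)
  tc2 <- config_from_yaml(f2)
  expect_equal(tc$batch_size, tc2$batch_size)
  expect_equal(tc$chunk_len, tc2$chunk_len)
})
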