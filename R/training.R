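# Training loop: joint CTC + KL objective with the paired causal decoders
# attached, Ranger optimization, plateau LR scheduling, and a JSONL step
# log. `train_basecaller()` is the package's single fitting entry point.

#' Training configuration
#'
#' The optimization recipe. The `"full"` preset is the full-scale recipe
#' (batch 140, 12 epochs, whole 4096-sample chunks), which presumes
#' GPU-class hardware; the `"desk"` preset (default) keeps the same
#' optimizer, learning rate, weight decay and scheduler but scales batch
#' size, epochs and chunk geometry to sizes a single CPU handles in
#' minutes.
#'
#' @param preset `"desk"` or `"full"`.
#' @param batch_size Examples per optimizer step.
#' @param epochs Training epochs.
#' @param learning_rate Initial learning rate.
#' @param weight_decay Decoupled L2 coefficient.
#' @param optimizer `"ranger"` (RAdam + Lookahead) or `"adamw"`.
#' @param scheduler_patience,scheduler_factor,scheduler_threshold,threshold_mode
#'   Reduce-on-plateau settings monitoring validation loss (threshold is
#'   relative by default, with an absolute mode flag).
#' @param grad_clip Global gradient-norm clip.
#' @param chunk_len,chunk_stride Chunk geometry in samples.
#' @param val_fraction Fraction of reads held out (by read-id hash) for
#'   validation.
#' @param label_smoothing Decoder label smoothing.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param log_path Optional JSONL file receiving one row per optimizer step.
#' @return Object of class `train_config`.
#' @export
train_config <- function(preset = c("desk", "full"),
                         batch_size = NULL, epochs = NULL,
                         learning_rate = 2e-3, weight_decay = 0.01,
                         optimizer = c("ranger", "adamw"),
                         scheduler_patience = 1L, scheduler_factor = 0.5,
                         scheduler_threshold = 0.1,
                         threshold_mode = c("rel", "abs"),
                         grad_clip = 5,
                         chunk_len = NULL, chunk_stride = NULL,
                         val_fraction = 0.05,
                         label_smoothing = 0.1,
                         seed = 1L, log_path = NULL) {
  preset <- match.arg(preset)
  optimizer <- match.arg(optimizer)
  threshold_mode <- match.arg(threshold_mode)
  if (preset == "full") {
    if (is.null(batch_size)) batch_size <- 140L
    if (is.null(epochs)) epochs <- 12L
    if (is.null(chunk_len)) chunk_len <- 4096L
    if (is.null(chunk_stride)) chunk_stride <- 4096L
  } else {
    if (is.null(batch_size)) batch_size <- 4L
    if (is.null(epochs)) epochs <- 3L
    if (is.null(chunk_len)) chunk_len <- 512L
    if (is.null(chunk_stride)) chunk_stride <- 512L
  }
  stopifnot(batch_size >= 1L, epochs >= 1L,
            scheduler_factor > 0, scheduler_factor < 1,
            scheduler_patience >= 0L,
            val_fraction >= 0, val_fraction < 1)
  structure(list(preset = preset, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 optimizer = optimizer,
                 scheduler_patience = as.integer(scheduler_patience),
                 scheduler_factor = scheduler_factor,
                 scheduler_threshold = scheduler_threshold,
                 threshold_mode = threshold_mode,
                 grad_clip = grad_clip,
                 chunk_len = as.integer(chunk_len),
                 chunk_stride = as.integer(chunk_stride),
                 val_fraction = val_fraction,
                 label_smoothing = label_smoothing,
                 seed = as.integer(seed), log_path = log_path),
            class = "train_config")
}

# Deterministic read-id hash in [0, 1) for the validation split.
.id_hash <- function(id) {
  v <- utf8ToInt(id)
  (sum(v * (seq_along(v) %% 7L + 1L)) %% 9973L) / 9973
}

# Joint forward pass for one example on a fresh tape.
.joint_example <- function(net, tape, ex, smoothing) {
  sig <- ex$chunk[seq_len(ex$valid_length)]
  ids <- if (nzchar(ex$target)) base_to_id(ex$target) else integer(0)
  enc <- .fwd_encoder(net, tape, sig)
  ctc <- ad_ctc(enc$logp, ids)
  lam <- net$config$lambda_weight
  if (length(ids) > 0L && isTRUE(net$has_decoders) && lam < 1) {
    df <- .fwd_decoder(net, tape, enc$memory, ids, "forward")
    dr <- .fwd_decoder(net, tape, enc$memory, ids, "reverse")
    klf <- ad_kl_rows(df$logp, smoothed_targets(df$targets_out,
                                                DEC_VOCAB_SIZE, smoothing))
    klr <- ad_kl_rows(dr$logp, smoothed_targets(dr$targets_out,
                                                DEC_VOCAB_SIZE, smoothing))
    joint <- ad_add(ad_scale(ctc, lam),
                    ad_scale(ad_add(klf, klr), (1 - lam) / 2))
    list(joint = joint, ctc = as.numeric(ctc$val),
         klf = as.numeric(klf$val), klr = as.numeric(klr$val))
  } else {
    list(joint = ad_scale(ctc, if (lam > 0) lam else 1),
         ctc = as.numeric(ctc$val), klf = NA_real_, klr = NA_real_)
  }
}

.prepare_examples <- function(reads, tc) {
  exs <- list()
  skipped <- 0L
  for (r in reads) {
    r$samples <- normalize_signal(r$samples)
    for (ex in chunk_read(r, tc$chunk_len, tc$chunk_stride)) {
      if (is.na(ex$target) || !nzchar(ex$target) || !ctc_feasible(ex)) {
        skipped <- skipped + 1L
        next
      }
      exs[[length(exs) + 1L]] <- ex
    }
  }
  list(examples = exs, skipped = skipped)
}

#' Fit the basecaller
#'
#' Trains the network on mapped reads by optimizing the joint CTC +
#' KL-divergence loss with the forward/reverse decoders attached. Reads are
#' med-MAD normalized, cut into chunks, and split into training and
#' validation sets by a deterministic read-id hash. The learning rate is
#' halved whenever validation loss fails to improve beyond the relative
#' threshold for `scheduler_patience` + 1 evaluations (one per epoch).
#' Chunks whose targets are empty or CTC-infeasible are skipped and
#' counted. A non-finite loss aborts with a diagnostic.
#'
#' @param data Path to a Taiyaki-style mapped-signal HDF5 file, or a list of
#'   mapped reads (`raw_read`/`simulated_read`).
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @param net Optionally, a pre-initialized [init_network()] to continue
#'   training.
#' @param quiet Suppress per-epoch messages.
#' @return Object of class `basecaller`: the fitted network plus configs,
#'   per-step and per-epoch training history, and bookkeeping counts.
#' @export
train_basecaller <- function(data, config = model_config(),
                             tc = train_config(), net = NULL,
                             quiet = FALSE) {
  stopifnot(inherits(config, "model_config"), inherits(tc, "train_config"))
  reads <- if (is.character(data)) read_mapped_hdf5(data) else data
  set.seed(tc$seed)
  if (is.null(net)) net <- init_network(config, seed = tc$seed)
  is_val <- vapply(reads, function(r) .id_hash(r$read_id) < tc$val_fraction,
                   FALSE)
  if (!any(is_val)) is_val[1L] <- TRUE
  if (all(is_val)) stop("validation split consumed every read")
  tr <- .prepare_examples(reads[!is_val], tc)
  va <- .prepare_examples(reads[is_val], tc)
  if (length(tr$examples) == 0L) stop("no trainable chunks after filtering")
  if (!quiet) {
    message(sprintf("training on %d chunks (%d reads), validating on %d chunks (%d reads), %d skipped",
                    length(tr$examples), sum(!is_val),
                    length(va$examples), sum(is_val),
                    tr$skipped + va$skipped))
  }
  opt <- optimizer_new(tc$optimizer, lr = tc$learning_rate,
                       weight_decay = tc$weight_decay)
  sched <- plateau_scheduler(tc$learning_rate, tc$scheduler_factor,
                             tc$scheduler_patience, tc$scheduler_threshold,
                             tc$threshold_mode)
  log_con <- if (!is.null(tc$log_path)) file(tc$log_path, open = "w")
  on.exit(if (!is.null(log_con)) close(log_con))
  steps <- list()
  epochs <- list()
  step <- 0L
  infeasible <- 0L
  for (epoch in seq_len(tc$epochs)) {
    perm <- sample(length(tr$examples))
    batches <- split(perm, ceiling(seq_along(perm) / tc$batch_size))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      zero_grads(net)
      comp <- c(ctc = 0, klf = 0, klr = 0, joint = 0)
      nb <- 0L
      for (i in idx) {
        tape <- tape_new(train = TRUE)
        out <- .joint_example(net, tape, tr$examples[[i]], tc$label_smoothing)
        jv <- as.numeric(out$joint$val)
        if (!is.finite(jv)) {
          if (!is.finite(out$ctc)) { infeasible <- infeasible + 1L; next }
          stop(sprintf("non-finite loss at epoch %d step %d (read %s)",
                       epoch, step + 1L, tr$examples[[i]]$source_read))
        }
        ad_backward(tape, out$joint, seed = matrix(1 / length(idx), 1, 1))
        comp <- comp + c(out$ctc, out$klf, out$klr, jv)
        nb <- nb + 1L
      }
      if (nb == 0L) next
      clip_gradients(net, tc$grad_clip)
      opt$lr <- sched$lr
      optimizer_step(opt, net)
      step <- step + 1L
      row <- list(step = step, epoch = epoch, lr = opt$lr,
                  ctc = comp[["ctc"]] / nb, kl_fwd = comp[["klf"]] / nb,
                  kl_rev = comp[["klr"]] / nb, joint = comp[["joint"]] / nb)
      steps[[step]] <- row
      if (!is.null(log_con)) {
        writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA),
                   log_con)
      }
    }
    vl <- validation_loss(net, va$examples, tc$label_smoothing)
    lr_now <- scheduler_step(sched, vl)
    epochs[[epoch]] <- list(epoch = epoch, val_loss = vl, lr = lr_now)
    if (!quiet) {
      message(sprintf("epoch %d: val loss %.4f, lr %.2e", epoch, vl, lr_now))
    }
  }
  structure(list(net = net, config = config, train_config = tc,
                 history = list(
                   steps = do.call(rbind.data.frame, steps),
                   epochs = do.call(rbind.data.frame, epochs)),
                 counts = list(n_train = length(tr$examples),
                               n_val = length(va$examples),
                               skipped_chunks = tr$skipped + va$skipped,
                               infeasible_in_training = infeasible),
                 call = match.call()),
            class = "basecaller")
}

# Mean joint loss over examples in inference mode (no dropout, running BN).
validation_loss <- function(net, examples, smoothing = 0.1) {
  if (length(examples) == 0L) return(NA_real_)
  tot <- 0
  n <- 0L
  for (ex in examples) {
    tape <- tape_new(train = FALSE)
    out <- .joint_example(net, tape, ex, smoothing)
    jv <- as.numeric(out$joint$val)
    if (is.finite(jv)) { tot <- tot + jv; n <- n + 1L }
  }
  if (n == 0L) NA_real_ else tot / n
}

#' Save / load a fitted basecaller
#'
#' The checkpoint is a single-file archive of configuration plus weights
#' (and batch-norm running statistics). By default the training-only
#' decoders are stripped: they are not used at inference.
#'
#' @param model A `basecaller`.
#' @param path Destination file.
#' @param include_decoders Keep the decoder weights in the checkpoint.
#' @return `save_basecaller` returns `path` invisibly; `load_basecaller`
#'   returns the restored `basecaller`.
#' @export
save_basecaller <- function(model, path, include_decoders = FALSE) {
  stopifnot(inherits(model, "basecaller"))
  nms <- ls(model$net$params)
  if (!include_decoders) nms <- nms[!startsWith(nms, "dec.")]
  weights <- lapply(stats::setNames(nms, nms),
                    function(nm) model$net$params[[nm]]$value)
  bn <- lapply(model$net$bn, function(e) {
    list(running_mean = e$running_mean, running_var = e$running_var)
  })
  obj <- list(config = model$config, train_config = model$train_config,
              weights = weights, bn = bn,
              has_decoders = include_decoders,
              history = model$history, counts = model$counts)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_basecaller
#' @export
load_basecaller <- function(path) {
  obj <- readRDS(path)
  net <- init_network(obj$config, seed = 1L,
                      include_decoders = obj$has_decoders)
  for (nm in names(obj$weights)) net$params[[nm]]$value <- obj$weights[[nm]]
  for (k in names(obj$bn)) {
    net$bn[[k]]$running_mean <- obj$bn[[k]]$running_mean
    net$bn[[k]]$running_var <- obj$bn[[k]]$running_var
  }
  structure(list(net = net, config = obj$config,
                 train_config = obj$train_config,
                 history = obj$history, counts = obj$counts,
                 call = NULL),
            class = "basecaller")
}

#' Write or read a model configuration as YAML
#'
#' @param config A [model_config()] (or [train_config()]).
#' @param path YAML file path.
#' @return `config_to_yaml` returns `path` invisibly; `config_from_yaml`
#'   returns the restored object.
#' @export
config_to_yaml <- function(config, path) {
  obj <- unclass(config)
  obj$.class <- class(config)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "model_config")) {
    do.call(model_config, obj[intersect(names(obj), names(formals(model_config)))])
  } else if (identical(cls, "train_config")) {
    do.call(train_config, obj[intersect(names(obj), names(formals(train_config)))])
  } else {
    stop("unrecognized config YAML: ", path)
  }
}
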