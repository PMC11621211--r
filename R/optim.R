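# Optimizers and the plateau learning-rate scheduler.
#
# Ranger (RAdam with Lookahead) is implemented in-repo: RAdam rectifies the
# adaptive term while its variance estimate warms up, and Lookahead blends
# fast weights into slow weights every k steps. A plain AdamW is available
# as a fallback.

optimizer_new <- function(name = c("ranger", "adamw"),
                          lr = 2e-3, weight_decay = 0.01,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          lookahead_k = 6L, lookahead_alpha = 0.5) {
  name <- match.arg(name)
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$lr <- lr
  e$weight_decay <- weight_decay
  e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$k <- as.integer(lookahead_k); e$alpha <- lookahead_alpha
  e$t <- 0L
  e
}

optimizer_step <- function(opt, net) {
  opt$t <- opt$t + 1L
  t <- opt$t
  b1 <- opt$beta1; b2 <- opt$beta2
  rho_inf <- 2 / (1 - b2) - 1
  rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
  rect <- if (rho_t > 4) {
    sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
         ((rho_inf - 4) * (rho_inf - 2) * rho_t))
  } else {
    NA_real_
  }
  for (nm in ls(net$params)) {
    p <- net$params[[nm]]
    g <- p$grad
    if (identical(g, 0)) next
    if (is.null(p$m)) { p$m <- p$value * 0; p$v <- p$value * 0 }
    p$m <- b1 * p$m + (1 - b1) * g
    p$v <- b2 * p$v + (1 - b2) * g * g
    mhat <- p$m / (1 - b1^t)
    if (opt$weight_decay > 0) {
      p$value <- p$value - opt$lr * opt$weight_decay * p$value
    }
    if (opt$name == "adamw" || !is.na(rect)) {
      vhat <- sqrt(p$v / (1 - b2^t))
      r <- if (opt$name == "adamw") 1 else rect
      p$value <- p$value - opt$lr * r * mhat / (vhat + opt$eps)
    } else {
      # RAdam warmup: un-rectified SGD-with-momentum step
      p$value <- p$value - opt$lr * mhat
    }
    if (opt$name == "ranger") {
      if (is.null(p$slow)) p$slow <- p$value
      if (t %% opt$k == 0L) {
        p$slow <- p$slow + opt$alpha * (p$value - p$slow)
        p$value <- p$slow
      }
    }
  }
  invisible(opt)
}

# Global-norm gradient clipping across every parameter.
clip_gradients <- function(net, max_norm = 5) {
  total <- 0
  for (nm in ls(net$params)) {
    g <- net$params[[nm]]$grad
    if (!identical(g, 0)) total <- total + sum(g * g)
  }
  nrm <- sqrt(total)
  if (is.finite(nrm) && nrm > max_norm) {
    sc <- max_norm / nrm
    for (nm in ls(net$params)) {
      p <- net$params[[nm]]
      if (!identical(p$grad, 0)) p$grad <- p$grad * sc
    }
  }
  nrm
}

# Reduce-on-plateau: the learning rate is multiplied by `factor` when the
# monitored validation loss fails to improve beyond `threshold` for
# `patience` + 1 consecutive evaluations.
plateau_scheduler <- function(lr, factor = 0.5, patience = 1L,
                              threshold = 0.1,
                              threshold_mode = c("rel", "abs")) {
  stopifnot(factor > 0, factor < 1, patience >= 0)
  threshold_mode <- match.arg(threshold_mode)
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$factor <- factor; e$patience <- as.integer(patience)
  e$threshold <- threshold; e$mode <- threshold_mode
  e$best <- Inf; e$wait <- 0L
  e
}

scheduler_step <- function(sched, val_loss) {
  improved <- if (sched$mode == "rel") {
    val_loss < sched$best * (1 - sched$threshold)
  } else {
    val_loss < sched$best - sched$threshold
  }
  if (!is.finite(sched$best)) improved <- is.finite(val_loss)
  if (improved) {
    sched$best <- val_loss
    sched$wait <- 0L
  } else {
    sched$wait <- sched$wait + 1L
    if (sched$wait > sched$patience) {
      sched$lr <- sched$lr * sched$factor
      sched$wait <- 0L
    }
  }
  sched$lr
}
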