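# Independent oracles and small fixtures shared across the test files.
# Every oracle here is implemented from the definition, separately from the
# package's computational path it checks.

# Total probability of a target under CTC by brute-force enumeration of all
# V^T frame paths, collapsing repeats and dropping blanks (column 1).
enum_ctc_loss <- function(lp, target) {
  Tn <- nrow(lp)
  V <- ncol(lp)
  paths <- do.call(expand.grid, rep(list(seq_len(V)), Tn))
  tot <- -Inf
  for (i in seq_len(nrow(paths))) {
    p <- as.integer(paths[i, ])
    col <- p[c(TRUE, diff(p) != 0)]
    col <- col[col != 1L]
    if (length(col) == length(target) && all(col == target)) {
      lpp <- sum(lp[cbind(seq_len(Tn), p)])
      m <- max(tot, lpp)
      tot <- m + log(exp(tot - m) + exp(lpp - m))
    }
  }
  -tot
}

# Posterior over collapsed label sequences by the same enumeration; returns
# the lexicographically-first argmax sequence (as a base string).
enum_ctc_best_labeling <- function(lp) {
  Tn <- nrow(lp)
  V <- ncol(lp)
  paths <- do.call(expand.grid, rep(list(seq_len(V)), Tn))
  post <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(paths))) {
    p <- as.integer(paths[i, ])
    col <- p[c(TRUE, diff(p) != 0)]
    col <- col[col != 1L]
    # "#" sentinel keeps the empty labeling a valid environment name
    key <- paste(c("#", c("-", "A", "C", "G", "U")[col]), collapse = "")
    lpp <- sum(lp[cbind(seq_len(Tn), p)])
    cur <- post[[key]]
    post[[key]] <- if (is.null(cur)) lpp else {
      m <- max(cur, lpp); m + log(exp(cur - m) + exp(lpp - m))
    }
  }
  keys <- sort(ls(post))
  vals <- vapply(keys, function(k) post[[k]], 0)
  substring(keys[vals == max(vals)][1], 2L)
}

# Explicit-gather oracle for the relative shift: out[i, j] is the score of
# query i at offset i - j, read directly from the per-offset columns
# (column c holds offset T - c, 1-based).
gather_shift_oracle <- function(x) {
  Tn <- nrow(x)
  out <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn)) {
    for (j in seq_len(Tn)) out[i, j] <- x[i, Tn - (i - j)]
  }
  out
}

# Plain multi-head scaled dot-product attention, written directly from the
# definition (no position terms, no biases on Q).
plain_mhsa_oracle <- function(X, net, block = 1L) {
  p <- function(nm) net$params[[sprintf("enc.b%d.att_%s", block, nm)]]$value
  d <- ncol(X)
  H <- net$config$n_heads
  dk <- d %/% H
  lin <- function(M, W, b) sweep(M %*% W, 2L, as.numeric(b), "+")
  Q <- lin(X, p("Wq"), p("Wq_b"))
  K <- lin(X, p("Wk"), p("Wk_b"))
  V <- lin(X, p("Wv"), p("Wv_b"))
  ctx <- matrix(0, nrow(X), d)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    P <- exp(S - apply(S, 1L, max))
    P <- P / rowSums(P)
    ctx[, idx] <- P %*% V[, idx, drop = FALSE]
  }
  lin(ctx, p("Wo"), p("Wo_b"))
}

# Semi-global alignment oracle: enumerate every reference substring and run
# an independent *global* Needleman-Wunsch on it, maximizing the same
# lexicographic objective (score, matches, mismatches, deletions); the
# semi-global optimum with free reference end gaps is the best over
# substrings (including the empty window: the all-insertion alignment).
oracle_align <- function(query, reference) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  n <- length(q)
  gt <- function(a, b) {
    for (k in seq_along(a)) {
      if (a[k] > b[k]) return(TRUE)
      if (a[k] < b[k]) return(FALSE)
    }
    FALSE
  }
  nw_global <- function(rr) {
    m <- length(rr)
    # cell = c(score, matches, mismatches, deletions)
    D <- array(0, c(n + 1L, m + 1L, 4L))
    D[, 1L, 1L] <- -2 * (0:n)
    if (m > 0) D[1L, , 1L] <- -2 * (0:m)
    if (m > 0) D[1L, , 4L] <- 0:m
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        mt <- q[i] == rr[j]
        diag <- D[i, j, ] + c(if (mt) 1 else -1, mt, !mt, 0)
        del <- D[i + 1L, j, ] + c(-2, 0, 0, 1)
        ins <- D[i, j + 1L, ] + c(-2, 0, 0, 0)
        best <- diag
        if (gt(del, best)) best <- del
        if (gt(ins, best)) best <- ins
        D[i + 1L, j + 1L, ] <- best
      }
    }
    D[n + 1L, m + 1L, ]
  }
  best <- c(-Inf, 0, 0, 0)
  for (s in seq_len(length(r) + 1L)) {
    for (e in (s - 1L):length(r)) {
      rr <- if (e < s) character(0) else r[s:e]
      cand <- nw_global(rr)
      if (gt(cand, best)) best <- cand
    }
  }
  list(score = best[1], matches = as.integer(best[2]),
       mismatches = as.integer(best[3]), deletions = as.integer(best[4]),
       insertions = n - as.integer(best[2]) - as.integer(best[3]))
}

# Nearest-level reconstruction of a noise-free simulated read: map each
# dwell's level back to its k-mer and take the central base.
reconstruct_noise_free <- function(read, model) {
  lv <- model$level_mean
  k <- model$k
  cpos <- (k - 1L) %/% 2L + 1L
  ends <- c(read$boundaries[-1L], length(read$samples))
  bases <- vapply(seq_along(read$boundaries), function(i) {
    x <- read$samples[(read$boundaries[i] + 1L):ends[i]][1L]
    km <- names(lv)[which.min(abs(lv - x))]
    substr(km, cpos, cpos)
  }, "")
  paste(bases, collapse = "")
}

# Shared tiny fixtures.
tiny_model_config <- function(...) {
  args <- list(d_model = 16L, n_heads = 2L, n_blocks = 2L,
               ff_expansion = 2L, conv_kernel = 5L, dropout = 0,
               n_decoder_layers = 2L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(model_config, args)
}

random_rna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Random valid row-log-probability matrix.
random_logprobs <- function(Tn, V) {
  x <- matrix(stats::rnorm(Tn * V), Tn)
  x - log(rowSums(exp(x)))
}
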