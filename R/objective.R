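# Joint training objective: CTC loss on the encoder frames plus
# KL-divergence losses on the teacher-forced forward/reverse decoder
# outputs, mixed by lambda.

# CTC forward(-backward) recursion in log space (C++ kernel).
# lp: T x V matrix of per-frame log-probabilities, column 1 = blank.
# target: integer vector of label columns (each in 2..V); may be empty.
# Returns loss = -log P(target | lp) and, optionally, the gradient of the
# loss with respect to lp.
ctc_forward_backward <- function(lp, target, want_grad = FALSE) {
  target <- as.integer(target)
  if (length(target) && (any(target < 2L) || any(target > ncol(lp)))) {
    stop("CTC target labels must lie in 2..ncol(lp)")
  }
  r <- cpp_ctc(lp, target, isTRUE(want_grad))
  list(loss = r$loss, grad = if (want_grad) r$grad, feasible = r$feasible)
}

#' CTC loss
#'
#' Negative log of the total probability of all frame-level paths that
#' collapse (merge adjacent repeats, drop blanks) to the target sequence,
#' computed by the standard forward recursion in log space. Targets longer
#' than the frame count (counting the mandatory blank between repeated
#' labels) are infeasible and score `Inf`.
#'
#' @param frames A `frame_logprobs` object or a T x V matrix of per-frame
#'   log-probabilities with column 1 the blank symbol.
#' @param target Target base string over A, C, G, U (may be empty), or an
#'   integer vector of label columns in 2..V.
#' @return The loss (nonnegative scalar, possibly `Inf`), with attribute
#'   `feasible`.
#' @export
ctc_loss <- function(frames, target) {
  lp <- if (inherits(frames, "frame_logprobs")) {
    frames$frames[seq_len(frames$valid_length), , drop = FALSE]
  } else {
    frames
  }
  stopifnot(is.matrix(lp))
  ids <- if (is.character(target)) {
    if (nzchar(target)) base_to_id(target) else integer(0)
  } else {
    as.integer(target)
  }
  if (length(ids) && (any(ids < 2L) | any(ids > ncol(lp)))) {
    stop("target labels out of range for the frame matrix")
  }
  res <- ctc_forward_backward(lp, ids)
  structure(res$loss, feasible = res$feasible)
}

# Label-smoothed one-hot target distributions over the decoder vocabulary.
smoothed_targets <- function(ids, vocab_size, smoothing) {
  q <- matrix(smoothing / (vocab_size - 1L), length(ids), vocab_size)
  q[cbind(seq_along(ids), ids)] <- 1 - smoothing
  if (smoothing == 0) {
    q[] <- 0
    q[cbind(seq_along(ids), ids)] <- 1
  }
  q
}

#' KL-divergence decoder loss
#'
#' Mean over target positions of KL(q || p), where p is the decoder's
#' predicted distribution and q the label-smoothed one-hot target. With
#' `smoothing = 0` this reduces to the cross-entropy of one-hot targets.
#'
#' @param decoded A `decoder_output` from [decoder_forward()], or a matrix of
#'   per-position log-probabilities.
#' @param target Ignored when `decoded` carries its own teacher-forced
#'   targets; otherwise an integer vector of target token ids (one per row).
#' @param smoothing Label smoothing mass in `[0, 1)`.
#' @return Nonnegative scalar.
#' @export
kldiv_loss <- function(decoded, target = NULL, smoothing = 0.1) {
  if (inherits(decoded, "decoder_output")) {
    lp <- decoded$frames
    ids <- decoded$targets_out
  } else {
    lp <- decoded
    ids <- as.integer(target)
  }
  stopifnot(is.matrix(lp))
  if (length(ids) != nrow(lp)) {
    stop("number of target tokens must match decoder output rows")
  }
  q <- smoothed_targets(ids, ncol(lp), smoothing)
  lq <- ifelse(q > 0, log(q), 0)
  sum(q * (lq - lp)) / nrow(lp)
}

#' Joint CTC + KL-divergence loss
#'
#' `joint = lambda * ctc + (1 - lambda) * (kl_forward + kl_reverse)/2`.
#' The decoder term is the unweighted mean of the forward and reverse
#' decoder losses.
#'
#' @param x_E Encoder output (`frame_logprobs` or T x 5 log-prob matrix).
#' @param x_D List with elements `forward` and `reverse`, each a
#'   `decoder_output` (either may be omitted only when `lambda = 1`).
#' @param y Target base string.
#' @param lambda Mixing weight in `[0, 1]` (the configuration default is 0.5).
#' @param smoothing Label smoothing for the decoder targets.
#' @return Object of class `loss_report`: list with `ctc`, `kl_forward`,
#'   `kl_reverse`, `joint`, `batch_size`.
#' @export
joint_loss <- function(x_E, x_D, y, lambda = 0.5, smoothing = 0.1) {
  stopifnot(lambda >= 0, lambda <= 1)
  ctc <- as.numeric(ctc_loss(x_E, y))
  klf <- if (!is.null(x_D$forward)) kldiv_loss(x_D$forward, smoothing = smoothing) else 0
  klr <- if (!is.null(x_D$reverse)) kldiv_loss(x_D$reverse, smoothing = smoothing) else 0
  dec <- (klf + klr) / 2
  structure(list(ctc = ctc, kl_forward = klf, kl_reverse = klr,
                 joint = lambda * ctc + (1 - lambda) * dec,
                 batch_size = 1L),
            class = "loss_report")
}
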