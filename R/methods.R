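# S3 methods for the fitted model and the small result classes.

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s, d_model %d, %d heads, %d blocks%s\n",
              x$block_type, x$d_model, x$n_heads, x$n_blocks,
              if (!x$use_relative_shift) " (no relative shift)" else ""))
  cat(sprintf("  frontend channels %s, kernels %s, strides %s\n",
              paste(x$frontend_channels, collapse = "/"),
              paste(x$frontend_kernels, collapse = "/"),
              paste(x$frontend_strides, collapse = "/")))
  cat(sprintf("  ff x%d, conv kernel %d, dropout %.2f, lambda %.2f, %d decoder layers\n",
              x$ff_expansion, x$conv_kernel, x$dropout, x$lambda_weight,
              x$n_decoder_layers))
  invisible(x)
}

#' @export
print.basecaller_net <- function(x, ...) {
  cat(sprintf("<basecaller_net> %s, %.2fM inference parameters%s\n",
              x$config$block_type,
              count_parameters(x$config, include_decoders = FALSE) / 1e6,
              if (isTRUE(x$has_decoders)) " (+ training decoders)" else ""))
  invisible(x)
}

#' @export
print.basecaller <- function(x, ...) {
  cat("Nanopore RNA basecaller (Conformer-CTC)\n")
  print(x$config)
  np <- count_parameters(x$config, include_decoders = FALSE)
  cat(sprintf("  %.2fM inference parameters\n", np / 1e6))
  ep <- x$history$epochs
  if (!is.null(ep) && nrow(ep) > 0) {
    cat(sprintf("  trained %d epochs; final validation loss %.4f\n",
                nrow(ep), ep$val_loss[nrow(ep)]))
  }
  invisible(x)
}

#' @export
summary.basecaller <- function(object, ...) {
  st <- object$history$steps
  ep <- object$history$epochs
  cat("Nanopore RNA basecaller — training summary\n")
  cat(sprintf("  chunks: %d train / %d val (skipped %d)\n",
              object$counts$n_train, object$counts$n_val,
              object$counts$skipped_chunks))
  if (!is.null(st) && nrow(st) > 0) {
    cat(sprintf("  steps: %d; joint loss %.4f -> %.4f (ctc %.4f -> %.4f)\n",
                nrow(st), st$joint[1], st$joint[nrow(st)],
                st$ctc[1], st$ctc[nrow(st)]))
  }
  if (!is.null(ep) && nrow(ep) > 0) {
    for (i in seq_len(nrow(ep))) {
      cat(sprintf("  epoch %d: val %.4f (lr %.2e)\n",
                  ep$epoch[i], ep$val_loss[i], ep$lr[i]))
    }
  }
  invisible(object)
}

#' Model coefficients (trainable parameter tensors)
#'
#' @param object A `basecaller`.
#' @param include_decoders Include the training-only decoder weights.
#' @param ... Unused.
#' @return Named list of parameter matrices.
#' @export
coef.basecaller <- function(object, include_decoders = FALSE, ...) {
  nms <- ls(object$net$params)
  if (!include_decoders) nms <- nms[!startsWith(nms, "dec.")]
  lapply(stats::setNames(nms, nms),
         function(nm) object$net$params[[nm]]$value)
}

#' Basecall with a fitted model
#'
#' @param object A `basecaller`.
#' @param newdata Reads (list, single read, or mapped-signal HDF5 path).
#' @param dc A [decode_config()].
#' @param ... Unused.
#' @return List of `basecall_result` objects (see [basecall()]).
#' @export
predict.basecaller <- function(object, newdata, dc = decode_config(), ...) {
  basecall(object, newdata, dc)
}

#' Training-curve plot
#'
#' Joint and CTC loss per optimizer step, with per-epoch validation loss.
#'
#' @param x A `basecaller`.
#' @param ... Passed to [plot()].
#' @export
plot.basecaller <- function(x, ...) {
  st <- x$history$steps
  if (is.null(st) || nrow(st) == 0) stop("no training history to plot")
  plot(st$step, st$joint, type = "l", xlab = "optimizer step",
       ylab = "loss", main = "training curves", ...)
  graphics::lines(st$step, st$ctc, lty = 2)
  ep <- x$history$epochs
  if (!is.null(ep) && nrow(ep) > 0) {
    last_steps <- cumsum(rep(nrow(st) / nrow(ep), nrow(ep)))
    graphics::points(last_steps, ep$val_loss, pch = 19)
  }
  graphics::legend("topright", c("joint", "ctc", "validation"),
                   lty = c(1, 2, NA), pch = c(NA, NA, 19), bty = "n")
  invisible(x)
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("joint %.4f = lambda*ctc (%.4f) + decoder KL (fwd %.4f, rev %.4f)\n",
              x$joint, x$ctc, x$kl_forward, x$kl_reverse))
  invisible(x)
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("alignment: %d match, %d mismatch, %d ins, %d del (length %d, score %g)\n",
              x$matches, x$mismatches, x$insertions, x$deletions,
              x$alignment_length, x$score))
  invisible(x)
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("identity %.2f%%  mismatch %.2f%%  insertion %.2f%%  deletion %.2f%%\n",
              x$identity_pct, x$mismatch_pct, x$insertion_pct,
              x$deletion_pct))
  invisible(x)
}

#' @export
print.evaluation <- function(x, ...) {
  cat(sprintf("evaluation of %d read(s)\n", nrow(x$per_read)))
  ov <- x$overall
  cat(sprintf("  median identity %.2f%%, mismatch %.2f%%, insertion %.2f%%, deletion %.2f%%\n",
              ov["identity"], ov["mismatch"], ov["insertion"], ov["deletion"]))
  if (!is.null(x$by_bin)) {
    cat("  by reference-length bin:\n")
    print(x$by_bin, row.names = FALSE)
  }
  if (length(x$unmatched) > 0) {
    cat(sprintf("  %d call(s) had no truth record\n", length(x$unmatched)))
  }
  invisible(x)
}

#' @export
print.basecall_result <- function(x, ...) {
  cat(sprintf(">%s (%d bases, %d chunk(s), mean frame confidence %.3f)\n%s\n",
              x$read_id, nchar(x$sequence), x$n_chunks,
              x$mean_frame_confidence,
              if (nchar(x$sequence) > 60)
                paste0(substr(x$sequence, 1, 60), "...")
              else x$sequence))
  invisible(x)
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model> k = %d (%d k-mers), levels in [%.2f, %.2f]\n",
              x$k, length(x$level_mean), min(x$level_mean),
              max(x$level_mean)))
  invisible(x)
}

#' @export
print.simulated_read <- function(x, ...) {
  cat(sprintf("<simulated_read> %s: %d samples, %d bases\n",
              x$read_id, length(x$samples), nchar(x$sequence)))
  invisible(x)
}
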