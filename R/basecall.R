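# CTC decoding and end-to-end basecalling: chunk, encode, trim overlapping
# flanks at the frame level, decode (greedy or prefix beam search), and
# emit FASTA/FASTQ.

#' Decoding configuration
#'
#' @param mode `"greedy"` (argmax-collapse) or `"beam"` (prefix beam search).
#' @param beam_width Beam width (>= 1) for `"beam"` mode.
#' @param overlap Samples shared between adjacent chunks at inference.
#' @param chunk_len Chunk length in samples.
#' @param emit_quality Attach a Phred-scaled summary quality when writing
#'   FASTQ.
#' @param reverse_output Reverse final sequences (direct RNA passes the pore
#'   3' to 5'; synthetic data defaults to sequencing order, so off).
#' @param dna_alphabet Emit T instead of U.
#' @return Object of class `decode_config`.
#' @export
decode_config <- function(mode = c("greedy", "beam"), beam_width = 8L,
                          overlap = 200L, chunk_len = 4096L,
                          emit_quality = TRUE, reverse_output = FALSE,
                          dna_alphabet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(beam_width >= 1L, overlap >= 0L, chunk_len >= 1L,
            overlap < chunk_len)
  structure(list(mode = mode, beam_width = as.integer(beam_width),
                 overlap = as.integer(overlap),
                 chunk_len = as.integer(chunk_len),
                 emit_quality = isTRUE(emit_quality),
                 reverse_output = isTRUE(reverse_output),
                 dna_alphabet = isTRUE(dna_alphabet)),
            class = "decode_config")
}

.frames_of <- function(frames) {
  if (inherits(frames, "frame_logprobs")) {
    frames$frames[seq_len(frames$valid_length), , drop = FALSE]
  } else {
    frames
  }
}

#' Greedy CTC decoding
#'
#' Takes the argmax symbol of every frame, collapses consecutive repeats,
#' and deletes blanks.
#'
#' @param frames A `frame_logprobs` or T x 5 log-probability matrix
#'   (column 1 = blank).
#' @return A base string (possibly empty).
#' @export
greedy_decode <- function(frames) {
  lp <- .frames_of(frames)
  ids <- max.col(lp, ties.method = "first")
  ids <- ids[c(TRUE, diff(ids) != 0)]
  ids <- ids[ids != 1L]
  if (length(ids) == 0L) "" else id_to_base(ids)
}

# log(exp(a) + exp(b)) guarded against -Inf
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.finite(m), m + log(exp(a - m) + exp(b - m)), -Inf)
}

#' Prefix beam search CTC decoding
#'
#' Standard CTC prefix beam search: hypotheses that collapse to the same
#' prefix are merged (tracking blank-ending and label-ending probability
#' mass separately); the `width` best prefixes by total mass are kept per
#' frame. Ties are broken lexicographically, so decoding is deterministic.
#' Width 1 need not equal greedy decoding (greedy follows per-frame
#' argmaxes, the beam follows prefix posteriors). For tiny frame counts a
#' sufficiently wide beam recovers the exact maximum-posterior label
#' sequence.
#'
#' @inheritParams greedy_decode
#' @param width Beam width (>= 1).
#' @return A base string.
#' @export
beam_decode <- function(frames, width = 8L) {
  lp <- .frames_of(frames)
  stopifnot(width >= 1L)
  Tn <- nrow(lp)
  V <- ncol(lp)
  # parallel state vectors; prefix keys carry a "#" sentinel so the empty
  # prefix is a valid name
  keys <- "#"
  pb <- 0
  pnb <- -Inf
  for (t in seq_len(Tn)) {
    cand_b <- new.env(parent = emptyenv())
    cand_nb <- new.env(parent = emptyenv())
    bump <- function(env, key, val) {
      cur <- env[[key]]
      env[[key]] <- if (is.null(cur)) val else .lse2(cur, val)
    }
    for (k in seq_along(keys)) {
      key <- keys[k]
      tot <- .lse2(pb[k], pnb[k])
      last <- substr(key, nchar(key), nchar(key))
      bump(cand_b, key, tot + lp[t, 1L])
      for (v in 2:V) {
        ch <- VOCAB[v]
        if (identical(ch, last)) {
          # repeat extends only from blank-ending mass; label-ending mass
          # collapses onto the same prefix
          bump(cand_nb, key, pnb[k] + lp[t, v])
          bump(cand_nb, paste0(key, ch), pb[k] + lp[t, v])
        } else {
          bump(cand_nb, paste0(key, ch), tot + lp[t, v])
        }
      }
    }
    allk <- sort(unique(c(ls(cand_b), ls(cand_nb))))  # lexicographic ties
    bv <- vapply(allk, function(k) {
      v <- cand_b[[k]]; if (is.null(v)) -Inf else v
    }, 0)
    nbv <- vapply(allk, function(k) {
      v <- cand_nb[[k]]; if (is.null(v)) -Inf else v
    }, 0)
    tot <- .lse2(bv, nbv)
    keep <- utils::head(order(-tot), width)
    keys <- allk[keep]
    pb <- unname(bv[keep])
    pnb <- unname(nbv[keep])
  }
  tot <- .lse2(pb, pnb)
  best <- sort(keys[tot == max(tot)])[1]
  substring(best, 2L)
}

#' Stitch overlapping chunk outputs
#'
#' Adjacent inference chunks share `overlap` samples, i.e. `overlap/10`
#' encoder frames. The overlapping flanks are trimmed at the frame level —
#' interior chunks on both sides, the first and last chunk on one — so the
#' retained frames partition the read's frames exactly, and the
#' concatenated frame matrix is decoded once. No base can be emitted twice.
#'
#' @param chunk_frames List of per-chunk outputs in signal order, each a
#'   list with `frames` (or a `frame_logprobs`) and `offset` (the chunk's
#'   first sample, 0-based; offsets must be multiples of the 10x
#'   downsampling so frames align on the global grid).
#' @param overlap Samples shared between adjacent chunks.
#' @param downsample Frontend downsampling factor.
#' @return The stitched T x V log-probability frame matrix.
#' @export
stitch_chunks <- function(chunk_frames, overlap = 200L, downsample = 10L) {
  n <- length(chunk_frames)
  stopifnot(n >= 1L)
  mats <- lapply(chunk_frames, function(cc) .frames_of(cc$frames))
  offs <- vapply(chunk_frames, function(cc) as.integer(cc$offset), 0L)
  if (n == 1L) return(mats[[1L]])
  if (is.unsorted(offs, strictly = TRUE)) {
    stop("chunks must be in signal order with strictly increasing offsets")
  }
  if (any(offs %% downsample != 0L)) {
    stop("chunk offsets must be multiples of the downsampling factor")
  }
  fstart <- offs %/% downsample
  fend <- fstart + vapply(mats, nrow, 0L)  # half-open global frame ranges
  if (any(fstart[-1L] >= fend[-n])) {
    stop("adjacent chunks do not overlap as announced")
  }
  pieces <- vector("list", n)
  lo <- fstart[1L]
  for (i in seq_len(n)) {
    hi <- if (i < n) (fstart[i + 1L] + fend[i]) %/% 2L else fend[i]
    keep <- (lo - fstart[i] + 1L):(hi - fstart[i])
    pieces[[i]] <- mats[[i]][keep, , drop = FALSE]
    lo <- hi
  }
  do.call(rbind, pieces)
}

#' Basecall raw reads
#'
#' End-to-end inference: med-MAD normalize each read, cut into overlapping
#' chunks, run the encoder, stitch the frame matrices, and CTC-decode.
#'
#' @param model A fitted `basecaller` (or a bare `basecaller_net`).
#' @param reads A list of reads (`raw_read`/`simulated_read`), a single
#'   read, or a path to a mapped-signal HDF5 file.
#' @param dc A [decode_config()].
#' @return List of `basecall_result` objects: `read_id`, `sequence`,
#'   `mean_frame_confidence`, `n_chunks`.
#' @export
basecall <- function(model, reads, dc = decode_config()) {
  net <- if (inherits(model, "basecaller")) model$net else model
  stopifnot(inherits(net, "basecaller_net"), inherits(dc, "decode_config"))
  if (is.character(reads)) reads <- read_mapped_hdf5(reads)
  if (!is.null(reads$samples)) reads <- list(reads)
  stride <- dc$chunk_len - dc$overlap
  stride <- max(10L, (stride %/% 10L) * 10L)  # keep frames on the global grid
  lapply(reads, function(r) {
    x <- normalize_signal(r$samples)
    n <- length(x)
    offs <- if (n <= dc$chunk_len) 0L else {
      o <- seq.int(0L, n - 1L, by = stride)
      # drop windows fully inside the previous one
      o[c(TRUE, (o + dc$chunk_len)[-length(o)] < n)]
    }
    chunks <- lapply(offs, function(off) {
      hi <- min(off + dc$chunk_len, n)
      list(frames = encoder_forward(net, x[(off + 1L):hi]), offset = off)
    })
    frames <- stitch_chunks(chunks, overlap = dc$overlap)
    seq <- if (dc$mode == "beam") beam_decode(frames, dc$beam_width)
           else greedy_decode(frames)
    if (dc$reverse_output) {
      seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    }
    if (dc$dna_alphabet) seq <- chartr("U", "T", seq)
    conf <- mean(exp(apply(frames, 1L, max)))
    structure(list(read_id = r$read_id, sequence = seq,
                   mean_frame_confidence = conf,
                   n_chunks = length(chunks)),
              class = "basecall_result")
  })
}

#' Write basecalls as FASTA or FASTQ
#'
#' FASTQ quality is a per-base constant derived from the read's mean frame
#' confidence, Phred-scaled and capped at 40. When `dna_alphabet` is set,
#' U is written as T.
#'
#' @param results Nonempty list of `basecall_result` objects.
#' @param path Output file.
#' @param format `"fasta"` or `"fastq"`.
#' @param dna_alphabet Emit T instead of U.
#' @return `path`, invisibly.
#' @export
write_calls <- function(results, path, format = c("fasta", "fastq"),
                        dna_alphabet = FALSE) {
  format <- match.arg(format)
  stopifnot(length(results) >= 1L)
  ids <- vapply(results, `[[`, "", "read_id")
  seqs <- vapply(results, `[[`, "", "sequence")
  if (dna_alphabet) seqs <- chartr("U", "T", seqs)
  x <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path)
  } else {
    conf <- vapply(results, `[[`, 0, "mean_frame_confidence")
    phred <- pmin(40L, pmax(0L, as.integer(round(-10 * log10(pmax(1e-9, 1 - conf))))))
    quals <- Biostrings::BStringSet(vapply(seq_along(seqs), function(i) {
      strrep(rawToChar(as.raw(phred[i] + 33L)), nchar(seqs[i]))
    }, ""))
    names(quals) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  }
  invisible(path)
}
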