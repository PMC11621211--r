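# Mapped-signal I/O, robust normalization, and chunking of reads into
# fixed-length training/inference examples. Coordinates are 0-based
# half-open throughout.

#' Read a Taiyaki-style mapped-signal HDF5 file
#'
#' Reads every read group under `/Reads` (raw signal, integer-encoded
#' reference, base-to-sample mapping), decoding bases to letters. Groups are
#' read one at a time; a malformed group is skipped with a warning naming
#' the read, and an error is raised only if the file yields no reads at all.
#'
#' @param path Path to the HDF5 file.
#' @param ids Optional character vector restricting which reads to load.
#' @return A list of `raw_read` objects: each has `read_id`, `samples`,
#'   `sequence` (over A, C, G, U; `NA` if absent) and `boundaries`
#'   (0-based first-sample index per base).
#' @export
read_mapped_hdf5 <- function(path, ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  all_ids <- h5_list_reads(path.expand(path))
  if (length(all_ids) == 0L) stop("no reads in ", path)
  if (!is.null(ids)) all_ids <- intersect(all_ids, ids)
  raw <- h5_read_reads(path.expand(path), all_ids)
  reads <- list()
  for (id in all_ids) {
    r <- raw[[id]]
    if (is.null(r)) {
      warning("skipping malformed read group: ", id, call. = FALSE)
      next
    }
    L <- length(r$reference)
    reads[[id]] <- structure(
      list(read_id = id,
           samples = r$signal,
           sequence = paste(RNA_BASES[r$reference + 1L], collapse = ""),
           boundaries = r$ref_to_signal[seq_len(L)]),
      class = "raw_read")
  }
  if (length(reads) == 0L) stop("no readable reads in ", path)
  unname(reads)
}

#' Median/MAD signal normalization
#'
#' Centers by the median and scales by the scaled median absolute deviation
#' `1.4826 * median(|x - median(x)|)`. If the scaled MAD falls below `eps`
#' (e.g. a constant signal), `eps` is used as the divisor, so a constant
#' vector maps to zeros. Applied per read, not per chunk.
#'
#' @param samples Nonempty numeric vector.
#' @param eps Lower bound on the divisor.
#' @return Numeric vector of the same length.
#' @export
normalize_signal <- function(samples, eps = 1e-8) {
  if (length(samples) == 0L) stop("cannot normalize an empty signal")
  med <- stats::median(samples)
  s <- stats::mad(samples, center = med)  # 1.4826 * median absolute deviation
  (samples - med) / max(s, eps)
}

#' Cut a read into fixed-length chunks
#'
#' Windows of `chunk_len` samples at offsets 0, stride, 2*stride, ...; the
#' final partial window is zero-padded with its valid length recorded. When
#' the read carries a base-to-sample mapping, each chunk's target is the
#' bases whose dwell lies inside the window \[offset, offset + chunk_len):
#' a base straddling the right edge is excluded.
#'
#' @param read A `raw_read` (or `simulated_read`) with `samples` and
#'   optionally `boundaries` + `sequence`.
#' @param chunk_len Window length in samples (>= 1).
#' @param stride Offset step, 1 <= stride <= chunk_len.
#' @return List of `training_example` objects: `chunk` (length `chunk_len`),
#'   `valid_length`, `target` (base string, `NA` if unmapped),
#'   `source_read`, `offset`.
#' @export
chunk_read <- function(read, chunk_len = 4096L, stride = chunk_len) {
  chunk_len <- as.integer(chunk_len)
  stride <- as.integer(stride)
  stopifnot(chunk_len >= 1L, stride >= 1L, stride <= chunk_len)
  x <- read$samples
  n <- length(x)
  offs <- seq.int(0L, n - 1L, by = stride)
  mapped <- !is.null(read$boundaries) && !is.null(read$sequence) &&
    !identical(read$sequence, NA)
  if (mapped) {
    b <- read$boundaries
    bases <- strsplit(read$sequence, "")[[1]]
    dwell_end <- c(b[-1L], n)
  }
  lapply(offs, function(off) {
    hi <- min(off + chunk_len, n)
    chunk <- numeric(chunk_len)
    chunk[seq_len(hi - off)] <- x[(off + 1L):hi]
    target <- NA_character_
    if (mapped) {
      keep <- b >= off & b < off + chunk_len & dwell_end <= off + chunk_len
      target <- paste(bases[keep], collapse = "")
    }
    structure(list(chunk = chunk,
                   valid_length = hi - off,
                   target = target,
                   source_read = read$read_id,
                   offset = off),
              class = "training_example")
  })
}

# Number of encoder output frames for a signal of length L under the
# frontend's 10x (stride-product) downsampling with same padding.
n_frames <- function(valid_length, downsample = 10L) {
  (as.integer(valid_length) - 1L) %/% downsample + 1L
}

# CTC feasibility: a chunk is trainable only if its target (plus mandatory
# blanks between repeated bases) fits in its output frames.
ctc_feasible <- function(example, downsample = 10L) {
  if (is.na(example$target)) return(FALSE)
  ids <- if (nzchar(example$target)) base_to_id(example$target) else integer(0)
  L <- length(ids)
  reps <- if (L > 1L) sum(ids[-1L] == ids[-L]) else 0L
  L + reps <= n_frames(example$valid_length, downsample)
}
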