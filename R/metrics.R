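# Alignment-based accuracy metrics: identity, mismatch, insertion and
# deletion rates from the single optimal pairwise alignment of each call
# against its reference.

# Scoring of the in-repo aligner: match +1, mismatch -1, gap -2 (linear),
# semi-global with free end gaps on the reference (the call is the query
# and must align end to end; reference overhangs are free and excluded
# from the alignment length).
ALN_MATCH <- 1
ALN_MISMATCH <- -1
ALN_GAP <- -2

# Alignments are ranked lexicographically: maximize score, then matches,
# then mismatches, then deletions. This yields one deterministic optimum
# (the stated preference match > mismatch > deletion > insertion) and lets
# counts be carried through the DP, so the brute-force oracle and the DP
# agree exactly.
.tuple_gt <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(TRUE)
    if (a[k] < b[k]) return(FALSE)
  }
  FALSE
}

#' Align a basecall against its reference
#'
#' Optimal semi-global pairwise alignment (query global, free end gaps on
#' the reference) under match +1, mismatch -1, gap -2, with deterministic
#' tie-breaking (match preferred over mismatch over deletion over
#' insertion). Counts are extracted from the optimal alignment; reference
#' overhangs outside the aligned span are free and uncounted. Insertions
#' are bases in the query absent from the reference; deletions are
#' reference bases absent from the query.
#'
#' @param query Basecalled sequence (nonempty).
#' @param reference Reference sequence (nonempty). U and T are equivalent.
#' @return Object of class `alignment_summary`: `matches`, `mismatches`,
#'   `insertions`, `deletions`, `alignment_length`, `score`.
#' @export
align_read <- function(query, reference) {
  if (!nzchar(query) || !nzchar(reference)) {
    stop("query and reference must be nonempty")
  }
  q <- strsplit(chartr("Tt", "Uu", toupper(query)), "")[[1]]
  r <- strsplit(chartr("Tt", "Uu", toupper(reference)), "")[[1]]
  n <- length(q); m <- length(r)
  # tuple components per cell: score, matches, mismatches, deletions
  Sc <- matrix(0, n + 1L, m + 1L)
  Ma <- matrix(0L, n + 1L, m + 1L)
  Mi <- matrix(0L, n + 1L, m + 1L)
  De <- matrix(0L, n + 1L, m + 1L)
  Sc[, 1L] <- ALN_GAP * (0:n)  # query prefix against nothing: insertions
  for (i in 1L + seq_len(n)) {
    qi <- q[i - 1L]
    for (j in 1L + seq_len(m)) {
      is_match <- qi == r[j - 1L]
      diag <- c(Sc[i - 1L, j - 1L] + if (is_match) ALN_MATCH else ALN_MISMATCH,
                Ma[i - 1L, j - 1L] + is_match,
                Mi[i - 1L, j - 1L] + !is_match,
                De[i - 1L, j - 1L])
      del <- c(Sc[i, j - 1L] + ALN_GAP, Ma[i, j - 1L], Mi[i, j - 1L],
               De[i, j - 1L] + 1L)
      ins <- c(Sc[i - 1L, j] + ALN_GAP, Ma[i - 1L, j], Mi[i - 1L, j],
               De[i - 1L, j])
      best <- diag
      if (.tuple_gt(del, best)) best <- del
      if (.tuple_gt(ins, best)) best <- ins
      Sc[i, j] <- best[1]; Ma[i, j] <- best[2]
      Mi[i, j] <- best[3]; De[i, j] <- best[4]
    }
  }
  # free trailing reference overhang: best endpoint on the last row,
  # smallest column on full ties
  jbest <- 1L
  best <- c(Sc[n + 1L, 1L], Ma[n + 1L, 1L], Mi[n + 1L, 1L], De[n + 1L, 1L])
  for (j in 1L + seq_len(m)) {
    cand <- c(Sc[n + 1L, j], Ma[n + 1L, j], Mi[n + 1L, j], De[n + 1L, j])
    if (.tuple_gt(cand, best)) { best <- cand; jbest <- j }
  }
  matches <- as.integer(best[2])
  mismatches <- as.integer(best[3])
  deletions <- as.integer(best[4])
  insertions <- n - matches - mismatches
  structure(list(matches = matches, mismatches = mismatches,
                 insertions = insertions, deletions = deletions,
                 alignment_length = matches + mismatches + insertions + deletions,
                 score = best[1]),
            class = "alignment_summary")
}

#' Alignment-derived error rates
#'
#' Each rate is its count divided by the alignment length, times 100:
#' identity = matched bases / alignment length, and likewise for
#' mismatches, insertions and deletions. The four rates sum to 100.
#'
#' @param summary An `alignment_summary` from [align_read()].
#' @return Object of class `rate_report`: `identity_pct`, `mismatch_pct`,
#'   `insertion_pct`, `deletion_pct`.
#' @export
compute_rates <- function(summary) {
  al <- summary$alignment_length
  if (is.null(al) || al < 1) stop("alignment length must be at least 1")
  counts <- c(summary$matches, summary$mismatches, summary$insertions,
              summary$deletions)
  if (sum(counts) != al) stop("alignment summary counts do not add up")
  r <- 100 * counts / al
  structure(list(identity_pct = r[1], mismatch_pct = r[2],
                 insertion_pct = r[3], deletion_pct = r[4]),
            class = "rate_report")
}

.read_seqs <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  x <- Biostrings::readBStringSet(path, format = format)
  s <- as.character(x)
  names(s) <- sub("\\s.*$", "", names(x))
  s
}

#' Evaluate basecalls against reference sequences
#'
#' Aligns every call to the truth record with the same id and reports
#' per-read identity/mismatch/insertion/deletion rates, their overall
#' medians, and medians stratified by reference length. Calls without a
#' truth record are reported and excluded with a warning.
#'
#' @param calls Path to a FASTA/FASTQ of basecalls (format inferred from
#'   the extension).
#' @param truth Path to a FASTA of reference sequences.
#' @param bins Optional numeric vector of reference-length bin edges.
#' @return Object of class `evaluation`: `per_read` data frame, `overall`
#'   named medians, `by_bin` data frame (or `NULL`), `unmatched` ids.
#' @export
evaluate_dataset <- function(calls, truth, bins = NULL) {
  cs <- .read_seqs(calls)
  ts <- .read_seqs(truth)
  unmatched <- setdiff(names(cs), names(ts))
  if (length(unmatched) > 0L) {
    warning(length(unmatched), " call(s) without a truth record excluded: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ...", call. = FALSE)
  }
  keep <- intersect(names(cs), names(ts))
  if (length(keep) == 0L) stop("no call ids match the truth records")
  rows <- lapply(keep, function(id) {
    rt <- compute_rates(align_read(cs[[id]], ts[[id]]))
    data.frame(read_id = id, length = nchar(ts[[id]]),
               identity = rt$identity_pct, mismatch = rt$mismatch_pct,
               insertion = rt$insertion_pct, deletion = rt$deletion_pct)
  })
  per_read <- do.call(rbind, rows)
  med <- function(df) c(identity = stats::median(df$identity),
                        mismatch = stats::median(df$mismatch),
                        insertion = stats::median(df$insertion),
                        deletion = stats::median(df$deletion))
  by_bin <- NULL
  if (!is.null(bins)) {
    per_read$bin <- cut(per_read$length, breaks = bins, include.lowest = TRUE)
    by_bin <- do.call(rbind, lapply(split(per_read, per_read$bin), function(df) {
      if (nrow(df) == 0L) return(NULL)
      cbind(data.frame(bin = df$bin[1], n = nrow(df)),
            as.data.frame(as.list(med(df))))
    }))
    rownames(by_bin) <- NULL
  }
  structure(list(per_read = per_read, overall = med(per_read),
                 by_bin = by_bin, unmatched = unmatched),
            class = "evaluation")
}
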