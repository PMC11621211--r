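# Build a frame matrix whose argmax path follows `ids` (1 = blank).
frames_from_path <- function(ids, V = 5L, peak = 4) {
  lp <- matrix(-peak, length(ids), V)
  lp[cbind(seq_along(ids), ids)] <- 0
  lp - log(rowSums(exp(lp)))
}

test_that("greedy decoding collapses repeats and drops blanks", {
  expect_identical(greedy_decode(frames_from_path(c(1L, 2L, 2L, 1L, 3L))), "AC")
  expect_identical(greedy_decode(frames_from_path(rep(1L, 6))), "")
  expect_identical(greedy_decode(frames_from_path(c(2L, 1L, 2L))), "AA")
  set.seed(1)
  for (i in 1:20) {
    Tn <- sample(1:12, 1)
    out <- greedy_decode(random_logprobs(Tn, 5))
    expect_lte(nchar(out), Tn)
  }
})

test_that("beam search agrees with the exhaustive posterior argmax on tiny inputs", {
  set.seed(7)
  for (i in 1:12) {
    Tn <- sample(2:3, 1)
    lp <- random_logprobs(Tn, 5)
    expect_identical(beam_decode(lp, width = 125L), enum_ctc_best_labeling(lp))
  }
  # saturation: once every prefix is retained, widening changes nothing
  for (i in 1:5) {
    lp <- random_logprobs(4, 5)
    expect_identical(beam_decode(lp, width = 2000L),
                     beam_decode(lp, width = 100000L))
  }
  lp <- random_logprobs(5, 5)
  expect_identical(beam_decode(lp, 8L), beam_decode(lp, 8L))
})

test_that("stitching trims overlapping flanks into an exact frame partition", {
  pm <- make_pore_model(3, seed = 61)
  cfg <- sim_config(noise_sd_scale = 0)
  r <- simulate_read(random_rna(120, seed = 62), pm, cfg, seed = 63)
  n <- length(r$samples)
  # ideal frames: one emitting frame per base, blanks elsewhere, so
  # collapsing recovers the sequence exactly whatever the cut points
  nfr <- (n - 1L) %/% 10L + 1L
  ids <- rep(1L, nfr)
  L <- nchar(r$sequence)
  ids[3L * (seq_len(L) - 1L) + 1L] <- squigglecall:::base_to_id(r$sequence)
  full <- frames_from_path(ids)
  expect_identical(greedy_decode(full), r$sequence)

  chunk_len <- 2000L
  overlap <- 200L
  offs <- seq(0L, n - 1L, by = chunk_len - overlap)
  offs <- offs[c(TRUE, (offs + chunk_len)[-length(offs)] < n)]
  chunks <- lapply(offs, function(off) {
    hi <- min((off + chunk_len - 1L) %/% 10L, nfr - 1L)
    list(frames = full[(off %/% 10L + 1L):(hi + 1L), , drop = FALSE],
         offset = off)
  })
  expect_gt(length(chunks), 1)
  stitched <- stitch_chunks(chunks, overlap = overlap)
  expect_identical(dim(stitched), dim(full))
  expect_identical(greedy_decode(stitched), r$sequence)
  # single chunk passes through; zero overlap concatenates
  expect_identical(stitch_chunks(chunks[1], overlap = 0L), chunks[[1]]$frames)
  halves <- list(list(frames = full[1:100, ], offset = 0L),
                 list(frames = full[101:nfr, ], offset = 1000L))
  expect_error(stitch_chunks(halves, overlap = 0L), "overlap")
  bad <- list(chunks[[2]], chunks[[1]])
  expect_error(stitch_chunks(bad, overlap = overlap), "order")
})

test_that("basecall runs end to end over single and multiple chunks", {
  net <- init_network(tiny_model_config(), seed = 71, include_decoders = FALSE)
  pm <- make_pore_model(3, seed = 72)
  r <- simulate_read(random_rna(150, seed = 73), pm,
                     sim_config(noise_sd_scale = 0), seed = 74)
  res <- basecall(net, r, decode_config(chunk_len = 4096L, overlap = 200L))
  expect_length(res, 1)
  expect_identical(res[[1]]$n_chunks, 2L)
  expect_true(grepl("^[ACGU]*$", res[[1]]$sequence))
  expect_gt(res[[1]]$mean_frame_confidence, 0)
  expect_lte(res[[1]]$mean_frame_confidence, 1)
  # decoding options propagate
  res2 <- basecall(net, r, decode_config(mode = "beam", beam_width = 4L,
                                         chunk_len = 8192L,
                                         dna_alphabet = TRUE))
  expect_identical(res2[[1]]$n_chunks, 1L)
  expect_true(grepl("^[ACGT]*$", res2[[1]]$sequence))
  rev <- basecall(net, r, decode_config(chunk_len = 8192L,
                                        reverse_output = TRUE))
  fwd <- basecall(net, r, decode_config(chunk_len = 8192L))
  expect_identical(rev[[1]]$sequence,
                   paste(rev(strsplit(fwd[[1]]$sequence, "")[[1]]),
                         collapse = ""))
})

test_that("write_calls emits valid FASTA and FASTQ", {
  res <- list(
    structure(list(read_id = "r1", sequence = "ACGUACGU",
                   mean_frame_confidence = 0.99, n_chunks = 1L),
              class = "basecall_result"),
    structure(list(read_id = "r2", sequence = "GGCC",
                   mean_frame_confidence = 0.5, n_chunks = 1L),
              class = "basecall_result"),
    structure(list(read_id = "r3", sequence = "UUUU",
                   mean_frame_confidence = 0.9, n_chunks = 2L),
              class = "basecall_result"))
  fa <- tempfile(fileext = ".fasta")
  write_calls(res, fa, "fasta")
  x <- Biostrings::readBStringSet(fa)
  expect_length(x, 3)
  expect_identical(names(x), c("r1", "r2", "r3"))
  expect_identical(as.character(x[["r3"]]), "UUUU")
  fq <- tempfile(fileext = ".fastq")
  write_calls(res, fq, "fastq")
  y <- Biostrings::readBStringSet(fq, format = "fastq")
  expect_identical(unname(as.character(y)),
                   vapply(res, `[[`, "", "sequence"))
  # U -> T substitution flag
  fa2 <- tempfile(fileext = ".fasta")
  write_calls(res, fa2, "fasta", dna_alphabet = TRUE)
  x2 <- Biostrings::readBStringSet(fa2)
  expect_identical(as.character(x2[["r3"]]), "TTTT")
  expect_error(write_calls(list(), fa, "fasta"))
})
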