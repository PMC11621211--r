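make_mapped_file <- function(n = 5, noise = 0, seed = 13) {
  pm <- make_pore_model(3, seed = 1)
  cfg <- sim_config(noise_sd_scale = noise)
  h5 <- tempfile(fileext = ".h5")
  reads <- simulate_dataset(n, c(30, 60), pm, cfg, h5, seed = seed)
  list(path = h5, reads = reads, model = pm)
}

test_that("mapped-signal HDF5 round-trips exactly", {
  fx <- make_mapped_file(5)
  back <- read_mapped_hdf5(fx$path)
  expect_length(back, 5)
  for (i in seq_along(back)) {
    orig <- fx$reads[[i]]
    expect_identical(back[[i]]$read_id, orig$read_id)
    expect_identical(back[[i]]$sequence, orig$sequence)
    expect_identical(back[[i]]$boundaries, orig$boundaries)
    expect_equal(back[[i]]$samples, orig$samples)
  }
})

test_that("corrupted read groups are skipped with a warning; empty files fail", {
  # nine good reads plus one whose mapping has the wrong length
  pm <- make_pore_model(2, seed = 1)
  cfg <- sim_config()
  reads <- lapply(1:9, function(i) {
    simulate_read(random_rna(20, seed = i), pm, cfg, seed = i,
                  read_id = sprintf("good_%02d", i))
  })
  h5 <- tempfile(fileext = ".h5")
  ids <- c(vapply(reads, `[[`, "", "read_id"), "bad_read")
  squigglecall:::h5_write_mapped(
    h5, ids,
    c(lapply(reads, `[[`, "samples"), list(rnorm(50))),
    c(lapply(reads, function(r) {
      match(strsplit(r$sequence, "")[[1]], c("A", "C", "G", "U")) - 1L
    }), list(c(0L, 1L, 2L))),
    c(lapply(reads, function(r) c(r$boundaries, length(r$samples))),
      list(c(0L, 10L)))  # should be length 4 for 3 reference bases
  )
  expect_warning(back <- read_mapped_hdf5(h5), "bad_read")
  expect_length(back, 9)

  h5e <- tempfile(fileext = ".h5")
  squigglecall:::h5_write_mapped(h5e, character(0), list(), list(), list())
  expect_error(read_mapped_hdf5(h5e), "no reads")
  expect_error(read_mapped_hdf5(tempfile()), "no such file")
})

test_that("normalize_signal matches the med-MAD formula and its limits", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(normalize_signal(x), (x - 3) / 1.4826, tolerance = 1e-12)
  expect_equal(normalize_signal(rep(7, 10)), rep(0, 10))
  set.seed(1)
  y <- rnorm(501, mean = 4, sd = 3)
  ny <- normalize_signal(y)
  expect_lt(abs(median(ny)), 1e-9)
  # idempotence: normalizing a normalized vector changes it negligibly
  expect_equal(normalize_signal(ny), ny, tolerance = 1e-6)
  expect_error(normalize_signal(numeric(0)), "empty")
})

test_that("chunk_read windows, pads and targets as specified", {
  # 10000 samples at chunk 4096 / stride 4096: 3 chunks, last padded
  fake <- structure(list(read_id = "r", samples = rnorm(10000),
                         sequence = NA, boundaries = NULL),
                    class = "raw_read")
  ch <- chunk_read(fake, 4096L, 4096L)
  expect_length(ch, 3)
  expect_identical(vapply(ch, `[[`, 0L, "valid_length"),
                   c(4096L, 4096L, 10000L - 8192L))
  expect_length(ch[[3]]$chunk, 4096L)
  expect_true(all(ch[[3]]$chunk[(10000 - 8192 + 1):4096] == 0))
  # concatenating unpadded samples reproduces the original prefix
  expect_identical(
    unlist(lapply(ch, function(e) e$chunk[seq_len(e$valid_length)])),
    fake$samples)

  pm <- make_pore_model(3, seed = 5)
  r <- simulate_read(random_rna(40, seed = 3), pm,
                     sim_config(noise_sd_scale = 0), seed = 4)
  # a chunk covering the whole read carries the full sequence as target
  whole <- chunk_read(r, 2L^15L)
  expect_length(whole, 1)
  expect_identical(whole[[1]]$target, r$sequence)

  # membership by dwell: every base whose dwell fits in one window is
  # assigned exactly once when stride == chunk_len
  ch2 <- chunk_read(r, 512L, 512L)
  ends <- c(r$boundaries[-1], length(r$samples))
  n_win <- vapply(seq_along(r$boundaries), function(i) {
    sum(vapply(ch2, function(e) {
      r$boundaries[i] >= e$offset && r$boundaries[i] < e$offset + 512L &&
        ends[i] <= e$offset + 512L
    }, FALSE))
  }, 0L)
  expect_true(all(n_win <= 1))
  straddler <- vapply(seq_along(r$boundaries), function(i) {
    any(r$boundaries[i] < ends[i] &
          (r$boundaries[i] %/% 512L != (ends[i] - 1L) %/% 512L))
  }, FALSE)
  expect_true(all(n_win[!straddler] == 1))
  expect_identical(paste(vapply(ch2, `[[`, "", "target"), collapse = ""),
                   paste(strsplit(r$sequence, "")[[1]][n_win == 1],
                         collapse = ""))

  # 50% overlap: the order-respecting union of targets is the full sequence
  ch3 <- chunk_read(r, 1024L, 512L)
  ends_ok <- TRUE
  merged <- character(0)
  pos <- 0L
  for (e in ch3) {
    keep <- which(r$boundaries >= e$offset &
                    r$boundaries < e$offset + 1024L &
                    ends <= e$offset + 1024L)
    new <- keep[keep > pos]
    if (length(new)) {
      if (!all(new == (pos + 1L):(pos + length(new)))) ends_ok <- FALSE
      pos <- max(new)
      merged <- c(merged, strsplit(r$sequence, "")[[1]][new])
    }
  }
  expect_true(ends_ok)
  expect_identical(paste(merged, collapse = ""), r$sequence)
})

test_that("CTC feasibility filter drops over-long targets", {
  ex <- structure(list(chunk = numeric(64), valid_length = 64L,
                       target = "ACGU", source_read = "r", offset = 0L),
                  class = "training_example")
  expect_true(squigglecall:::ctc_feasible(ex))      # 7 frames >= 4 labels
  ex$target <- strrep("A", 8)                       # 8 + 7 repeats > 7
  expect_false(squigglecall:::ctc_feasible(ex))
  ex$target <- NA_character_
  expect_false(squigglecall:::ctc_feasible(ex))
})
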