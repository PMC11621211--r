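# Synthetic direct-RNA squiggle simulator: k-mer pore model, dwell-time
# model, and Taiyaki-style mapped-signal dataset generation. Gives every
# downstream stage (training, decoding, evaluation) a ground-truthed input
# at desk scale.

RNA_BASES <- c("A", "C", "G", "U")

all_kmers <- function(k) {
  if (k == 1L) return(RNA_BASES)
  g <- do.call(expand.grid, c(rep(list(RNA_BASES), k),
                              stringsAsFactors = FALSE))
  # first base varies slowest for a stable, readable ordering
  apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic k-mer pore model
#'
#' Assigns each of the 4^k k-mers over A, C, G, U a mean current level and a
#' within-dwell noise standard deviation. The level of a k-mer is the sum of
#' a well-separated center for its central base (-1.5, -0.5, 0.5, 1.5 in
#' normalized signal units, randomly assigned to bases) and a small
#' context-dependent offset in \[-0.2, 0.2\] for the flanking bases, so the
#' central base dominates the current — as in real pores — while neighbors
#' still shift it. All 4^k levels are distinct with a minimum pairwise gap
#' of `min_gap`, so a noise-free signal determines the k-mer sequence
#' exactly. Levels are in normalized (median/MAD-scaled) units, not
#' picoamperes: no public pore table is assumed.
#'
#' @param k K-mer length, 1 to 6.
#' @param seed Integer seed; the table is deterministic in it.
#' @param min_gap Minimum pairwise gap between level means, in normalized
#'   units. Defaults to half the context-grid spacing `0.4/(4^(k-1) - 1)`
#'   (for k = 1, half the center spacing).
#' @return Object of class `pore_model`: list with `k`, `level_mean` and
#'   `level_sd` (named by k-mer).
#' @export
make_pore_model <- function(k, seed = 1L, min_gap = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 6L) {
    stop("k must be an integer between 1 and 6")
  }
  n_ctx <- 4L^(k - 1L)
  spacing <- if (k == 1L) 1 else 0.4 / max(1L, n_ctx - 1L)
  if (is.null(min_gap)) min_gap <- spacing / 2
  if (min_gap > spacing) {
    stop("min_gap cannot exceed the context grid spacing ", signif(spacing, 3))
  }
  jit <- (spacing - min_gap) / 2
  kmers <- all_kmers(k)
  center_pos <- (k - 1L) %/% 2L + 1L  # central base of each k-mer
  central <- substr(kmers, center_pos, center_pos)
  with_seed(seed, {
    centers <- stats::setNames(sample(c(-1.5, -0.5, 0.5, 1.5)), RNA_BASES)
    levels <- numeric(length(kmers))
    for (b in RNA_BASES) {
      idx <- which(central == b)
      off <- if (length(idx) == 1L) 0 else {
        sample(seq(-0.2, 0.2, length.out = length(idx))) +
          stats::runif(length(idx), -jit, jit)
      }
      levels[idx] <- centers[b] + off
    }
    sds <- stats::runif(length(kmers), 0.08, 0.12)
  })
  structure(list(k = k,
                 level_mean = stats::setNames(levels, kmers),
                 level_sd = stats::setNames(sds, kmers)),
            class = "pore_model")
}

#' Simulation configuration
#'
#' Physical parameters of the simulated pore. Defaults reflect typical
#' direct-RNA sequencing: 3012 samples/s and 70 bases/s translocation
#' (direct RNA translocates at about or below 100 bases/s), giving a mean
#' dwell of `sampling_rate / translocation_speed` samples per base.
#'
#' @param sampling_rate Signal samples per second (> 0).
#' @param translocation_speed Bases per second, in (0, 100\].
#' @param dwell_dispersion Dimensionless spread of the per-base dwell:
#'   1 gives a geometric dwell (the default), 0 a deterministic dwell;
#'   intermediate values interpolate via a shifted negative binomial.
#' @param noise_sd_scale Multiplier on the pore model's per-k-mer noise sd;
#'   0 gives noise-free piecewise-constant signal.
#' @param reverse_signal Emit the read in reversed order (direct RNA is
#'   read 3' to 5'); the stored sequence and mapping are reversed together
#'   so the base-to-sample mapping stays valid.
#' @param seed Default RNG seed used by [simulate_dataset()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 3012,
                       translocation_speed = 70,
                       dwell_dispersion = 1,
                       noise_sd_scale = 1,
                       reverse_signal = FALSE,
                       seed = 1L) {
  stopifnot(sampling_rate > 0,
            translocation_speed > 0, translocation_speed <= 100,
            dwell_dispersion >= 0, noise_sd_scale >= 0)
  structure(list(sampling_rate = sampling_rate,
                 translocation_speed = translocation_speed,
                 dwell_dispersion = dwell_dispersion,
                 noise_sd_scale = noise_sd_scale,
                 reverse_signal = isTRUE(reverse_signal),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# K-mer context of each base: the window centred on the base, with the
# terminal bases repeated so every position has a full context.
seq_kmers <- function(bases, k) {
  L <- length(bases)
  kl <- (k - 1L) %/% 2L
  kr <- k - 1L - kl
  padded <- c(rep(bases[1L], kl), bases, rep(bases[L], kr))
  if (k == 1L) return(padded)
  vapply(seq_len(L), function(i) paste(padded[i:(i + k - 1L)], collapse = ""), "")
}

draw_dwells <- function(L, cfg) {
  m <- cfg$sampling_rate / cfg$translocation_speed
  if (cfg$dwell_dispersion == 0) {
    rep(max(1L, as.integer(round(m))), L)
  } else {
    1L + stats::rnbinom(L, size = (m - 1) / cfg$dwell_dispersion, mu = m - 1)
  }
}

#' Simulate one direct-RNA read
#'
#' Draws a dwell (number of signal samples) for every base from a
#' positive-support distribution with mean
#' `sampling_rate / translocation_speed`, then emits, within each dwell, the
#' pore model's level for the base's k-mer context plus Gaussian noise
#' scaled by `noise_sd_scale`. The returned mapping gives each base's first
#' signal sample (0-based).
#'
#' @param sequence Base string over A, C, G, U (T accepted as U), length at
#'   least the pore model's k.
#' @param model A [make_pore_model()] table.
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the read is deterministic in it.
#' @param read_id Identifier stored with the read.
#' @return Object of class `simulated_read`: list with `read_id`, `samples`,
#'   `sequence`, `boundaries` (0-based, strictly increasing, one per base).
#' @export
simulate_read <- function(sequence, model, cfg = sim_config(), seed = 1L,
                          read_id = "read_1") {
  stopifnot(inherits(model, "pore_model"), inherits(cfg, "sim_config"))
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) < model$k) {
    stop("sequence must be at least as long as the pore-model k")
  }
  if (!all(bases %in% RNA_BASES)) {
    stop("sequence contains characters outside {A,C,G,U/T}")
  }
  L <- length(bases)
  with_seed(seed, {
    dwells <- draw_dwells(L, cfg)
    kmers <- seq_kmers(bases, model$k)
    levels <- model$level_mean[kmers]
    sds <- model$level_sd[kmers] * cfg$noise_sd_scale
    samples <- stats::rnorm(sum(dwells),
                            mean = rep(levels, dwells),
                            sd = rep(sds, dwells))
  })
  if (cfg$reverse_signal) {
    bases <- rev(bases)
    dwells <- rev(dwells)
    samples <- rev(samples)
    sequence <- paste(bases, collapse = "")
  }
  boundaries <- cumsum(c(0L, dwells[-L]))
  structure(list(read_id = read_id,
                 samples = as.numeric(samples),
                 sequence = sequence,
                 boundaries = as.integer(boundaries)),
            class = "simulated_read")
}

#' Simulate a mapped-signal dataset
#'
#' Draws `n_reads` uniformly random sequences with lengths in
#' `length_range`, simulates each read, and writes a Taiyaki-style
#' mapped-signal HDF5 file (`Reads/<id>` groups with the raw signal, the
#' integer-encoded reference and the base-to-sample mapping) readable by
#' [read_mapped_hdf5()]. Optionally writes the ground-truth sequences as
#' FASTA for the evaluator.
#'
#' @param n_reads Number of reads (>= 1).
#' @param length_range Integer pair (min, max) of sequence lengths; min must
#'   be at least the pore-model k.
#' @param model A [make_pore_model()] table.
#' @param cfg A [sim_config()].
#' @param out_path Output HDF5 path.
#' @param seed Integer seed; the dataset is reproducible under it (defaults
#'   to the seed in `cfg`).
#' @param truth_fasta Optional path for a FASTA of the true sequences.
#' @return Invisibly, the list of `simulated_read` objects written.
#' @export
simulate_dataset <- function(n_reads, length_range, model, cfg = sim_config(),
                             out_path, seed = cfg$seed, truth_fasta = NULL) {
  stopifnot(n_reads >= 1, length(length_range) == 2L)
  lo <- as.integer(length_range[1]); hi <- as.integer(length_range[2])
  if (lo < model$k) stop("minimum length must be at least the pore-model k")
  if (hi < lo) stop("length_range must be (min, max) with min <= max")
  dir_ok <- dir.exists(dirname(out_path))
  if (!dir_ok) stop("cannot write to ", out_path, ": directory does not exist")
  reads <- vector("list", n_reads)
  with_seed(seed, {
    lens <- sample(lo:hi, n_reads, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(RNA_BASES, L, replace = TRUE), collapse = "")
    }, "")
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_reads)
  })
  for (i in seq_len(n_reads)) {
    reads[[i]] <- simulate_read(seqs[i], model, cfg, seed = sub_seeds[i],
                                read_id = sprintf("read_%05d", i))
  }
  ids <- vapply(reads, `[[`, "", "read_id")
  h5_write_mapped(
    path.expand(out_path), ids,
    lapply(reads, `[[`, "samples"),
    lapply(reads, function(r) match(strsplit(r$sequence, "")[[1]], RNA_BASES) - 1L),
    lapply(reads, function(r) c(r$boundaries, length(r$samples)))
  )
  if (!is.null(truth_fasta)) {
    x <- Biostrings::RNAStringSet(stats::setNames(
      vapply(reads, `[[`, "", "sequence"), ids))
    Biostrings::writeXStringSet(x, truth_fasta)
  }
  invisible(reads)
}
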