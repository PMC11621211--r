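---
title: "Methods: a Conformer-CTC basecaller for nanopore direct RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Conformer-CTC basecaller for nanopore direct RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A nanopore sequencer reports the ionic current through a pore as an RNA
strand translocates it. The current at any instant depends on the several
bases occupying the pore (a k-mer), the strand moves at a non-uniform
speed of roughly 70 bases/s (direct RNA stays at or below ~100 bases/s),
and the signal-to-noise ratio is low. Basecalling — decoding the raw
current trace ("squiggle") into the base sequence — is therefore a
sequence-transduction problem with an unknown, many-to-one alignment
between signal samples and bases.

`squigglecall` implements a convolution-augmented Transformer (Conformer)
basecaller for this setting, together with everything needed to train and
evaluate it at desk scale: a squiggle simulator with ground truth, signal
normalization and chunking, CTC decoding with overlap stitching, and
alignment-based accuracy metrics.

## Architecture

The encoder maps a normalized signal chunk of length $L$ to
$T = \lfloor (L-1)/10 \rfloor + 1$ frames of log-probabilities over
$\{\varnothing, A, C, G, U\}$ ($\varnothing$ is the CTC blank):

1. **Convolutional frontend.** Three 1-D convolutions with output channels
   $(4, 6, d)$, kernels $(5, 5, 19)$ and strides $(1, 1, 10)$, each
   followed by a swish activation, with same padding throughout. The
   stride-10 layer performs the 10x downsampling.
2. **Conformer blocks** ($N$ of them). Each block is the macaron
   composition
   $x \mathrel{+}= \tfrac12\,\mathrm{FF}_1(x)$;
   $x \mathrel{+}= \mathrm{MHSA}_{rel}(x)$;
   $x \mathrel{+}= \mathrm{Conv}(x)$;
   $x \mathrel{+}= \tfrac12\,\mathrm{FF}_2(x)$;
   $x = \mathrm{LayerNorm}(x)$, with pre-layer-norm inside every
   sub-module and residual connections around each.
3. **CTC head.** A linear projection to 5 symbols and a row-wise
   log-softmax.

At the full-size defaults ($d = 512$, $h = 8$ heads, feed-forward
expansion 4, depthwise kernel 31, $N = 8$) the inference network holds
about 50 million trainable parameters; `count_parameters()` reports the
exact figure and `scripts/acceptance.R` recomputes it.

### Relative-position attention

Each head scores query $i$ against key $j$ as

$$
S_{ij} = \frac{(Q_i + b_k) K_j^\top +
  \big[\mathrm{shift}\!\big((Q + b_p) K_p^\top\big)\big]_{ij}}{\sqrt{d_k}},
$$

where $K_p = R\,W_p$ projects sinusoidal encodings $R$ of the *relative
offsets*, and $b_k$, $b_p$ are learned per-head content/position bias
vectors. The position-score matrix $(Q + b_p)K_p^\top$ has one column per
offset $T-1, \dots, 0, \dots, -(T-1)$ — $2T-1$ columns for $T$ queries —
and `relative_shift()` rearranges it by the flatten-drop-reshape-slice
trick so that entry $(i, j)$ holds the score of query $i$ at offset
$i - j$. The encoder attends bidirectionally, which is why the signed
offset range (and hence a $T \times (2T-1)$ score matrix) is required:
with only $T$ columns the classic shift trick leaves meaningless
row-crossing entries in the upper triangle, which is acceptable only
under a causal mask. The unit tests verify the shift against an explicit
offset-gather oracle exactly.

Two ablation switches reproduce reduced architectures:

* `use_relative_shift = FALSE` computes position scores against
  *absolute*-position sinusoidal encodings ($T$ columns, no shift);
  everything else, including parameter shapes, is unchanged.
* `block_type = "transformer"` replaces each Conformer block with a
  standard pre-norm Transformer encoder layer (self-attention plus one
  feed-forward, absolute sinusoidal positions added after the frontend,
  no convolution sub-block).

### Gated depthwise-separable convolution

The convolution sub-module is: layer norm, pointwise convolution
$d \to 2d$, a gated linear unit
$\mathrm{GLU}(a, b) = a \otimes \sigma(b)$ over the channel split,
a depthwise convolution (kernel 31, same padding, one filter per
channel), batch normalization, swish, and a pointwise convolution
$d \to d$. Batch-norm statistics are taken over the time axis per channel
during training and replaced by running averages at inference
(momentum 0.1).

### Training-only decoders

During training two 2-layer Transformer decoders are attached on top of
the encoder states and dropped from the saved inference checkpoint. The
forward decoder is teacher-forced left to right under a lower-triangular
causal mask; the reverse decoder consumes the reversed target under the
same mask, which is algebraically identical to an anti-lower-triangular
mask on the original order. Each decoder has its own embeddings and
cross-attention parameters (nothing is shared), a 7-symbol vocabulary
(blank, four bases, start, end), and predicts the next token at every
position. Causality is verified by perturbation tests at every position.

## Objective

The joint loss is

$$
L_{joint}(x, y) = \lambda\, L_{CTC}(x_E, y) +
  (1 - \lambda)\, L_{KL}(x_D, y), \qquad \lambda = 0.5,
$$

with $x_E$ the encoder frame log-probabilities and $x_D$ the decoder
outputs. $L_{CTC}$ is the standard forward-recursion CTC loss in log
space (verified against exhaustive path enumeration); a chunk whose
target cannot fit its frames — counting the mandatory blank between
repeated bases — is infeasible, scored $\infty$, and excluded. $L_{KL}$
is the mean over the two decoders of the per-position
$\mathrm{KL}(q \,\|\, p)$ with label-smoothed one-hot targets
($\varepsilon = 0.1$); the unweighted mean was chosen because no relative
weighting of the two directions is implied by the formulation. With
$\varepsilon = 0$ the loss reduces to cross-entropy.

## Optimization

Training uses Ranger — RAdam (rectified adaptive steps during the
variance warm-up) with Lookahead ($k = 6$, $\alpha = 0.5$) — at learning
rate 0.002 and decoupled weight decay 0.01, with global gradient-norm
clipping at 5. The learning rate is halved (factor 0.5) whenever the
validation loss fails to improve by more than a 10% *relative* threshold
for patience + 1 = 2 consecutive epoch-end evaluations; an absolute
threshold mode is available as well, since either convention is common. Validation reads are selected by a deterministic read-id
hash (5%).

Two presets are shipped. The `"full"` preset is the full-scale recipe
(batch 140, 12 epochs, whole 4096-sample chunks, dropout 0.1); it
presumes GPU-scale hardware. The `"desk"` preset — the default — keeps
the optimizer, learning rate, weight decay and scheduler but uses
512-sample chunks at stride 512, batch 4, and (for the tiny
configurations used in the examples and tests) no dropout. The rationale:
shorter chunks yield easier early CTC alignment and four times as many
optimizer steps per epoch at equal compute, which is what a few-epoch
CPU budget needs, and a sub-million-parameter model trained on unlimited
synthetic data does not benefit from dropout regularization. Dropout is
applied to sub-module outputs (attention output projection, feed-forward
hidden and output, convolution output, decoder embeddings), not to the
attention probabilities.

## The squiggle simulator

The simulator provides ground-truthed training data with the statistical
structure that matters for this architecture, at desk scale:

* **Pore model.** Each k-mer receives a mean level equal to a
  well-separated center for its *central* base
  ($\pm 0.5, \pm 1.5$ in normalized units, randomly assigned to bases per
  seed) plus a small context offset in $[-0.2, 0.2]$ determined by the
  flanking bases, with all $4^k$ levels distinct and a configurable
  minimum pairwise gap. This mirrors real pores, where the central
  base(s) dominate the current and neighbors perturb it, and it keeps a
  noise-free signal exactly decodable (nearest level → k-mer → central
  base), so the learnability experiments are well-posed. Per-k-mer noise
  standard deviations are drawn in $[0.08, 0.12]$ and scaled globally by
  `noise_sd_scale`.
* **Dwells.** Each base occupies the pore for
  $1 + \mathrm{NB}(\mathrm{size} = (m-1)/\phi,\ \mu = m-1)$ samples with
  $m = \texttt{sampling\_rate}/\texttt{translocation\_speed}$;
  $\phi = 1$ gives the geometric dwell used by default (the simplest
  positive-support model of non-uniform translocation), $\phi = 0$ a
  deterministic dwell. Defaults are 3012 samples/s and 70 bases/s,
  typical direct-RNA values, i.e. a mean dwell of ~43 samples.
* **Output.** Taiyaki-style mapped-signal HDF5 (`Reads/<id>` groups with
  the raw signal, integer-coded reference and per-base first-sample
  indices) plus optional truth FASTA. A `reverse_signal` flag emits reads
  3'→5' (as direct RNA actually passes the pore) with the stored sequence
  and mapping reversed together; synthetic data defaults to sequencing
  order.

What the simulator does *not* emulate: picoampere/DAC scaling (values are
already on a normalized scale), adapter and poly(A) segments, event
artifacts, homopolymer-specific noise, or a measured pore table. Passing
the desk-scale tests therefore demonstrates that the architecture,
losses, decoding and metrics are implemented correctly and can be learned
end to end — not that the model reaches production-grade accuracy on real
reads, which requires real training data at scale.

## Signal processing and decoding

Signals are normalized per read (not per chunk) by the median and the
scaled median absolute deviation, $1.4826 \cdot \mathrm{MAD}$, guarded by
$\varepsilon = 10^{-8}$ for constant stretches — robust to current
spikes. Chunking uses 0-based half-open windows; the final partial window
is zero-padded with its valid length recorded, and training targets are
the bases whose dwell lies inside the window (a base straddling the right
edge is excluded: its signal is split, so neither side sees all of it).

At inference, chunks overlap by `overlap` samples (default 200 over
4096-sample chunks). Each chunk's frame matrix is trimmed at the frame
level to the midpoint of every overlap — first and last chunks on one
side, interior chunks on both — so the retained frames partition the
read's frame sequence exactly; the concatenated matrix is then decoded
once. Decoding once over the stitched frames (rather than concatenating
per-chunk strings) is what prevents a base whose frames straddle a cut
from being emitted twice, and is exact on noise-free reads. Chunk offsets
are kept on the 10-sample frame grid for this reason.

Greedy decoding takes per-frame argmaxes, collapses repeats and drops
blanks. The prefix beam search merges hypotheses that collapse to the
same prefix, tracking blank-ending and label-ending mass separately, and
breaks ties lexicographically, so decoding is fully deterministic; on
tiny inputs a wide beam provably recovers the exact
maximum-posterior labeling (tested against enumeration). Width 1 is not
guaranteed to equal greedy: greedy follows frame argmaxes, the beam
follows prefix posteriors.

## Evaluation

Calls are aligned to references with an in-repo semi-global dynamic
program: match +1, mismatch −1, gap −2, query (the call) global,
reference end gaps free. Ties are resolved by a lexicographic objective —
maximize score, then matches, then mismatches, then deletions — which
both makes the aligner deterministic (the stated preference
match > mismatch > deletion > insertion) and lets the optimal counts ride
along the recursion. The four reported rates are each count divided by
the alignment length (matches + mismatches + insertions + deletions),
times 100; they sum to 100 by construction. Insertions are bases in the
call absent from the reference. One caveat inherent to free reference
end gaps: a drastically truncated call can still score high identity
because unaligned reference overhang is uncounted — identity should be
read alongside call length. `evaluate_dataset()` reports per-read rates,
overall medians, and medians stratified by reference-length bins, and
lists calls without a truth record.

## Numerical choices and degenerate inputs

* Layer/batch norm use $\varepsilon = 10^{-5}$; softmax and log-softmax
  subtract row maxima; CTC and the beam search work in log space with
  $-\infty$ guards.
* Weights are Xavier-uniform, biases and attention position/content
  biases zero, normalization gains one, embeddings $\mathcal N(0, 0.02)$.
* A single-frame input ($T = 1$) degenerates cleanly everywhere: the
  relative shift is the identity, a single-key softmax is 1, batch norm
  falls back to its $\varepsilon$ floor.
* All randomness (initialization, shuffling, dropout, simulation) is
  driven by explicit seeds; repeated runs are bitwise reproducible.
  Checkpoints store config plus weights; by default the training-only
  decoders are stripped.

## Desk-scale experiment sizes

The test suite trains real models, sized so the whole suite runs on one
CPU in tens of minutes: the learnability experiments use a k = 3 pore
model, 200 training reads and 50 held-out reads of 30–60 bases, a tiny
network (d_model 64, 4 heads, 2 blocks) and 3 epochs, under the noise-free
and `noise_sd_scale = 0.3` conditions; the architecture-ablation
comparison trains matched-seed pairs (Conformer vs Transformer blocks)
for 2 epochs on the same 200 reads and compares training loss at equal
step counts over three seed pairs. These sizes are the package's chosen
desk-scale study conditions; the full-size preset exists for real
hardware.

## Known limitations

* The implementation is CPU-oriented R with C++ kernels; it is meant for
  method study and desk-scale experiments, not production basecalling
  throughput.
* No real pore table ships with the package; transferring to real reads
  requires real mapped training data and the full-size preset.
* Quality scores in FASTQ output are per-read summaries (Phred-scaled
  mean frame confidence, capped at 40), not per-base posteriors.
* The aligner is quadratic; for genome-scale references an external
  aligner should produce the alignments and the rates can be computed
  from its counts.
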