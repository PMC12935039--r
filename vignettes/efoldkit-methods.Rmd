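---
title: "Models and methods behind efoldkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind efoldkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efoldkit)
```

# Scope

efoldkit implements the computational stack used to build a chemically
probed RNA secondary-structure database and to train a pairing-matrix
neural predictor on it: the DMS reactivity quality-control pipeline, the
structure-vs-probing concordance statistics, the modular segmentation of
long structures, the two-channel sequence/pair network with its two
ablations and constrained postprocessing, a desk-scale training harness,
and a synthetic-data generator so that every component is exercisable
without any external dataset. Wet-lab steps, read alignment and mutation
counting, BLAST redundancy removal, and GPU-scale training are outside the
package: the toolkit consumes per-base count tables and emits structure
models and metrics.

# The probing model and the QC pipeline

DMS methylates the Watson-Crick face of unpaired adenine and cytosine;
after reverse transcription and sequencing, the per-base mutation fraction
(`mutations / coverage`) is a noisy readout of unpairedness. G and U are
chemically silent, so they are masked with the sentinel value -1000, as
are bases with coverage below the read threshold and primer-covered
positions. The pipeline order is fixed:

1. **Coverage gate** — a record is dropped when its total aligned reads
   fall below `min_reads` (3000 by default) or when fewer than half of its
   bases reach that coverage. The reactivity table carries per-base
   coverage, not a read count, so total aligned reads are taken as the
   maximum per-base coverage; for amplicon probing data the two agree.
2. **Anomaly check** — any base with a mutation rate above 0.3 (in the
   untreated control when present, otherwise in the treated sample, a
   deliberately weaker check) flags the record for discard, because such
   rates usually indicate a wrong reference. Reference re-assignment is a
   manual step and out of scope; flagged records are simply dropped.
3. **Masking**, as above.
4. **Replicate gate and merge** — Pearson correlation on raw reactivities
   at jointly unmasked positions; below 0.8 the record is rejected,
   otherwise replicates are averaged (mask wherever any replicate is
   masked) and their counts summed. With more than two replicates every
   pairwise correlation must pass; the merged profile is the mean across
   all. Correlation precedes normalization to mirror the processing order
   of the original pipeline.
5. **Normalization** — unmasked reactivities are divided by their 95th
   percentile and clipped to 1. The percentile uses linear interpolation
   between order statistics (R's default type-7 estimator); the estimator
   is stated here because it is not otherwise pinned down and results
   should be bit-stable.
6. **Folding and the AUROC gate** — when a folding engine is configured,
   records are folded with the reactivity as a constraint, and any
   structure whose AUROC against the signal falls below 0.8 is excluded.

A preset mirroring public-database curation (`ribonanza_qc_config()`)
relaxes the coverage gate to 500 reads and adds a signal-to-noise gate
(mean A/C reactivity over mean G/U reactivity greater than 1).

Because both raw and normalized values are carried in the reactivity CSV,
re-running the pipeline on its own output recomputes identical results;
this no-op property is asserted in the tests.

**Binomial bootstrap.** Sampling error in the mutation fraction is modeled
as `Binomial(N, r) / N` at each unmasked base. Ten bootstrap profiles per
record, refolded with the engine, measure whether read-depth noise changes
the structure model; at 3000 reads it essentially never does, and the test
suite asserts that at least 9 of 10 default-condition records refold to
the identical structure under every bootstrap draw.

# Concordance statistics

**AUROC** treats the reactivity as a classifier score separating unpaired
(positive) from paired (negative) bases and computes the area under the
ROC curve as the Mann-Whitney statistic `U / (n1 n0)` with ties counted
one half. It is a rank statistic, hence invariant to monotone transforms —
in particular, computing it before or after percentile normalization gives
the same value, which the tests assert; the pipeline computes it on the
normalized profile. Masked bases are excluded, so after G/U masking the
statistic is driven by A/C bases only. When one class is empty the value
is undefined and the caller decides the record's fate — the aggregation
reports skipped records explicitly rather than silently dropping them.

**Base-pair F1** scores a predicted structure against a reference by exact
`(i, j)` matches: precision `tp / (tp + fp)`, sensitivity `tp / (tp + fn)`,
F1 their harmonic mean. No ±1 slip tolerance is applied — published
comparisons that allow slack will read slightly higher. Pseudoknotted
pairs count as ordinary pairs. Degenerate conventions keep F1 total: two
empty pair sets score 1, exactly one empty scores 0, and an undefined
precision or recall is treated as 0 inside the harmonic mean. Whether
reference pseudoknots should enter the metric is not settled usage; they
are included here, and the representation keeps them available so a
sensitivity analysis only needs a filter.

Test-set summaries average each metric per structure first and then across
structures (macro average). This deliberately differs from pooling counts,
which would weight long structures more; the tests pin the distinction
with a two-structure counterexample.

# Segmentation of long structures

A cut position is *closed* when no base pair spans it; fragments cut only
at closed boundaries carry a self-contained piece of the parent structure,
so the union of fragment pairs equals the parent pairs and the pre-refold
fragment-vs-parent F1 is exactly 1. All pairs block cuts, including
pseudoknotted ones. Cuts are placed greedily left to right inside a target
window of 150-300 nt, preferring the cut closest to the window midpoint for
balanced fragments; a one-step lookahead discards window candidates whose
remainder could be segmented no further (without it, a greedy midpoint cut
can strand a remainder slightly longer than the window with no interior
boundary). When the window holds no boundary at all the nearest boundary
beyond it (up to a 2000-nt hard ceiling) is used, then the last one before
it, and a stretch with no usable boundary is emitted whole with a warning.

Validation refolds each fragment with its sliced probing signal through a
folding engine and retains the fragment only when the refolded model agrees
with the signal (AUROC > 0.8) and with the parent's restricted pairs
(F1 > 0.8). A `--no-validate` mode skips this last filter, matching how
long non-coding RNA reference sets are segmented. The engine interface is a
plain function `(sequence, profile) -> structure`; adapters for external
command-line engines read FASTA plus reactivity CSV and return CT, and the
bundled reactivity-guided Nussinov engine is the test default.

# The synthetic-data generator

The generator defines the conditions the rest of the package is tested
under, and its defaults are fixed once:

* coverage 3000 reads per base — the pipeline's own threshold;
* per-base mutation-rate class means 0.006 (paired A/C) and 0.03
  (unpaired A/C), the two modes of the observed reactivity distribution;
  marginal A/C-vs-G/U means are reported in that distribution, so reading
  them as paired/unpaired class means is a modeling choice for test data
  only;
* per-base true rates drawn from a Beta distribution moment-matched to
  the class mean with a coefficient of variation of 0.3 — probing data
  show substantial per-base rate heterogeneity, and 0.3 keeps the two
  classes clearly separated while not trivially so;
* two replicates, each with an additional multiplicative log-normal
  jitter of 0.05 on the true rates, emulating library-to-library
  variability;
* sequence composition i.i.d. with GC content 0.5 and lengths uniform in
  a configurable range.

Ground-truth structures come from a maximum-weight Nussinov dynamic
program (GC = 3, AU = 2, GU = 1, hairpin loops of at least 3 nt) with an
optional reactivity pseudo-penalty `lambda` times the normalized
reactivity of each paired base; `lambda = 2` is enough to flip a mispaired
toy helix under an ideal signal and is a test-engine knob, not a
scientific claim. The traceback is deterministic (leftmost base, smallest
admissible partner). What the generator does **not** emulate: sequencing
error, PCR jackpotting, sequence-context effects on DMS chemistry,
alternative conformations, and non-nested ground truth. Tests passing on
this generator therefore show pipeline correctness and internal
consistency, not accuracy on real probing data.

# The pairing-matrix network

The model maps a sequence to an L-by-L matrix of pairing probabilities.
Input one-hot sequences pass through a learned embedding of width 64. The
pair channel starts from the Kronecker input: 16 one-hot base-combination
indicator channels plus one stacking-energy channel that accumulates
Gaussian-decayed complementarity weights along outward and inward
diagonals, truncated at the first non-complementary encounter
(AU/UA = 2, GC/CG = 3, GU/UG = 0.8), and zeroed within the sharp-loop
band. `N` bases contribute a uniform quarter soft one-hot to the
indicators and nothing to the energy channel.

Each of the four blocks runs, on the sequence channel: multihead
self-attention with a learned relative-position bias (per-head scalar by
clipped offset; clipping at ±64 is what lets the model run on sequences
longer than it was trained on) and a bias projected per head from the pair
representation, added to the logits before the softmax; a feed-forward
layer; a pointwise/depthwise/pointwise 1D convolution (hidden width 128,
back to width 64); another feed-forward layer; and a two-layer transition
MLP — all with residual connections and pre-layer-norm. The sequence
channel then updates the pair channel through an outer-product module
(two linear projections, elementwise outer combination, linear map back to
17 channels), and the pair channel runs a dilated 2D ResNet with two
residual blocks (dilations 1 and 2) followed by a two-layer pair
transition. The decoder head — a 3x3 convolution, layer norm, one 2D
residual block, and a 1x1 single-channel output — reads the final pair
representation. Output logits are symmetrized as `(Z + t(Z)) / 2` before
the sigmoid; the symmetrization point is a design choice, stated so that
the deterministic outputs are reproducible. Inference runs one sequence at
a time and needs no padding, so no padding-invariance is assumed anywhere.

## Calibration of the free widths

The published description fixes the embedding width (64), the conv widths
(128/64), the number of blocks (4), the pair-trunk depth (2 residual
blocks), the 17-channel pair input, and three total parameter counts —
1,493,420 for the full model, 595,100 for ablation 1, 992,720 for
ablation 2 — but not the attention heads, feed-forward and transition
widths, kernel sizes, dilations, outer-product width, pair-trunk hidden
width, or decoder widths. Those free hyperparameters were calibrated once
against the three totals as three exact integer constraints:

* the pair representation stays at 17 channels end to end, so the decoder
  is shared unchanged across all variants (required for ablation 1, which
  feeds the Kronecker input straight to the decoder);
* ablation 1 equals the decoder alone: head width 197, residual hidden
  159, with entry 3x3 convolution, one layer norm and 1x1 output, giving
  595,100 exactly;
* ablation 2 adds the embedding, four blocks without pair CNNs or
  pair-bias projections, and a single outer-product module after the last
  block; with 8 heads, relative-position clipping 64, feed-forward width
  192, depthwise kernel 7, sequence transition width 75 and outer width
  109 this lands on 992,720 exactly;
* the full model adds per-block pair-bias projections, pair trunks
  (hidden width 179) and pair transitions (hidden width 86), reaching
  1,493,420 exactly.

`count_parameters()` recomputes all three totals by instantiating the
parameter arrays and summing their sizes, and the test suite asserts exact
equality, so the calibration is verified rather than assumed. Within the
constraint surface several integer solutions exist; the shipped one keeps
every width in a conventional range (heads dividing the embedding width,
feed-forward expansion about 3x). Where no solution satisfied all three
counts the discrepancy would have been reported per component rather than
absorbed; none was needed.

## Ablations

Ablation 1 (convolution-only) removes every block and passes the
Kronecker pair input directly to the unchanged decoder. Ablation 2
(attention-only, no exchange) keeps the full sequence trunk but removes
the pair CNNs and transitions from every block — which also removes the
pair-bias feedback into attention — and derives one pair representation
from the last block's sequence features via the outer-product module. In
ablation 2 the decoder reads that outer-product representation alone; the
Kronecker tensor is not re-added, following the reading that the pair
representation is "derived from the sequence features".

## Postprocessing

Constraints: no pair with `|i - j| < 4` (a hairpin loop of at least three
unpaired bases remains legal; whether the convention should be `< 4` or
`<= 4` is ambiguous in common use, so the bound is exposed in the
configuration), one partner per base, optionally canonical pairs only, and
a fixed calling threshold of 0.5. The grid is symmetrized and the
forbidden entries zeroed, which can only lower scores. Pair calling then
maximizes the total called score subject to one-partner-per-base: an exact
deterministic branch-and-bound runs whenever the conflict graph is small
(at most 48 candidate entries over at most 16 bases — always the case for
the desk-scale grids the guarantees are stated for), and denser grids take
a descending-score greedy pass refined by deterministic (1,2)-swap hill
climbing. Pure greedy was measured at a median 95% but worst-case 70% of
the matching optimum on dense random grids, which is why the exact matcher
backs it up; on the near-binary score grids a trained network emits, all
routes coincide, and calling at thresholds 0.4 and 0.6 gives identical
structures. Greedy imposes no nesting constraint, so pseudoknots can be
called; `nested_only` filters crossing pairs for downstream consumers that
need nested structures.

# Training and evaluation

The loss is plain element-wise binary cross entropy between the sigmoid
score grid and the 0/1 reference pairing matrix over the full L-by-L grid
— no masking of the diagonal band and no positive-class weighting, exactly
as specified for the original recipe (a `pos_weight`-style reweighting was
considered and rejected as a deviation). Optimization is Adam at learning
rate 3e-4, micro-batch 1 (no padding), gradient accumulation to an
effective batch of 256, 15 epochs, and the final weights are the
element-wise mean of the last five epoch checkpoints ("epochs 10 to 15"
counts six endpoints; this implementation reads it as the last five saved
checkpoints). Training is bit-for-bit reproducible under a fixed seed in
single-device mode; the published multi-device strategy is replaced by a
single-device loop with identical effective-batch semantics.

The whole network, including backpropagation, is implemented directly on
dense arrays with BLAS matrix products (the 3x3 im2col/col2im gather and
scatter and the Nussinov dynamic program are the only compiled routines).
Analytic gradients are verified against central finite differences in the
tests; the comparison perturbs all parameters slightly off zero first,
because freshly initialized zero biases put entire ReLU channels exactly
at the kink where one-sided numeric slopes legitimately disagree with the
subgradient convention.

**Desk-scale sizes.** The test suite trains a two-block model
(sequence width 32, 4 heads, feed-forward 64, pair trunk hidden 24,
decoder width 32) on 32 Nussinov-folded sequences of 24-64 nt for 60
epochs at learning rate 3e-3 with an effective batch of 2 — about a
thousand optimizer steps — and reaches training-set F1 of 1.0 after
postprocessing. The published recipe's batch of 256 is designed for
hundreds of thousands of sequences; at 32 examples it would allow a
handful of optimizer steps per epoch, so the desk-scale recipe trades
batch size for step count while keeping the loss, the optimizer family and
the averaging scheme. Checkpoints are stored as R-serialized files holding
the named parameter arrays with the configuration embedded.

# Numerical choices and degenerate inputs

* Internal coordinates are 1-based with inclusive spans, the natural R
  convention; CT files are 1-based by definition, and dot-bracket I/O is
  position-free. Cut positions count residues in the left part.
* Bracket-layer assignment on writing pseudoknots is greedy first-fit over
  four alphabets; structures needing more than four layers raise an error.
* Ties in pair calling break lexicographically by `(i, j)`; ties in the
  segmentation midpoint rule break toward the smaller cut; the Nussinov
  traceback prefers the leftmost base and smallest partner. Every
  tie-break is deterministic so that repeated runs agree exactly.
* Degenerate inputs raise errors rather than returning silent defaults:
  empty profiles, an all-zero normalization divisor, AUROC with an empty
  class, non-reciprocal CT files, sequences over the training length cap,
  and non-finite losses all abort with a diagnostic.

# Known limitations

The bundled folding engine is a maximum-pairing heuristic, not a
thermodynamic model; it defines consistent synthetic ground truth but
should not be used to model real RNA. One visible consequence: its score
landscape contains near-co-optimal helix register shifts whose
alternatives differ mostly at masked (penalty-blind) G/U bases, so under
binomial read-resampling a few percent of bootstrap draws refold to a
shifted register even though the vast majority refold identically — a
thermodynamic engine separates such registers by stacking energies the
heuristic lacks. The generator's independence
assumptions make its QC pass rates optimistic relative to real libraries.
Training at the published scale (hundreds of thousands of sequences,
multi-GPU) is out of scope, and no pretrained weights ship with the
package, so published benchmark F1 values on external test sets are not
reproducible here. The R implementation favors clarity over throughput;
inference on sequences beyond a few hundred nucleotides is functional but
slow compared to an accelerator implementation.
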