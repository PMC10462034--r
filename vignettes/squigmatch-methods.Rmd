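---
title: "Classifying raw nanopore signal with a run-length BWT index"
author: "squigmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying raw nanopore signal with a run-length BWT index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squigmatch)
```

## The problem

Nanopore sequencers emit a raw ionic-current trace (picoamps at ~4 kHz) as a
DNA molecule translocates through a pore. Many applications — host
depletion, taxonomic pre-filtering, adaptive sampling ("read until") — need
to decide *which reference a read came from* within seconds, and basecalling
is by far the most expensive step of that decision. squigmatch classifies
the raw signal directly: it discretizes current into a small alphabet of
picoamp ranges, matches the resulting symbol string against a reference
rendered into the same alphabet, and votes over localized matches. Because
matching runs on a run-length compressed BWT (r-index style), the reference
can be large and repetitive — the structures grow with the number of BWT
runs `r`, not the text length `n`.

## The pipeline

### Query side: signal to bin sequence

1. **Event detection.** A rolling two-window Welch t-test over the samples
   places event boundaries at t-statistic peaks: a short window (3 samples)
   for abrupt level changes above threshold 4.30265, a long window (6
   samples) for subtle ones above 2.57058, with peak prominence 1.0 and
   long-window peaks masked near short-window peaks. Each event is
   summarized by its mean current `ec` and dwell `et`. These five constants
   are configuration, not truth: the tool family this detector descends
   from chooses them per chemistry, and they are recorded in every
   classification report. We kept these defaults after a sweep over window
   sizes 2–4/4–8 and thresholds 1–15 on simulated signal showed no
   configuration that matched better.
2. **Normalization.** Event means are affinely rescaled so their running
   mean and standard deviation (maintained with Welford's single-pass
   update, so streaming and batch agree) match the moments of the pore
   model's level means. This removes per-read offset and gain. It is a
   finite-sample estimate: a read's true levels never have exactly the
   model's global moments, so normalization is exact only asymptotically —
   which is why the zero-noise closure identity below is stated with
   normalization off.
3. **Quantization.** The pore model's level-mean range `[min_p, max_p]` is
   cut into `n = 6` equal bins of width `s_p = (max_p - min_p)/n`; an event
   mean below the range maps to bin 0, above it to bin `n-1`, otherwise to
   `floor((ec - min_p)/s_p)`. Bins are left-closed/right-open, with
   `ec = max_p` assigned to the top bin — the floor formula leaves that
   boundary open, and a half-open convention keeps quantization monotone
   and total. Six bins balance noise robustness (wide bins) against match
   specificity (alphabet size).
4. **Run compression.** Adjacent equal symbols collapse to one. Stay
   errors — several events for one k-mer — have the signature of repeated
   similar levels, which usually land in one bin and vanish here. The
   reference is compressed identically so true repeats stay queryable.

### Reference side

Each input sequence and (by default) its reverse complement is converted
k-mer by k-mer to expected current via the pore model, quantized, and
compressed. Both strands are indexed because reads sample either strand and
signal space has no reverse-complement symmetry. k-mer windows containing
ambiguous bases map to a sentinel symbol outside the query alphabet, so
matches can never extend through unknown sequence. Every strand-sequence
ends in one terminator; terminators are encoded as distinct smallest
symbols in document order (the standard multi-document suffix-sorting
device), presented externally as a single `$`.

Positions are partitioned into equal-length, non-overlapping **shreds**
(default 100,000 symbols), each with its own document id and class label —
equal-sized documents prevent long references from dominating the vote, and
shred-level locality is what turns half-MEM statistics into a co-linearity
signal. The final partial shred keeps its own id; the complexity weighting
below compensates for length effects. Reverse-strand intervals share the
document ids of the mirrored forward shreds (by proportional coordinate
mirroring, since run-compressed lengths differ between strands), so votes
aggregate per locus rather than per strand.

### The index

The index stores the BWT of the reference text as maximal equal-symbol
runs, per-symbol rank tables over those runs, a **thresholds** structure
(for each gap between consecutive runs of a symbol, the LCP-argmin offset
where extension preference switches from the preceding to the following
run; ties resolve toward the preceding run), and a **sampled document
array**: the document label of the suffix at the first and last offset of
every run. Per-shred sequence complexity is computed here once. At desk
scale construction uses an explicit suffix array (prefix doubling) and
Kasai's LCP algorithm; the persisted index keeps only the run-length
structures plus samples, and all query semantics are defined run-wise, so a
fully compressed construction would be drop-in.

### Matching: pseudo-matching lengths

For a query of length `m` the index returns `P`, the per-position
pseudo-matching lengths (PMLs), and `D`, per-position document labels, in
one pass. PMLs are truncated matching statistics: `P[i]` is the length of
the greedy exact match extending right from `i` within its match segment,
so `P` is bounded above by the half-MEM matching statistics `MS` and decays
by at most 1 per step. The query loop maintains:

* the backward-search **interval** of the pattern matched so far — the
  match extends while the interval stays non-empty and resets otherwise,
  which guarantees the full decreasing ramp `[m..1]` whenever the query is
  an exact substring of the reference;
* a tracked **row** inside the interval that carries the document label:
  while `BWT[row]` equals the query symbol the label propagates through
  the LF step; on a mismatch the thresholds structure repositions the row
  to the nearer-in-context boundary of the preceding or following run of
  the needed symbol, where the sampled document array gives the label
  exactly.

A match segment is attributed to the document known when the segment
*closes*, i.e. with its longest and therefore most specific pattern —
longer matches tend to occur in a single document, so the close-time label
is the best estimate of the true origin. (Attributing each position as it
is consumed would label the vote-carrying peak position with the
maximally ambiguous length-1 pattern; in simulation that mis-attributes
almost half of all long true matches.)

**Streaming direction.** PMLs are classically computed right-to-left, but
adaptive sampling delivers signal left-to-right. The index therefore stores
each strand-sequence *reversed*, and the query loop scans the read's
symbols in arrival order; a pattern matched in the reversed text is exactly
the read's substring in the forward reference. The running lengths are
rewritten per closed segment into the decreasing ramp, which restores the
conventional start-based PML semantics while keeping the pass resumable:
the streaming state is exactly the interval, the tracked row, the open
match length, and its document. Concatenating the fragments emitted per
chunk plus a final flush reproduces the batch profile bit for bit.

### Classification

Peaks of the PML vector (`P[i] >= P[i-1]`, with position 1 a peak by
convention) mark match starts; summing only peak PMLs counts each match
once. The read's score for document `d` is

```
score(d) = C_d * sum_i P[i] * [D[i] = d] * [peak at i]
```

where `C_d` is the shred's order-0 empirical entropy over the bin alphabet
divided by `log2(nBins)` — matches into low-complexity (tandem-repeat-like)
shreds are likely coincidental and are down-weighted. `C_d` is computed at
build time from shred content; the alternative of estimating complexity
from the matched substrings at query time is out of scope here because the
build-time variant is precomputable, deterministic and index-resident.

* **Multi-class:** the read takes the class of the argmax document; ties
  break toward the lexicographically smallest reference name, then the
  smallest doc id (determinism matters for testing). All-zero scores yield
  `unclassified` — the only abstention the classifier can produce, and it
  is counted and reported.
* **Binary:** the top positive-class score is divided by the top
  null-class score; the read is positive iff the ratio strictly exceeds
  the spike-ratio threshold `tau` ("greater than" in the rule is read as
  strict). `tau = 1` suits roughly equal class abundances; otherwise
  `calibrateThreshold()` sets `tau` to the `(1 - f)` quantile (linear
  interpolation between order statistics) of burn-in ratios for an
  expected positive fraction `f`. A zero null score with positive evidence
  gives ratio `+Inf` (positive); no evidence at all abstains — the rule's
  denominator conventions are not covered by the vote definition and are
  fixed here.
* **Streaming:** after each ~4,000-sample chunk the event stream,
  normalization, bin sequence and PML pass are extended and a call is
  emitted; because normalization is computed over all events seen so far,
  the re-derived prefix can change, in which case the PML pass restarts
  (the resumable pass is used whenever the prefix is stable). The final
  streamed decision equals the batch decision on the full signal.

## The simulator

Every test runs against simulated signal with ground truth; no external
data is needed. For each k-mer of a reference window the generator draws a
dwell from `Normal(9, dwellSd)` samples, truncated below at 1 and rounded,
and emits that many samples from `Normal(level_mean, factor * level_sd)`.
Optional stay/skip probabilities re-emit or drop k-mers. Defaults are the
study conditions used throughout: mean read length 10,000 bp (length
`Normal(mean, mean/4)` truncated at 500 bp — only the mean is prescribed;
the spread is this package's choice of a realistic long-read profile),
amplitude noise factor 2.0, dwell sd 8.0. Classes are assigned round-robin
so a 200-read dataset has exactly 100 reads per class; starts and strands
are uniform, records weighted by length.

What the generator does *not* emulate: current drift, adapter/stall
signal, pore clogging, non-Gaussian noise, and sequence-dependent dwell.
Passing tests therefore demonstrate the algorithmic contract under
idealized noise, not performance on real flow cells.

**Pore model.** The full-scale experiments use a synthetic k=6 model:
level means uniform over 60–130 pA (the extremes pinned so the bin range
is exact) and level spreads uniform over 1–3 pA, deterministic in a seed —
the shape and ranges of a typical R9.4-era table, clearly labelled
synthetic. A tiny evenly spaced k=2 model ships as a TSV fixture for the
format-level tests. Real ONT model dumps load unchanged through
`loadPoreModel()`.

## Numerical and design notes

* Zero-noise closure (`signalToBinSeq` of a noise-free simulated read
  equals the reference's bin subsequence exactly) holds with
  `normalize = FALSE` and both noise sources at zero; random dwell alone
  produces 1–2-sample dwells no windowed detector can segment.
* Suffix order is total because terminators are pairwise distinct; BWT
  inversion from the terminator rows is a structural test run on every
  index.
* `n/r` of a single random 50 kb two-class index is ~1.25 (random text
  barely compresses); eight identical copies of a 20 kb reference grow `r`
  by ~0.1%, the repetitive-reference regime the r-index exists for.
* Problem sizes in the test suite (two 50 kb references, 200 reads at
  10 kb mean for the recovery property; 1,000 random instances for the
  oracle-dominance property) are chosen so the whole suite runs in about a
  minute on one core while keeping every property at a scale where failure
  modes show.

## Worked example

```{r example, eval = FALSE}
model <- syntheticPoreModel(k = 6)
cfg <- makeBins(model, 6)
refs <- syntheticReferences(c(target = 50000, background = 50000))
ref <- buildReference(refs, model, cfg,
                      classRoles = c(target = "positive",
                                     background = "null"))
idx <- buildIndex(ref)
ds <- simulateDataset(refs, 20, model, simParams(), seed = 1)
calls <- classifyReads(ds$signals, idx, model, cfg, mode = "binary")
evaluateCalls(calls, ds$truth, positiveClass = "target")
```

## Known limitations

* Dwell times are carried but unused in matching.
* Exact matching over 6 symbols is sensitive to event-segmentation errors;
  accuracy under heavy noise depends on read length (the vote integrates
  evidence along the read).
* The binary rule needs both a positive and a null reference in the index;
  classifying against a positive reference alone (null-free operation) is
  out of scope.
* Real-signal container formats (FAST5/SLOW5/POD5) are adapter territory;
  the package reads a plain-text signal fixture format and documents the
  reader contract (read id + sample vector) those adapters must meet.
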