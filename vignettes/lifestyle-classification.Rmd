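---
title: "Phage lifestyle classification: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phage lifestyle classification: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bacteriophages follow two broad lifestyles. Virulent (strictly lytic) phages
replicate by lysing their host; temperate phages can additionally integrate
into the host genome and persist as prophages. The two lifestyles carry
distinct gene repertoires — integrases and excisionases on the temperate
side, lysis- and nucleotide-metabolism-associated genes on the virulent side
— so the lifestyle is, in principle, decodable from nucleotide sequence
alone. `lysotyper` does exactly that: it takes assembled contigs (often
short, fragmented ones from virome or metagenome assemblies), and returns a
per-contig probability of being virulent, with temperate as the negative
class and virulent as the positive class throughout.

# The pipeline

1. **Segmentation.** Training contigs are sampled into fixed-length 512 bp
   segments at an expected per-base coverage of 10: a contig of length $L$
   contributes $\lceil 10 L / 512 \rceil$ segments with uniformly random
   start positions (sampled with replacement). At prediction time contigs
   are instead tiled contiguously into non-overlapping 512 bp windows; a
   trailing partial window is kept when it is at least 50 bp (shorter tails
   are untokenizable noise). Coordinates are 0-based, half-open. Because
   strand orientation of assembled contigs is unknown, every dataset is
   augmented with reverse complements, and at prediction time both strands
   of every window are scored.

2. **LCA tokenization.** Segments are converted to overlapping
   (Local Context Aware) k-mer tokens: windows of length $k$ advancing by
   `shift` $\le k$ positions, so consecutive tokens share $k-\mathrm{shift}$
   bases. The vocabulary is four special tokens (`[PAD]`, `[UNK]`, `[CLS]`,
   `[SEP]`; ids 0-3) followed by all $4^k$ k-mers in lexicographic order.
   Windows containing `N` map to `[UNK]` in place, preserving positional
   structure. Encoded segments are framed as `[CLS] ... [SEP]`, truncated
   with `[SEP]` retained, and padded.

3. **Encoder with learnable pooling.** A pre-norm transformer encoder
   (token + learned absolute position embeddings, masked multi-head
   self-attention, GELU feed-forward blocks) produces one hidden state per
   token. A single learnable scoring vector assigns a scalar to every real
   (non-pad) position; the scores are softmax-normalized over real
   positions and the pooled representation is the score-weighted sum of
   hidden states. Padding contributes exactly zero: pad keys receive
   $-\infty$ attention scores and pad positions $-\infty$ pooling scores,
   and $e^{-\infty} = 0$ in floating point. A linear map to two logits and
   a softmax give $(p_\mathrm{temperate}, p_\mathrm{virulent})$.

4. **Weighted voting.** Segment probabilities for a contig are combined as
   a weighted mean with weights equal to segment length in bases, so a
   50 bp tail counts proportionally and both strand copies pool into one
   vote. The contig is called virulent when the vote reaches the decision
   threshold (ties resolve to virulent).

5. **Leakage control.** Pairwise sequence similarity is estimated with
   bottom-k MinHash sketches: the 300 smallest distinct MurmurHash3 values
   (x64 128-bit variant, first word, seed 3) of a sequence's canonical
   21-mers. Canonical (strand-minimum) k-mers make sketches
   strand-invariant, which matters because the pipeline explicitly treats
   both strands. Jaccard similarity is estimated from merged sketches and
   converted to ANI via the Mash relation
   $\mathrm{ANI} = 1 + \tfrac1k \ln\frac{2j}{1+j}$. A strict holdout
   removes every training sequence with at least 80% ANI to any test
   sequence; when FastANI output is supplied the full two-part rule (ANI
   $\ge$ 80% over $\ge$ 80% of the training record's length) applies,
   while the sketch-based path applies the ANI criterion alone because an
   aligned fraction is not derivable from a sketch. The standard holdout
   performs no removal and represents deployment against phages whose
   relatives were seen in training.

# Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| segment length | 512 | bp | classifier input unit; matches the encoder's context |
| training coverage | 10 | x | expected per-base sampling depth of training segments |
| fragment lengths | 500, 2000, 10000 | bp | benchmark grid spanning typical virome contig sizes |
| tokenizer k | 6 (1 for the character variant) | — | 6-mers balance vocabulary size ($4^6$) and resolution |
| tokenizer shift | 1 (standard), 2 (desk-scale training) | tokens advance per step | smaller shift = more context, more compute |
| sketch k | 21 | bp | long enough that random collisions are negligible |
| sketch size | 300 | hashes | Jaccard standard error $\sqrt{j(1-j)/300} \approx 0.03$ |
| hash seed | 3 | — | fixed so signatures are portable across runs |
| ANI threshold | 0.80 | fraction | excludes close relatives without erasing distant ones |
| aligned-fraction threshold | 0.80 | fraction | FastANI path only |
| decision threshold | 0.5, or calibrated | probability | see calibration below |
| learning rate | 2e-3 (desk protocol) | — | AdamW peak rate; warmup 10%, cosine decay |

# The desk-scale training protocol

Two architecture presets exist: `model_config_tiny()` (2 layers, 4 heads,
width 64) and `model_config_full()` (6 layers, 6 attention heads), the
latter mirroring the full-scale architecture class. All development and
validation here uses the tiny preset, which trains on one CPU core in
minutes; the protocol (in `train_lifestyle_model()`) is:

* strand-augment the training contigs, sample the 512 bp segment pool at
  coverage 10, and subsample a class-balanced budget of 10000 segments;
* tokenize with $k = 6$, shift 2 (the shift-2 variant halves the token
  count of a 512 bp segment to 254, quartering attention cost while still
  covering every base — the standard shift-1 variant remains the package
  default for the tokenizer itself);
* train a single pass with AdamW ($\beta_2 = 0.98$), peak learning rate
  2e-3, batch 16, 10% linear warmup then cosine decay, global
  gradient-norm clipping at 1, dropout 0.1 on the residual branches, and
  decoupled weight decay 0.01 on weight matrices;
* keep the checkpoint with the best validation balanced accuracy.

Two behaviours of small from-scratch transformers shaped this protocol.
First, they can sit on a constant-output saddle for many steps before
features form; training is therefore monitored on validation
segment AUC — a threshold-free criterion — and a run ending below 0.65 is
diagnosed as under-converged and restarted once with a shifted seed (the
best attempt by AUC is kept). Second, segments that
carry no lifestyle signal (background between motif cassettes) acquire a
small, direction-unpredictable probability drift during training, which
shifts the whole vote distribution off 0.5. The package therefore
calibrates the contig-vote decision threshold on validation fragments
(`calibrate_vote_threshold()`): the threshold maximizing validation
balanced accuracy, ties broken towards 0.5. Both mechanisms use only
training-side data and are deterministic given the seed.

# What the synthetic generator emulates — and what it does not

`generate_genome()` produces 20–100 kb genomes (uniform length, GC 0.5,
Markov order 0 or 1 background) in which lifestyle is encoded by planted
motif cassettes: 100 copies per genome of 30-mers drawn from a class's
panel of 12 fixed motifs, inserted at uniform non-overlapping positions and
independently point-mutated at 5% per site. The two panels share no
canonical 21-mer, so the classes are separable in principle but each
individual 512 bp window contains a motif only with moderate probability —
at the default density a 500 bp fragment is genuinely hard while a 10 kb
fragment almost surely contains several cassettes. This reproduces the
qualitative difficulty gradient of fragment-length benchmarks: accuracy
must rise from ~0.7 at 500 bp towards ~1 at 10 kb.

`generate_family()` produces divergence-controlled relatives by per-site
substitution without indels, so true ANI to the ancestor is analytically
$1 - d$; at $d = 0.05$ the sketch pipeline must estimate ANI $\approx$
0.95 (removed by the strict holdout), at $d = 0.30$ ANI $\approx$ 0.64
(retained).

The generator does **not** emulate gene/operon structure, codon bias,
horizontal transfer, repeats, indels, or sequencing error. Passing tests
on this generator therefore demonstrate that the pipeline's machinery —
segmentation arithmetic, tokenization, optimization, voting, leakage
filtering, metrics — is correct and that the encoder can extract a
composition-encoded lifestyle signal; they do not certify accuracy on real
phage genomes, which requires real training collections.

# Numerical choices

* Hashes are carried as fixed-width 16-digit hex strings (R lacks a
  64-bit integer); lexicographic order equals numeric order, so bottom-k
  selection and merged-sketch estimation are exact.
* The merged-sketch Jaccard denominator is $\min(300, |\mathrm{union}|)$;
  for sequences with fewer than 300 distinct 21-mers the sketch is the
  complete hash set and the estimator reduces to the exact Jaccard.
* A Jaccard of exactly 0 carries no distance information; the ANI is
  reported as 0 with an `undefined` flag rather than extrapolated.
* Metrics with zero denominators (e.g. sensitivity without positives) are
  `NA` and flagged, never silently 0.
* Segments shorter than the tokenizer's $k$ receive a neutral, flagged
  p = 0.5 and are excluded from votes whenever an unflagged segment
  exists, so degenerate contigs still get a call.
* The GELU uses the sigmoid approximation $z\,\sigma(1.702 z)$; softmax
  rows are max-shifted; cross-entropy clamps probabilities at 1e-300.
* All randomness flows through explicit integer seeds; training is
  bitwise reproducible on one device.

# Problem sizes used in validation

The packaged validation trains the tiny preset on 100 synthetic genomes
(60/20/20 train/val/test split, class-balanced), one pass over 10000
segments, and evaluates on 50 fragments per class per length at 500, 2000
and 10000 bp. Sketch accuracy is validated on 10 kb pairs across an
engineered true-Jaccard grid of 0.1–0.9 against brute-force exact Jaccard,
and metric formulas against an independent expanded-vector route on 1000
random confusion matrices. These sizes were chosen so the entire validation
runs on a single CPU core in minutes while keeping every statistical check
adequately powered.

# Known limitations

* The exact pooling formula and voting weights of the original full-scale
  system are not public in detail; the single-scoring-vector pooling and
  length-weighted voting implemented here are the minimal faithful
  readings, recorded as such.
* The sketch-based strict holdout cannot evaluate the aligned-fraction
  clause; FastANI ingestion exists for the full rule.
* Inference speed (classified nucleotides per second) is measured end to
  end but is hardware-dependent and carries no accuracy meaning.
* The tiny preset is a validation instrument; real-data use would start
  from the 6-layer preset and a pretrained initialization, neither of
  which this package ships.
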