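# lysotyper

Classify bacteriophage contigs as **virulent** (strictly lytic) or
**temperate** (capable of lysogeny) directly from nucleotide sequence — no
gene annotation, no protein database. Phage sequences from virome and
metagenome assemblies are usually fragmented (often ≤ 10 kb), and
database-driven lifestyle predictors degrade badly both on short fragments
and on phages unlike anything in their reference sets. `lysotyper`
implements an alignment-free pipeline for exactly this setting, together
with the evaluation machinery needed to measure it honestly: fragment-length
benchmark grids and similarity-based train/test leakage control.

## The method

A contig $S$ is tiled into 512 bp segments $S_1, \dots, S_m$. Each segment
is tokenized into overlapping **Local Context Aware (LCA) k-mers** (6-mers
advancing by a shift ≤ 6, framed by `[CLS]`/`[SEP]`) and scored by a compact
transformer encoder. The encoder's token representations $h_1,\dots,h_T$ are
pooled with learnable weights,

$$u_t = v^\top h_t + c,\qquad \alpha = \mathrm{softmax}(u_{\text{real}}),\qquad
z = \sum_t \alpha_t h_t,$$

and a linear head gives segment probabilities
$(P_{\mathrm{tem}}, P_{\mathrm{vir}})$, temperate being the negative class.
Segment probabilities are combined by **weighted voting** with weights equal
to segment length in bases,

$$P_{\mathrm{vir}}(S) = \frac{\sum_i w_i \, p_i}{\sum_i w_i}, \qquad w_i = |S_i|,$$

both strands included, yielding one probability per contig. Training uses
cross-entropy with AdamW on 512 bp segments sampled at 10× expected
coverage, with reverse-complement augmentation.

Dataset independence is enforced with bottom-k **MinHash sketches** (300
smallest MurmurHash3 values, seed 3, of canonical 21-mers): sketch Jaccard
→ ANI via $1 + \frac{1}{k}\ln\frac{2j}{1+j}$, and any training sequence
with ≥ 80 % ANI to a test sequence is removed (*strict holdout*; FastANI
output can be supplied for the full "80 % ANI over 80 % of length" rule).
Performance is reported as accuracy, balanced accuracy, sensitivity,
specificity, F1 and MCC over simulated fragment sets of 500, 2000 and
10 000 bp.

Because no public phage collection ships with this package, a synthetic
generator (`generate_dataset()`) produces labeled 20–100 kb genomes whose
lifestyle is encoded by planted, mutation-noised motif cassettes, plus
divergence-controlled genome families for testing the leakage filter. See
the methods vignette (`vignettes/lifestyle-classification.Rmd`) for the
full model description and design rationale.

## Worked example

```r
library(lysotyper)

# 100 labeled synthetic phage genomes: 60 train / 20 validation / 20 test
ds <- generate_dataset(n_per_class = 50, generator_config(), seed = 101)

# desk-scale encoder: 2 layers, 4 heads, width 64; one pass over 10000
# segments sampled at 10x coverage
model <- train_lifestyle_model(ds$train, ds$val, seed = 202, quiet = TRUE)
thr <- calibrate_vote_threshold(model, ds$val, seed = 404)

frags <- simulate_fragments(ds$test, c(500, 2000, 10000),
                            n_per_class_per_length = 50, seed = 303)
benchmark_fragments(function(x) predict_contigs(model, x, threshold = thr),
                    frags)
```

Output from the run above (seeds as shown):

```
  fragment_length holdout_mode accuracy balanced_accuracy sensitivity
1             500     standard     0.73              0.73        0.72
2            2000     standard     0.88              0.88        0.92
3           10000     standard     0.96              0.96        0.98
  specificity        f1       mcc
1        0.74 0.7272727 0.4600920
2        0.84 0.8846154 0.7624437
3        0.94 0.9607843 0.9207369
```

Balanced accuracy climbs from 0.73 on 500 bp fragments to 0.96 on 10 kb
fragments: short fragments frequently contain no lifestyle-informative
motif, while long fragments aggregate many informative segments through the
length-weighted vote. `predict_contigs()` returns one row per contig with
`p_virulent`, the hard `label`, the number of voted segments and the bases
classified.

A command-line wrapper covers the same pipeline
(`system.file("scripts", "lysotyper", package = "lysotyper")`):
`simulate`, `segment`, `simulate-fragments`, `dedup`, `train`, `predict`,
`benchmark`, `speed`. Every artifact-writing command records a JSON run
manifest with its configuration, seed and input/output hashes.

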