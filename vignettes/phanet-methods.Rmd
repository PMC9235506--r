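---
title: "Methods: alignment-free phage-host association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-free phage-host association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A phage infects a narrow set of bacterial hosts, and resident mobile
elements drift toward the compositional habits of their host — nucleotide
usage, codon and di-codon bias shaped by the host's replication and
translation machinery. Metagenomic assemblies deliver phage and bacterial
*contigs*, often only hundreds of bases long, for which alignment- or
CRISPR-spacer-based host assignment has nothing to grab onto.
`phanet` scores a (phage contig, host contig) pair directly from
sequence, with a convolutional network whose global pooling accepts any
contig length.

## Encodings and the codon transformer

Each contig is represented at two granularities:

* **Base level** — an $L \times 4$ one-hot matrix, columns fixed as
  (A, C, G, T); any other character (N, IUPAC ambiguity codes) encodes
  as an all-zero row. Input is uppercased first.
* **Codon level** — the three forward reading frames are each encoded
  against the 64 codons and stacked along the row axis in frame order
  0, 1, 2, giving $\sum_{f=0}^{2}\lfloor (L-f)/3 \rfloor$ rows by 64
  channels. A codon containing any non-ACGT character is an all-zero
  row. Codon channels are ordered lexicographically over (A, C, G, T);
  the ordering is arbitrary but must be fixed, and it is shared between
  `encode_codons()` and the filter bank below.

The codon matrix need not be computed by string manipulation: with a
fixed filter bank $F$ of 64 kernels, each kernel the $3 \times 4$ base
one-hot of one codon, the window map

$$f(M) = \mathrm{ReLU}(F * M - 2)$$

applied to every 3-row window of the base matrix yields exactly the
codon one-hot: the matching kernel attains inner product 3 and every
other kernel at most 2, so subtracting 2 and rectifying leaves a single
1 (and a window touching an ambiguous base yields all zeros, since no
kernel can reach 3). `apply_codon_transformer()` implements this and is
bit-identical to `encode_codons()`; the test suite asserts the
equivalence over thousands of random sequences. Inside the network the
transformer is a fixed layer — it is never trained.

Only the forward strand is read (no 6-frame encoding, no amino-acid
translation). Whether reverse strands should augment training is an open
modelling question; the encoders are strand-faithful and augmentation
can be done upstream by reverse-complementing inputs.

## The four-path network

Each side (phage, host) runs a base path and a codon path:

* per path, two valid 1-D convolution blocks (base path kernels 7 then
  5; codon path 3 then 3; channels 64 then 256 under defaults), each
  ReLU-activated and followed by width-4 non-overlapping local max
  pooling;
* a terminal **global pooling** over the position axis, making the
  output length-independent: 256 features per path, 512 per contig
  under defaults. The global pool is a **mean** by default, with max
  available. The choice follows the reading of the convolutional stack
  as a learned k-mer-frequency extractor: a frequency is the *average*
  of an indicator convolution over positions, and averaging is the
  summary whose expectation does not drift with contig length. Global
  max pooling is also supported, but on composition-style signals its
  features concentrate on extreme windows: empirically (see the
  feature-probe note below) random-weight max-pooled features separate
  associated from non-associated pairs far worse than mean-pooled ones,
  and gradients flow through a single position per feature;
* the four feature blocks are concatenated in the fixed order
  phage-base, phage-codon, host-base, host-codon and passed through a
  fully connected head (1024 → 256 → 1 by default) with a terminal
  sigmoid, read as the probability that the pair is associated. The
  head's hidden activation is a leaky rectifier (slope 0.01): because
  the head's inputs are globally pooled post-ReLU features and hence
  all non-negative, a hard rectifier makes a hidden unit whose weights
  drift negative dead for *every* input, irreversibly — a failure mode
  that reproducibly collapsed small-budget training runs to constant
  output. The convolutional paths keep the plain ReLU. The first head
  layer is initialized as a **comparator**: with shared extractors the
  head sees [phage features, host features], and each hidden unit
  starts antisymmetric — weights u on the phage block, -u on the host
  block — so it reads a signed feature difference from the first step.
  Association is a relation between the two blocks (a linear readout of
  the concatenation is provably uninformative for a symmetric pair
  distribution), and starting inside the comparator subspace removes
  the long, seed-dependent plateau in which a generically initialized
  head searches for that structure. Training is free to leave the
  subspace; only the starting point is structured.

**Shared weights.** By default the phage-side and host-side parameters
of each path are literally the same storage, which makes the
convolutional stack a role-agnostic feature extractor — the same
sequence yields the same 512 features whether presented as phage or
host. This mirrors how $k$-mer frequency methods treat both sequences
identically and extract identical features; `share_weights = FALSE`
gives each side its own parameters for the comparison experiment, and
single-path configurations (`paths = "base"` or `"codon"`) support the
ablation experiments.

The exact published layer inventory (depths, widths, kernel sizes,
pooling flavour) is not recoverable from the text we model; the defaults
above are this package's declared architecture and every one of them is
exposed in `phanet_config()` so the ablation surface stays open. The
minimum accepted contig length defaults to 200 bases — the shortest
length in the evaluation menus; shorter inputs are rejected with an
explicit error rather than padded, since padding would silently bias
the global pooling statistics.

All linear algebra runs through small RcppArmadillo kernels (a valid
convolution as $k$ shifted GEMMs, pooling with argmax bookkeeping);
gradients are hand-derived and verified against numerical
differentiation in the test suite.

## Training protocol

`phanet()` minimizes binary cross-entropy with Adam (learning rate
0.001, batch size 32 by default). Per epoch:

* every positive pair is matched with one fresh negative — the same
  phage paired with a host drawn uniformly among hosts with no recorded
  positive association for it (1:1 class balance);
* pairs are shuffled into batches; for each batch one phage length and
  one host length are drawn from the menus (defaults 200, 500, 1000,
  5000, 10000, 50000 bases for phages; the same plus 100000 for hosts),
  and each genome contributes a fresh uniformly-positioned substring.
  A genome shorter than the drawn length is used whole: rejecting such
  genomes would bias species representation. Hosts with several
  assemblies contribute one uniformly drawn assembly per sample.

Early stopping watches the validation loss with tolerance `1e-5` and
patience 50 epochs (defaults), and the returned parameters are those of
the best validation epoch. The monitored quantity is a design choice
(loss, with AUROC logged alongside): monitoring a loss is smoother than
AUROC at small validation sizes. Validation pairs are instantiated
*once* at training start — lengths and substrings drawn and then frozen
— so the early-stopping signal is not re-randomized every epoch; the
training stream itself stays fully stochastic. A NaN loss aborts with
the epoch/batch and lengths in the message rather than training on.

`phanet_grid_search()` reproduces the hyper-parameter search shape
(learning rate × batch size, k-fold cross-validation, arg-min mean fold
loss) at a deliberately reduced default epoch budget; the published-scale
search (4 × 4 grid, ten folds, thousands of epochs) is the same call
with larger arguments.

**Leakage-aware splitting.** `split_pairs()` consumes an external
clustering of phage sequences (e.g. CD-HIT/MMseqs2 at 95% identity, 50%
coverage — running the clusterer is out of scope), keeps one random
representative per cluster, splits 80/20 at random, then iteratively
moves any training pair whose phage cluster *or* host taxon also occurs
in validation into the validation set, to a fixed point. The invariant —
no phage cluster and no host taxon spans both sets — is asserted in
tests. On corpora with few hosts this rule is aggressive (ten pairs
sharing one host all travel together); that is the rule's intent, not an
artifact.

## Perturbation models

**Sequencing errors** act per input base: an error occurs with
probability $\mu + \delta$; conditional on an error it is a substitution
with probability $\mu/(\mu+\delta)$ (the base changes to one of the
*other* three, uniformly — never resampled to itself), a deletion with
probability $\delta/(2(\mu+\delta))$, or an insertion with the same
probability (a uniform base placed after the current one). At most one
event occurs per original base (single pass, no compounding). The
marginal rates are therefore $\mu$ substitutions and $\delta/2$
insertions and deletions each per base; the tests check realized counts
against their binomial expectations at a megabase. The model is a
contig-level abstraction — no read simulation, no quality strings.

**Chimeras** model assembly joins: a contiguous segment of length
`round(fraction * L)` at a uniform position is exchanged with an
equal-length segment of a partner contig; lengths are preserved and the
combined base multiset is invariant. Contiguity is a modelling choice
(the motivating artifact is a mis-join, which splices a contiguous
foreign block). The harness only swaps phage with phage and host with
host. `corrupt_eval_set()` samples evaluation contigs at fixed lengths
(5000/5000 by default) *before* perturbing, so the unperturbed columns
are identical across settings under one seed.

## Evaluation

`compute_auroc()` uses the rank (Mann–Whitney) formulation with midrank
ties — the probability a random positive outscores a random negative,
ties counted half; a brute-force pair count is the test oracle.
`evaluate_length_grid()` scores every (phage length, host length) cell
by re-sampling contigs `reps` times (default 10) with fresh 1:1
negatives, and by default pools all scores into one AUROC per cell;
averaging per-repetition AUROCs is available (`pool = FALSE`). Pooling
was chosen because per-repetition AUROCs at small pair counts are
high-variance. A naive baseline — L1 distance between normalized
$k$-mer frequency vectors, negated as a score — stands in for external
alignment-free comparators and doubles as a null-model probe.

## The synthetic corpus

`generate_corpus()` plants exactly the signal the network is meant to
exploit and nothing else. Clades are order-2 Markov transition tables
(Dirichlet(0.5) rows) over A/C/G/T, resampled until all pairwise
total-variation distances between stationary base compositions reach
0.1, so clades are separable but not trivially so. Host genomes follow
their clade's chain; each phage genome follows its host's chain with
probability `signal_strength` per base and a uniform background
otherwise. Defaults: 5 clades × 4 hosts × 10 phages per host (20 hosts,
200 phages, 200 kb / 40 kb genomes), signal 0.8.

What this emulates: many phages per host taxon, and a shared
compositional signature between associated genomes. What it deliberately
does not: genes, repeats, prophages, GC skew, real phylogenetic
structure, or hosts with multiple divergent assemblies. Passing the
end-to-end checks therefore demonstrates that the implementation can
learn a compositional association signal at metagenomic contig lengths —
not that it reproduces published performance on real databases, which
depends on data and trained weights that are out of scope here.

`holdout_split()` holds out unseen phages of seen clades (the
within-distribution task) by default; `by = "clade"` holds out whole
compositional neighbourhoods (the harder generalization task). The
strict `split_pairs()` leakage rule is intentionally *not* used here:
with 20 hosts it would move nearly all pairs to validation, and the
synthetic design already guarantees no phage sequence is shared.

## Problem sizes and numerical choices

The package's own verification runs at desk scale, chosen once:

* End-to-end checks train on the default corpus with reduced widths
  (channels 16 then 64, 32 hidden head units), learning rate 0.003,
  batch size 4, 30 epochs, length menus 200/500/1000/5000 on both
  sides. The association signal lives entirely in the *interaction*
  between phage and host features (a linear model on the concatenated
  features sits at chance while one on |phage - host| does not), and
  discovering that interaction from random initialization is the slow
  part of optimization: it is step-count-bound, not epoch-bound. At
  320 pairs per epoch, batch 4 gives 2400 optimizer steps in 30
  epochs, which crosses that threshold reliably across corpus draws
  where batch 32 (300 steps) does not; the learning rate 0.003
  similarly compensates for the short budget, while higher rates
  destabilize the small model. 5 kb is included in the menus so the model sees
  the lengths at which the length grid is later read, as the full
  protocol's menus do. Held-out AUROC is read from pooled length-grid
  cells (10 repetitions at 1 kb).
* Feature-probe note: on a default corpus, a logistic model on
  |phage features - host features| from an *untrained* reduced-width
  network separates held-out pairs at AUROC ~0.83 with mean global
  pooling versus ~0.60 with max - the observation that fixed the
  default pooling flavour.
* Unit tests use miniature corpora (kilobase genomes) and a
  four-channel architecture; the gradient check compares every
  parameter block against finite differences at tolerance 5e-4.
* Ties in global max pooling route the gradient to the first maximal
  position; local pooling drops trailing rows that do not fill a block;
  probabilities are clamped by `1e-12` inside the cross-entropy only.
* All randomness flows through R's RNG, so a single `set.seed()` (or
  the `seed` slots of the config objects) reproduces corpora, training
  and evaluation bit for bit on one platform. Single-threaded BLAS is
  assumed for exact cross-run determinism of training.

## Known limitations

* The duplicated-sequence monotonicity of max pooling
  (features of `s+s` ≥ features of `s`) is exact only when pooling
  blocks align (`|s|` divisible by the pool width) and on the base
  path; the codon path's stacked frames break window-superset structure
  at frame boundaries. The property is tested in that regime.
* Training is CPU-bound R/Armadillo; it is sized for hundreds of pairs
  and kilobase-to-10-kb contigs, not for database-scale corpora.
* No pretrained weights ship with the package; published real-data
  AUROC levels are not reproducible without the original databases and
  weights, and are not claimed.
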