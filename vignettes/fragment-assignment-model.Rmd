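---
title: "The fragem model: batch EM fragment assignment with bias correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fragem model: batch EM fragment assignment with bias correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragem)
```

## The problem

High-throughput sequencing reads are aligned to a set of target sequences
(for RNA-Seq, the transcriptome) before most downstream analyses. A large
fraction of fragments — often over a quarter in mammalian transcriptomes —
align acceptably to more than one target: isoforms of a gene share exons,
gene families share domains. Discarding these fragments biases abundance
estimates against targets with few unique regions. fragem resolves the
ambiguity by maximum likelihood: each fragment is assigned a posterior
probability over its candidate origins, and abundances are estimated by
the batch expectation-maximization (EM) algorithm over the full alignment
set.

## The likelihood

Let $\tau_t$ be the *sampling probability* of target $t$: the probability
that a randomly drawn sequenced fragment originates from $t$. A fragment
$f$ with candidate alignment $a$ to target $t$, 5' end at position $p$,
3' end at position $q$ and implied length $\ell = q - p + 1$ contributes

$$
P(f, a) \;=\; \frac{\tau_t}{\tilde\ell_t}\; \cdot\; P_{\mathrm{fld}}(\ell)
\;\cdot\; P_{\mathrm{err}}(r_5)\, P_{\mathrm{err}}(r_3)
\;\cdot\; w_5(t, p)\, w_3(t, q),
$$

with the factors:

* **Effective length** $\tilde\ell_t$: the number of valid start sites
  averaged over the fragment length distribution,
  $\sum_\ell P_{\mathrm{fld}}(\ell)\,\max(L_t - \ell + 1, 0)$. When bias
  correction is active it additionally absorbs the per-target total bias
  weight (below), so that $\tau$ remains a proper sampling probability.
* **Fragment length distribution** $P_{\mathrm{fld}}$: a pmf over
  $1..800$, initialized uniform, re-estimated from posterior-weighted
  implied lengths. Single-end fragments have no observed length, so the
  term is omitted for them; lengths beyond the support get a floor of
  $10^{-12}$.
* **Error model** $P_{\mathrm{err}}$: per-read-position $4\times4$
  conditional substitution matrices $P(\text{observed}\mid\text{reference},
  \text{position})$, one bank for the first-sequenced end and one for the
  other. Initialized uniform; read positions beyond the modeled length
  reuse the last position's matrix. Because the compact record format
  stores mismatches only (no qualities), the model conditions on position
  and reference base, not on quality scores.
* **Bias weights** $w_5, w_3$: ratios of *observed* to *expected*
  probabilities of the sequence window around each fragment end
  (8 nt upstream through 12 nt downstream of the end base, 21 nt total).
  Both are Markov chains over window slots; observed chains are counted
  from posterior-weighted fragment-end windows, expected chains by
  sliding windows along every target position weighted by
  $\tau_t/\tilde\ell_t$ and the fld mass of fragments whose end can fall
  there. With equal chains every weight is 1, which is also the initial
  state.

All terms are kept in log space; per-fragment posteriors are normalized
with log-sum-exp and exponentiated only when incrementing the count
accumulators.

## EM, freezing and convergence

Each iteration runs a full-data E-step (posterior assignment) and an
M-step (Laplace-smoothed re-estimation). Abundances are updated every
iteration. The *auxiliary* parameters — everything except $\tau$ — are
updated at every iteration for the first 20, then every 100 iterations up
to 1000, and are frozen afterwards: they are few and converge early, and
with fixed auxiliaries the objective is log-linear, so EM provably
converges to its global maximum. Convergence is declared when every
target with $\tau_t \ge 10^{-7}$ changes by at most $10^{-2}$ relative to
the previous iteration (denominator: the previous value).

Smoothing constants: the auxiliary count banks use a Laplace pseudocount
of 1.0; the abundance counts use $10^{-8} \cdot n_{\text{fragments}}$ — a
full pseudo-fragment per target would visibly distort small datasets.

Two numerical details in the bias machinery matter and were found the
hard way:

1. **Mass-matched smoothing.** Raw expected-window counts integrate
   $\tau/\tilde\ell$ weights and sum to $O(1)$, while observed counts sum
   to about $21\,n_{\text{fragments}}$. A flat pseudocount applied to
   both would flatten the expected chains to uniform and make every
   weight spurious, so expected counts are rescaled to the observed mass
   before the shared pseudocount is added.
2. **Bias-adjusted effective length.** The weights $w_5, w_3$ reweight
   positions *within* a target; without a per-target normalizer the
   estimated $\tau$ is a pure count share and correction cannot undo the
   target-level sampling distortion that sequence bias causes. fragem
   therefore divides the likelihood by
   $\tilde\ell_t^{\mathrm{adj}} = \big(\sum_p w_5(t,p) F(L_t - p)\big)
   \big(\sum_q w_3(t,q) F(q+1)\big) / \tilde\ell_t$
   (with $F$ the fld cdf) and reports the length-normalized relative
   abundance as $\tau_t/\tilde\ell_t^{\mathrm{adj}}$, rescaled to one
   million.

### Bias chain order

The window geometry follows the common fragment-end window (8 up / end /
12 down). The Markov order of the chains defaults to **0** — positional
nucleotide preferences — rather than a higher order. This is a deliberate
capacity choice: at the package's desk-scale study condition (50,000
fragments) an order-3 chain has tens of thousands of ratio cells, so the
learned log-weight field carries estimation noise comparable to or larger
than the bias signal, and the exponential aggregation into adjusted
effective lengths amplifies exactly those errors until correction costs
more accuracy than it buys. Order-0 chains estimate cleanly at this
depth and recover the dominant (positional) component of priming bias;
`bias_order` in `em_config()` raises the order for deeply sequenced
datasets.

## The distributed executor

`run_em_parallel()` reproduces the broadcast/accumulate architecture on
local worker processes: fragment partitions (default 10,000 fragments)
are compiled once and cached on the workers; each round the master
broadcasts a read-only parameter snapshot, workers return additive count
accumulators, and the master combines them **in ascending partition
ordinal order** before the M-step. The fixed reduction order makes
results bit-identical across worker counts at a fixed partition size
(a cluster combining in arrival order would differ in low-order bits);
with a single partition the arithmetic is identical to the serial engine.
Workers never mutate the broadcast snapshot — verified by a checksum
before and after every round. On bias-update rounds the expected-window
counts are likewise mapped over target partitions. A failed worker round
is retried once on the master before raising.

## The record format

Datasets are exchanged as two newline-delimited text files — one base64
line per fragment or target — wrapping a Protocol-Buffers-style binary
serialization with nucleotides packed at 2 bits per base and alignments
reduced to endpoints plus mismatch positions and bases. One record per
line means any line range is an independently parseable partition, which
is what the partitioned executor (and any distributed file system)
needs; the base64 step exists purely to keep newlines out of the payload.
The cost of this compactness: only `A/C/G/T` is representable (records
with other IUPAC codes are rejected at preprocessing) and gapped
alignments are skipped with a warning, since the schema encodes
substitutions only.

## The simulator

`simulate_experiment()` draws data from the model's own generative
process, so estimator and simulation are matched by construction:

* targets in isoform-like groups sharing an identical internal segment
  (half the group's minimum length by default) — the source of genuinely
  ambiguous fragments;
* molar abundances $\rho \sim$ symmetric Dirichlet(0.3), giving the
  heavy-tailed spread real transcriptomes show;
* fragment lengths truncated-normal (200 ± 40, bounded by the read
  length and the target), paired 76-nt reads, i.i.d. substitution errors
  at 0.5%;
* optional 5'-end sequence bias: an order-3 chain whose conditionals are
  position-specific base preferences (log-sd 0.5) with mild per-context
  modulation (log-sd 0.15), raised to `bias_strength`. Draws follow the
  joint law $P(t, p, \ell) \propto \rho_t\, P_{\mathrm{fld}}(\ell)\,
  w(p)^{s}$, so bias distorts target-level sampling — the phenomenon
  correction exists for. A fully context-random chain was rejected: it
  encodes bias with no low-order structure, which neither any estimator
  nor any real protocol exhibits.
* reads are placed back with an exhaustive substitution-only aligner
  (pigeonhole seeding, at most 3 mismatches by default), so records
  carry every placement an idealized aligner would report.

What the simulator does **not** emulate: indels, quality-score error
structure, strand orientation (the record schema has no strand field, so
everything lives on the forward strand), 3'-end bias, positional
coverage decay, or multi-isoform splicing structure beyond the shared
segment. Passing recovery tests on these simulations therefore
demonstrates correctness of the estimator under its own model
assumptions, not robustness to real-data pathologies.

The evaluation convention follows the estimates-versus-ground-truth
protocol: Spearman rank correlation of expected counts against realized
true counts for unbiased data, and of length-normalized abundance
against the molar $\rho$ for biased data (realized counts are themselves
bias-distorted, so count recovery cannot distinguish corrected from
uncorrected estimates).

## Problem sizes

The reference study condition used throughout the tests and the
acceptance script is 300 targets in 100 groups and 50,000 paired-end
fragments — large enough that every code path (ambiguity, bias learning,
partitioned execution) is exercised with stable statistics, small enough
that the full suite runs on a laptop in minutes. Unit tests use the same
generators at 45–60 targets and a few thousand fragments.

## Known limitations

* Substitution-only: indel-containing alignments are dropped at
  preprocessing.
* Single-end fragments contribute no fragment-length information and
  only a 5' bias weight.
* The rescue method is provided as a reference/diagnostic, not a fast
  path; it equals one E-step initialized at the unique-count abundance
  estimate.
* The worker pool is process-local. The broadcast/accumulate contract
  (read-only snapshots, additive accumulators, ordinal reduction) is the
  part that would carry to a real cluster; scheduling, fault tolerance
  and distributed storage are out of scope.
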