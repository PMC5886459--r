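---
title: "Model and methods: decoding pooled haplotypes by coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: decoding pooled haplotypes by coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolphase)
```

## The model

A pooled sample contains amplicons from $n$ individuals (here $n = 3$)
mixed at known concentrations $r_1{:}r_2{:}r_3$, normalized to frequencies
$f_h = r_h / \sum_j r_j$. Under the core assumption — that read coverage is
proportional to input concentration, and that local coverage fluctuations
affect all pool members proportionally — the haplotype of origin of a read
is informative through coverage shares alone.

The alignment of reads to a reference is scanned with a sliding window of
$w$ columns. In each window the reads that fully span it are grouped by
their (gapped) window sub-sequence and the three most frequent
sub-sequences are retained with their counts $(c_1 \ge c_2 \ge c_3)$,
together with the residual count $c_e$ of spanning reads carrying any
other sub-sequence. The observation at a window is the count vector
$(c_1, c_2, c_3, c_e)$.

**States.** A hidden state is an assignment $a \in \{1,2,3\}^3$: $a_h$ is
the sub-sequence carried by haplotype $h$, giving $3^3 = 27$ states.
Haplotypes assigned the same sub-sequence are locally identical, so state
$a$ implies expected category proportions

$$p_c(a) = (1 - \varepsilon) \sum_{h:\,a_h = c} f_h, \qquad
  p_e = \varepsilon,$$

with $\varepsilon$ a small expected fraction of off-category (error)
reads. For 1:2:5 the reachable proportion patterns are exactly the merged
expectations of the design — $\{.125,.25,.625\}$, $\{.375,.625\}$,
$\{.25,.75\}$, $\{.125,.875\}$, $\{1\}$ — all distinct, which is what
`pool_scheme()` validates (and warns about when violated, as happens for
designs such as 1:1:1).

**Emissions.** Counts are modelled Dirichlet-multinomially,
$\mathbf{c} \sim \mathrm{DM}(\alpha_c = s \cdot p_c(a))$, where the scale
$s$ is a smoothed regional coverage: a triangular weighted mean of the
total window coverage over the trailing 400 alignment positions (weights
decay linearly from the most recent position to zero at the span edge;
renormalized near the start boundary). Tying the concentration to local
depth makes the model exactly multinomial-informative when coverage is
stable and increasingly overdispersed where coverage drifts — the known
failure mode of coverage-based indexing. Zero-probability categories get a
concentration floor ($10^{-3}$) so that stray counts remain representable
rather than annihilating a path.

**Transitions.** Between consecutive windows the sub-sequences assigned to
each haplotype must agree on their overlapping columns. With window step
$t$ the overlap is $L = w - t$ columns; the transition penalty uses
$D$, the Hamming distance (gap counted as a fifth symbol) summed over
haplotypes between the overlap of the sub-sequence assigned in the current
window and that assigned in the next:

$$\log P(a \to a') \propto D \log \mu + (3L - D)\log(1 - \mu),$$

normalized over the 27 destination states. $\mu$ is a per-base mismatch
rate (default 0.01). This is the simplest probabilistic reading of a
summed-Hamming-distance penalty; it makes assignment switches cheap
exactly where the retained sub-sequences genuinely change and expensive
where they do not.

**Seed and decoding.** Decoding starts at the window where three distinct
sub-sequences best match the design frequencies under a plain multinomial
likelihood, rank-matching counts to frequencies (smallest count with the
smallest frequency). At that window the state is fixed to the rank-order
assignment — the $k$-th most frequent sub-sequence belongs to the $k$-th
most concentrated haplotype — which is precisely the configuration the
seed search certified. The Viterbi algorithm then runs once toward each
end of the alignment; the two half-paths share the seed window and are
joined. Each haplotype's sequence is assembled by column-wise majority
vote over the sub-sequences assigned to it in all decoded windows
(deterministic tie-break in fixed symbol order), gap columns are dropped,
and columns never covered by a decoded window become `N`.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_size` | 50 | alignment columns | wide enough to hold a discriminating variant at ~1% divergence, narrow enough to track local coverage |
| `window_step` | 1 | columns | one observation per position; larger steps trade resolution for speed |
| `regional_span` | 400 | nucleotides | coverage smoothing horizon; shorter spans track drift faster but overfit noise |
| `mismatch_rate` | 0.01 | per base | transition mismatch rate between consecutive overlaps |
| `error_rate` | 0.005 | fraction | expected off-category read mass (sequencing/mapping noise) |
| `alpha_floor` | 1e-3 | concentration | keeps zero-probability categories representable |
| `ratios` | 1:2:5 | — | the pool design; any positive vector with distinct subset sums works |

The error category deserves a note: the three-category coverage model is
extended with an explicit fourth category so that spanning reads outside
the retained sub-sequences have a home. Without it, any window containing
a sequencing-error read would receive zero likelihood. Because the error
category's expected mass is the same under every state, it does not
distort state discrimination; it only absorbs residual counts.

## The simulator

`sim_config()` / `make_haplotypes()` / `simulate_pool()` generate: a
uniform-random reference; haplotypes diverged from it by independent
per-site substitutions (default 1%, matching closely related mitochondrial
haplotypes; optional 1 bp indels, default off); and paired 2x151 bp reads
whose fragment is assigned to a haplotype with probability equal to the
design frequency. Fragment starts are drawn over a range extended by one
read length beyond each amplicon end and clipped, so amplicon ends keep
coverage — the analogue of end-anchored fragments produced when an
amplicon is fragmented. Sequencing error is a uniform per-base
substitution (default 0, study settings use 0.2%); qualities are constant
Q30. The SAM emitted carries the true sampling coordinates, so the decoder
can be exercised without an external mapper.

What the simulator deliberately does **not** model: GC-dependent and
motif-dependent coverage bias, quality-dependent error profiles, mapping
loss in diverged regions, chimeric reads, and pipetting error in the pool
proportions. Passing tests therefore demonstrate correctness of the
decoding machinery under proportional coverage — they do not certify
performance on real libraries, where coverage bias that hits pool members
unequally is the dominant risk.

## Numerical choices and degenerate inputs

* All probabilities are handled in log space; emission and transition
  vectors are checked (in tests) to normalize to 1 within $10^{-9}$.
* Ties: equal window counts rank N-free sub-sequences first, then break
  lexicographically; equal seed likelihoods take the leftmost window;
  equal Viterbi scores take the lowest state index; equal column votes
  take the earliest symbol in `A,C,G,T,N,-`. Every run is therefore
  deterministic — all stochasticity lives in the simulator seeds.
* Windows with zero spanning reads are skipped; a run of skipped windows
  breaks the Markov chain, which restarts emission-only at the next
  observed window, and uncovered columns are reported as `N` rather than
  guessed.
* Windows with fewer than three retained sub-sequences are decoded
  normally (absent categories carry zero counts; an assignment pointing
  at an absent sub-sequence is Hamming-penalized maximally in
  transitions).
* If no window shows three distinct sub-sequences (haplotypes identical
  over the amplicon) the seed search fails with an explicit error rather
  than decoding an undecodable design.
* In `filter_reads()` both mates are dropped when either fails, keeping
  paired files coherent; the filter is idempotent.
* Lane counts in the cost model use an epsilon-tolerant ceiling so a
  mathematically exact full lane is not split by floating-point noise.
* The error metric aligns globally with unit mismatch and gap costs
  (opening 0, extension 1) and divides mismatches + indels by the truth
  length; `N` counts as a mismatch.
* Sub-sampling arithmetic uses 300 effective nucleotides per read pair
  and nearest-integer rounding.

## Problem sizes in the test-suite and acceptance runs

Simulation-backed checks use a 2,000 bp amplicon (the simulator default is
5,000 bp, a typical long-amplicon size) with 10 replicates per setting:
error-free pools at 50x/100x/250x must be recovered exactly, and noisy
pools (0.2% per-base error) are compared at 10x/20x/50x versus
100x/200x/500x on matched seeds. The exhaustive Viterbi cross-check runs
100 random instances of up to 6 windows with 2 haplotypes and 2
sub-sequences (4 states), where complete path enumeration is feasible.

## Known limitations

* Designed and validated for pools of three; the state space generalizes
  (`enumerate_states()` is generic and the decoder takes any scheme), but
  decoding quality for larger pools (e.g. 1:2:4:8, whose merged
  proportions nearly collide at 46.67% vs 53.3%) is not validated here.
* Decoding is Viterbi-only; no posterior (forward-backward) confidence is
  reported per window.
* Reconstruction quality degrades where haplotypes are locally identical
  over long stretches and coverage noise mimics a different merged
  pattern; with low coverage the lowest-proportion haplotype is the first
  to suffer, since its absolute read count is smallest.
* The mapper is out of scope: the package consumes SAM (or its own
  simulator's truth SAM). Mapping loss in highly diverged regions will
  bias local proportions before the model ever sees them.
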