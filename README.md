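# poolphase

Reconstruct individual haplotype sequences from a pooled amplicon
sequencing sample in which each haplotype was mixed at a known, distinct
concentration — without per-individual barcodes.

## The problem

Amplicon sequencing of many individuals usually pools everyone on one lane
and tells the reads apart with per-sample barcodes, but each barcode costs
a library preparation. If instead the amplicons of (say) three individuals
are mixed at concentrations 1:2:5, each haplotype is marked *a priori* by
an expected share of the read coverage — 0.125, 0.25 and 0.625 — and those
shares can be used to assign reads back to individuals. Locally identical
haplotypes simply merge their coverage: any subset of haplotypes that
shares a sub-sequence is expected at the sum of its members' frequencies
(for 1:2:5 the attainable merged proportions 0.375, 0.75, 0.875 and 1 are
all distinct, which is what makes the design decodable).

## The method

`poolphase` implements the full decoding pipeline:

1. **Gap-consistent pileup.** Mapped reads (SAM) are stacked against the
   reference; every insertion found in any read opens a shared gap column
   in all rows, so alignment columns are comparable across reads
   (`load_sam()`, `gapped_alignment()`).
2. **Windowed observations.** A 50-column window slides along the
   alignment; at each position the (at most) three most frequent read
   sub-sequences and their coverages are extracted (`window_iterator()`).
3. **Seed window.** The decoder starts where three distinct sub-sequences
   best match the design frequencies under a multinomial likelihood,
   rank-matching counts to frequencies (`find_start_window()`).
4. **Hidden Markov model.** Hidden states are the 27 assignments of the
   three sub-sequences to the three haplotypes. Emissions are
   Dirichlet-multinomial over the category counts (three sub-sequences
   plus an error category), with concentrations proportional to a
   triangularly smoothed regional coverage over the trailing 400
   positions. Transitions penalize the summed Hamming distance between the
   sub-sequences assigned to each haplotype in consecutive overlapping
   windows. The Viterbi algorithm decodes the state path in both
   directions from the seed and the two half-paths are joined
   (`reconstruct_haplotypes()`).
5. **Evaluation and design tools.** Global-alignment error rate against
   known truth (`evaluate_reconstruction()`), coverage sub-sampling
   arithmetic (`subsample_count()`, `subsample_reads()`),
   quality-weighted consensus calling (`consensus_call()`), a paired-read
   pool simulator with ground-truth SAM (`simulate_pool()`), and a
   pooled-versus-barcoded sequencing cost model (`cost_model()`,
   `savings_percent()`).

## Worked example

Simulate a 1:2:5 pool of three haplotypes (2 kb amplicon, 1% divergence,
0.2% per-base sequencing error, 50x/100x/250x depth) and reconstruct them:

```r
library(poolphase)

scheme <- pool_scheme(c(1, 2, 5))
scheme
#> Pool mixing design: 1:2:5
#> Expected read proportions: 0.125 0.250 0.625

cfg  <- sim_config(ref_length = 2000, divergence = 0.01,
                   depth_lowest = 50, per_base_error = 0.002, seed = 1)
haps <- make_haplotypes(cfg)
sim  <- simulate_pool(haps, cfg)
aln  <- pool_alignment(sim)   # or load_sam("reads.sam", reference)
aln
#> Gapped alignment: 5298 reads over 2000 columns ( 2000 reference bases, 0 insertion columns )
#> Mean depth: 400  max: 706

fit <- reconstruct_haplotypes(aln, scheme)
fit
#> Pooled-haplotype reconstruction (Dirichlet-multinomial HMM)
#> Design 1:2:5  haplotypes: 3
#> Windows decoded: 1951  seed window at column 884
#> Path log-likelihood: -55162.4
#> Sequence lengths: H1=2000 H2=2000 H3=2000

evaluate_reconstruction(fit, haps$haplotypes)
#>   haplotype mismatches insertions deletions truth_length error_rate
#> 1        H1          0          0         0         2000          0
#> 2        H2          0          0         0         2000          0
#> 3        H3          0          0         0         2000          0
```

All three haplotypes — including the one contributing only 12.5% of the
reads — are recovered exactly. `error_rate` is mismatches plus indels
divided by the truth length, so 0 means perfect recovery.

The cost model compares the pooled design against one-barcode-per-individual
sequencing; with MiSeq-style parameters (20M reads/lane, 150 bp reads,
$2000/lane, $50/library, 5 kb target at 1000x):

```r
savings_percent(51)
#> [1] 37
```

A command-line wrapper over the same functions ships in
`inst/scripts/poolphase.R` with subcommands `simulate`, `filter`,
`reconstruct`, `evaluate`, `subsample` and `cost`.

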