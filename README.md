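# ligbias

Quantify the sequence preference of single-stranded DNA (ssDNA) ligases, and
explain it kinetically.

ssDNA ligases (T4 RNA ligase relatives such as TS2126 RNA ligase, CircLigase
II, and the recently characterized Tph ssDNA ligase) join a 5′-phosphorylated
*donor* to the 3′-OH end of an *acceptor*. Two properties of these enzymes
matter for sequencing library preparation, and this package implements the
computational analysis of both:

1. **Terminal-nucleotide ligation bias.** When a randomized 40-mer (N40) is
   ligated to a fixed adaptor and sequenced, the base composition near the
   ligation junction deviates from the pool composition. For junction-proximal
   position *p* and base *b*,

   ```
   enrichment(p, b) = freq(p, b) / baseline(b)
   DB(p)            = max_b enrichment(p, b) / min_b enrichment(p, b)
   ```

   where `baseline(b)` is the mean composition of the 30 distal window
   positions (this normalization absorbs batch-dependent composition skew of
   synthesized oligo pools). `DB`, the *degree of bias*, is 1 for an unbiased
   enzyme; the headline DB is reported at position 1, the junction-adjacent
   base.

2. **Adenylation-limited kinetics.** The ligase mechanism has three
   reactions: (1) self-adenylation `E + pppA -> EpA + PPi`, (2) adenylyl
   transfer `EpA + pD -> E + AppD`, (3) ligation of the adenylated donor
   `AppD + R -> RpD + pA`, catalyzed by the *free* enzyme only. Because the
   adenylated enzyme cannot perform step 3, adenylation-proficient ligases
   self-inactivate at high ATP, while a low-adenylation enzyme keeps ligating.
   `simulate_kinetics()` integrates the mass-action model
   (`v1 = k1(1+αR)·E·pppA`, `v2 = k2(1+αR)·EpA·pD`, `v3 = k3·E·AppD·R`) and
   `preset_params()` provides parameter sets for the two enzyme classes.

The package also maps **strand-biased read depth**: unsealed lagging-strand
(Okazaki) fragments from ligase-deficient *cdc9* yeast switch their strand of
origin at replication origins; `binned_strand_depth()`, `smooth_score()` and
`call_transitions()` turn stranded BED reads into origin-candidate calls, and
`gc_bias_profile()` profiles GC-content-dependent coverage. A synthetic-data
module (`generate_pool()`, `simulate_ligation()`, `generate_strand_reads()`)
emulates both assay types so the full pipeline is testable without sequencing
data.

## Worked example

Simulate a donor-side N40 bias assay in which a terminal G ligates 4× faster
than the other bases, with 1% of the 200,000-molecule pool ligated (the
low-extent regime), then run the bias analysis:

```r
library(ligbias)
run_simulate_reads(n_pool = 200000, w_terminal = c(A = 1, C = 1, G = 4, T = 1),
                   f = 0.01, anchor = "AGATCGGAAGAGC", side = "donor5", seed = 3,
                   out_fastq = "assay.fastq")
#> simulate-reads: 2000 of 200000 molecules ligated -> assay.fastq
res <- run_calc_bias("assay.fastq", "AGATCGGAAGAGC", side = "donor5",
                     out_prefix = "assay")
#> calc-bias: 2000 reads, 2000 anchored, headline DB = 4.181
round(res$profile$enrichment[1:3, ], 3)
#>          A     C     G     T
#> [1,] 0.541 0.618 2.261 0.557
#> [2,] 1.026 1.004 0.955 1.017
#> [3,] 0.980 1.048 0.955 1.019
```

The position-1 G enrichment (2.261) matches the analytic low-extent limit
`(4/7)/(1/4) = 16/7 ≈ 2.286` up to Monte-Carlo noise, and the headline DB
(4.181) approaches the weight ratio 4; positions ≥ 2 are unbiased (DB ≈ 1),
as `assay.db.tsv` shows:

```
position  db       zero_cell_flag
1         4.18107  FALSE
2         1.07388  FALSE
3         1.09756  FALSE
```

The kinetics of an adenylation-deficient (SDL-like) enzyme across ATP levels:

```r
run_kinetics(preset = "adenylation_deficient", out_prefix = "kin")$summary
#>   atp       RpD         AppD       pD
#> 1   0 0.3620795 5.273085e-05 1.637868
#> 2  50 0.4087124 1.020391e-04 1.591186
#> 3 500 0.7357430 5.586956e-04 1.263698
```

Product (`RpD`, µM) forms at every ATP concentration — even at 0 µM, from the
pre-adenylated enzyme fraction — and the adenylated donor (`AppD`) stays
below 0.03% of the donor, the signature of an adenylation-limited but
ligation-proficient enzyme.

A shell entry point wrapping the same functions ships with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "ligbias", package = "ligbias"))') \
  calc-bias --reads assay.fastq --anchor AGATCGGAAGAGC --side donor5 --out-prefix assay
```

Subcommands: `calc-bias`, `simulate-reads`, `simulate-strand`, `kinetics`,
`strand-bias`, `gc-bias`; every run writes a JSON manifest with flags, seed,
input checksums and version for reproducibility.

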