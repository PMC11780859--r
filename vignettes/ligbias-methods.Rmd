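---
title: "Methods: quantifying ssDNA ligation bias, ligase kinetics and strand-biased coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ssDNA ligation bias, ligase kinetics and strand-biased coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligbias)
```

This vignette is the package's account of its models and numerical choices:
what is computed, under which assumptions, with which defaults, and what the
synthetic-data generators do and do not emulate.

## 1. The degree-of-bias statistic

Single-stranded DNA ligases prefer certain terminal nucleotides. The assay
that measures this ligates a chemically synthesized oligo with a randomized
40-base stretch (N40) to a fixed adaptor and sequences the products. Reads
are anchored on the adaptor (`anchor_and_extract()`), and the randomized
window is re-indexed so that position 1 is always the base adjacent to the
ligation junction and position 40 the most distal, regardless of whether the
randomized side is the donor's 5′ end (`side = "donor5"`) or the acceptor's
3′ end (`side = "acceptor3"`). This side-agnostic coordinate system lets the
same statistics serve both assay layouts.

For each window position $p$ and base $b$, `nt_composition()` counts
occurrences. Two normalizations follow:

* **Baseline** (`distal_baseline()`): the unweighted mean of the
  per-position frequency vectors over the 30 most distal positions,
  renormalized to sum 1. Chemically synthesized oligo pools differ in base
  composition between batches; positions far from the junction see no
  selection, so their composition estimates the pool composition.
* **Enrichment** (`proximal_enrichment()`): for the 10 junction-proximal
  positions, $e_{p,b} = f_{p,b} / \text{baseline}_b$. By construction the
  baseline-weighted mean of enrichments at any position is exactly 1.

The **degree of bias** at position $p$ is
$\mathrm{DB}(p) = \max_b e_{p,b} / \min_b e_{p,b} \ge 1$, and the headline
DB is $\mathrm{DB}(1)$. Published analyses sometimes quote a single DB for a
multi-position pattern (e.g. acceptor-side enrichment spanning the terminal
five bases); because it is ambiguous whether such a figure is the position-1
value or an aggregate, the package reports the full per-position DB table
and fixes the headline at position 1, the junction-adjacent base.

Numerical choices:

* **N handling.** An N at position $p$ removes the window from position
  $p$'s denominator only (tallied in `n_excluded_N`), maximizing data use
  while keeping totals reconcilable.
* **Pseudocounts.** None by default — the default reproduces the plain
  frequency-ratio definition. A zero enrichment cell makes DB infinite
  (flagged, not silently clamped); `pseudocount > 0` adds the value to every
  count cell and is the documented escape for sparse data.
* **Window layout.** W = 40 = 10 proximal + 30 distal by default, matching
  the N40 assay; all three are arguments.
* **Anchor search.** Hamming-distance scan, no indels (adaptors are short
  fixed synthetic sequences; indel handling would add failure modes without
  need at this scale). The best hit wins; ties on the minimum mismatch count
  make the read *ambiguous* and it is dropped, never guessed. Reads are
  uppercased; characters outside A/C/G/T/N drop the read with its own tally
  so that the report always reconciles:
  `n_total = n_anchored + n_no_anchor + n_ambiguous + n_short + n_bad_char`.
* **Orientation.** Some sequencing configurations report the strand
  complementary to the assay layout; `revcomp` is therefore a user switch,
  not an auto-detection.

## 2. The synthetic bias-assay generator

The generator defines the conditions under which the statistics are
validated:

* `generate_pool(n_pool, insert_len, theta, seed)` draws i.i.d. bases from
  the pool composition `theta` (the batch-skew knob). The default pool size
  used throughout validation is 200,000 molecules of length 40 — large
  enough that counting noise on a 10 × 4 enrichment table is below 0.01,
  small enough to run in seconds.
* `simulate_ligation(pool, model, f, seed)` performs weighted sampling
  *without replacement* of $\lceil f \cdot n \rceil$ molecules, where a
  molecule's weight is the product of the `bias_model()` positional weights
  over its junction-proximal bases (default: only position 1 weighted).
  Sampling without replacement is the depletion mechanism: longer incubation
  (larger ligated fraction $f$) exhausts the preferred molecules, so the
  measured DB decreases monotonically in $f$ and reaches 1 at $f = 1$. This
  reproduces, with a single parameter, the empirical observation that
  extended incubation alleviates the bias. In the low-extent limit
  $f \to 0$ the terminal-base law is analytic,
  $p(b) \propto w(b)\,\theta(b)$: with a G weight of 4 and uniform pool,
  $p(G) = 4/7$, terminal-G enrichment $= 16/7 \approx 2.286$ and DB
  $\to 4$. These closed forms are the oracles for the acceptance tests (at
  $f = 0.01$ of a 200,000 pool, i.e. 2,000 selected molecules, the
  Monte-Carlo standard error on the enrichment is ≈ 0.045, so fixed seeds
  are part of the validation conditions).
* Implementation: selection uses exponential keys ($k_i = E_i / w_i$,
  smallest $\lceil fn \rceil$ kept), which is distribution-identical to
  sequential weighted draws without replacement but $O(n \log n)$. R's RNG
  makes this deterministic across platforms for a fixed seed.
* `emit_fastq()` assembles reads as adaptor + insert (`donor5`) or reversed
  insert + adaptor (`acceptor3`), so the insert's position-1 base always
  abuts the junction in the read and extraction recovers the generator's
  ledger exactly — the basis of the round-trip oracle tests.

What the generator does **not** emulate: sequencing errors (off by default;
bias statistics, not error correction, are the target), PCR duplicates,
quality-score structure, or bisulfite chemistry beyond the all-C→T
transform used in composition sanity checks. Passing tests therefore
validate the statistics and their estimators, not robustness to platform
artifacts.

## 3. The three-reaction kinetic model

States are concentrations (µM) of nine species: free enzyme E, adenylated
enzyme EpA, ATP (pppA), pyrophosphate PPi, phosphorylated donor pD,
adenylated donor AppD, acceptor R, product RpD and AMP (pA). Rates:

$$v_1 = k_1 (1+\alpha R)\, E \cdot \mathrm{pppA},\quad
  v_2 = k_2 (1+\alpha R)\, \mathrm{EpA} \cdot \mathrm{pD},\quad
  v_3 = k_3\, E \cdot \mathrm{AppD} \cdot R$$

Modeling decisions, made where the mechanism is stated but no rate data
exist:

* Reaction 3 is a single trimolecular step with **E (not EpA)** as catalyst
  — this is how "the adenylated enzyme cannot execute the third reaction"
  enters the model. A full enzyme–substrate complex cascade would add
  parameters that nothing at desk scale could identify.
* Acceptor stimulation of reactions 1–2 is the simplest monotone form, a
  linear multiplier $(1+\alpha R)$; $\alpha = 0$ disables it.
* The low adenylation proficiency of the SDL-like preset is modeled as low
  $k_1$. An alternative (fast reverse adenylation) would produce similar
  phenomenology; absent data to separate them, the one-parameter version is
  used.
* Default initial condition: 2 µM enzyme, 2 µM donor, 2 µM acceptor, ATP
  per titration level (0/50/500 µM) — assay-scale values with enzyme in
  stoichiometric excess of neither substrate. Both presets start with 20%
  of the enzyme adenylated (`epa0_frac = 0.2`): purified ligase preparations
  are partially adenylated, and this is what lets an adenylation-deficient
  enzyme form product even at 0 µM ATP, as observed.
* All preset rate constants are **invented** and pinned only by the
  qualitative contrasts they must reproduce: the proficient preset
  (k1 = 0.5, k2 = 1, k3 = 0.2) depletes the donor within 60 min at 500 µM
  ATP, plateaus early (RpD(480)/RpD(60) < 1.2) and yields more product at
  50 than at 500 µM ATP; the deficient preset (k1 = 10⁻⁶, k2 = 1.5 × 10⁻³,
  k3 = 1) keeps AppD under 10% of the donor at 480 min while RpD more than
  doubles between 60 and 480 min at every ATP level.

Integration uses `deSolve::lsoda` with rtol 10⁻⁹, atol 10⁻¹² over an
evenly spaced output grid (default 201 points). Four linear invariants
(enzyme, donor, acceptor, AMP moiety) are monitored by
`conservation_drift()`; observed drift is ~10⁻¹⁵, far inside the 10⁻⁸
acceptance bound, and RpD = pA holds identically when AMP starts at 0. The
$k_1 = 0$ reduction with symmetric AppD/R start has the closed form
$\mathrm{RpD}(t) = c - c/(1 + k_3 E_0 c t)$, used as an independent
integration oracle (agreement ≤ 10⁻⁹ relative on a 50-point grid).

## 4. Strand-biased coverage and origin calling

Unsealed lagging-strand fragments switch their strand of origin at
replication origins. The analysis:

1. `binned_strand_depth()`: midpoint binning (fragments are short, so
   spreading coverage across bins adds nothing but blur), separate +/−
   tallies, per-bin score $(plus-minus)/(plus+minus) \in [-1, 1]$, `NA`
   where both strands are 0. Undefined bins are **excluded**, never imputed
   — imputation fabricates signal in coverage gaps.
2. `smooth_score()`: centered moving average over defined bins only.
3. `call_transitions()`: a call is a sign change flanked by at least
   `min_run_bins` defined bins of consistent sign on each side, with
   amplitude — the difference of the mean smoothed score over the
   `min_run_bins` flanking bins on each side — at least `min_amp`.
   Measuring the amplitude on the flanking runs rather than on the two
   adjacent bins matters because smoothing turns a step into a ramp whose
   adjacent-bin increment is only ~2/window; for an unsmoothed clean ±1
   step the definition reduces to amplitude 2. The position is the midpoint
   of the flanking bin centers; the direction ("up" = minus-to-plus)
   distinguishes origin-type switches from the opposite-direction switches
   at fork-convergence (termination) zones midway between origins, which
   are genuine features of the pattern, not false calls.

Defaults for the yeast-scale use case — bin 100 bp, smoothing window 15
bins, `min_amp` 0.5, `min_run_bins` 5 — are package choices (no published
algorithm exists for this display-style analysis); all are arguments. Under
the validation scenario (300 kb genome, 3 origins, 50,000 reads, 10% strand
noise, ≈ 17 reads/bin) the smoothed plateau score is ± 0.9 with ≈ 0.03
noise, so recovery within ± 2 bins with zero false origin-direction calls
has a wide margin.

The strand-read generator assigns each uniformly placed midpoint the
polarity of its *nearest* origin (`left_plus`/`left_minus` is a
configuration: the mapping of lagging-strand reads onto Watson/Crick is
dataset-dependent) and randomizes the strand with probability
`noise_frac`. It does not model replication timing, fork stalling, or
origin efficiency — transitions in real data are shallower and asymmetric,
so recovery rates here bound the clean-signal behavior only.

`gc_bias_profile()` groups genome bins by GC-fraction deciles (quantile
breaks, collapsed when the GC distribution is degenerate) and reports mean
depth per group normalized by global mean depth; groups with fewer than 10
bins are flagged rather than dropped.

## 5. Interfaces, determinism, problem sizes

Every `run_*()` wrapper writes a JSON manifest (subcommand, flags, seed,
input MD5s, package version, timestamp); re-running with the manifest's
flags reproduces outputs bit-identically. Gzip input is detected by magic
bytes, not file extension. All tables are TSV with headers and 6
significant digits; genomic tracks are 0-based half-open bedGraph.

Validation problem sizes were chosen so the whole suite runs in well under
a minute per stage: 200,000-molecule pools for bias statistics (counting
noise ≤ 0.01 per enrichment cell), 481-point grids over 480 min for
kinetics, and a 3,000-bin genome with 50,000 reads for origin recovery.
Larger inputs change nothing structurally; all stages are linear in reads
or bins except ligation sampling ($O(n \log n)$).

## Known limitations

* DB is a point estimate; the package deliberately provides no significance
  test for bias (the estimator's noise floor is documented above instead).
* The kinetic model is minimal mass action: no reverse reactions, no
  enzyme–substrate complexes, no temperature dependence, no PEG/crowding
  effects; rate constants are qualitative-class placeholders, not fits.
* The ligated-fraction parameter $f$ maps to incubation time only
  qualitatively; the package makes no claim about the $f(t)$ curve.
* BAM input is out of scope by design: strand analysis consumes BED6
  (convert upstream with `bedtools bamtobed`), keeping the module testable
  without alignment machinery.
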