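---
title: "Inferring monosynaptic networks from viral genomic barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring monosynaptic networks from viral genomic barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbctrace)
```

## The measurement

Monosynaptic tracing with glycoprotein-deleted rabies virus starts in
"starter" cells — postsynaptic cells engineered (via Cre-dependent rAAVs)
to express the TVA receptor and the rabies glycoprotein. EnvA-pseudotyped
rabies particles infect only TVA+ starters; each founder infection then
replicates clonally and crosses exactly one synapse retrogradely into the
starter's presynaptic partners. When every particle carries a random 20-bp
viral barcode (VBC) in the 3′ UTR of its EGFP gene, the barcode is a clonal
label: cells that share a barcode were, with the right caveats, infected by
one clone that entered through one starter. Single-cell RNA-seq reads out,
per cell, the barcodes (with UMIs), the host transcriptome (cell typing),
the rAAV-derived transcripts (starter identification), and the rabies genes
(infection load).

The caveats are the substance of this package:

1. **Sequencing errors masquerade as barcodes.** PCR and sequencing
   substitutions surround every true barcode with a cloud of low-abundance
   "sibling" sequences, and strand-displacement chimeras re-attach a read's
   UMI to the wrong barcode within a cell.
2. **Abundant barcodes lie.** A barcode frequent in the infecting library
   can seed founder infections in several starters, conflating their
   networks. Only barcodes rare enough to have entered the experiment once
   define a *unitary clonal infectivity path* (uCIP).
3. **Some barcodes misbehave empirically.** Barcodes absent from the
   sequenced library yet recurrent across cells, or recurrent far beyond
   their library frequency, or co-packaged as concatemer pairs, must be
   excluded on evidence from no-spread control experiments.

## Error correction

**Library collapse.** Barcodes are swept from most to least abundant; each
unclaimed barcode becomes a family parent and the family grows breadth-first
through sequences within Hamming distance 1 of any member, iterating until
no new sibling appears. The family inherits the parent's sequence; UMIs
pooled on a parent are deduplicated with the same scheme (radius 1).
Abundance ties break lexicographically, making output order-invariant. The
implementation enumerates candidate neighbor pairs by hashing sequences
under every position mask (exact for the radius used); the test suite
checks it against an independent brute-force oracle that builds the full
distance graph.

**Within-cell collapse.** Per cell, entries passing the pre-collapse UMI
threshold (5 UMIs on v3 chemistry, 3 on v2) undergo the same mutational
collapse, then a bipartite pass targets chimeras: for each barcode pair,
the fraction of the smaller barcode's UMIs matching a UMI of the larger
barcode within Hamming distance 2 is computed, and at a sharing fraction
strictly above 0.5 the smaller barcode is absorbed (UMIs transfer, then
dedupe; parents are processed most-abundant first, to a fixed point). A
final sweep guarantees no cell-UMI is counted under two barcodes. The
`ADAPTIVE` variant of the mutational radius is exposed as an
abundance-gated option (`adaptive_umi_gate`): when a cell's top barcode
reaches the gate, the radius rises by one. The default leaves it off, since
the gating rule is a judgment call and radius 1 is the documented baseline.

## The uCIP filter

For a barcode of library frequency $f$, the probability of avoiding a
second founder infection over $N$ independent founders is $(1-f)^N$. The
*founder-infection trust* inverts this:

$$\mathrm{FI\,trust}_p = \frac{\log_{10} p}{\log_{10} (1-f)},$$

the number of founder infections tolerable before a second occurrence is
expected at avoidance probability $p$ (default $p = 0.9$, i.e. a <10%
repeat risk). It satisfies $(1-f)^{\mathrm{trust}} = p$ exactly, decreases
in $f$, and — because a stricter avoidance requirement tolerates fewer
founders — decreases as $p \to 1$. A barcode set (a co-occurring pair)
takes the product of member frequencies; barcodes absent from the library
are presumed rare and imputed the smallest representable frequency, one
UMI over the library total.

$N$ itself is estimated per experiment by a birthday-collision
calibration: draw barcodes with replacement from the library's frequencies
until the number of distinct barcodes drawn matches the number of barcodes
observed in two or more cells (the spreading founders); the draw count,
medianed over 10 replicates, is the founder estimate. Candidate units
(single barcodes in ≥2 cells, pairs co-occurring in ≥2 cells) are retained
when trust exceeds that estimate; each retained unit defines a network as
the set of cells carrying all of its barcodes. Member sets that are strict
subsets of another retained network are dropped; identical member sets
merge, preferring the more specific pair-defined unit.

Exclusion lists from no-spread controls implement the empirical rules:
library-absent barcodes in more than one control starter ("felony"),
library-present barcodes exceeding their frequency-dependent occupancy
bounds (>2 cells below $10^{-6}$, >8 below $10^{-5.5}$; "misdemeanor"),
library-absent barcodes recurring across independent experiments, and
concatemer pairs. The source text gives no formula for concatemer
detection; here a pair is flagged when its control co-occurrence count
exceeds the Bonferroni-corrected binomial upper tail under independence of
the marginal per-cell rates — the simplest test consistent with "appear
together more than chance allows". The source also describes a first-stage
removal of library-abundant barcodes via a trust-score cutoff whose stated
direction is inconsistent with the formula (high abundance gives *low*
trust); rather than guess the intended rule, the pre-filter here removes
barcodes above a configurable library-frequency quantile (default 0.999)
and the main guard remains the trust-vs-founder-estimate comparison.

## Starter identification

Starters are called from transcription alone: recombined TVA-mCherry UMIs
(relative to total rAAV UMIs) and total rAAV UMIs (relative to total cell
UMIs) must both be enriched beyond chance. Each cell gets two one-sided
binomial upper-tail tests against experiment-wide background rates,
Bonferroni-corrected over cells, with both tests required at $p < 0.01$.
Background rates are estimated by a hard-assignment iteration: pool rates
over currently-unflagged cells (add-one smoothing keeps them inside
$(0,1)$), re-test, re-flag, repeat to a fixed point (≤20 iterations,
tolerance $10^{-6}$) — the simplest scheme consistent with an
"EM-like" update. The fixed point is checked invariantly: rates recomputed
on the final background reproduce the final flags. Networks then receive
at most one flagged member as their starter; none leaves the network
starter-orphaned (all members presumed presynaptic); two or more marks it
ambiguous and excludes it from starter-stratified statistics.

## Downstream statistics

* **Composition and size.** Presynaptic type composition across starter
  types uses a chi-square test on the aggregated count table; network-size
  comparisons use Kruskal–Wallis plus pairwise Wilcoxon rank-sum tests.
  Presynaptic size categories are small (2–4 ascertained cells), medium
  (5–6), large (7+).
* **DE by network size.** Within each starter subtype, small-vs-large
  comparisons run in three stages: aggregated Fisher's exact test per gene
  with ≥25 pooled UMIs (Bonferroni within subtype, cut 0.05), a per-cell
  Wilcoxon test on CP100K-normalised expression (rabies UMIs removed
  before normalisation, cut 0.05), and 100 permuted cohorts in which every
  starter profile is replaced by a random presynaptic profile of the same
  subtype — genes nominated by two or more permuted replicates are flagged
  as potentially spurious. Fold changes are log2 ratios of CP100K
  aggregates with a pseudocount of 1.
* **Infectivity screen.** Cells ordered by (externally supplied)
  pseudotime are split into 10 equal-occupancy bins (quantile bins avoid
  empties; occupancies differ by ≤1). Per bin: the infected-cell fraction,
  and a meta-control cell summing uninfected cells' UMIs normalised to
  100,000. Genes with Pearson $r \ge 0.75$ against the infected fraction
  across bins are the infectivity-correlated set; zero-variance genes are
  excluded as having undefined correlation. Control gene sets for
  enrichment comparisons are drawn either uniformly from expressed genes
  or matched per expression decile of a reference profile (a decile short
  of candidates samples with replacement, with a warning).
* **Aggregate immune score.** Mean CP100K over a supplied gene list;
  invariant to uniform count rescaling. A two-way ANOVA helper serves the
  viral-load/immune-score versus type-and-size-category tests.

## The simulator

`sim_config()` fixes the experimental conditions the package is validated
under; `simulate_library()`, `simulate_experiment()` and
`add_read_noise()` generate data with complete ground truth.

* **Library**: 1.29 million unique random 20-mers (the scale of the deeply
  sequenced library the method characterises), log-normal UMI counts with
  meanlog 1.4 and sigma 1 — giving ≈6.5 mean UMIs per barcode, matching
  the observed ≈6.4 — plus 88 planted "jackpot" barcodes strictly more
  abundant than the rest. A designated subset (default 1000 barcodes) is
  regenerated until pairwise Hamming distances are ≥3, making
  error-correction identifiability testable; real libraries offer no such
  guarantee, so collapse behaviour near distance-2 founders is *not*
  covered by these tests.
* **Infection**: 50 starter cells per simulated well, founder MOI drawn
  zero-truncated Poisson with λ = 1.5, founder barcodes drawn with
  replacement from library frequencies (so realistic collisions occur —
  at these defaults the per-well collision probability is just under 1%).
  Starter types come from a four-type catalog (glutamatergic neurons,
  interneurons, SPNs, astrocytes) whose type-specific negative-binomial
  presynaptic sizes default to means 3.6, 3.7, 6.7, 4.6. All clones of a
  starter spread into the starter's presynaptic partner set; each partner
  receives each clone with probability 0.9 (at least one).
* **Ascertainment**: presynaptic cells are captured at 25%, starters at
  2.5% — the tenfold differential starter loss that leaves most inferred
  networks starter-orphaned — yielding roughly 10% capture overall.
* **Molecules**: per (cell, clone) UMI counts are negative binomial with
  class-dependent means (neurons 100, glia 15; dispersion 2), mirroring
  the much heavier barcode transcription of infected neurons. Infected
  cells transcribe ~15% (neurons) or ~5% (glia) rabies RNA; uninfected
  cells carry 0.3% ambient rabies. Starters carry ~600 rAAV UMIs with 80%
  recombined TVA; background cells 0.5% rAAV with 2% recombined — the
  background rates the starter caller must learn. Reads per UMI are
  1 + Poisson(2); substitutions hit each base independently at 0.005 and
  chimeras swap a read's barcode within its cell at 0.01.
* **Planted effects**: optional fold-change genes in starters of large
  networks and monotone pseudotime-trajectory genes, for testing the DE
  and infectivity screens; pseudotime skews late for infected cells so
  the infected fraction rises across bins.

What the simulator does not emulate — ambient barcode contamination
between cells, doublets, empty droplets, batch effects, realistic
transcriptome covariance structure, polysynaptic or TVA-independent spread
— bounds what passing tests show about real data: they validate the
statistical machinery under the stated generative model, not robustness to
every failure mode of droplet scRNA-seq.

## Numerical and design choices

* Draws *with* replacement model independent founder infections
  (uniqueness curves, founder estimation); downsampling a library for
  comparison across depths is *without* replacement (multivariate
  hypergeometric), modelling resequencing.
* Mixed libraries namespace their barcodes by library index: "equivalent"
  libraries are independently generated barcode sets, and identical
  sequences across libraries are distinct genomes.
* All abundance ties break lexicographically; writers emit content-sorted
  rows, so every output file is byte-stable across runs.
* Thresholds are strict where the definitions are strict: infection needs
  *more than* 1% rabies UMIs; bipartite absorption needs sharing *above*
  0.5; UMI inclusion uses ≥.
* Degenerate inputs fail loudly: zero-total cells cannot be classified,
  founder targets beyond the library size are errors, a starter call that
  flags every cell reports a degenerate background, a pseudotime bin
  without control cells stops the screen.
* Test problem sizes are chosen for a laptop-scale run: the full-pipeline
  recovery check simulates three wells against the default 1.29M-barcode
  library (~40 s), the MOI calibration uses 1200 no-spread starters, the
  DE null uses two subtypes × 12 starters × 100 permuted cohorts, and the
  collapse oracle runs 100 random instances of up to 200 barcodes.

## Limitations

Pseudotime and cell-type labels are inputs, not computations; alignment
and barcode extraction from raw reads sit upstream of this package. The
founder estimator assumes the sequenced library faithfully represents the
infecting particle pool; systematic depletion of rare barcodes biases the
estimate downward. Concatemer detection and the abundance pre-filter are
reconstructions of under-specified rules, flagged above. The dataset-scale
figures of the motivating study (tens of thousands of starter profiles,
thousands of networks) depend on data external to this package; the test
suite validates the machinery on simulated conditions instead.
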