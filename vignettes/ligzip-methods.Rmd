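---
title: "Splint-ligation isoform profiling: models, design rules and decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splint-ligation isoform profiling: models, design rules and decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligzip)
```

## The problem

Genes with several distant regions of alternative splicing — mutually
exclusive cassette-exon clusters, alternative 3' splice sites — can encode
thousands of mRNA isoforms, and short sequencing reads cannot say which
choices co-occur on one molecule. Splint ligation sidesteps reverse
transcription: a pool of 40–60-nt DNA oligos ("ligamers") hybridizes along
a single RNA molecule, each internal ligamer binding the two ends of one
exon (or of a whole constitutive block) and looping out the sequence in
between. Adjacently hybridized ligamers are joined by an RNA-templated DNA
ligase, so each molecule yields one short DNA product whose sequence of
barcodes records the molecule's full combination of exon choices.
`ligzip` implements the computational side of this assay: thermodynamic
arm design, pool planning, isoform and product-index enumeration, control
simulations, read decoding, and coordination statistics.

## Duplex thermodynamics

Arm trimming and specificity screening rest on two quantities computed by
the `thermo` functions:

* `melting_temp()` — nearest-neighbor two-state Tm of a sequence against
  its perfect complement: summed stack enthalpies/entropies with terminal
  initiation terms (unified DNA parameter set of SantaLucia 1998), the
  entropic salt correction $\Delta S' = \Delta S + 0.368\,n\,\ln[\mathrm{Na^+}]$,
  and $T_m = 1000\,\Delta H / (\Delta S' + R \ln(C_T/4)) - 273.15$.
* `duplex_free_energy()` — $\Delta G$ at a stated temperature (default
  37 °C) for a probe aligned gap-free to a target region; stacks touching a
  mismatched position contribute no nearest-neighbor term and incur a
  uniform penalty (default +1 kcal/mol per mismatched stack).

Defaults are 50 mM monovalent salt and 500 nM total oligo, exposed through
`duplex_params()`. DNA:RNA hybrid duplexes are approximated with DNA:DNA
parameters; `parameter_table_id` accepts any substitute table shipped in
the same plain-text format. All design decisions in this package are
threshold-relative (trim *until* Tm ≤ 65 °C; flag when a free-energy *gap*
is small), so any consistent, monotone duplex model preserves the
behavior; absolute ΔG values from different literature parameterizations
will differ, and the published −67/−36 kcal/mol figures for one specific
receptor gene are not reproduced numerically.

One subtlety the tests document: appending a perfectly pairing nucleotide
always makes ΔG more negative, but Tm is *not* strictly increasing —
exchanging the terminal initiation term when a weak A·T pair follows a
G·C end can lower Tm by up to ~1 °C. The trimming scans therefore evaluate
every candidate length rather than assuming monotonicity.

## Ligamer design rules

* **Terminal ligamers** anchor the two ends of the profiled span. The arm
  is the longest prefix/suffix of its region whose Tm does not exceed
  `tm_max` (65 °C), found by trimming from the side away from the ligation
  junction; the PCR primer tail is appended on the outward side. Regions
  that never reach the threshold return the full-length arm flagged
  `exhausted`.
* **Internal ligamers** bind the beginning and end of their target with
  the barcode opposite the loop. Both arms must fall in the 60 ± 5 °C
  window and the whole oligo must stay within 60 nt including the barcode.
  The search trims from the inside of the target outward, fixes the
  upstream arm at the longest feasible length that leaves room for a
  feasible downstream arm, then maximizes the downstream arm — a
  deterministic tie-break the tests verify against exhaustive enumeration.
  When both arms sit on one exon their combined footprint is additionally
  capped at the exon length so they cannot overlap.
* **Pool planning** emits one terminal ligamer per end, one internal
  ligamer per variant exon (a skip outcome adds none; its neighbors become
  ligation-adjacent), and one internal ligamer per interior constitutive
  block. Hence 2 + #variants + #separating blocks ligamers; a
  three-cluster 12/48/33 model with two separating blocks needs 97.
* **Barcodes** are random codes (default 7 nt) with pairwise Hamming
  distance ≥ 3 and no homopolymer above 3, generated reproducibly from a
  seed. Every internal ligamer is barcoded and barcodes are unique across
  the whole experiment — this makes product sequences injective and lets
  the decoder anchor on them. In dual-coded designs (`plan_dual_pools()`)
  *every* internal ligamer carries a different code in the two pools, a
  superset of the published two-exons-per-cluster coding chosen so that
  any cross-pool chimera is detectable by construction.
* **Specificity screening** replaces a genome-alignment check with a
  deterministic exact/1-mismatch substring search of every arm against the
  supplied transcript set, plus a free-energy comparison of each variant
  ligamer against every variant in its cluster. The report flags ligamers
  whose cognate-vs-nearest-near-cognate gap falls below `dg_gap_min`
  (default 5 kcal/mol — deliberately conservative relative to the ≥ 12
  kcal/mol gaps reported for a real cluster).

Ligamer arms are stored in the sense (target) orientation and products are
reported in target-RNA coordinate order; the physical oligo is the reverse
complement of the stored string. This keeps design, indexing and decoding
in a single coordinate system and changes no thermodynamic quantity.

## Isoform space and the product index

`enumerate_isoforms()` forms one key per combination of variant choices
(product of cluster sizes; skip counts as one outcome), and
`build_product_index()` assembles, for each isoform, the unique ligamer
chain whose hybridization footprints abut along that isoform, erroring on
any coverage gap. Per product it records the concatenated sequence, the
RNA span from first to last hybridized base (primer tails excluded), and
the fold compression span/length. A per-variant `exclude` argument lets
one build both the full space and a space without a known pseudo-exon
(12 × 48 × 33 = 19,008 vs 12 × 47 × 33 = 18,612); pools still target every
variant, so an excluded exon's absence from decoded data is evidence, not
an assumption.

## What the simulator emulates — and what it does not

`synth_gene()` builds models whose clusters have a tunable fraction of
conserved positions (`similarity`); expected pairwise identity is
$s + (1-s)/4$. Region termini are drawn GC-biased (60%) so that arms in
the 55–65 °C window exist at the realistic 12–25-nt lengths — the
generator emulates *designable* target sites, as a practitioner would
choose. Defaults (150-nt exons and blocks, similarity 0.75) give
seven-ligamer products of roughly 350–400 nt, the scale at which 250-nt
paired-end mates overlap at their 3' ends.

`simulate_isoform_mix()` draws molecules multinomially (e.g. the 100:10:1
control ratio); `simulate_ligation()` produces one product per molecule
with two artifact modes:

* **Template switching** (probability `switch_rate`): a single crossover
  at a uniformly chosen junction joins the 5' chain of one molecule to the
  3' chain of another (from the other pool when dual-coded). Junctions are
  restricted to those leaving a barcoded ligamer on each side, because a
  switch in an unbarcoded segment is invisible to any decoder and produces
  a sequence identical to a non-chimeric product. The mechanism is modeled
  only through its barcode signature, matching how the assay defines it.
* **Near-cognate ligation** (probability `near_cognate_rate`): one variant
  ligamer is replaced by the sibling with the smallest free-energy gap on
  the true exon. The resulting product is sequence-identical to a genuine
  product of the wrong isoform — such events are *not* detectable from a
  single product and are measured with known-input control mixtures; the
  truth ledger records them so simulations can quantify the misassignment
  they cause. (The decoder's separate `near_cognate` read status flags a
  different, detectable signature: a barcode whose flanking arms match a
  different variant, as arises in partially chimeric molecules.)

Reads are substitution-only with constant qualities; no indels,
position-dependent error profiles, PCR amplification bias, or
concentration-dependent cis/trans hybridization kinetics are modeled.
Passing tests therefore demonstrate correctness of the design/decode
logic under calibrated artifact rates, not robustness to every property
of real libraries.

## Decoding

`merge_pairs()` reverse-complements mate 2 and picks the overlap
maximizing matching bases (minimum 10 nt, mismatch fraction ≤ 0.1),
resolving overlap bases in favor of read 1 but recording every
disagreement position with read 2's base. Pairs without a qualifying
overlap are kept and counted `unassigned` — the loss is explicit.

`assign_reads()` then performs barcode-anchored decomposition:

1. locate every barcode exactly; a rescue pass allows one mismatch, which
   the Hamming-distance ≥ 3 code design keeps unambiguous;
2. keep an anchor only when the read context flanking it matches its
   ligamer's arms within `max_mismatch_per_segment` (default 2) — this
   discards chance hits inside arms; an anchor whose flanks instead match
   a *different* variant's arms marks the read `near_cognate`;
3. anchors from both pool codings co-occurring mark the read `switched`;
4. otherwise the ordered anchors name a chain looked up in the product
   index; with exactly one candidate, the read is verified arm by arm
   (mismatches where the mates disagreed but read 2 agrees with the
   product are forgiven — both observations of the overlap count) and
   becomes `assigned`; several candidates give `ambiguous`, none
   `unassigned`. The given orientation is tried before the reverse
   complement; the first consistent decomposition wins.

Statuses are mutually exclusive and always sum to the read-pair count.
This replaces the published local-alignment + mapping-quality filter with
a deterministic procedure of the same intent: unique, high-confidence
assignments only. At zero error the decoder reproduces the truth ledger
exactly; at 0.5% per-base error its accuracy stays above 99%.

## Coordination statistics

`marginal_exon_freq()` computes per-cluster variant-use fractions from
assigned counts; `expected_combinations()` multiplies them into expected
frequencies of pairwise or higher-order exon combinations under the
no-coordination null (a complete set sums to 1, and marginalizing a
three-way expectation reproduces the pairwise ones exactly).
`coordination_test()` compares each observed combination count to its
expectation with a two-sided exact binomial test at n = total assigned
reads and Benjamini–Hochberg correction, flagging q ≤ 0.05. The published
analysis fed expected-vs-observed pairs to a count-dispersion package
intended for two-condition comparisons, with an unstated dispersion
procedure; the exact binomial substitution is fully specified, testable,
and appropriate because the expectations here are deterministic functions
of the marginals. Combinations with expected count < 1 are annotated
`low_power` rather than dropped. Under a simulated independence null the
fraction of replicates with any flag stays below 0.07 at q ≤ 0.05.

`replicate_correlation()` reports Pearson's r on log(count + 1) over the
union of isoform keys with a Fisher-z p-value, the standard
replicate-agreement summary for such count tables; the pseudo-count
(default 1) is configurable since no transform was stated in the original
analysis.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open on the transcript strand.
* Isoform keys are byte-order (radix) sorted; ties never depend on locale.
* Pool design, barcode generation and every simulation are deterministic
  under their seeds; RNG state is restored after each seeded call.
* Empty regions, variant regions at the span's ends, unknown isoform keys,
  zero totals, and fewer than four shared correlation keys raise typed
  errors (`ligzip_error_*`); infeasible arm designs name the violated
  constraint (Tm window vs length bound).
* Identical variants in a cluster are legal: the screen reports a zero
  free-energy gap and flags both ligamers rather than erroring.

## Problem sizes used in tests and the acceptance script

Module tests run on 1–4-cluster models with 1–5 variants (full 12/48/33
planning and indexing are exercised once); decode batteries use a few
hundred to a few thousand read pairs per seed; the mixture-recovery check
decodes 50,000 error-free pairs; the null-calibration of the coordination
test uses 500 replicates of 2,000 counts. These sizes were chosen so every
stochastic check sits far from its decision boundary while the whole suite
stays interactive.

## Known limitations

* Tm/ΔG values are model-relative; only threshold logic is calibrated.
* No hairpin/secondary-structure screening of the looped-out RNA, no
  divalent-salt or dangling-end corrections.
* Template switching is modeled as a single crossover; multi-crossover
  chimeras and unbarcoded-junction switches are out of scope (the latter
  are undetectable in principle).
* The decoder assumes substitution-only errors; indels fail verification
  and fall into `unassigned`.
* Near-cognate products that replace a full ligamer are counted as the
  wrong isoform by any sequence-based decoder; quantifying that rate
  requires known-input controls, which the simulator provides.
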