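---
title: "Methods: clade-specific SSU rRNA assay design, screening and quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade-specific SSU rRNA assay design, screening and quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeassay)
```

cladeassay implements the computational half of a clade-specific small-subunit
(SSU, 18S) rRNA gene assay: discovering degenerate group-specific primers from
a grouped alignment, profiling their specificity by IUPAC-aware mismatch
counting, predicting PCR products and RFLP types in silico, clustering
amplicon sequences into OTUs with Kimura two-parameter (K2P) distances, and
converting qPCR cycle-threshold readings into absolute rDNA copy numbers.
The motivating use case is quantifying peritrich ciliates in environmental
water samples, but nothing in the machinery is peritrich-specific: any clade
with a conserved primer-accessible region can be targeted.

## Sequence model and degeneracy algebra

Bases are IUPAC codes held internally as 4-bit masks over {A, C, G, T}; two
codes are *compatible* when their expansion sets intersect, and a
primer-template mismatch is a position where they do not. This set-based
matching is exactly equivalent to enumerating all concrete expansions of a
degenerate primer and taking the minimum Hamming distance — a property the
test suite asserts against an enumeration oracle — but runs in constant time
per position. Inputs are upper-cased and U is mapped to T on entry; gaps are
legal only in alignments, never in primers.

GC% of a degenerate oligo uses the *expected-fraction* convention: each
position contributes the GC share of its expansion set (R contributes 1/2, S
contributes 1), which equals the mean GC% over all expansions. This is the
convention that reproduces the published GC column for the assay primers
shipped in `assay_primers()`, so it is fixed rather than configurable.

Melting temperature is method-pluggable (`"salt_gc"`, the salt-adjusted GC
formula at [Na+] = 50 mM, and `"wallace"`), computed per expansion with the
min/max reported. No implemented method is claimed to reproduce any
particular vendor's published Tm ranges: oligo-house formulas differ and the
original values' provenance is unstated, so Tm is informational here.

## Primer matching and specificity

`match_at()`/`scan_primer()` perform ungapped sliding-window matching on
both strands; minus-strand sites are reported by their plus-strand interval.
Mismatches are reported as offsets from both primer ends because the ends
are what matter chemically: a 5'-end mismatch barely perturbs priming while
a 3'-terminal one blocks extension. Indels are not modelled — specificity
evaluation in this field counts substitutions only, matching the style of
BLAST/probe-check reports. A template N is compatible with any primer base,
which can flatter a primer; the count of ambiguous template positions inside
each site is therefore carried on every match row.

`specificity_profile()` reduces a target/non-target sequence panel to the
assay designer's two headline numbers: the percentage of targets with a
perfect site and the minimum mismatch count over all non-targets. No fixed
mismatch threshold separates "match" from "mismatch" classes — published
practice treats single 5'-end mismatches as tolerable — so thresholds are
parameters everywhere, not constants.

## Primer discovery from a grouped alignment

`design_candidates()` formalizes what is usually done by eye. For every
window (default 18–26 nt, bracketing typical specific-primer lengths) it
builds a degenerate consensus from the target rows: each column keeps every
base at frequency >= `min_base_freq` (default 0.10, low enough to keep real
minor alleles and high enough to exclude sequencing noise), and a column
dominated by gaps disqualifies the window. Windows whose consensus exceeds
`max_degeneracy` 8 are dropped — larger primer pools dilute each variant at
synthesis.

Evaluation is two-stage by design. A fast screen works on alignment columns:
if some non-target already shows fewer than `min_nontarget_mm` mismatches at
the aligned offset, the window cannot achieve the required separation (the
aligned offset is one of the offsets the full scan would consider) and is
rejected; the aligned-column target coverage is used the same way as a
screening heuristic. Survivors are then re-scored by scanning the consensus
against the *ungapped* member sequences on both strands, because PCR acts on
unaligned molecules and alignment artifacts must not mask or fake binding.
All reported candidate numbers (coverage, non-target separation) come from
this ungapped stage, which is why every candidate re-checked through
`specificity_profile()` meets its claimed values. Ranking is lexicographic —
non-target separation, coverage, low degeneracy, then start column — so
output is deterministic; reverse-orientation candidates are emitted as the
reverse complement of the window consensus, i.e. as synthesized.
`map_to_reference()` converts an alignment column to an ungapped coordinate
on a named reference row, feeding the conventional `<prefix><pos><F|R>`
naming via `format_primer_name()`.

## In-silico PCR, semi-nested screening and RFLP

`predict_amplicons()` pairs plus-strand forward sites with downstream
minus-strand reverse sites under per-primer mismatch limits (default 2) and
forbids 3'-terminal mismatches by default, since a blocked 3' end is the
discriminating feature specific assays rely on. Product length uses the
inclusive-span convention — forward primer 5' base through the plus-strand
image of the reverse primer 5' base, both footprints included — which is the
convention under which the shipped assay geometry yields its published
441-bp product (see `synthetic_ssu_reference()`).

`nested_screen()` reproduces colony-PCR screening: a clone is
positive only when an inner-pair product lies entirely within an outer-pair
product of the same template. `digest()` cuts at every IUPAC-aware
recognition-site occurrence (MspI, C^CGG, is shipped as `enzyme_mspi()`);
fragment lengths always sum to the molecule length, linear or circular.
`rflp_group()` bins digest patterns with an absolute per-rank tolerance
(default 10 bp, a coarse stand-in for agarose gel resolution — the true
resolution of the original gels is unstated, so this is a documented
parameter). Grouping is greedy against first-seen representatives after a
canonical sort, making it deterministic under input permutation; note that
greedy binning has no guarantee of optimality, only of reproducibility.

## Distances and OTU clustering

`k2p_distance()` implements the K2P closed form
d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)) with transitions P and transversions
Q computed over pairwise-complete sites: any position where either sequence
has a gap *or an ambiguity code* is excluded, following the distance-tool
defaults the assay's published workflow relied on. Saturated pairs (log
argument <= 0) return `Inf` and can never merge at a finite cutoff.

`cluster_furthest_neighbor()` is complete-linkage agglomeration: merge while
the smallest maximum inter-cluster pairwise distance is at or below the
cutoff. The 99% similarity OTU convention maps to a 0.01 distance cutoff on
K2P distances. Ties are broken by the lexicographically smallest pair of
smallest member ids, and OTU indices are ordered by smallest member id, so
partitions are bit-reproducible and invariant under input permutation. The
suite checks the partition against a from-first-principles re-computation at
every step and against `hclust(method = "complete")` on tie-free matrices.
`shared_otus()` does the cross-sample bookkeeping (per-sample OTU counts,
global OTU count, which OTUs occur at multiple sites). Pooled clustering of
all samples at once is the default mode; per-sample clusterings can be run
separately and reconciled if a workflow demands it.

## qPCR model

The standard curve is the usual log-linear model C_T = k lg(copies/uL) + b,
fitted by ordinary least squares (`fit_standard_curve()`), with replicate
C_T values averaged per dilution level by default. A working assay has k < 0
(one decade of template per |k| cycles); published curves sometimes print
the slope with its sign dropped, and `efficiency()` deliberately refuses a
positive slope — E = (10^(-1/k) - 1) x 100% is only meaningful for k < 0.
A slope of -3.5187 gives 92.4% efficiency; -1/lg 2 (about -3.32) gives
100%.

Absolute quantitation chains three exact formulas: standard copy number
molecules/uL = a / (L x 660) x 6.022e23 (`molecules_per_ul()`; a the
measured concentration in g/uL, L the standard fragment length in bp, 660
g/mol/bp the mean double-stranded base-pair weight), curve inversion
copies = 10^((C_T - b)/k) (`ct_to_copies()`), and the volume chain
copies/L = copies/uL x (extract volume / template volume) x (1000 /
filtered mL) (`copies_per_liter()`). Between-sample ratios are invariant to
a common rescaling of extract volumes, which is why ratio comparisons
across samples survive unknown elution volumes. The limit of detection is
an *input* (the lowest reliably detected standard, convertible to cell
equivalents with `detection_limit_cells()`); no statistical LOD model is
fitted, because the calibration data needed for one are not part of this
workflow.

## Synthetic data: what it emulates and what it does not

The generators exist so every module can be scored against known truth.

* `generate_family()` builds target/non-target families from a shared
  random ancestor under a two-rate-class substitution process (per-site
  substitution probability, transition:transversion odds kappa:2, default
  kappa = 2). Planted sites are overwritten after background divergence, so
  site content is exact by construction: targets receive concrete
  expansions of the planted degenerate oligo (a configurable subset instead
  receives 2–4 "off-plan" mismatches), non-targets receive at least the
  planned mismatch count, with each planted mismatch drawn from bases
  incompatible with the degenerate code. Defaults (49 targets, 56
  non-targets) mirror a realistic design alignment for a ciliate subclass;
  the default 600 bp represents the primer-bearing region rather than a
  full-length gene, purely a problem-size choice.
* `generate_library()` draws clones from a template pool either
  multinomially or with exact counts, with optional single-crossover
  chimeras at a uniform breakpoint (chimeras are *labelled*, never
  detected — chimera detection is out of scope).
* `generate_dilution_series()` produces tenfold dilution ladders with
  Gaussian C_T noise around a true line (default truth: slope -3.5187,
  intercept 32.035 — a realistic published-style calibration).
* `synthetic_ssu_reference()` is a labelled synthetic stand-in for an SSU
  reference sequence: random background with the universal forward site at
  position 1, the clade forward sites at 974/979 overlapping the internal
  reverse site ending at 1004 (their real geometric relationship — the
  overlap is resolved by intersecting the three primers' base sets), and
  the distal reverse site ending at 1414, so the clade pair yields one
  441-bp product.

What the generators do **not** emulate: rRNA secondary-structure-constrained
evolution, among-site rate variation, alignment uncertainty (generated
families are gap-free, so alignment and sequence coordinates coincide), PCR
amplification bias, and multi-breakpoint chimeras. Passing recovery tests on
these simulations therefore demonstrates correctness of the algorithms under
their own model assumptions, not field performance on real environmental
libraries.

## Numerical and testing choices

* All randomness is seed-controlled; generators are pure functions of their
  spec. Test and simulation sizes were chosen once as realistic small-scale
  study conditions: 100 seeded families for planted-primer recovery (15
  targets/10 non-targets of 400 bp each), 200 seeded trials of up to 8
  sequences for the clustering oracle, 500 seeded dilution series
  (8 levels x 3 replicates, sigma_CT = 0.15) for slope-recovery bias, 1,000
  random molecules for digest conservation, and a 50-clone library with 11
  planted target clones for screening.
* Degenerate expansion is capped (default 4096) to fail loudly on
  pathological oligos instead of exhausting memory.
* K2P returns `Inf` (not `NA`) for saturated pairs so clustering can treat
  them as "never mergeable" without special cases.
* `rflp_group()` tolerance comparison is per sorted rank against the group
  representative — deterministic, order-independent, and transparent, at
  the cost of not being a globally optimal binning.
* The command-line layer (`cli_main()`, `inst/cli/cladeassay.R`) is a thin
  shell over the exported functions; every threshold is echoed into output
  headers and input digests are logged to stderr, so a run can be
  reproduced from its artifacts alone. Exit codes: 0 success, 2 usage
  error, 3 missing/invalid input.

## Known limitations

Ungapped matching cannot see indel-mediated binding differences;
thermodynamic (nearest-neighbour duplex) modelling is absent, so predicted
specificity is a mismatch count, not a binding energy; the RFLP tolerance
is a crude gel model; and the qPCR layer starts at C_T values — raw
fluorescence processing, melt-curve analysis and MIQE-style reporting are
out of scope.
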