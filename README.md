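# cladeassay

Design and evaluation of clade-specific SSU rRNA gene PCR and qPCR assays.

Molecular surveys of specific microbial eukaryote groups (the motivating
case: peritrich ciliates in environmental water samples) hinge on one
engineered object — a pair of clade-specific 18S rDNA primers — and a chain
of routine but error-prone calculations around it. `cladeassay` implements
that chain end to end for R users:

* **Degeneracy algebra** — IUPAC-aware reverse complement, expansion,
  expected GC% and Tm ranges of degenerate oligos
  (`reverse_complement()`, `expand_degenerate()`, `gc_content()`,
  `melting_temperature()`).
* **Primer discovery** — sliding-window degenerate-consensus design over a
  grouped multiple alignment with coverage and non-target-separation
  thresholds (`design_candidates()`, `map_to_reference()`).
* **Specificity profiling** — per-sequence minimum-mismatch accounting with
  5'/3' end resolution against target and non-target panels
  (`scan_primer()`, `specificity_profile()`).
* **In-silico PCR** — amplicon prediction, semi-nested clone screening and
  restriction-digest (RFLP) typing (`predict_amplicons()`,
  `nested_screen()`, `digest()`, `rflp_group()`).
* **OTU calling** — Kimura 2-parameter distances
  (d = -1/2 ln((1-2P-Q)sqrt(1-2Q)), pairwise deletion) and
  furthest-neighbour clustering at a distance cutoff (`k2p_distance()`,
  `cluster_furthest_neighbor()`, `shared_otus()`).
* **qPCR quantitation** — standard-curve fitting of
  C_T = k lg(copies/uL) + b, efficiency E = (10^(-1/k) - 1) x 100%,
  standard copy number a/(L x 660) x 6.022e23, curve inversion and the
  volume chain to copies per liter of source water
  (`fit_standard_curve()`, `efficiency()`, `molecules_per_ul()`,
  `ct_to_copies()`, `copies_per_liter()`, `detection_limit_cells()`).
* **Synthetic data** — seeded generators for sequence families with
  planted primer sites, clone libraries with labelled chimeras, and noisy
  dilution series, each with complete ground-truth records
  (`generate_family()`, `generate_library()`,
  `generate_dilution_series()`, `synthetic_ssu_reference()`).

Everything takes and returns tibbles, so calls chain with the pipe; fitted
objects support `tidy()`, `glance()` and `autoplot()`. A thin command-line
front end (`inst/cli/cladeassay.R`, subcommands `design`, `evaluate`,
`pcr`, `screen`, `digest`, `cluster`, `qfit`, `quantify`, `simulate`) wraps
the same functions for shell pipelines.

## Worked example

The five assay primers ship with the package. Their expected GC% under the
degenerate-average convention (R and Y count half):

```r
library(cladeassay)
p <- assay_primers()
tibble::tibble(name = p$name, gc = round(gc_content(p$seq), 1))
#> # A tibble: 5 × 2
#>   name         gc
#>   <chr>     <dbl>
#> 1 EukA       52.4
#> 2 Peri974F   42
#> 3 Peri979F   42.5
#> 4 Peri1004R  41.7
#> 5 Peri1403R  50
```

In-silico PCR of the clade pair against the synthetic reference (primer
sites planted at their canonical coordinates) gives the assay's
characteristic 441-bp product:

```r
s <- setNames(p$seq, p$name)
ref <- synthetic_ssu_reference()
predict_amplicons(ref, s["Peri974F"], s["Peri1403R"])[, 1:7]
#> # A tibble: 1 × 7
#>   template_id             fwd_start fwd_mismatches rev_start rev_end rev_mismatches product_length
#> 1 synthetic_ssu_reference       974              0      1396    1414              0            441
```

Fit a standard curve from a (here noiseless, simulated) tenfold dilution
series and quantify samples:

```r
curve <- fit_standard_curve(generate_dilution_series(ct_noise_sd = 0))
glance(curve)
#> # A tibble: 1 × 6
#>   slope intercept    r2 efficiency_percent n_levels n_points
#> 1 -3.52      32.0     1               92.4        8        8
ct_to_copies(curve, 23)
#> [1] 369.581
detection_limit_cells(96, 160000)
#> [1] 6e-04
```

A C_T of 23 on this calibration corresponds to about 370 rDNA copies per
microliter of template; 96 detectable copies correspond to 0.0006 cell
equivalents for an organism carrying 160,000 rDNA copies per cell.

Cluster amplicon sequences into OTUs at the 99% similarity convention
(distance cutoff 0.01):

```r
fam <- generate_family(family_spec(n_target = 12, n_nontarget = 0,
                                   sequence_length = 300,
                                   target_divergence = 0.03, seed = 5))
cluster_furthest_neighbor(k2p_matrix(fam$sequences), cutoff = 0.01)
#> OTU assignment: 12 sequences in 12 OTUs at distance cutoff 0.01
```

See `vignettes/cladeassay-methods.Rmd` for the model conventions, defaults
and their rationale.

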