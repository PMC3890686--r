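# barcodegap

Distance-based DNA-barcoding analysis for aligned COI matrices: does a
barcode gap exist, what distance threshold separates species, how well
does leave-one-out identification work, which molecular clusters (MOTUs)
does the data support, and which specimens look morphologically
misidentified?

The package targets the standard workflow of COI barcoding studies of
animals — for example, delimiting species in a gastropod genus from a
few dozen sequenced specimens — and is aimed at researchers who have an
aligned FASTA and a specimen table and want the complete distance-based
analysis chain with reproducible, machine-readable outputs.

## What it computes

* **K2P distances** with pairwise deletion of gap/ambiguous columns:
  `d = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`, with `P`, `Q` the observed
  transition/transversion proportions per pair. Saturated pairs are hard
  errors by default (or flagged missing on request).
* **Barcode gap**: intra- vs interspecific distance partitions, medians
  and ranges, Wilcoxon rank-sum test (exact for small tie-free samples),
  and a per-specimen table comparing the nearest non-conspecific with
  the furthest conspecific.
* **Threshold optimisation**: Gaussian kernel density of all pairwise
  distances (rule-of-thumb bandwidth `0.9·min(sd, IQR/1.34)·n^(−1/5)`,
  512 grid points); the first local minimum — the dip between the
  intra- and interspecific modes — is the proposed threshold.
* **Leave-one-out identification** under three criteria: best close
  match (correct / incorrect / ambiguous / no ID at the optimised
  threshold), near neighbour (true / false), and a fixed 1% radius
  emulating the BOLD identification rule.
* **MOTU delimitation** by single-linkage chaining (`d ≤ threshold`
  connected components) with a congruence report listing every specimen
  whose label disagrees with its MOTU's majority species.
* **A COI-like simulator** (star phylogeny, two-parameter substitution
  process stationary at a target base composition, injectable label
  errors) so the whole chain is testable against known ground truth.

## Worked example

Simulate a study-shaped dataset — 5 species sampled 9/12/4/11/20 times,
654 bp, AT-rich composition, expected within-species K2P 0.004 and
between-species 0.15, with 5 injected misidentifications — and run the
full pipeline:

```r
library(barcodegap)

cfg <- simulation_config(inter_depth = 0.073, n_mislabels = 5, seed = 2013)
man <- run_pipeline(pipeline_config(out_dir = "bg-run", sim = cfg))
cat(render_summary(man), sep = "\n")
```

```
== Barcode gap ==
intraspecific: median 0.005, range 0.000-0.162 (n = 378 pairs)
interspecific: median 0.141, range 0.000-0.175 (n = 1162 pairs)
Wilcoxon rank-sum: two-sided p = 1.33e-116 (inter > intra: p = 6.65e-117; normal approximation)
note: pairwise distances are non-independent; p-values are descriptive
gap by medians: TRUE | gap by extremes: FALSE

== Threshold ==
selected threshold d = 0.067 (first_local_minimum; bandwidth 0.003463, 2 minima)

== Identification (leave-one-out) ==
best_close_match correct 31 (55.36%) | incorrect 7 (12.50%) | ambiguous 18 (32.14%) | no_id 0 (0.00%)
near_neighbour   true 49 (87.50%) | false 7 (12.50%)
thresh_id        correct 31 (55.36%) | incorrect 3 (5.36%) | ambiguous 22 (39.29%) | no_id 0 (0.00%)

== MOTUs ==
5 MOTUs at threshold 0.067
MOTU_01: species_05 (20)
MOTU_02: species_02 (10), species_04 (2)
MOTU_03: species_04 (11)
MOTU_04: species_01 (7), species_02 (1), species_05 (1)
MOTU_05: species_02 (1), species_03 (3)
label/MOTU mismatches: 5
  SIM010 labeled species_04 sits in MOTU_02 (majority species_02)
  SIM012 labeled species_04 sits in MOTU_02 (majority species_02)
  SIM005 labeled species_02 sits in MOTU_04 (majority species_01)
  SIM008 labeled species_05 sits in MOTU_04 (majority species_01)
  SIM025 labeled species_02 sits in MOTU_05 (majority species_03)
```

Reading it: the pooled distances are strongly bimodal (medians 0.005 vs
0.141), so a barcode gap exists and the density dip proposes d = 0.067
as the threshold. The per-specimen "gap by extremes" flag is FALSE
because the five mislabelled specimens sit genetically inside the wrong
species, which also drags best-close-match accuracy down to 55% under
the (partly wrong) observed labels. The MOTU stage recovers the clean
five-cluster structure regardless, and the congruence report flags
exactly the five injected misidentifications (compare
`man$results$sim$swapped_ids`).

The same stages run file-by-file as numbered scripts: `Rscript
analysis/01_simulate.R` through `analysis/06_motu.R`, each reading its
inputs from `results/` and writing TSV/JSON outputs there.

Real data enters through `read_alignment()` (aligned FASTA; first
header token = specimen ID) and `read_metadata()` (TSV/CSV with
`specimen_id`, `species_label`, optional `locality` and `outgroup`
columns), joined by `build_dataset()`. Alignment is an input contract:
unaligned sequences are an error, not auto-aligned.

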