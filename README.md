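# g4screen

Analysis toolkit for an NMR screen of a 496-member mutational variant
library of a monomeric reference G-quadruplex (G4).

G-quadruplexes are four-stranded DNA structures of stacked guanine tetrads.
The standard consensus motif G<sub>3+</sub>N<sub>1-7</sub>G<sub>3+</sub>N<sub>1-7</sub>G<sub>3+</sub>N<sub>1-7</sub>G<sub>3+</sub>
misses many sequences that still fold into G4s — typically by multimerising
(dimers, tetramers) or by folding slowly. A 17-nt monomeric reference G4
(three tetrads; central tetrad at positions 2, 6, 11, 15; loops at 4, 8, 9,
13) is the scaffold of a library that probes exactly this: a tetrad
sub-library (all 4^4 = 256 variants of the central tetrad) plus three loop
sub-libraries (all 3^4 = 81 A/C/T loop variants, in the reference, a
dimer-forming and a tetramer-forming background). After merging the three
sequences shared between sub-libraries, the library has 496 unique members.

The package implements the screen's analysis end to end, for researchers
working on G4 sequence–structure–function relationships:

* **Library design** — enumeration, mutational-signature annotation,
  IUPAC pattern matching, and a rule-based spectral-class assignment in
  which the position of central-tetrad mutations determines the class:
  both halves (2,6)/(11,15) intact → Class 17.3 (monomer); only (2,6)
  intact → Class 17.63 (tetramer); only (11,15) intact → the dimer-forming
  17.4 family, refined by the adenosine count at loop positions 4, 8, 9.
* **Synthetic data** — class-conditioned ¹H imino-region spectra
  (Lorentzian lines, 10–12 ppm), ion-exchange chromatograms (one Gaussian
  peak per multimeric state in its diagnostic elution window) and
  five-activity tables (Flu, Tet, Dim, Per, GTP) with small within-class
  relative SD. All stages run on these generators; the original raw data
  are not publicly deposited.
* **Spectra prep** — trimming to 10–12 ppm, 0–1 scaling, robust noise
  estimation, signal filtering, peak picking, two-timepoint comparison.
* **Spectral clustering** — bucketed Ward clustering with adjusted-Rand /
  purity agreement against the rule classes.
* **Ion exchange** — apex detection and typing into the elution windows
  (non-G4 5.1–5.4, many-mutations 5.55–5.7, dimeric 6.1–6.7, tetrameric
  6.8–7.4, monomeric 7.7–9.0 mL).
* **Activity profiles** — per-class means renormalised 0–100 for radar
  plots, plus a permutation null testing within-class homogeneity.

## Worked example

```r
library(g4screen)

lib <- assign_rule_class(enumerate_library())
nrow(lib)                                  # 496
sort(table(lib$class), decreasing = TRUE)
#> no_G4_signals  17.63   17.3  17.4s26  17.4  17.36  17.49  no_pattern
#>           174     95     81       60    35     10      9           9
#> 17.154  17.28  17.180
#>      8      8       7
```

174 heavily mutated sequences are expected to show no G4 signals; 81
sequences (16.3% of the library) keep an unmutated central tetrad and fold
like the reference monomer; 95 form the tetramer class and the 17.4 family
(35 + 60) the dimer classes.

```r
set.seed(7)
act  <- simulate_activities(lib$class, g4_sim_config(), seq_ids = lib$seq_id)
prof <- class_profiles(act)
prof[prof$class %in% c("17.3", "17.63", "17.4"),
     c("class", grep("_renorm$", names(prof), value = TRUE))]
#>  class Flu_renorm Tet_renorm Dim_renorm Per_renorm GTP_renorm
#>   17.3     100.00       6.38       6.21      100.0       65.2
#>   17.4      10.00       6.23     100.00       30.7        8.3
#>  17.63       8.09     100.00      12.40       10.1      100.0
```

Each activity is renormalised so the best class scores 100: Class 17.3
dominates fluorescence and peroxidase activity, 17.63 tetramer formation
and GTP binding (≈12-fold the 17.4 GTP mean), and 17.4 dimer formation.

The `analysis/` directory holds the full narrative workflow as numbered
scripts — `01_enumerate_library.R` through `05_activity_profiles.R` — each
a thin driver over the package that prints what it found and writes its
tables under `results/`.

## Package layout

* `R/` — implementation; `tests/testthat/` — unit, property and
  acceptance suites; `analysis/` — the numbered workflow drivers;
  `vignettes/g4-screening-methods.Rmd` — the methods notes (model,
  parameters, design choices, limitations).
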