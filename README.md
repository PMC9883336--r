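# fufatags

Identification of triacylglycerols carrying furan fatty acids (FuFA-TAGs)
in centroided LC-HRMS² spectra.

## The problem

Furan fatty acids (FuFAs) are powerful natural antioxidants present at
trace levels in fish oils, mushrooms and plant lipids, almost entirely
esterified in triacylglycerols (TAGs). Standard TAG lipidomics overlooks
them: their quasi-molecular ions are faint, nominally isobaric with
ordinary TAGs (exact-mass gaps of only 0.0364 Da, "O vs CH₄", or
0.0575 Da, "C₂ vs H₈O"), and MS¹ screening is equivocal. FuFA-TAGs can,
however, be identified from MS² spectra by a small set of diagnostic
fragment ions. `fufatags` implements that screen end to end for anyone who
wants to search their own LC-MS² data — or simulated data — for
FuFA-containing TAGs.

## The method

FuFAs are named by number-letter-number short forms (`9M5`: 9-carbon
carboxyalkyl chain, one ring methyl, 5-carbon alkyl chain) and their
formulas derive from structural rules (conventional FA: C<sub>n</sub>H<sub>2n−2d</sub>O₂;
FuFA: C<sub>n</sub>H<sub>2n−6</sub>O₃; TAG = glycerol + 3 FA − 3 H₂O).
For every candidate TAG the package predicts

* the protonated and ammoniated precursors,
* the diacyl ions [M−RCOO]⁺ (loss of one acyl as RCOOH, mass-conserving
  against the precursor),
* the FuFA acylium ion [FCO]⁺ (the MS² base peak; only six m/z values
  cover the twelve screenable FuFAs, each value shared by two chain
  isomers),
* the furan core ion (resolves which member of the [FCO]⁺ pair is
  present), and
* the McLafferty ion (m/z 109.0653 for monomethyl, ≈123.081 for dimethyl
  FuFAs).

A spectrum is annotated when precursor, [FCO]⁺, furan core and McLafferty
ions all match within a ppm tolerance (default 4 ppm); diacyl ions then
assign the conventional fatty acids (tier `FULL`) or, when co-elution hides
them, the TAG is reported FuFA-only with an `XY` name prefix (tier
`FUFA_ONLY`). Candidates whose evidence is a strict subset of a better
explanation are discarded; truly indistinguishable compositions are
flagged `ambiguous` instead of guessed between.

## Worked example

```r
library(fufatags)

tag <- build_tag("L", "L", "9M5")      # dilinoleoyl + 9M5
fragment_table(tag)
#>        ion_type        label    formula        mz
#> 1   precursor_h   [LL9M5+H]+   C58H99O7 907.73908
#> 2 precursor_nh4 [LL9M5+NH4]+ C58H102NO7 924.76563
#> 3        diacyl      [L9M5]+   C40H67O5 627.49885
#> 4        diacyl        [LL]+   C39H67O4 599.50394
#> 5       acylium      acyl(L)    C18H31O 263.23749
#> 6           fco    acyl(9M5)   C19H31O2 291.23241
#> 7    furan_core    core(9M5)    C11H17O 165.12794
#> 8    mclafferty     McL(9M5)      C7H9O 109.06534
```

The precursor (907.7391) is what the instrument isolates; 599.5039 and
627.4989 prove the two linoleic acids; 291.2324 / 165.1279 / 109.0653 are
the FuFA's diagnostic trio. Screening a whole run — here the package's
deterministic fixture reconstructing 18 published mushroom
identifications — takes under a second:

```r
db <- enumerate_candidates(fufa_per_tag = 1:2)   # 1650 candidate TAGs
ann <- annotate_run(table6_fixture(), db)
head(ann[, c("name", "tier", "rt", "formula", "precursor_obs",
             "carbon_number", "intensity")], 5)
#>         name      tier    rt   formula precursor_obs carbon_number intensity
#> 1      LL7D5      FULL 20.80  C57H96O7      893.7233            54    284000
#> 2      XY9D5 FUFA_ONLY 20.80  C57H96O7      893.7233            54    570000
#> 3 15:0-Ln9D5      FULL 21.65  C56H96O7      881.7230            53   1010000
#> 4      LL9M5      FULL 21.66  C58H98O7      907.7379            55    230000
#> 5    L9D59D5      FULL 21.89 C61H102O8      963.7649            58   9980000
```

Each row is one identified FuFA-TAG: canonical name (conventional acids by
ascending mass, FuFA last — sn-positions are *not* claimed), retention
time, neutral formula, observed precursor, acyl carbon number and the
[FCO]⁺ base-peak intensity. `XY9D5` is a co-eluting TAG whose FuFA (9D5)
was proven while its conventional acids were not. Real data come in via
`read_mzml()`, `read_mgf()` or `read_peaklist_tsv()`, and a command-line
wrapper (`inst/exec/fufatag`) exposes `enumerate`, `predict`, `simulate`
and `annotate` subcommands.

See the vignette (`vignettes/fufa-tag-screening.Rmd`) for the model, the
filter's arbitration rules, simulation scope and known limitations.

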