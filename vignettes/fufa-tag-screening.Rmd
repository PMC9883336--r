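---
title: "Screening triacylglycerols for furan fatty acids in MS² spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening triacylglycerols for furan fatty acids in MS² spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fufatags)
```

## The problem

Furan fatty acids (FuFAs) are potent radical scavengers present at trace
levels (typically below 1% of the lipids) in fish, mushrooms and plant oils.
They occur almost exclusively esterified, largely in triacylglycerols
(TAGs), but TAG lipidomics routinely overlooks them: in first-dimension
(MS¹) spectra a FuFA-containing TAG is just one faint quasi-molecular ion
among co-eluting signals spread over orders of magnitude of abundance, and
exact mass alone is equivocal. `fufatags` implements a screening strategy
that instead exploits a small set of *diagnostic fragment ions* in
second-dimension (MS²) spectra, where the FuFA substructure produces an
unmistakable signature.

## Building blocks and nomenclature

FuFAs are described by number-letter-number short forms, `9M5` meaning a
9-carbon carboxyalkyl chain in α-position of the furan ring, one ring methyl
(`M`; `D` for two), and a 5-carbon α′-alkyl chain. Structural rules generate
the formulas rather than per-compound lookup tables:

* conventional fatty acid with $n$ carbons and $d$ double bonds:
  $\mathrm{C}_n\mathrm{H}_{2n-2d}\mathrm{O}_2$;
* FuFA with $n$ total carbons ($n = p + q + 5$ for M-types, $p + q + 6$ for
  D-types): $\mathrm{C}_n\mathrm{H}_{2n-6}\mathrm{O}_3$ — the ring, its two
  double bonds and the carboxyl account for four degrees of unsaturation;
* TAG: glycerol + three fatty acids − three waters.

This supports arbitrary chain-length/methylation combinations and was
validated against every printed reference formula. The shipped default set
(`default_building_blocks()`) contains twelve FuFAs — the eight most
relevant species plus the four chain partners (7M5, 7D5, 13M3, 13D3) that
share acylium masses with them — and eleven conventional fatty acids: the
seven typical of fish and plant oils plus Pn (16:1), S (18:0) and the
odd-chain 15:0 and 17:0 seen in mushroom TAGs. 13M3 is included although it
is rare; it costs nothing at screening time because a candidate only fires
when all its diagnostic ions are present.

## Diagnostic ions

For a protonated TAG the screen predicts, per composition:

* **diacyl ions** $[\mathrm{M{-}RCOO}]^+$ — loss of one fatty acid as RCOOH;
  one ion per *distinct* acyl, so one to three values. Exact mass
  conservation ties them to the precursor: diacyl m/z + leaving-acid mass =
  $[\mathrm{M{+}H}]^+$ m/z;
* the **acylium ion** of each acyl ($[\mathrm{RCO}]^+$, the acid minus OH).
  For FuFAs — written $[\mathrm{FCO}]^+$ — it is the base peak of clean
  FuFA-TAG MS² spectra; for conventional acids it is minor and carries no
  weight in identification;
* the **furan core ion**, an allylic fragment retaining the ring, methyls
  and α′ chain: $\mathrm{C}_m\mathrm{H}_{2m-5}\mathrm{O}$ with
  $m = 5 + \text{methyls} + q$;
* the **McLafferty rearrangement ion**, depending only on methylation:
  C₇H₉O (m/z 109.0653) for M-types, C₈H₁₁O (≈123.081) for D-types. These
  are fixed rules, not a rearrangement engine: both outcomes are confirmed
  by observation and are chain-length independent.

The twelve default FuFAs share only six $[\mathrm{FCO}]^+$ masses — each
value belongs to exactly two species whose chains trade two carbons (9M5 ↔
11M3, 9D5 ↔ 11D3, …). The furan core ion breaks that tie, because it keeps
the α′ chain: within every degenerate pair the core masses differ by two
methylenes. This complementarity is what makes the filter decisive.

## The identification filter

`screen_spectrum()` applies four steps per spectrum at a ppm tolerance
(default 4 ppm, the method's stated maximum deviation):

1. precursor match against the candidate database ($[\mathrm{M{+}H}]^+$;
   optionally $[\mathrm{M{+}NH_4}]^+$). An in-spectrum precursor peak is
   recorded as corroborating evidence when present;
2. $[\mathrm{FCO}]^+$ present → FuFA narrowed to a positional-isomer pair;
3. furan core ion present → concrete FuFA selected; McLafferty ion must
   agree with the methylation degree. TAGs with two distinct FuFA species
   need the trio once per species;
4. diacyl ions assign the conventional fatty acids.

Annotations are tiered: **FULL** when at least one diacyl ion consistent
with the composition is found, **FUFA_ONLY** when none is — the FuFA is
proven but the conventional acids are not, and the TAG is reported with the
`XY` name prefix. That situation is real: co-eluting TAGs share MS² scans
in which the strong $[\mathrm{FCO}]^+$ survives but the diacyl ions of the
minor component drown.

Two arbitration rules resolve systematic degeneracies that a naive
implementation would trip over:

* **Diacyl coverage.** Isomeric acyl *pairs* are ubiquitous (L+L weighs
  exactly O+Ln; P+O weighs Pn+S), so a wrong candidate sharing the FuFA
  always matches the observed pair ion. Among candidates sharing the
  spectrum and FuFA, only those matching the maximal fraction of their
  expected diacyl ions are kept: the true composition explains *all* pair
  ions, the impostor explains a subset.
* **Evidence domination.** Across candidates with different FuFA keys, an
  annotation whose matched diagnostic peaks form a strict subset of another
  annotation's is dropped as an isobaric shadow. Annotations with
  *identical* matched peak sets — which happens for mixed two-FuFA TAGs
  drawn from two acylium-degenerate pairs, e.g. 9M3+9M5 versus 7M5+11M3,
  where every diagnostic mass coincides — are all kept and flagged
  `ambiguous`. This is an information-theoretic limit of the ion set, not
  an implementation artefact, and the package flags rather than guesses.

Positional (sn-) isomers are never claimed: canonical names list
conventional acids in ascending molecular weight with the FuFA last, and
every annotation carries a `positional_isomers = "unresolved"` marker. (The
reference material itself is inconsistent on the display order; the
ascending convention is the one its result tables actually use.)

## Mass conventions

Monoisotopic masses use C = 12 exactly, H = 1.00782503207,
O = 15.9949146196, N = 14.0030740048 Da. The electron mass
(0.000549 Da per charge) is *not* subtracted by default because the
printed reference m/z values are plain atom-inventory sums; a flag restores
the physically exact convention. The difference (≈0.6 ppm at m/z 900,
≈3 ppm at m/z 165) is well inside the 4 ppm matching window either way, so
screening behaviour does not depend on the choice. Display rounding is half
away from zero — 4 decimals for m/z, 3 for ppm — while all internal
computation is full precision.

Two nominal-isobar classes matter for FuFA-TAGs: "O vs CH₄" (Δm =
0.0364 Da; a FuFA ion against a conventional ion with one double-bond
equivalent less) and "C₂ vs H₈O" (Δm = 0.0575 Da; against polyunsaturated
isobars). `required_resolution()` and `find_isobaric_conflicts()` quantify
whether an instrument separates them; at the 0.0575 Da class and m/z ≈926
the required resolving power is ≈16,100, far below modern Orbitrap
settings.

## The candidate database

`enumerate_candidates()` builds all acyl multisets with the requested FuFA
count. The screening default is one *or* two FuFAs per TAG
(`fufa_per_tag = 1:2`): trace-level FuFAs make single-FuFA TAGs the main
target, but double-FuFA species are real and observed, so excluding them
would silently mislabel their spectra. Over the default blocks this yields
1650 candidates; fragment sets are cached at build time since the same
static list is screened against many spectra.

## What the synthetic spectra emulate — and what they do not

`simulate_spectrum()` produces centroided peak lists with (i) every
predicted diagnostic ion, Gaussian m/z error of 1 ppm (1σ; a typical
Orbitrap calibration spread), (ii) an intensity hierarchy mirroring clean
FuFA-TAG spectra — $[\mathrm{FCO}]^+$ as base peak, diacyl ions at 0.2–0.6
of it, core and McLafferty at 0.05–0.2, surviving precursor at 0.1 — and
(iii) uniform decoy peaks (default 20 over m/z 50–1000) below the
diagnostic heights. Sampled heights are uniform within their ranges; seeds
fix the whole stream.

`table6_fixture()` is different: it is fully deterministic and rebuilds one
spectrum per published mushroom identification from the *printed observed*
masses and base-peak intensities, with fixed sub-maximal heights for the
unprinted ions. It preserves quirks of the printed data, including one
diacyl value (601.4830 in the 15:0-Ln9D5 row) that is ~2 Da away from any
ion of the named composition — the screen still calls the row FULL because
two of its three expected diacyl ions match, which is exactly why the tier
rule demands *at least one* consistent diacyl ion rather than all.

What the simulations deliberately do not model: chromatographic peak
shapes and co-elution-induced suppression (the dominant real-world failure
mode of this screen), isotope envelopes, chimeric isolation windows, and
intensity prediction from structure. Passing the synthetic suite therefore
demonstrates the *logic* of the filter — completeness and specificity of
the mass arithmetic and the decision flow — not robustness to matrix
effects.

Validation scales used by the test suite: the noise-free recall sweep runs
over all 1650 default candidates (100% recall; unique recovery for every
single-FuFA candidate; degenerate two-FuFA twins flagged ambiguous), and
the negative control screens 10,000 independently seeded decoy-only
spectra (zero annotations).

## Reporting operations

`annotate_run()` deduplicates per TAG name across spectra, keeping the
occurrence with the strongest $[\mathrm{FCO}]^+$ — retention time is
carried for reporting but never used for identity, since the filter is
purely mass-based. `relative_abundances()` normalises replicate runs to
the most abundant TAG of the first run (per class, FuFA vs conventional)
and reports relative standard deviations. `estimate_contents()` allocates
a known total FuFA content over annotated TAGs proportionally to their
intensities, assuming similar MS² response — defensible because the
dominant diagnostic ions arise from the shared FuFA substructure — which
turns a transmethylation-derived sum value into per-TAG estimates and a
detection floor without authentic standards.

## Known limitations

* sn-positions and double-bond positions/geometry are out of reach of the
  ion set and are never reported.
* Mixed two-FuFA TAGs spanning two acylium-degenerate pairs are
  indistinguishable from their swapped twins; both are emitted flagged.
* The screen assumes centroided spectra; no peak picking is provided.
* Under poor chromatographic separation the real method fails for reasons
  (suppression of minor diagnostic ions) that the synthetic spectra do not
  reproduce; decoy robustness results should not be read as co-elution
  robustness.
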