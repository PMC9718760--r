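---
title: "Methods: modelling S-linked GAG analogs with thiogag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling S-linked GAG analogs with thiogag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiogag)
```

## Scope and model

`thiogag` models thio-glycosidic ("S-linked") analogs of heparosan, the
unsulfated precursor of heparin/heparan sulfate, whose backbone is the
alternating repeat [→4)-GlcA-(1→4)-GlcNAc-(1→]. In the hemi-A analog the
GlcA→GlcNAc bond is a C–S–C thioglycoside while the GlcNAc→GlcA bond stays
natural. The package covers four connected pieces of desk-scale
computation: chain mass prediction, enzymatic cleavage-rule simulation,
six-membered-ring puckering analysis, and a synthetic conformational
ensemble generator with its downstream geometry pipeline.

Chains are ordered from the **non-reducing** to the **reducing** end and
indexed 1-based from the non-reducing terminus; bond *i* joins the
anomeric carbon (C1) of residue *i* to the position-4 heteroatom of
residue *i + 1*. An S-link therefore *is* the statement that the
downstream residue carries sulfur at its 4-position — the package counts
each such sulfur exactly once whether it is declared as an explicit
`4-thio` modification (a free terminal thiol) or implied by an `S` linkage
token.

## Mass conventions

Residue compositions are glycosyl residues (monosaccharide − H₂O); a free
chain is the residue sum plus one H₂O; an aglycone contributes its R-group
composition minus one H (the glycosidic substitution of the anomeric
hydroxyl). All ion masses are **monoisotopic `[M−H]⁻`**: the source data
for the reference products are reflector-negative MALDI spectra that do
not state the ion convention, and this choice reproduces all six reference
"predicted" masses to ≤ 0.005 Da, which we take as its validation
(`selftest()` asserts it). Average masses are available through
`ion_species(mass_type = "average")` but are never the default. Atomic
masses are fixed package constants (IUPAC/CODATA); deprotonation subtracts
the proton mass (H minus the retained electron).

AMAC labelling adds C₁₃H₁₀N₂O + H₂ − H₂O (+194.0844 Da): condensation of
2-aminoacridone with the reducing-end aldehyde followed by cyanoborohydride
reduction. Nominal m/z is the exact `[M−H]⁻` rounded half away from zero,
matching the printed integers 588/572. The exact composition of the
fluorescein-tagged acceptor linker is not fully specified upstream; it
ships as an editable table entry flagged as a synthetic stand-in.

## Cleavage rules

A bond is cleavable iff its donor/acceptor residues match the enzyme's
pattern **and** the linkage heteroatom is O. Heparanase is modelled as
plain hydrolysis of GlcA-*O*-hexosamine bonds (each cut adds one H₂O
across the new termini). Heparin lyase cuts hexosamine-*O*-GlcA bonds by
β-elimination: no water is added and the GlcA gaining the new non-reducing
end becomes the 4,5-unsaturated ΔUA (composition GlcA − H₂O), so the
fragment mass multiset conserves the parent mass exactly — both facts are
tested. Digestion is exhaustive (every matching bond cut), which is the
regime of the overnight digests being modelled.

One consequence worth stating: lyase digestion of a *finite* hemi-A
[GlcA-GlcNAc]ₙ chain yields n disaccharides of which the original
non-reducing one keeps its saturated GlcA (`GlcA-S-GlcNAc`); only the
n − 1 interior products are `dUA-S-GlcNAc`. For the ~45-repeat polymers
the end effect is invisible in LC-MS, and the package reports it
faithfully rather than forcing every fragment to ΔUA.

## Cremer–Pople conventions

Ring atoms are always ordered O5, C1, C2, C3, C4, C5 (j = 0…5).
Displacements are taken against the mean plane through the geometric
centre with the normal defined by the standard R′ × R″ construction, so
Σz<sub>j</sub> = 0 by construction. The orientation question — which ring
traversal handedness makes the ⁴C₁ chair come out at θ = 0 rather than
θ = 180 — is resolved by calibration: `canonical_ring()` builds its base
hexagon clockwise when viewed from +z, which makes the puckering normal
point +z, puts the ideal ⁴C₁ chair (O5 up, alternating signs) at θ = 0,
and the ᴼ³B boat (O5 and C3 above the plane) at φ = 0. This matches the
stated convention of the figures being reproduced ("θ = 0° is a perfect
⁴C₁ chair … φ = 0° represents the ᴼ³B boat"), which pins only those two
points; how that orientation relates to any particular published axis
choice is deliberately left undocumented beyond the calibration, and
`selftest()` asserts it at start-up precision (1e-6°).

The 38-label reference grid is: chairs at the poles; boats at the equator
at φ = 0°, 60°, …, 300°; skews interleaved at φ = 30°, 90°, …, 330°;
envelopes and half-chairs interleaved at 30° spacing on the tetrahedral
bands θ = 54.74° / 125.26°. The envelope/boat/skew names at each grid
point were derived from the inverse transform (which atoms sit above or
below the plane at that (θ, φ)), so grid and nomenclature are mutually
consistent. Two simplifications are intentional:

* an ideal half-chair's exact CP latitude is ≈ 50.8°/129.2°, but the
  *reference grid* places half-chairs on the same 54.74° band as
  envelopes. The grid is a set of classification anchors, not a geometric
  claim; nearest-reference classification is unaffected.
* classification minimises great-circle distance on the (θ, φ) sphere,
  ignoring Q; ties break by the fixed canonical row order of
  `conformer_table()` (chairs, boats, skews, envelopes, half-chairs,
  ascending φ), making the classifier deterministic.

Numerical choices: rings with Q < 1e-4 Å are flagged planar and their
angles are undefined (classification errors out rather than guessing);
φ values within round-off (1e-7°) of 360 wrap to 0; the sinusoidal
projection uses latitude ψ = θ − 90 (⁴C₁ at the *south* pole, matching
the plot orientation being reproduced) and assigns the ±180° longitude
boundary to +180.

## The ensemble generator: a stated world

`build_ensemble()` is a stand-in for μs explicit-solvent MD, not a
re-implementation of it. Per frame it draws one canonical conformer per
residue from configured mixture weights, emits each ring as a *rigid*
idealised conformer (amplitude Q = 0.57 Å, a typical pyranose chair
amplitude), and joins consecutive rings through glycosidic internal
coordinates:

* bond lengths and the C–X–C angle are sampled from the Boltzmann
  marginals of the harmonic energy `E = K (x − x₀)²` — the AMBER
  convention without the ½, hence variance `k_B T / (2K)` with
  k_B = 0.0019872 kcal mol⁻¹ K⁻¹, at 298 K by default. The S-link
  constants are the quantum-derived values used verbatim
  (1.8392 Å / 215.9; 99.24° / 60.2). The O-link equilibria use the
  approximate natural ether geometry (1.43 Å, 116°) with force constants
  mirrored from the S-link values, because no O-link constants are given
  upstream and the stock carbohydrate force field is out of scope; all
  four numbers are configurable.
* glycosidic torsions φ (O5–C1–X–C4) and ψ (C1–X–C4–C5) are independent
  von Mises draws. Defaults, chosen once: mean 180° for both (an extended
  chain baseline) with concentration κ = 10 for O-links and κ = 3 for
  S-links. The lower S concentration is the single knob that encodes
  "the thio linkage is floppier"; it makes S-ensembles spread wider in
  end-to-end length, which is asserted as a variance ordering, not as a
  reproduction of any simulated histogram.
* frames with non-bonded heavy atoms of non-adjacent residues closer than
  1.8 Å are rejected and their torsions resampled (50 retries, then a
  diagnostic error). This prevents unphysical collapse without
  implementing any non-bonded energetics.
* exocyclic groups (N-acetyl, carboxylate) are single pseudo-atoms placed
  at idealised tetrahedral directions; substituent directions generally
  are the tetrahedral splits of the ring-bond bisector with fixed face
  choices. This is sufficient for pucker, end-to-end and C–X–C readback
  analyses — the three quantities the pipeline consumes — and is declared
  in the atom roster (`N2`, `C6` pseudo-atoms).

Reproducibility: the seed is mandatory; frame *f* uses an RNG substream
seeded at `(seed + 1000003 f) mod (2³¹ − 1)`, so ensembles are
bit-identical for identical specs and frames are insensitive to how many
preceded them.

**What a green test establishes.** The generator's closure property is
that downstream analyses recover the configured inputs: mixture weights
within multinomial sampling error, linkage equilibria within Gaussian
standard errors, rings at their reference (θ, φ) to 1e-6° before
assembly. It does **not** establish anything about real chain energetics:
the MD-derived conformer frequencies (e.g. ~40–85% ¹C₄ GlcNAc or ~26–29%
skew/boat GlcA in S-linked chains), real end-to-end histograms, solvent
effects, or inhibition potencies are outside what this generator can
produce — the demo configuration ships such ranges purely as labelled
emulation presets, i.e. *inputs*. Which residues carry the 6-O-sulfo
group in the "mono-6OS" models is likewise unspecified upstream, so the
demo uses unsulfated chains.

## Pipeline and I/O choices

PDB (multi-MODEL, fixed width, 3-decimal Å) is the canonical interchange;
XYZ is supported for frictionless synthetic data, with the label column
carrying `name:residue:index` so the load stays lossless. Configuration
is JSON (schema-validated, unknown keys rejected, seed mandatory). CSVs
are comma-separated, dot-decimal, LF-terminated, written with a
deterministic number format and a provenance header comment
(`# thiogag <version> | seed | config-hash`), which makes reruns
byte-identical — the pipeline's regression contract. The config hash is a
32-bit FNV-1a implemented in modular double arithmetic (R's bitwXor
cannot hold 32-bit unsigned values).

Histograms default to 0.5 Å bins anchored at 0 (no binning is specified
upstream; the choice is explicit and configurable). End-to-end distances
run from O1 of the reducing sugar to the position-4 exocyclic heteroatom
of the non-reducing terminus; for a 4-thio terminal residue that atom is
S4, with a `strict_o4` flag to insist on the literal O4 and fail instead.
Conformer frequency reports default to the most internal disaccharide
(residues ⌊n/2⌋ and ⌊n/2⌋ + 1) to limit chain-end effects.

## Known limitations

* No furanose (five-membered) puckering, no free-energy surfaces, no
  isotope patterns or MS/MS prediction, no sulfation-site statistics.
* The generator has no electrostatics, van der Waals terms or solvent;
  conformer mixtures and torsion statistics are inputs by design.
* The classifier's grid is the idealised reference sphere; empirically
  distorted rings far from every anchor still get the nearest label, with
  the distance reported so users can filter.
* Binary trajectory formats (DCD/XTC) are not read; convert to
  multi-MODEL PDB or XYZ first.
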