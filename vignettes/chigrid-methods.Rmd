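---
title: "Methods: dihedral-angle distribution functions for bound and unbound protein surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dihedral-angle distribution functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chigrid)
```

## The question and the model

Protein side chains occupy a small number of preferred conformations
(rotamers), tightly clustered in χ-torsion space roughly 120° apart.
When two proteins bind, surface side chains rearrange; the question the
package quantifies is *how much* of that rearrangement survives at a
given resolution of conformational description. The instrument is the
dihedral-angle distribution function (DADF): for one amino-acid type
and one residue category, the empirical probability distribution of the
χ-angle vector over the cells of an n-dimensional cubic grid.

Four categories are built per residue type: interface bound, interface
unbound, non-interface-surface bound, non-interface-surface unbound.
Two DADFs X and Y on a shared grid are compared with the Pearson
correlation over all m cells (cell means are exactly 1/m since the
probabilities sum to one) and with the Manhattan distance
d = ½Σ|Xᵢ−Yᵢ|, which is 0 for identical and 1 for disjoint
distributions. Both are functions of the arbitrary grid origin, so each
comparison draws random split origins repeatedly (default 100×,
uniform per dimension on [0, spacing)) and reports means and standard
deviations over the repeats; both DADFs in a repeat share the same
origin, as cell-wise comparison requires. The *critical spacing* is the
smallest scanned spacing whose mean correlation reaches 0.7; a scan of
10°–90° in 10° steps is the default.

## Residue classification

Only surface residues are analyzed: relative SASA ≥ 25% in the bound
state and, when an unbound counterpart exists, in the unbound state as
well. Interface residues are those losing more than 1 Å² of SASA upon
binding; SASA loss is measured between the monomer extracted from the
complex coordinates and the same residues within the complex. The
bound-state exposure test also uses the extracted monomer — interface
residues would otherwise fail the 25% rule by construction. Proteins
with no free-form structure contribute bound residues under the
bound-only criteria; unbound residues inherit the class of their mapped
bound partner, since the interface is only defined on the complex.

SASA uses the Shrake–Rupley algorithm: each atom's probe-expanded
sphere (probe 1.4 Å) carries a deterministic golden-spiral point set
(default 960 points), and a point is buried if it lies inside any other
atom's expanded sphere. Radii are Chothia-style heavy-atom values
(N 1.65, O 1.40, S 1.85, sp³ C 1.87, sp²/aromatic C 1.76 Å) shipped as
`extdata/atom_radii.tsv`; relative SASA divides by the theoretical
per-type maxima in `extdata/max_sasa.tsv`. Both tables are plain text
and replaceable. Hydrogens are ignored throughout (crystal structures
rarely resolve them); alternate locations keep the highest-occupancy
conformer with ties broken by file order; only the first model of a
multi-model file is read. These policies are deterministic and
conventional rather than uniquely correct — borderline residues near
the 25% threshold can shift if a different radius or reference table is
substituted.

Bound↔unbound residue pairing uses global Needleman–Wunsch alignment
(match +1, mismatch −1, gap −2, traceback preferring diagonal, then up,
then left). At the > 97% identity typical of bound/unbound pairs any
sane scheme gives the same mapping; mismatched aligned positions stay
unpaired because a substituted residue's dihedrals are not comparable
across states. Identities below 0.97 trigger a warning but still map.

## Dihedrals and grids

χ angles follow the standard IUPAC heavy-atom quadruples (χ1 =
N–CA–CB–γ; Arg limited to χ1–χ4). χ counts per type: 1 for
Ser/Thr/Cys/Val, 2 for Pro/Ile/Leu/Asn/Asp/His/Phe/Tyr/Trp, 3 for
Met/Glu/Gln, 4 for Lys/Arg. Angles live in [−180°, 180°), with +180
normalized to −180; the last χ of Phe, Tyr, Asp and Glu is folded into
[0°, 180°) because the terminal aromatic or carboxylate group is
two-fold symmetric. Amide/imidazole flip ambiguity (Asn, Gln, His) is
deliberately not folded — only the four genuinely symmetric groups are.
A residue missing any required atom contributes no χ vector at all:
DADFs are n-dimensional, and a partial vector has no cell.

Each grid dimension is a circle — period 360°, or 180° for the folded
dimensions, where the symmetry makes the period genuine. Cell counts
follow the ceiling rule (e.g. 360/70° → 6 cells), so non-divisor
spacings produce one narrower wrap cell and every sample is binned for
every origin; the offset grid wraps at the range boundary rather than
truncating. Cells flatten row-major with χ1 slowest — an arbitrary but
fixed convention. Empty cells are retained with probability zero: the
comparison sums deliberately run over all m cells, which affects the
cell means and variances entering the correlation.

Degenerate cases: a uniform DADF has zero cell variance and an
undefined correlation; such repeats are skipped (not zero-filled, which
would bias the mean) and counted, and a comparison where every repeat
is undefined is an error. Identical probability vectors short-circuit
to r = 1 and d = 0 exactly, avoiding floating-point blur on the two
degenerate identities. Significance of the mean correlation uses
t = r√((m−2)/(1−r²)) on m−2 degrees of freedom, treating the m cells as
the observations of the correlation; it is reported as a sanity check,
not as the headline statistic. Correlations are averaged arithmetically
over repeats (not Fisher-z), and the Manhattan distance uses the same
random-origin protocol as the correlation.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
so the full pipeline runs and can be tested with no structure download:

- per χ, three rotamer centers 120° apart (−60°/60°/180°; 30°/90°/150°
  on folded dimensions, interior to the 180° range);
- skewed mixture weights, default 0.5/0.3/0.2. Real rotamer populations
  are unequal; with exactly uniform weights a rotamer flip leaves the
  mixture distribution invariant in expectation, which would make the
  flip rate invisible to any distribution-level comparison;
- wrapped-normal intra-rotamer jitter, default σ = 10°, the typical
  χ1 spread in backbone-independent rotamer libraries. Wrapped normal
  rather than von Mises because it samples exactly and only the
  clustered-with-tails shape matters here; a von Mises κ can be
  emulated via σ ≈ 180/π·κ^(−1/2) for concentrated distributions;
- paired ("bound" vs "unbound") pools: with probability `flip_prob`
  a sample's rotamer is redrawn uniformly among the other two, and
  wrapped-normal jitter of `jitter_sd` is always added. The benchmark
  defaults make interfaces change more than the rest of the surface:
  flip 0.2 / jitter 20° at the interface versus 0.02 / 10° elsewhere.

What the generator does *not* emulate: backbone-dependence of rotamer
populations, correlations between χ dimensions, residue-specific
rotamer frequencies, crystallographic noise, or unequal pool sizes.
Passing synthetic tests therefore demonstrates the machinery and the
qualitative behavior (correlation rising with spacing, flips and jitter
driving the critical spacing apart), not quantitative agreement with
any real structure set.

One consequence of the additive-jitter construction is worth stating
plainly: perturbing with jitter σⱼ widens the paired pool's marginal
spread to √(σ² + σⱼ²). With σ = σⱼ = 10° the offset-averaged Manhattan
distance at 30° spacing has a systematic, sample-size-independent floor
of about 0.105 (computable directly from normal CDFs), so paired pools
differing only by 10° readjustments measure d ≈ 0.10–0.11 there — the
distance tracks the marginal widening, not just cell reshuffling.

Toy coordinate fixtures are built by sequential internal-coordinate
(NeRF-style) placement with generic ideal bond lengths and angles
(N–CA 1.458 Å, side-chain bonds 1.52–1.53 Å, bond angles ≈ 111°),
setting each χ torsion to its target; prescribed χ vectors round-trip
through the torsion code to 10⁻⁶ degree for all 18 χ-bearing types.
Torsion values are unaffected by the generic geometry — only the
torsions themselves matter.

## Numerical choices and problem sizes

- Shrake–Rupley quadrature: 960 points per atom keeps the isolated-atom
  closed form within 1% and the total SASA rotation-invariant to a few
  tenths of a percent on multi-residue systems; both `n_points` and the
  probe radius are configurable. Tiny negative SASA differences
  (< 10⁻⁶ Å²) are clamped to zero, as occlusion can only reduce SASA
  when coordinates are shared.
- Comparisons require at least 20 samples per pool by default
  (`min_samples`); correlations between sparser histograms are noise.
- All randomness flows through R's RNG; every entry point accepts a
  seed, and fixed seeds make records, comparisons and output files
  bit-reproducible.
- Test and example runs use pools of 10²–2×10³ samples, 10–50 random
  origins and spacing scans of 5–9 values — large enough for the
  properties asserted (binomial/oracle bounds, trend signs,
  seed-averaged contrasts) while keeping a full suite run in tens of
  seconds.

## Known limitations

- The SASA implementation is numerical (point-count) rather than
  analytic; results differ slightly from slice-based or analytic
  programs, and borderline 25%/1 Å² classifications can move with the
  radius table.
- The significance model treats grid cells as independent
  observations, which overstates the effective sample size for smooth
  distributions; p-values are indicative only.
- Pooling is per amino-acid type across all cases; per-case or
  backbone-dependent analysis is out of scope.
- mmCIF input, assembly generation and symmetry mates are not
  supported; one PDB model per file is read.
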