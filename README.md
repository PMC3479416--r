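# chigrid

Side-chain dihedral-angle distribution functions (DADFs) on protein
surfaces: how similar are the side-chain conformations of a protein's
binding interface before and after complex formation, and how does that
similarity depend on how finely you bin the χ-angle space?

`chigrid` is aimed at structural bioinformaticians studying
conformational change upon protein–protein binding and at developers of
flexible docking protocols who need residue- and site-specific sampling
step sizes.

## What it computes

For each amino-acid type, the side chain is represented by its vector of
χ torsion angles (1–4 angles depending on the type; the last χ of Phe,
Tyr, Asp and Glu lives on [0°, 180°) because the terminal group is
two-fold symmetric). Pooled over many structures, the χ vectors of one
category of residues — interface or non-interface surface, bound or
unbound — are binned on an n-dimensional cubic grid of spacing *s* with
a randomized origin, giving a discrete distribution **X** = (X₁ … X_m)
over the m cells. Two categories are compared with:

- the Pearson correlation over cells,
  r = Σᵢ(Xᵢ−X̄)(Yᵢ−Ȳ) / √(Σᵢ(Xᵢ−X̄)² Σᵢ(Yᵢ−Ȳ)²), and
- the Manhattan distance d(X,Y) = ½ Σᵢ |Xᵢ−Yᵢ| ∈ [0, 1].

Because both depend on where the grid happens to start, each comparison
is repeated (default 100×) with uniformly random split origins and the
results averaged. The **critical grid spacing** is the smallest scanned
spacing at which the mean correlation reaches 0.7 — a practical summary
of how coarse a conformational sampling step can be before the
bound/unbound difference disappears.

Upstream of the statistics, the package provides everything needed to
build the category pools from PDB files: a minimal structure model (on
top of `bio3d`), Shrake–Rupley solvent-accessible surface area, surface
residues defined by relative SASA ≥ 25% in both states, interface
residues by > 1 Å² SASA loss upon binding, bound↔unbound residue
correspondence by global sequence alignment, and IUPAC χ torsions. A
synthetic generator (von Mises/wrapped-normal rotamer mixtures ~120°
apart, with rare inter-rotamer flips and small intra-rotamer
readjustments between paired pools) lets the whole pipeline run with no
external data.

## Worked example

Fully synthetic four-category benchmark for Ser (1 χ) and Asp (2 χ,
folded second dimension), 1000 residues per pool; interface pools are
perturbed bound→unbound with flip probability 0.2 and 20° jitter,
non-interface pools with 0.02 and 10°:

```r
library(chigrid)
rec <- synthetic_benchmark(synthetic_config(res_types = c("SER", "ASP"),
                                            n = 1000), seed = 42)
cfg <- chigrid_config(spacings = c(10, 30, 50, 70, 90),
                      n_repeats = 50, seed = 43)
an  <- run_analysis(rec, cfg)
subset(an$comparisons,
       res_type == "ASP" & category_pair == "interface_bound_vs_unbound",
       select = c(spacing, mean_r, sd_r, mean_d, p_value, m))
#>    spacing    mean_r       sd_r  mean_d      p_value   m
#> 21      10 0.4861540 0.02264831 0.55764 9.625106e-40 648
#> 22      30 0.8036452 0.06182685 0.36576 1.955548e-17  72
#> 23      50 0.8897712 0.06807991 0.24924 9.717192e-12  32
#> 24      70 0.8768600 0.07157030 0.19500 1.793970e-06  18
#> 25      90 0.9150003 0.04555639 0.14788 1.439084e-03   8
```

The correlation between the bound and unbound interface distributions
rises and the Manhattan distance falls as the grid coarsens: at 10° the
two distributions look different (r ≈ 0.49), by 30° they are already
highly correlated. The critical-spacing summary makes the site contrast
explicit:

```r
an$critical
#>   res_type                      category_pair critical_spacing
#> 1      SER         interface_bound_vs_unbound               10
#> 2      SER     non_interface_bound_vs_unbound               10
#> 3      SER unbound_non_interface_vs_interface               10
#> 4      SER   bound_non_interface_vs_interface               10
#> 5      ASP         interface_bound_vs_unbound               30
#> 6      ASP     non_interface_bound_vs_unbound               10
#> 7      ASP unbound_non_interface_vs_interface               30
#> 8      ASP   bound_non_interface_vs_interface               10
```

For Asp the interface needs a grid three times coarser than the
non-interface surface before bound and unbound distributions become
similar — the interface changes more upon binding. For real structures,
point `read_manifest()` at a TSV of complexes and unbound monomers and
use `process_manifest()` instead of the generator;
`inst/scripts/chigrid-cli.R` wraps the same steps for shell use
(`run`, `angles`, `compare`, `synth`, `counts`).

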