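# preorg

Solution-phase preorganization analysis of planar solute dimers around
crystal growth modifiers.

## The problem

Planar heterocyclic solutes (the urate monoanion is the motivating case)
self-associate in solution mainly by face-to-face π-stacking at ~4 Å —
and in solution that stacking is predominantly *antiparallel*, whereas
the crystal stacks *parallel*, so the dominant solution dimer is not in
registry with the lattice. The crystal's other packing motif is coplanar:
molecules in one plane joined by directional hydrogen bonds with contacts
below 2.5 Å. A dissolved modifier with a sufficiently large aromatic
surface can template neighboring solute pairs into exactly those
coplanar, crystal-compatible arrangements before they ever reach the
crystal surface — a solution-phase promotion mechanism distinct from
classical surface pathways.

`preorg` is an R package for people who have configuration ensembles
(from molecular simulation, or from the package's own synthetic
generator) and want to measure that effect.

## The framework

Every solute pair (a, b) within a pair-inclusion radius is reduced to
three order parameters:

- **r** — ring-centroid distance (Å, minimum-image under an orthorhombic
  box);
- **ψ** — angle between the a→b centroid vector and molecule a's ring
  plane normal: stacked pairs near 0 or π, coplanar pairs near π/2;
- **θ** — angle between the two intramolecular reference vectors, folded
  to [0, π].

On top of that sit: stacked/coplanar conformer classification (ψ bands +
a 2.5 Å hydrogen-bond contact criterion + a 3.0–5.5 Å stacking window),
stacking polarity (parallel/antiparallel), near-modifier vs bulk
population selection at a 4 Å heavy-atom cutoff, (r, θ, ψ) probability
histograms with marginals, differential probability maps (near − bulk),
−ln p free-energy maps, crystal-lattice-derived geometric fingerprints
with a conforming-dimer enrichment statistic (near probability normalized
to bulk), modifier-aligned spatial distribution function (SDF) occupancy
grids with isosurface component extents, and hydrogen/heavy-atom
contact-frequency tables.

A seeded synthetic generator produces ensembles with the statistical
structure this analysis assumes — stacked-dominant bulk, coplanar
hydrogen-bonded minority, and a modifier-proximal population whose
coplanar fraction grows with a templating-strength parameter and is
capped by the modifier's in-plane extent — so every stage is testable
against constructions with known answers. See the methods vignette
(`vignettes/preorganization-analysis.Rmd`) for the full model and the
design rationale.

## A worked example

```r
library(preorg)

report <- run_pipeline(list(
  ensemble = list(kind = "templated", n_frames = 120, n_solutes = 10,
                  templating_strength = 4, modifier_size = 3),
  seed = 11))
report
#> <run_report>
#>   frames: 120, dimers: 600 (near 120 / bulk 480 / excluded 0)
#>   coplanar psi-band mass: bulk 0.294, near 0.725
#>   crystal-conforming: p_near 0.1333, p_bulk 0.0688, enrichment 1.939
```

The bulk dimer population keeps its stacked-dominant character (coplanar
ψ-band mass 0.294), while dimers with a member within 4 Å of the
modifier are mostly coplanar (0.725). Judged against the coplanar
fingerprints extracted from the idealized lattice, near dimers are
crystal-conforming 1.94× more often than bulk dimers — the
preorganization signal.

Ranking modifiers of increasing aromatic extent at equal templating
strength:

```r
cmp <- compare_modifiers(lapply(
  c(small = 1, medium = 2, large = 3),
  function(size) list(
    ensemble = list(n_frames = 120, n_solutes = 8,
                    templating_strength = 4, modifier_size = size),
    sdf = list(enabled = FALSE), contacts = list(enabled = FALSE),
    seed = 9)))
cmp$ranking
#>   modifier    p_near     p_bulk enrichment rank
#> 1    large 0.1916667 0.08333333   2.300000    1
#> 2   medium 0.1583333 0.08333333   1.900000    2
#> 3    small 0.1333333 0.08611111   1.548387    3
```

Larger aromatic surfaces template more crystal-conforming dimers. The
run report also carries the contact-frequency table; the modifier's
side-chain hydrogen H13 dominates its row block:

```r
round(report$contact_table["H13", , drop = FALSE], 3)
#>      N3 O2    O6    O8
#> H13 0.5  0 0.025 0.067
```

External ensembles enter through `read_ensemble()` (multi-frame XYZ or
multi-model PDB plus a YAML topology sidecar mapping atom index ranges to
molecules and roles); real crystal fingerprints can replace the idealized
lattice through `read_fingerprints()` or a lattice coordinate file.

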