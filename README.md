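# camsite

Toolkit for locating and characterizing **1-4-7-8 calmodulin-binding
sites** — the atypical CaM-recognition motif in which hydrophobic anchor
residues at relative positions 1, 4, 7 and 8 of a short mixed α/3₁₀
helix (W79, L82, L85, V86 in AKAP79), followed by a basic stretch, are
gripped by both CaM lobes while only the C-lobe is in the open
Ca²⁺-bound conformation.

The package is aimed at structural biologists and signalling biochemists
who have some combination of:

- a crosslinking mass-spectrometry (XL-MS) link table for a CaM–target
  complex and want to localize the binding region,
- protein sequences to scan for candidate 1-4-7-8 motifs,
- a crystal structure of a CaM–peptide complex to characterize
  (helix geometry, compactness, interface burial, copy agreement),
- competition / Ca²⁺-titration / enzyme-activation curves to fit.

## What it computes

**Crosslink maps.** High-confidence links (`id_score > 20`,
`fdr < 0.05`, strict) are deduplicated across charge states, classified
as interlinks / intralinks / symmetric homodimer links, tallied, and the
binding region is triangulated as the detection-count-weighted mean of
target positions linked to the hot-spot partner residue, with a seeded
bootstrap interval:

```
s = Σᵢ cᵢ · posᵢ / Σᵢ cᵢ        (cᵢ = detections of interlink i)
```

**Motif scanning.** A Scansite-style position-specific scoring matrix
over a 15-residue window; window scores are normalized to
`s = (S_best − S)/(S_best − S_worst) ∈ [0, 1]`, lower is better.

**Helix geometry.** φ/ψ torsions, α vs 3₁₀ classification
(right-handed band φ ∈ [−100°, −30°], ψ ∈ [−80°, 0°]; 3₁₀ iff
ψ > −37°), geometric backbone H-bond detection with inferred amide H
(offset 4 = α, offset 3 = 3₁₀), terminal anchor Cα–Cα spacing, and
hydrophobic-face coherence of the anchor CA→CB vectors.

**Structure metrics.** Shrake–Rupley SASA (probe 1.4 Å, 960
points/atom, NACCESS-style radii), interface burial
`sasa(A alone) − sasa(A in complex)`, and reflection-corrected Kabsch
superposition / copy-vs-copy RMSD.

**Binding fits.** `R(x) = R_max − (R_max − R_min)·xʰ/(Kʰ + xʰ)`
(inhibition), its rising counterpart (activation), and
`v(x) = V_max·xⁿ/(Kⁿ + xⁿ)` (cooperative Michaelis–Menten), by
multi-start bounded Levenberg–Marquardt with K fitted on the log scale.

**Synthetic data.** Seeded generators with machine-readable ground
truth: ideal helices from torsion plans (NeRF construction), proteomes
with planted motifs, paper-shaped crosslink tables, noisy binding
curves.

## Worked example

```r
library(camsite)

# a paper-shaped synthetic XL-MS table with known ground truth
xt  <- make_xlink_table(xlink_spec(seed = 1))
map <- classify_links(deduplicate_links(filter_links(xt$records)),
                      c("AKAP79", "CaM"))
count_summary(map)
#> $total         213
#> $n_interlink    47
#> $n_intralink_a 148
#> $n_intralink_b  13
#> $n_symmetric     5

link_frequency(map, "CaM", 94)[1:3, ]
#>   protein_a pos_a protein_b pos_b count  category
#> 1    AKAP79    99       CaM    94    16 interlink
#> 2    AKAP79    96       CaM    94     7 interlink
#> 3    AKAP79    90       CaM    94     4 interlink

triangulate_site(map, "AKAP79", partner_pos = 94, seed = 1)$position
#> [1] 96.88889      # = (4*90 + 7*96 + 16*99) / 27
```

The interlink hot-spot (CaM K94 ↔ AKAP79 K90/K96/K99, 16 detections for
K99 alone) places the binding region near residue 97 of AKAP79. Scanning
the AKAP79 sequence around that region with the default 1-4-7-8 matrix:

```r
frag <- data.frame(id = "AKAP79", desc = "",
                   seq = paste0(strrep("X", 6), "GAWASLKRLVTRRKRS",
                                strrep("X", 10)))
scan_sequence(build_default_matrix(), frag, threshold = 0.5, offset = 71)
#>       id start anchor_pos          window score
#> 1 AKAP79    76         79 XGAWASLKRLVTRRK     0
```

The only hit anchors at **W79** with a perfect score — 18 residues
upstream of the triangulated position, i.e. the crosslink map and the
motif scan concur (`run_site_mapping()` automates this concordance
check). Fitting a noisy synthetic competition curve generated with the
16-mer peptide's inhibition constant (75 nM) as ground truth:

```r
cv <- make_binding_curve("hill_inhibition",
                         list(K = 75, h = 1, R_max = 1, R_min = 0),
                         exp(seq(log(1), log(1e4), length.out = 12)),
                         noise_sd = 0.05, seed = 42)
fit_hill_inhibition(cv)
#> hill_inhibition fit (converged), RSS = 0.01768
#>       estimate       se
#> K     66.85495 11.31016
#> h      1.02273  0.16946
#> R_max  1.02204  0.03965
#> R_min  0.07077  0.03227
```

The recovered K (66.9 ± 11.3 nM) brackets the generating 75 nM within
one standard error, as expected at 5% noise.

A command-line front-end over the same functions ships as
`inst/scripts/cam-site.R` (subcommands `scan`, `xlmap`, `helix`,
`compactness`, `superpose`, `fit`, `simulate`).

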