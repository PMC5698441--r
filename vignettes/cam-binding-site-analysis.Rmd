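---
title: "Mapping and characterizing 1-4-7-8 calmodulin-binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and characterizing 1-4-7-8 calmodulin-binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camsite)
```

## The scientific problem

Calmodulin (CaM) is the ubiquitous Ca²⁺ sensor of eukaryotic cells. Most
Ca²⁺/CaM targets present an amphipathic α-helix with hydrophobic anchor
residues spaced 1-5-10 or 1-8-14; both CaM lobes clamp around that helix.
The scaffolding protein AKAP79 is regulated by Ca²⁺/CaM but carries
neither canonical motif. Its binding site is instead a short, unusually
compact helix with hydrophobic anchors in a **1-4-7-8** pattern
(W79, L82, L85, V86 in AKAP79) followed by a basic stretch, with 3₁₀
helical character at the C-terminal turn of the helix.

`camsite` packages the computational analyses by which such a site is
located and characterized:

1. **Crosslink mapping** (`filter_links`, `deduplicate_links`,
   `classify_links`, `link_frequency`, `triangulate_site`,
   `count_summary`): turning a table of cross-linked peptide
   identifications from XL-MS into category totals and a
   detection-weighted estimate of the binding region.
2. **Motif scanning** (`build_default_matrix`, `score_window`,
   `scan_sequence`, `scan_proteome`): a position-specific scoring matrix
   (PSSM) for the 1-4-7-8 pattern and a proteome scanner with
   median/MAD score summaries.
3. **Helix geometry** (`compute_dihedrals`, `classify_helix`,
   `detect_backbone_hbonds`, `anchor_spacing`,
   `hydrophobic_face_check`): backbone torsions, α vs 3₁₀
   classification, hydrogen-bond offset spectra, terminal anchor
   spacing, and coherence of the hydrophobic face.
4. **Structure metrics** (`sasa`, `buried_area`, `superpose`,
   `region_rmsd`): Shrake–Rupley solvent-accessible surface area,
   interface burial, and Kabsch superposition of structure copies.
5. **Binding-curve fits** (`fit_hill_inhibition`, `fit_hill_activation`,
   `fit_coop_mm`, `normalize_emission`): Hill-type and cooperative
   Michaelis–Menten models for competition, Ca²⁺-titration and enzyme
   activation data.
6. **Synthetic data** (`make_helix`, `make_proteome`,
   `make_xlink_table`, `make_binding_curve`): seeded generators for every
   input class, each returning machine-readable ground truth.

## Crosslink link maps

An XL-MS experiment on a two-protein complex yields rows of cross-linked
peptide pairs with residue positions, an identification score, and a
false-discovery rate. The analysis keeps high-confidence rows
(`id_score > 20` and `fdr < 0.05`, both strict), collapses
identifications that differ only by precursor charge state or verbatim
technical repetition, and counts the remaining *unique detections* per
residue pair. Distinct peptide forms covering the same linked pair (from
variable enzymatic cleavage) and detections in different biological
replicates count separately: repeated detection of the same lysine pair
indicates that the two side chains are persistently well positioned for
the chemistry, which is the signal used for localization.

Within a duplicate group the retained representative is the member with
the highest id score (then lowest FDR). With per-charge confidence values
that disagree across a duplicate group, filtering before versus after
deduplication need not give identical results; the synthetic generator
emits charge duplicates with identical confidence, which is also how
pooled xQuest-style exports typically behave after per-link aggregation.

Links classify as *interlinks* (between the two proteins), *intralinks*
(within one protein), or *symmetric dimer* links (a position linked to
itself, only possible across two copies of the same protein, hence
evidence of a homodimer). Triangulation of the binding region follows the
hot-spot logic: the partner residue carrying the most interlink
detections serves as a reference point, and the detection-count-weighted
mean of the target-protein positions linked to it estimates the binding
site, with a percentile bootstrap over detections as a descriptive
interval (the bootstrap is seeded and its width is not an acceptance
quantity).

```{r xlink}
xt <- make_xlink_table(xlink_spec(seed = 1))
map <- classify_links(deduplicate_links(filter_links(xt$records)),
                      c("AKAP79", "CaM"))
count_summary(map)
triangulate_site(map, "AKAP79", partner_pos = 94, seed = 1)$position
```

The generator's default spec mirrors the published experiment: 47
interlinks (27 of them through the hot-spot partner residue CaM K94 to
AKAP79 K90/K96/K99 with multiplicities 4/7/16), 148 + 13 intralinks, 5
symmetric links, and a tail of sub-threshold decoys. Interlink background
positions are confined to a residue window (default 41–177) because
cross-links concentrate around the interface in practice; a uniform
background over the whole 427-residue protein would not resemble any real
link map. `hotspot_share()` reports the hot-spot share on two bases —
detections and unique pairs — because the two differ substantially
(57% vs 13% on the default map) and published percentages do not always
state their basis.

## The 1-4-7-8 scoring matrix

The exact numerical weights of the original scanning matrix are not
reproduced here; the shipped default encodes its verbal description over
a 15-residue window with the position-1 anchor at window index 4:

* window index 4 (motif position 1): W = 50, F/Y = 5, all else 1 — the
  anchor tryptophan carries the single strongest weight in the matrix;
* indices 7, 10, 11 (motif positions 4, 7, 8): L/I/V/M/F/W = 8,
  A/C = 4 (conservative substitutions), all else 1;
* indices 8, 9 (motif positions 5, 6): K = R = 6, Q/H = 3, all else 1;
* all other positions uniform.

A window's raw score is the sum of its per-position weights; the
normalized score is `s = (S_best − S) / (S_best − S_worst)`, bounded in
[0, 1] with 0 optimal (lower is better, matching the convention in which
a proteome-wide scan has a median score around 0.6). `X` and
non-canonical letters contribute the position minimum, a conservative
choice that never flatters a window. The weight of W was chosen so that
the anchor dominates: a window without W at position 1 scores at least
0.5625, so no such window can pass the default threshold of 0.5. Any
transcribed matrix (e.g. from the original supplementary material) can be
dropped in through `read_motif_matrix()`.

```{r scan}
m <- build_default_matrix()
frag <- data.frame(id = "AKAP79", desc = "",
                   seq = paste0(strrep("X", 6), "GAWASLKRLVTRRKRS",
                                strrep("X", 10)))
scan_sequence(m, frag, threshold = 0.5, offset = 71)
```

The proteome-wide published result (570 sites, median 0.633, MAD 0.108 on
a specific SwissProt release with the original matrix) is
database-version and matrix dependent and is deliberately not an
assertion of this package; what the tests assert instead is perfect
recall of planted consensus motifs, W-dominance of reported hits, and the
median/MAD arithmetic on synthetic proteomes.

## Helix geometry

Backbone torsions use the standard conventions (φ: C(i−1)–N–CA–C, ψ:
N–CA–C–N(i+1), IUPAC signs), with termini and chain breaks (peptide C–N
distance > 2 Å) flagged undefined rather than dropped. Classification
into α vs 3₁₀ uses a right-handed helical band φ ∈ [−100°, −30°],
ψ ∈ [−80°, 0°] and a ψ boundary of −37° — the midpoint between the
canonical α (−47°) and 3₁₀ (−26°) values — because the distinguishing
feature of the 3₁₀ turn is its more positive ψ. The boundary and band are
arguments, not constants.

Backbone hydrogen bonds use a geometric criterion (N···O ≤ 3.5 Å and
N–H···O angle ≥ 120°, sequence offset ≥ 2) with the amide hydrogen
inferred in the peptide plane opposite the C(i−1)/CA bisector at 1.01 Å,
so the detector works on hydrogen-free crystal structures. A
DSSP-style energy criterion was considered and not used: the geometric
rule is transparent, has two interpretable knobs, and reproduces the
textbook offset spectra (all offset-4 bonds on an ideal α helix, all
offset-3 on an ideal 3₁₀ helix, and a 4→3 switch at the transition point
of a mixed plan) — exactly the diagnostics this analysis relies on.

The hydrophobic-face check projects each anchor's CA→CB vector onto the
plane normal to the local helix axis (the first principal axis of the CA
trace over the anchor span) and calls the set coherent when all pairwise
projected angles stay below 120°. On ideal geometry the 1-4-7-8 anchors
of the mixed α/3₁₀ helix project within ~110° of each other, whereas
anchors placed at i and i+9 of a pure α helix (front and back) exceed the
threshold.

```{r helix}
plan <- helix_plan("GAWASLKRLVTR",
                   phi = c(rep(-57, 7), -49, -49, rep(-57, 3)),
                   psi = c(rep(-47, 7), -26, -26, rep(-47, 3)))
hm <- make_helix(plan, chain = "D", start = 77)
classify_helix(compute_dihedrals(hm, "D"))[, c("resno", "phi", "psi",
                                               "class")]
detect_backbone_hbonds(hm, "D")[, c("donor_resno", "acceptor_resno",
                                    "offset")]
anchor_spacing(hm, "D", 79, 86)
```

## Surface areas and superposition

Solvent-accessible surface area is computed by the Shrake–Rupley method
with a deterministic golden-spiral point set (default 960 points per
atom, probe 1.4 Å) and a NACCESS-style radius table (C 1.70, N 1.55,
O 1.52, S 1.80 Å; Ca²⁺ 1.74 Å so structural calcium ions can be counted
with the protein component). No SASA implementation exists in the
installed R ecosystem used here, so the quadrature is implemented in the
package and is validated against the analytic isolated-sphere area
(< 1% error at the default point count), additivity, occlusion
monotonicity and quadrature convergence. Interface burial is
`sasa(A alone) − sasa(A in complex)` with conformations frozen, computed
symmetrically for both components.

For the compactness comparison, "exposed surface area" is the SASA of
the CaM component *alone in its bound conformation*; the complex-context
value is reported alongside since printed values of this kind are
ambiguous between the two readings. Reports state areas in Å².

Superposition is a reflection-corrected Kabsch fit (SVD of the
cross-covariance; `det(R) = +1` enforced). Copy-vs-copy RMSD pairs CA
atoms by identical author residue numbers present in both copies;
unresolved residues are skipped and counted, so partially disordered
copies compare over their common core.

## Binding-curve models

Three standard response models are fitted by bounded multi-start
Levenberg–Marquardt least squares (`minpack.lm::nls.lm` driven directly
on the residual function):

* inhibition: `R(x) = R_max − (R_max − R_min)·xʰ/(K^h + xʰ)` — `K` is
  the concentration of half-maximal inhibition (a competition `K_i`);
* activation: `R(x) = R_min + (R_max − R_min)·xʰ/(K^h + xʰ)` — `K` is
  e.g. the half-maximal free-Ca²⁺ concentration of a titration, `h` the
  Hill coefficient;
* cooperative Michaelis–Menten: `v(x) = V_max·xⁿ/(K^n + xⁿ)` for enzyme
  activation with baseline zero.

The half-maximal concentration is fitted on the log scale, which keeps
the Jacobian well scaled across decades of concentration, and is
reported as `K` with a delta-method standard error; other parameters are
natural. Starts cross five log-spaced `K` values with `h` ∈ {0.5, 1, 2,
4}; bounds are `K ∈ [x_min/100, x_max·100]`, `h ∈ (0, 10]`. Fits are
unweighted by default (matching plain iterative least squares);
`weighted = TRUE` uses `1/y_err²`. The formula front-ends (`nls`,
`nlsLM`) reject exact zero-residual optima, which noiseless round-trip
fixtures legitimately reach, so the optimizer is driven on the raw
residual function and the covariance is assembled from the returned
Gauss–Newton Hessian. A direction mismatch (fitting an activation model
to falling data, or vice versa) surfaces as `converged = FALSE` via a
negative fitted amplitude rather than as a silently wrong `K`. Whether
the original competition fits floated the Hill coefficient is not
stated in the source material; the default floats `h` and `fix_h = 1`
reproduces the fixed-slope convention.

```{r fit}
cv <- make_binding_curve("hill_activation",
                         list(K = 0.64, h = 4.4, R_max = 100, R_min = 3),
                         exp(seq(log(0.05), log(10), length.out = 12)),
                         noise_sd = 0.02, seed = 1)
fit_hill_activation(cv)
```

## What the synthetic data do and do not emulate

The generators are pure functions of their spec and seed. They emulate
the *statistical structure* the analyses consume — ideal backbone
geometry with exact torsions, i.i.d. background sequence composition
with planted motifs, a link table with hot-spot multiplicity, replicate
and charge structure and a sub-threshold tail, Gaussian noise on smooth
response curves. They do not emulate real crystallographic coordinates
(thermal disorder, side chains beyond CB, lattice contacts), real
proteome composition biases, peptide detectability or length biases in
MS, or heteroscedastic assay noise. Green tests on synthetic data
therefore demonstrate the correctness of the algorithms under their
stated models, not the field performance of the thresholds; the
deposited-structure checks (anchor spacings 11.9/14.4/19.5 Å, copy RMSDs
0.834/0.276/0.87 Å, CaM SASA ≈ 8700 Å², buried ≈ 740 Å², six
right-handed helical residues, unit cell a = 76.46 Å) run whenever the
corresponding coordinate files are placed under `inst/extdata/pdb/`, and
the ideal-geometry analogues of the spacings are computed in the
acceptance script from the builder.

## Numerical choices and problem sizes

* Dihedral/H-bond/face thresholds are documented above and configurable.
* SASA uses 960 points per atom by default; tests use 240–1920 where
  convergence itself is the property under test.
* Bootstrap triangulation uses 1000 resamples by default, seeded.
* The test-suite problem sizes — 100-protein proteomes (120–300
  residues), link tables of tens to hundreds of rows, 12-point titration
  curves, 100 noisy fit replicates — are desk-scale versions of the real
  analyses chosen so the whole suite runs in well under a minute while
  every property still has room to fail.
* The acceptance script averages four replicate noisy curves per fitted
  constant, mirroring the n = 4 replication of the titration
  experiments it emulates.

## Known limitations

* The shipped matrix encodes a verbal description; scores are not
  comparable to runs with the original matrix, only the scale convention
  and dominance structure are.
* The H-bond detector handles backbone bonds only and infers hydrogens
  geometrically; bifurcated or side-chain-capped bonds (e.g. a helix
  C-cap satisfied by a partner side chain) appear simply as "no backbone
  partner".
* `deduplicate_links` assumes the id score/FDR of charge duplicates
  agree; discordant duplicates are resolved best-first, which can make
  filtering and deduplication order-dependent in principle.
* The triangulation interval is a descriptive bootstrap over detections,
  not a confidence statement about the binding site: detections of one
  pair are not independent observations of position.
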