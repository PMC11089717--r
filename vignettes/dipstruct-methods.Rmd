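---
title: "Models and methods behind dipstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dipstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dipstruct)
```

`dipstruct` analyses diploid single-cell chromatin contact data: it imputes
parental haplotypes on sparsely phased contacts, reconstructs a diploid 3D
model of each nucleus, and computes the architecture statistics that separate
pluripotent cell states — territory intermingling, radial CpG organisation,
single-cell compartments and A/B calls. This vignette explains the models,
the tunable parameters and the numerical choices, and states what the
synthetic data can and cannot establish.

## Coordinates and containers

All coordinates are 0-based; bins are half-open `[k*s, (k+1)*s)` so a
coordinate `c` falls in bin `floor(c/s)` — the BED convention, which makes
track and locus interchange unambiguous. A contact is a canonically ordered
pair of legs `(chromosome, bp, haplotype)` with haplotype `mat`, `pat` or
`unknown`; a structure is one particle per `(chromosome, haplotype, bin)`
with coordinates in model units where the backbone bond length is 1 and the
particle radius 0.5. In 3DG files the haplotype rides on the chromosome name
(`chr1(mat)`), keeping the five-column layout.

## Haplotype imputation in contact space

For a target contact with at least one unknown leg, the compatible haplotype
tuples are enumerated (4 when both legs are unknown, 2 when one is). Every
fully phased contact on the same chromosome pair votes for the single tuple
matching its own haplotypes, provided it lies within the evidence window in
the L^0.5 dissimilarity

\[(\sqrt{|\Delta x|} + \sqrt{|\Delta y|})^2,\]

which disfavours simultaneously large `dx` and `dy` — two tethered
chromosomes protrude into each other rather than mix fully, so informative
evidence is concentrated near the target in this geometry. It is not a norm
(no triangle inequality), which is why all neighbourhood searches are
explicit pair scans rather than metric-tree lookups.

The decision rules, all inclusive and checked with a `1e-9` absolute
tolerance so that exact boundary counts such as 9-of-10 at 90% behave as
printed:

* a tuple wins with `>= min_votes` (default 3) votes and
  `>= win_fraction` (default 0.90) of all cast votes; ties yield no winner
  (conservative, in the spirit of the 90% rule). Abstaining neighbours are
  not counted in the denominator — only cast votes are.
* intrachromosomal targets separated by `<= 10` Mb with one known leg are
  assumed intrahomologous without voting; intrachromosomal targets unknown on
  both legs are never imputed in contact space; a winning *inter*homologous
  tuple on an intrachromosomal target is accepted only at separations
  `>= 100` Mb. Intrahomologous contacts dominate at short range, and these
  gates encode that prior.
* for intrachromosomal pairs the leg pairing is ambiguous; the pairing
  minimising the L^0.5 distance is used (ties resolve to the direct
  pairing), and the evidence haplotypes travel with the pairing.
* evidence must be fully phased: a half-phased contact is in general
  compatible with more than one tuple and cannot cast the unambiguous vote
  the rule requires.

Rounds are synchronous: each round votes against the frozen output of the
previous round (self-votes excluded by contact id), so results do not depend
on iteration order. After the default three rounds, isolated contacts —
fewer than 2 other contacts with identical haplotypes within 10 Mb in
L^0.5 — are removed from the phased subset, evaluated simultaneously so the
filter is order-independent. Unresolved contacts are carried through: the
final round (cleaned evidence, interchromosomal both-unknown targets)
requires them, and they are the substrate for structure-based imputation
later. `score_imputation()` reports the resolved fraction and truth accuracy
over initially unknown legs, by contact id, so dropped contacts count as
unresolved.

At the default study conditions (30% leg phasing, 20,000 contacts per cell)
the contact-space stage resolves roughly two thirds of the unknown legs at
95%+ accuracy. Two structural ceilings cap the resolved fraction well below
100%: intrachromosomal contacts unknown on both legs are never imputed by
rule and contribute on the order of a fifth of all unknown legs for any
polymer-realistic contact list, and the 90% unanimity rule fails wherever
the 10-Mb window of a small toy genome mixes evidence from more than one
homolog-combination interface. Vote count scales with (window/genome size)^2
while vote purity scales the other way, so no toy-genome geometry relaxes
both at once; the remaining legs are recovered, where geometry permits, by
the 3D stage.

## Conditional contact density

Given one contact at `(x, y)` on a chromosome pair, the density of further
contacts at `(x+dx, y+dy)` is modelled as `(sqrt(dx)+sqrt(dy))^-2` and
compared with the `(dx+dy)^-1` null that full intermingling of the tethered
chromosomes would produce. `fit_contact_decay()` bins pair differences into
log-spaced 2D cells, estimates density as count/area, and regresses log
density on the log of each candidate metric (count-weighted least squares,
geometric bin centres); the model with the smaller weighted residual sum of
squares is preferred, and the slope on `log(sqrt(dx)+sqrt(dy))` estimates
the exponent (−2 under the L^0.5 law). Degenerate support (all mass at one
point, or fewer than 5 occupied bins) is an error rather than a fit.
`sample_decay_pairs()` inverts both laws exactly on a log-log support square
by rejection sampling against the laws' maximum (both densities increase in
both log-coordinates), providing the independent oracle for the fit.

## 3D reconstruction

Restraints from `build_restraints()`: harmonic backbone bonds between
consecutive present bins of each chromosome copy (stiffness 10, target =
bond length); one upper-bound contact restraint per distinct particle pair
(flat below the target distance, quadratic above, weight = contact
multiplicity, target = 2 bonds); a soft spherical wall at the radius giving
a 0.12 particle volume fraction; and short-range excluded-volume repulsion
`k(1-d/d_rep)^2` below `d_rep` = 2 particle radii, tracked with a linked
cell list. The repulsion term is load-bearing: with upper-bound contact
restraints alone the global energy minimum is a collapsed ball that
satisfies every restraint while destroying all distance information.

Annealing is single-particle Metropolis over a geometric temperature ladder
(default 20 steps, 4 → 0.02, proposal step 0.4·sqrt(T)). The resolution
ladder (default multipliers 8, 4, 2, 0.4, 0.2, 0.1) is interpreted as
successive stages: multipliers `>= 1` rebuild the model at
`multiplier × bin size` (bond lengths scale as sqrt(multiplier), the
random-walk statistics of chromatin at coarser binning) and seed the next
stage by linear interpolation along the backbone; multipliers `< 1` refine
at the base resolution with the starting temperature scaled by the
multiplier. Non-finite energy aborts with the stage index. Solutions are
defined only up to rigid motion and reflection — chirality is not
identifiable from contacts — so every downstream metric is invariant under
orthogonal transforms, and the tests assert this to 1e-9.

Structure-based imputation (`impute3d()`): for a contact with exactly one
unknown leg, the two candidate homolog particles are compared by distance to
the partner leg's particle, and the nearer one is assigned iff
nearer/farther `<= rho` (default 0.5). The gate is deliberately
conservative: a wrong 3D assignment corrupts the next reconstruction round,
and a 2:1 distance margin keeps the observed per-round accuracy at the level
of the 2D stage. `reconstruct_pipeline()` alternates reconstruction and 3D
imputation — 3 rounds at 5× the base bin size, then 2 rounds at base
resolution — rebuilding restraints from the newly resolved contacts each
round.

## Architecture metrics

* **Intermingling index**: per particle, the fraction of neighbours within
  3 particle radii (configurable) that belong to a different chromosome.
  Homologs count as the *same* chromosome by default — territory mixing is
  about chromosome names — with `homologs_distinct = TRUE` as the
  alternative. Particles with no neighbours are excluded from the cell mean
  and counted.
* **Compartmentalization score**: Spearman correlation (mean ranks on ties)
  between each particle's CpG and its neighbours' mean CpG; constant input
  returns 0 flagged degenerate.
* **Radial positions**: distance to the centre of mass divided by the cell
  mean, so the output has mean exactly 1 and cells of different size are
  comparable. Shell profiles average CpG over particles in equal-width
  shells of normalized radius (20 shells by default; particles, not genomic
  bins, are the averaging unit), per cell, then unweighted over the cells of
  a cohort.
* **Radial-CpG correlation**: per 1-Mb bin (haplotypes pooled), mean
  normalized radius vs bin CpG, Spearman by default (Pearson switchable).
  Its sign reads out "inside-out" (+, CpG-rich peripheral, primed-like) vs
  "out-inside" (−, naive-like).
* **Contacting CpG**: per bin, the contact-weighted mean CpG of partner
  bins, excluding self-partners. Diploid mode uses only fully phased
  contacts and keeps the two alleles as separate loci; cell-type mode pools
  alleles and uses all contacts. Cell clustering (PCA on centred vectors
  over loci present in every cell, then seeded 2-means on the top two
  components) uses cell-type mode: at 30% phasing and 20,000 contacts per
  cell the allele-resolved vectors are too sparse for stable clustering at
  n = 5+5, and cell identity is a cell-type feature, computed from all
  contacts. Diploid mode remains available for allele-level questions.
* **A/B compartments**: per chromosome, observed/expected normalisation by
  per-diagonal means over covered bins, Pearson correlation matrix, leading
  eigenvector, sign oriented so that the eigenvector correlates positively
  with CpG (A = positive = euchromatic); uncovered bins are masked, and the
  leading eigenvalue share is reported so compartment-free inputs can be
  recognised (the planted-null simulation leaves it well under 0.2).
* **Differential heatmaps**: `log2((A + 1) / (B' + 1))` with B scaled to A's
  total — invariant to sequencing depth, stabilised at sparse bins by the
  unit pseudo-count.

## The synthetic-nucleus generator

Each chromosome copy is a confined random walk (one particle per bin)
relaxed by Metropolis sampling (kT = 1, 400 sweeps) under harmonic bonds, a
hard spherical wall, and two planted fields: a radial CpG bias
`-sign × strength × z(CpG) × r/R` and a territory attraction
`strength × |x - anchor|^2 / r_t^2` toward the copy's initial centroid,
with `r_t` the radius a single compact territory would occupy. Contacts are
drawn uniformly from unordered particle pairs within the capture radius
(self and immediate backbone neighbours excluded — adjacent-bin contacts
carry no 3D information and would otherwise dominate), a uniform bp offset
within the bin, and each leg's haplotype revealed independently with the
phasing probability; the true haplotypes of every leg are recorded.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| genome | 20 chromosomes × 15 Mb, 1-Mb bins | 600 diploid particles; every chromosome stays large relative to the 10-Mb evidence window, and many chromosomes keep interchromosomal pairs dominant, as in a real karyotype |
| packing fraction | 0.15 | chromatin occupies roughly a tenth to a third of nuclear volume |
| capture radius | 2.5 bonds | generous proximity-ligation capture; keeps per-window vote counts usable at 20,000 contacts |
| contacts/cell | 20,000 | single-cell scale |
| phase rate | 0.3 | sparse heterozygous SNP coverage, modelled per leg without explicit SNPs |
| radial bias strength | 4 | plants radial-CpG correlations of clearly detectable magnitude with the correct sign in essentially every cell |
| territory strength | naive 6, primed 0.5 | chosen (on seeds held out from the test suite) so the planted intermingling *and* interchromosomal-fraction contrasts are detectable by rank tests at 5 cells per cohort, the cohort size the analysis targets |

The generator emulates: diploid particle models in a spherical nucleus,
backbone continuity, territory formation, both radial CpG architectures,
proximity-derived contacts, partial phasing. It does **not** emulate loop
extrusion, TADs as mechanistic objects, X inactivation, copy-number
variation, nor the read-level error processes of sequencing. Passing tests
therefore demonstrate that the pipeline recovers planted architecture from
contact lists with realistic sparsity — not that it would be similarly
accurate on any real library, whose contacts are deeper but noisier and
whose genome is 10× larger.

## Problem sizes and determinism

The shipped tests and the acceptance script run everything at the toy scale
above: single cells of 600 particles and 20,000 contacts, cohorts of 5 + 5
cells, up to ten cohorts for clustering stability, 50 random sets of up to
1,000 contacts for the brute-force voting oracle, and one full
multi-resolution reconstruction. Every stochastic step takes an explicit
seed (per-cell seeds derive arithmetically from a base seed; the RNG state
is restored afterwards), so cohorts, reconstructions and the whole
`run_pipeline()` are bit-reproducible.

## Known limitations

* The resolved-fraction ceiling of the contact-space imputation stage at
  sparse phasing (see above); the 3D stage recovers only the geometrically
  unambiguous remainder.
* Annealing is a stochastic optimiser: reconstruction fidelity is asserted
  as a distance-matrix rank correlation, not coordinate identity, and
  chirality is never resolved.
* A/B calling needs tens of covered bins per chromosome; the toy genome's
  15-Mb chromosomes are analysed for A/B only through the dedicated
  planted-compartment generator, whose single chromosome is sized for the
  eigenvector analysis.
* Cohort contrasts at n = 5 + 5 use exact rank tests; effects of the
  planted magnitude sit near the detection limit for the interchromosomal
  fraction, so occasional non-significant draws are expected and honest.
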