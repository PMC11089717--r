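# dipstruct

Diploid single-cell 3D genome reconstruction and nuclear-architecture
analysis in R.

Single-cell chromatin conformation capture with haplotype resolution
(Dip-C-style experiments) yields, per cell, a list of chromatin *contacts* —
pairs of genomic *legs* `(chromosome, coordinate, haplotype)` — in which most
legs have an unknown parental haplotype because phased SNPs are sparse. From
those contacts one can impute the missing haplotypes, fold a diploid 3D model
of the nucleus, and quantify nuclear architecture: how strongly chromosome
territories intermingle, whether euchromatin (CpG-rich chromatin) sits at the
nuclear centre or periphery, and how single cells cluster by their chromatin
compartments. These are the statistics that distinguish naive from primed
human embryonic stem cells: primed-like nuclei are more intermingled, with
more interchromosomal contacts and an "inside-out" radial architecture
(CpG-rich chromatin peripheral), naive-like nuclei the reverse.

`dipstruct` implements that pipeline end to end, together with a synthetic
diploid-nucleus generator that plants all of these architectural signals with
known ground truth, so every stage is testable without any sequencing data.

## What is implemented

* **Haplotype imputation (2D)** — neighbourhood voting in the L^0.5 contact
  distance `d((x1,y1),(x2,y2)) = (sqrt(|dx|) + sqrt(|dy|))^2`: an evidence
  contact within 10 Mb of a target votes for the unique compatible haplotype
  tuple; a tuple wins with >= 3 votes and >= 90% of all votes. Special
  intrachromosomal rules (<= 10 Mb intrahomologous shortcut, >= 100 Mb
  interhomologous acceptance, both-unknown never imputed), three rounds with
  the previous round as evidence, isolated-contact cleaning (< 2
  same-haplotype neighbours within 10 Mb), and a final interchromosomal round
  (`impute_round()`, `remove_isolated()`, `impute_pipeline()`).
* **Conditional contact-density law** — the empirical law
  `p(dx, dy) ∝ (sqrt(dx) + sqrt(dy))^-2` for contacts near an existing
  contact, fit against the `(dx + dy)^-1` full-intermingling null
  (`conditional_density()`, `fit_contact_decay()`, `sample_decay_pairs()`).
* **3D reconstruction** — restraint-based simulated annealing (harmonic
  backbone, upper-bound contact restraints, spherical confinement, excluded
  volume) over a multi-resolution ladder, alternated with structure-based
  haplotype imputation of the remaining unknown legs (`build_restraints()`,
  `anneal()`, `impute3d()`, `reconstruct_pipeline()`).
* **Structure metrics** — per-particle chromosome intermingling index,
  compartmentalization score (Spearman correlation of own vs neighbour CpG),
  mean-normalized radial positions, radial CpG shell profiles, radial-CpG
  correlation per 1-Mb bin, gene-locus radial placement, serial
  cross-sections (`intermingling_index()`, `compartment_score()`,
  `radial_cpg_profile()`, `radial_cpg_correlation()`, ...).
* **Contact metrics** — "contacting CpG" single-cell compartment vectors,
  PCA + 2-means cell clustering, interchromosomal fractions and pair maps,
  binned contact heatmaps with a depth-invariant differential view, and
  Lieberman-Aiden A/B compartment calling (observed/expected, correlation
  matrix, leading eigenvector oriented to CpG) (`contacting_cpg()`,
  `compartment_pca()`, `ab_compartments()`, ...).
* **Synthetic nuclei** — confined random-walk polymers relaxed under radial
  CpG bias and territory attraction; proximity-ligation contact sampling with
  partial phasing and full truth records (`make_toy_genome()`,
  `cell_archetype()`, `simulate_structure()`, `sample_contacts()`,
  `simulate_cohort()`).
* **Pipeline** — `run_pipeline()` chains simulate → impute → reconstruct →
  metrics → compare (Wilcoxon rank-sum cohort contrasts) with per-stage
  artifacts and full seed provenance.

File formats: a 6-column whitespace contact dialect (`.` = unknown
haplotype), the tab-delimited 3DG structure format (chromosome with
`(mat)`/`(pat)` suffix, bp, x, y, z), bedGraph CpG tracks and BED4 loci.

## Worked example

```r
library(dipstruct)

toy  <- make_toy_genome(seed = 1)         # 20 chromosomes x 15 Mb, 1-Mb bins
arch <- cell_archetype("primed_like", seed = 7)
st   <- simulate_structure(toy$genome, toy$cpg, arch, cell_id = "cell_1")
sc   <- sample_contacts(st, arch, toy$genome)
sc$contacts
#> <contact_set> cell 'cell_1', stage raw: 20000 contacts (16039 interchromosomal, 28075 unknown legs)

cleaned <- impute_pipeline(sc$contacts, verbose = TRUE)
#> input          20000 contacts,   28075 unknown legs
#> round_1        20000 contacts,   17234 unknown legs
#> round_2        20000 contacts,   11270 unknown legs
#> round_3        20000 contacts,    9878 unknown legs
#> cleaned        14187 contacts,       0 unknown legs
#> final          19845 contacts,    9326 unknown legs

score_imputation(sc$contacts, cleaned, sc$truth)[1:2]
#> $resolved_fraction
#> [1] 0.6678183
#> $accuracy
#> [1] 0.9492773

intermingling_index(st)$mean                    # territory mixing, 0..1
#> [1] 0.5040852
as.numeric(radial_cpg_correlation(st, toy$cpg)) # > 0: "inside-out" nucleus
#> [1] 0.52086
interchrom_stats(sc$contacts)$fraction
#> [1] 0.80195
```

Reading the output: at a 30% phasing rate this cell starts with 28,075
unknown legs; three voting rounds plus the final interchromosomal round
resolve about two thirds of them, 95% correctly against the simulator truth
(the residue is dominated by intrachromosomal contacts unknown on both legs,
which the 2D stage never imputes by design). The positive radial-CpG
correlation recovers the planted "inside-out" (primed-like) architecture,
and the high intermingling and interchromosomal fraction match the weak
territories of that archetype.

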