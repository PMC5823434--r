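---
title: "Specific conservation analysis of domain families"
author: "specon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specific conservation analysis of domain families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specon)
```

## The question and the model

Members of a protein interaction-domain family share a fold and a canonical
binding mode, yet individual members often bind distinct targets. specon
asks, position by position, which residues make a member unique. It
contrasts two alignments:

* the **paralog alignment** — every family member within one reference
  species (for the motivating system, the 28 SH3 domains of
  *S. cerevisiae*);
* one **ortholog alignment per member** — that member aligned with its
  direct relatives across related species (here, up to 29 fungal
  sequences spanning roughly a billion years of divergence).

Conservation at an alignment column is scored on a reduced alphabet.
Residues are binned into six **equivalency groups** — AVLIMC, FWYH, STNQ,
KR, DE, GP — and the column's **positional entropy** is

$$ E = \exp\Big(-\sum_{i=1}^{6} p_i \ln p_i\Big), $$

where $p_i$ is the fraction of grouped residues in group $i$. $E$ is the
effective number of groups at the position: 1 when perfectly conserved, 4
when four groups each occur 25% of the time, at most 6. Positions with too
many gaps carry no entropy: the **gap threshold** requires a non-gap
fraction of at least 0.64, i.e. 19 of 29 rows.

The **specific conservation (SC) value** of a canonical position in one
member is

$$ \mathrm{SC} = \frac{E_\text{paralog}}{E_\text{ortholog}}. $$

Housekeeping positions (conserved everywhere) give SC near 1. Positions
that vary freely in both alignments also hover near 1. High SC — variable
across the family, frozen within the member's own lineage — flags
candidate specificity-determining residues. An average SC of **1.7 or
more** over a region is treated as high (ortholog conservation roughly
twice paralog conservation).

## Canonical numbering and surfaces

All statistics are reported on a canonical 60-position domain numbering
anchored by a reference row: `buildCanonicalMap()` numbers the reference's
residues inside a user-supplied span, labels reference-gap columns as
insertions anchored to the canonical position on their left (`14a`,
`14b`, ...) and labels columns outside the span as N-/C-flanks. The span
is supplied rather than auto-detected because domain boundaries in full
protein alignments are a curation decision, not an alignment property.

Two binding surfaces partition the canonical positions
(`defaultSurfaces()`): **SI** = {8, 9, 10, 36, 37, 51–54}, the canonical
PxxP groove; **SII** = {13–17, 30–35, 38, 49}, the extended specificity
surface between the RT- and N-Src loops; `other` is the remainder.
`averageRegionSC()` averages SC over a surface, skipping undefined
positions in both numerator and denominator.

Conserved insertions are counted by `conservedInsertionCount()`: an
insertion or flank column counts when its ortholog entropy is defined and
**at or below 3.3**. Insertions are assigned to loops by their anchor
(RT-loop 11–19, N-Src 29–35, distal 42–48 — the publication names the
loops without printing residue ranges, so these ranges are configurable).

## PSSMs and family clustering

`buildPSSM()` tallies group occurrences per canonical position in each
ortholog alignment and normalises rows to frequencies.
`buildMasterMatrix()` flattens one row per member, position-major; with
the defaults this is the 28 × 360 family matrix. `subsetSurface()`
restricts it to a surface's blocks (SI → 54 columns, SII → 78), and the
matrix is clustered two ways: `clusterKmeans()` (Euclidean, 50 restarts,
seed recorded — default k = 4, matching the four main branches reported
for SI) and `clusterHierarchical()` (agglomerative; average linkage and
Euclidean distance as defaults, exportable as Newick). Both are provided
because a k-means partition cannot produce the published dendrograms; the
linkage behind those figures is unstated, so tree topology is treated as
qualitative. The reproducible claim — SII profiles spread family members
further apart than SI profiles — is checked through
`meanPairwiseDistance()` on the two surface restrictions.

All-gap positions keep zero-frequency blocks rather than being dropped,
so every member shares one column frame.

## Binding fractions

Peptide-array (SPOT) intensities are scored per species. After averaging
closely related within-species paralog columns (`mergeParalogs()`; the
four *S. cerevisiae* pairs take a 28-domain panel to 24), the **binding
fraction** of peptide $i$ for domain $d$ in species $j$ is

$$ \mathrm{BF}(i,j,d) = \frac{\mathrm{BI}(i,j,d)}
   {\sum_{k} \mathrm{BI}(i,j,k)}, $$

the denominator running over every merged domain assayed in that species.
Peptides whose intensity sum falls below **1000 units** are excluded
first (inclusive boundary: a sum of exactly 1000 is retained, since the
rule excludes sums *below* the floor). A fraction **strictly greater than
0.5** is a specific call, which makes at most one call per peptide and
species. `summarizeDomain()` reports, per domain, the number of specific
peptides, the best peptide by mean BF across species with data
(lexicographic id on ties), that mean, and species support; a species
lacking either the domain or the best peptide is dropped from both
support counts. Missing species data are represented as absent columns,
never as zeros. `rankPeptides()` ranks by mean BF or mean raw intensity —
the two orders disagree when promiscuous high-intensity peptides are
present, which is the point of the fraction.

## What the synthetic generator emulates

`generateFamily()` plants the three position classes the analysis is
meant to separate: housekeeping positions keep one group family-wide
(switch probability 0.02 in both alignments), specificity positions draw
an independent group per member and hold it within orthologs (switch
0.05), variable positions churn (switch 0.65). The default class map
places specificity on SII and housekeeping on SI, 28 members × 29
orthologs × 60 positions, per-cell gap probability 0.02, reference rows
ungapped so canonical mapping is exact. Residues are sampled uniformly
within a chosen group, because every statistic in scope is group-level.
Optional insertions (count and conservation per region) exercise the
insertion machinery.

`generateBinding()` emulates the assayed data's shape: 4 species × 300
peptides × 24 domains, log-normal background (meanlog $\ln 60$, sdlog 1,
giving row sums comfortably above the 1000-unit floor), 150 peptides
planted as specific binders of one domain each at a binding fraction near
0.7 (±5% jitter), and 10 peptides scaled below the signal floor. Both
generators are deterministic given their seed (R's Mersenne-Twister).

What the generator does **not** emulate: tree-structured evolution
(orthologs are i.i.d. around the member sequence, so real phylogenetic
correlation is absent), alignment error, compositional biases within
groups, and SPOT-array noise physics (saturation, spatial artefacts).
Passing tests therefore demonstrate that the statistics recover planted
structure under clean conditions, not that real alignments are free of
the curation issues the canonical-mapping step exists to manage.

## Numerical choices and edge cases

* $p_i$ is computed over grouped residues only; gaps and ambiguity
  letters (X, B, Z, ...) count neither in numerator nor denominator, and
  the gap threshold handles depth separately. This keeps
  $\sum_i p_i = 1$ so the entropy is well defined. Ambiguity letters are
  retained by the reader but treated as gaps downstream.
* $0 \ln 0 \equiv 0$ (the standard entropy limit).
* The gap threshold applies to both alignments independently; SC is
  undefined unless both entropies are defined.
* SC tables carry full precision plus a 1-decimal display column, since
  rounding the entropies before dividing distorts the ratio.
* The entropy cutoff 3.3 for insertions and the 1.7 SC line are inclusive
  (≤ and ≥); the binding-fraction call is strict (> 0.5), so a perfectly
  split 0.5/0.5 peptide is specific for neither domain.
* k-means labels follow R's 1..k convention; seeds and restart counts are
  recorded in the `ClusterResult`.

## Problem sizes

The test suite and the reproduction script run entirely on generated
data at the study conditions: families of 28 × 29 × 60 (seconds to
profile), the 28 × 360 master matrix, and 4 × 300 × 24 binding panels.
Smaller toys (3–10 rows) are used where a hand-computable answer is the
oracle.

## Worked example

```{r example, eval = FALSE}
fam <- generateFamily(familySpec(seed = 1))
dom <- "Dom01"
o <- fam$orthologs[[dom]]
pmap <- buildCanonicalMap(fam$paralog, dom, c(1, 60))
omap <- buildCanonicalMap(o, alignmentIds(o)[1], c(1, 60))
prof <- scProfile(profileAlignment(fam$paralog, pmap),
                  profileAlignment(o, omap), dom)
averageRegionSC(prof, defaultSurfaces()$SII)
runPipeline(runConfig(seed = 1), "specon-out")
```

## Limitations

SC is a fixed-cutoff heuristic: no significance test accompanies the 1.7
line, and single-position SC cannot capture the "deviant but conserved"
mode in which a member's canonical surface is conserved around a
non-canonical identity. Cluster topology depends on unstated linkage
choices and is treated as qualitative. Binding fractions measure relative
specificity within the assayed panel only; a domain specific against its
family may still cross-react inside the cell.
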