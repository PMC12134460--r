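---
title: "Comparing DDR protein repertoires and lengths across eukaryotes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing DDR protein repertoires and lengths across eukaryotes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

The DNA damage response (DDR) is a network of several hundred proteins that
recognise, signal and repair DNA lesions. Across eukaryotes this network is
unevenly preserved: free-living organisms tend to keep most of it, while
parasites — especially intracellular and intranuclear parasites with
compacted genomes, such as microsporidia — shed large parts of it.
`repairome` implements a comparative pipeline for quantifying this erosion
and the accompanying changes in protein length architecture:

1. Which human-anchored orthologue families survive in which genomes
   (presence/absence, with a rescue step for orthologues missed by global
   clustering)?
2. How preserved is each pathway in each genome (*preservation values*),
   and how does preservation vary with lifestyle?
3. How do protein lengths differ between pathway groups (DDR, DNA
   replication, metabolic, housekeeping), and where in the protein does the
   variation live — inside Pfam functional domains, or in the interdomain
   space?

Because the original inputs (dozens of proteomes, orthology-tool and
domain-scanner outputs) are too large to reproduce at desk scale, the
package pairs the analysis code with a seeded synthetic-world generator
whose ground truth is known. Every pipeline stage is tested by parameter
recovery on those worlds, and by closed-form or brute-force oracles where
they exist.

## Orthology model

**Family extraction.** Orthogroups are ingested in the Orthofinder
`Orthogroups.tsv` dialect. Each human *anchor protein* maps to the (unique)
orthogroup containing it; an anchor in no orthogroup maps to none. Two
anchors may share an orthogroup (co-orthology); each then receives the
orthogroup's members independently — this matches what parsing a single
clustering output without gene-tree resolution can support, and is noted as
a confound rather than resolved.

**Presence and representative length.** For each (anchor, species) pair,
the cell is *present* when the anchor's orthogroup has members in that
species. The representative length is the **maximum** over in-paralogues
(with the copy count recorded); the mean is available behind
`rep_rule = "mean"`. The maximum is the default because the length analyses
of interest concern the longest proteins in each family, and because
in-paralogue counts are small and recorded alongside.

**Excluded absences.** A species whose proteome is known to be severely
incomplete can be flagged `excluded_absences`. Its absences become
`excluded` rather than `absent` and leave both numerator and denominator of
every preservation value and of the audit. Its presences are kept — an
observed protein is evidence regardless of assembly completeness.

**Bait rescue.** Global orthology clustering can miss true orthologues in
distant lineages. The rescue step routes around this: each clade declares a
reference species with an independently confirmed anchor-to-reference
orthology table (ingested as a file; it stands in for a pairwise orthology
database lookup). For an absent cell, if the anchor has a confirmed
reference orthologue, that reference accession is used as *bait* in the
reference-vs-query pairwise ortholog table; if the bait co-occurs with
query-species accessions, the cell becomes present with provenance
`rescued`. Rescue never touches present or excluded cells and is
idempotent, so presence counts are monotone under it.

**Calling-reliability audit.** Anchors present in more than 95% of
assessable species are so widely conserved that their few absences are
plausibly methodological. The audit asks: if every absence were an
independent per-species calling failure at rate *f*, how probable is
observing at least the recorded number of absences? That is the binomial
tail `P(X >= k)`, `X ~ Binomial(n, f)`. The default `f = 0.045` is one
minus the lower bound of the audited calling coverage (95.5%). The binomial
tail is a documented modelling choice — the simplest model consistent with
reporting a probability range across conserved groups — not a
reconstruction of any particular published calculation.

## Preservation scoring

The preservation value of pathway *P* in species *s* is

$$v_{s,P} = \frac{\#\{\text{anchors of } P \text{ present in } s\}}
                 {\#\{\text{assessable anchors of } P \text{ in } s\}}.$$

Summaries are unweighted means of these values within cells (by species,
by pathway, or by lifestyle x pathway-group). A species' *overall*
preservation is the mean of its pathway values rather than the pooled
protein fraction, so that small pathways (e.g. a six-protein nucleotide
pool modulation pathway) are not swamped by large ones; the pooled fraction
is available behind `pooled = TRUE`. Cells with no assessable anchors are
missing, never zero. Error bars in lifestyle summaries are standard errors
over species within a lifestyle (the alternative — over pathways — is
obtainable from the per-pathway table).

## Domain decomposition

Domain extent is taken from **envelope** coordinates of `pfam_scan` hits
(HMMER's probabilistic domain bounds); alignment coordinates are parsed and
validated but do not define extent. All coordinates are 1-based inclusive
and converted nowhere. Per protein:

- merged intervals: the disjoint union of hit envelopes, with overlapping
  *and bookended* (`end + 1 == next start`) intervals coalesced, so no
  residue is double-counted;
- functional domain length `D` = total covered residues;
- interdomain length `I = L - D`, which deliberately **includes N- and
  C-terminal tails** — terminal extensions are part of the interdomain
  expansion under study;
- footprint `D / L`; and domain density = raw hit count per covered
  residue (also per 100 covered residues). The density numerator counts
  **raw hits before merging**, because the claim of interest is about
  packing more individual domains into a small footprint; the merged
  segment count is recorded alongside.

`D + I = L` holds exactly (integer identity) for every protein; hits
outside `[1, L]` are an error (an annotation/length mismatch), never
clipped. No E-value filtering is applied beyond the scanner's own defaults;
an optional threshold knob exists but defaults to off.

**Correlation unit.** The Spearman correlations between protein length,
`D` and `I` are computed on species-level means (one triple per species) by
default: with 68 species this gives the `n - 2 = 66` degrees of freedom
that published correlations of this design report. Whether such analyses
pool proteins instead is often unstated; both modes are emitted
(`corr_unit = "protein"` pools).

## Statistical kernel

- **Spearman**: Pearson correlation of average ranks; p from the t
  approximation `t = rho * sqrt((n-2)/(1-rho^2))`; an exact permutation p
  (via the exact reference distribution) is available for `n <= 10` without
  ties. Constant inputs yield a flagged missing result.
- **One-way ANOVA**: classic `F = MS_between / MS_within`, df `(g-1, n-g)`.
  A zero within-group mean square reports `F = Inf` with a warning.
- **Two-way ANOVA with interaction**: fixed effects, sum-to-zero
  contrasts, **Type III** sums of squares by default, computed as
  residual-sum-of-squares differences between the full least-squares fit
  and fits with the effect's columns removed. Type III matches the
  conventions of mainstream biostatistics GUIs whose reporting style these
  analyses mirror; Types I and II sit behind `ss_type`. Empty cells are an
  error instructing aggregation to cell means. In the pipeline the
  observation unit is one (species, pathway-group) cell mean, giving the df
  patterns `F(3, 64)` for 68 species in 4 lifestyles and `F(9, 256)` /
  `F(3, 264)` for the 272-cell two-way designs.
- The published F values of the emulated study are properties of its real
  data; the pipeline reproduces the factors and df arithmetic and validates
  its kernel against oracles, not against those F values.
- p-values are carried at machine precision; "< 0.0001"-style truncation
  belongs to rendering, not storage.

## The synthetic world generator

The generator's defaults are the study conditions, fixed once:

| parameter | default | rationale |
|---|---|---|
| species | 28 free-living (incl. the human anchor), 20 extracellular, 16 cytoplasmic, 4 intranuclear | 68 genomes, with intranuclear eukaryotes as rare as they are in public data |
| catalogue | 432 DDR (12 pathways, incl. a 6-anchor nucleotide pool modulation pathway), 35 replication, 38 metabolic, 21 housekeeping | the emulated catalogue sizes |
| lengths | log-normal; housekeeping median 400 aa, log-sd 0.35; medians x1.84 for DDR and replication, x1.84/1.24 for metabolic | right-skewed lengths; the multipliers encode "DDR ~84% longer than housekeeping, ~24% longer than metabolic" as median effects |
| retention | monotone decline free-living -> intranuclear; replication >= housekeeping >= metabolic >= DDR in every lifestyle (0.98..0.35) | graded loss with replication most indispensable |
| footprints | DDR 0.40, replication 0.45, metabolic 0.55, housekeeping 0.60; mean hit counts 4/4/2/2 | DDR/replication: small footprint, high domain density |
| clustering-miss rate q | 0.045 | one minus the 95.5% lower bound of audited calling coverage |
| in-paralogue probability | 0.05 | occasional duplicates; longest copy is representative |
| interactions | Poisson means 15 (DDR), 12, 8, 6 (housekeeping) | the DDR-vs-housekeeping interaction-count contrast |

A planted miss removes a truly present orthologue from the orthogroup
table but keeps it in the clade-reference pairing file, making it exactly
the signature the rescue step hunts. Misses are never planted in the human
species, in clade-reference species, or in the truncated (excluded)
species: a missed reference could not serve as bait, and rescue never
touches excluded cells, so such plants would be unrecoverable by
construction rather than by biology — the planted set is kept identical to
the rescuable-by-design set plus those whose reference genuinely lacks the
anchor.

Randomness is organised as per-species and per-purpose substreams derived
from the master seed by a stable string hash, so a fixed seed reproduces
the world bit-for-bit and adding a species does not reshuffle the others.

Domain placement draws a hit count per protein, splits the target coverage
`round(c * L)` into segments of at least 5 residues, and spaces them with
at least one uncovered residue so segments never bookend. A configurable
fraction of hits is then duplicated as *nested* sub-intervals: this
exercises interval merging while leaving true coverage — hence the
footprint ground truth — unchanged. A coverage target that would leave no
interdomain residues is a configuration error.

**What the generator does not emulate:** realistic amino-acid composition
(sequences are i.i.d. residues, generated only when worlds are written to
FASTA), phylogenetic correlation of losses along a tree, indel-level
sequence evolution, and annotation error beyond the one truncated
proteome. Passing recovery tests on these worlds therefore shows the
pipeline measures what it claims on data of this structure — not that real
proteome annotation noise is benign.

## Numerical and interface choices

- TSV dialect everywhere: tab-separated UTF-8, header row, '.' decimal,
  no quoting, empty string for missing. Readers reject dialect violations
  with located errors; no silent coercion.
- FASTA files are taken at face value: one record = one predicted protein;
  isoform collapsing is the data-preparer's job.
- In the heatmap export, absent cells are blank and excluded cells are the
  literal string `NA`, so the two kinds of non-presence stay
  distinguishable after a round trip.
- Ties when a bait pairs with several query accessions: all are family
  members; the representative follows the max-length rule.
- The worked preservation example (4 of 6 anchors present) is reported as
  the unrounded fraction 0.667; presentation rounding is left to reports.
- Species-set bookkeeping is config-driven (an anchor species plus any
  number of others); eukaryote-only versus all-species summaries are a
  matter of which species the metadata declares, and outputs always carry
  per-cell n.

## Problem sizes in the test-suite

The suite checks interval merging against a per-residue coverage oracle on
1,000 random architectures (up to 200 intervals, proteins up to 5,000
residues); the ANOVA/Spearman kernel against closed forms, projection-matrix
sums of squares and exhaustive rank computations; null calibration of all
three tests at 2,000 replicates; parameter recovery (length ratio,
preservation ordering, footprint gap) on 200 replicate worlds at the full
68-species design; rescue exactness at miss rates 0, 0.05 and 0.2; the
binomial audit tail against exhaustive enumeration for all n <= 12; and
byte-identical reproduction of a seeded end-to-end run. These sizes were
chosen to give the Monte-Carlo checks comfortable binomial standard errors
while keeping a default test run quick on a laptop.

## Known limitations

- Species are treated as independent observations; there are no
  phylogenetically independent contrasts, so lifestyle effects inherit
  whatever phylogenetic signal the species sample carries. This mirrors the
  emulated design and is the main inferential caveat.
- No post-hoc multiple-comparison machinery (Tukey etc.) is provided.
- Co-orthologous anchors double-count shared orthogroups by design.
- The audit's single failure rate f is a deliberate simplification; per
  species or per-clade failure rates would need a richer manual audit than
  the ingested configuration carries.
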