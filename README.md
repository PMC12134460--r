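# repairome

Comparative analysis of DNA damage response (DDR) protein repertoires and
lengths across eukaryote proteomes.

## What this is for

Parasitic eukaryotes with compacted genomes — microsporidia and other
intracellular or intranuclear lineages above all — shed large parts of the
DNA damage response while keeping DNA replication machinery almost intact.
`repairome` is an R implementation of the comparative pipeline behind that
kind of survey, for anyone who has per-species proteomes, an
orthology-clustering output and Pfam domain scans and wants to quantify:

- **Repertoires**: which human-anchored orthologue families are present in
  which genomes, as a presence/length matrix, including a *bait rescue*
  step that recovers orthologues missed by global clustering by routing
  through a clade-reference species, and a binomial audit of
  orthologue-calling reliability on >95%-conserved families.
- **Preservation**: per-(species, pathway) preservation values
  `v = n_present / n_assessable`, summarised by species, pathway and
  lifestyle (free-living, extracellular, cytoplasmic, intranuclear).
- **Length architecture**: each protein decomposed via merged Pfam hit
  envelopes into functional-domain length `D`, interdomain length
  `I = L − D` (terminal tails included) and footprint `D / L`, with domain
  density (hits per covered residue); Spearman correlations among `L`, `D`,
  `I`; one-way and two-way fixed-effects ANOVAs (Type III, sum-to-zero
  contrasts) of length against lifestyle, organelle status and pathway
  group; and pairwise percent length ratios between the four pathway groups
  (DDR, DNA replication, metabolic, housekeeping).

Because the real inputs are tens of proteomes plus orthology/domain tool
outputs, the package ships a seeded **synthetic-world generator**
(`world_config()`, `generate_world()`, `write_world()`) that emits every
input format with known ground truth — lifestyle-graded orthologue loss,
log-normal group length effects (DDR/replication 1.84× housekeeping),
group-specific domain footprints, planted clustering misses, one truncated
proteome — so the whole pipeline is testable end to end without downloads.

## Worked example

```r
library(repairome)

res <- run_pipeline(run_config(world = world_config(), seed = 1,
                               out_dir = "results/run"))
res$ratios[res$ratios$group_b == "housekeeping", ]
```

The same run, stage by stage with narrative output, is the `analysis/`
workflow:

```sh
Rscript analysis/01_simulate_world.R   # world -> results/world/
Rscript analysis/02_orthology.R        # presence matrix, rescue, audit
Rscript analysis/03_preservation.R     # preservation values and summaries
Rscript analysis/04_domains.R          # domain/interdomain decomposition
Rscript analysis/05_stats.R            # ANOVAs, ratios, interactions
```

On the default design (68 species, 526 anchor families, seed 1) this
prints, among other things:

```
presence: 26429 direct, 1014 rescued via clade-reference baits
mean overall preservation by lifestyle:
  free_living extracellular   cytoplasmic  intranuclear
        0.913         0.786         0.634         0.402
preservation ~ lifestyle: F(3, 64) = 361.25, P = 4.79e-40
mean footprint by pathway group:
         DDR housekeeping    metabolic  replication
        0.40         0.60         0.55         0.45
domains per 100 covered residues (density):
         DDR housekeeping    metabolic  replication
        1.41         0.90         0.68         1.27
species-level Spearman correlations:
                pair   rho  n df        p
  length~interdomain 0.992 68 66 2.28e-61
DDR proteins are 82% longer than housekeeping and 25% longer than metabolic proteins
```

Read: preservation declines monotonically from free-living to intranuclear
lifestyles; every one of the 1,014 recoverable clustering misses is rescued
through the clade-reference pairing files; DDR proteins are the longest
group yet carry the *smallest* domain footprint with the *highest* domain
density, and length variation is carried almost entirely by the
interdomain space — exactly the structure the generator encodes, recovered
by the estimation path rather than read off the ground truth.

Each stage writes plain TSVs under `results/`; `run_pipeline()` writes the
same tables in one call and is byte-reproducible for a fixed seed.

## Layout

- `R/` — the package: I/O readers/writers, synthetic worlds, orthology,
  preservation, domains, statistical kernel, pipeline orchestration.
- `analysis/` — numbered narrative drivers over the package.
- `scripts/acceptance.R` — one-shot reproduction of the main quantities.
- `vignettes/ddr-comparative-analysis.Rmd` — models, parameter choices,
  design decisions and limitations.
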