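# coibarcode

Distance-based DNA-barcoding analysis for COI reference libraries, written
for taxonomists and molecular ecologists who identify unknown specimens —
typically immature life stages such as caterpillars — by matching their
barcode sequences against a library built from expert-identified adults.

The package covers the complete workflow around the standard ~658 nt
fragment of the mitochondrial *cytochrome c oxidase subunit I* (COI) gene:

- **Reference library assembly** from FASTA + specimen metadata, with
  length filtering (short museum fragments down to 267 nt are retained),
  life-stage partitioning and a shared left-anchored coordinate frame.
- **Pairwise distances** under the Kimura two-parameter (K2P) model with
  pairwise deletion,

  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),

  where P and Q are the proportions of comparable sites showing
  transition and transversion differences; uncorrected p-distances are
  also available, and saturated or low-overlap pairs are flagged rather
  than guessed.
- **Neighbour-joining trees** (Saitou–Nei Q-criterion, deterministic
  lexicographic tie-breaks, negative branch estimates clamped to zero)
  returned as `ape` `phylo` objects and serialisable to Newick.
- **Barcode-cluster (split) detection**: each species is partitioned into
  single-linkage clusters at a divergence threshold (default 2% K2P);
  species with two or more clusters are flagged as putative cryptic
  species and their clusters receive interim names
  (`Genus speciesECO01`, `ECO02`, ...).
- **Divergence summaries by rank** (within species / within genus /
  within family), the classic barcoding-gap table.
- **Query identification**: nearest-neighbour K2P matching under the 2%
  rule, with BOLD-style similarity percentages, runner-up margins and
  ambiguity/no-match statuses.
- **A K80 simulator** that generates whole libraries and query sets with
  recorded ground truth (hierarchical genus/species/specimen depths,
  planted deep splits, truncated museum fragments), so every stage can be
  validated without external data.

## Worked example

Simulate a small survey (12 species, one of which carries a planted deep
split), fit the divergence analysis, and identify larval queries:

```r
library(coibarcode)

cfg <- sim_config(n_genera = 4, species_per_genus = 3, specimens_per_species = 5,
                  split_plan = data.frame(species = 5, n_clusters = 2, depth = 0.04),
                  query_plan = data.frame(species = c(2, 5), cluster = c(1, 2), n = c(3, 2)),
                  seed = 2026)
sim <- simulate_library(cfg)
fit <- barcode_fit(sim$ref)
summary(fit)
```

```
Library of 60 specimens in 12 species

K2P divergence by taxonomic rank (percent):
           rank comparisons   min  mean   max    se
 within_species         110  0.00  0.36  1.23 0.023
   within_genus         300  3.75  5.41  8.23 0.060
  within_family        1350 13.31 15.98 19.38 0.035
(1 flagged species excluded, policy 'within_species')

Barcode cluster report: 12 species, 1 flagged at 2.00% divergence
  Genus02 sp02: 2 clusters (sizes 3/2), mean between-cluster 3.84%
```

Conspecific specimens differ by ~0.4% on average while congeneric species
differ by ~5% — the "barcode gap" that makes identification work.  The
planted split in `Genus02 sp02` is recovered and its two clusters named
`Genus02 sp02ECO01/ECO02`.  Identifying the five simulated caterpillars:

```r
ids <- predict(fit, simulate_queries(sim)$records)
ids
```

```
Identification of 5 queries at 2.0% threshold: 5 assigned, 0 ambiguous, 0 no match
Per-taxon mean nearest-match distance (%):
             taxon n mean_dist_pct
      Genus01 sp02 3          0.25
 Genus02 sp02ECO02 2          0.15
```

All queries land well below the 2% threshold; the two larvae drawn from
the split species are correctly labelled with the interim cluster name of
their nearest cluster.  `plot(fit)` draws the NJ tree, and
`run_pipeline(fasta, metadata, out_dir)` executes the same analysis from
files on disk, writing PHYLIP/TSV distance exports, a Newick tree, the
split/rank/identification tables and a run log.

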