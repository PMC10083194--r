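# attforge

Discovery and characterization of large serine recombinase (LSR)
attachment sites from comparative genomics, with downstream motif,
integration-site, and enrichment analyses.

## The problem

Large serine recombinases are phage- and mobile-element integrases that
catalyze unidirectional recombination between a genomic attachment site
(attB) and an element-borne site (attP), crossing over at a 2-bp core
dinucleotide shared by both sites. They are prized genome-engineering
tools — but each LSR comes with its own attachment sites, and those sites
are not annotated anywhere: they must be reconstructed by comparing a
genome that carries the integrated element against a close relative that
lacks it. The post-integration locus has the structure

```
B1 - D - P1 - E - P2 - D - B2
```

(flanks B1/B2, target-site duplication D, element E with terminal segments
P1/P2), from which both sites follow by concatenation:

```
attB = B1 + D + B2        attP = P2 + D + P1
```

attforge implements this comparative workflow end to end for
bioinformaticians characterizing LSR candidates:

* **Boundary detection** (`find_insertion`, `measure_ani`) — locate
  insertions in a genome pair with leftmost-canonical breakpoints and
  duplication inference; fragment-level average nucleotide identity.
* **Attachment sites** (`reconstruct_sites`, `find_center`,
  `derive_attL_attR`) — 50-bp site windows, homology centers, core
  dinucleotides, and post-recombination attL/attR.
* **Quality control** (`apply_filters`, `vote_mge_category`) — the
  eight-filter candidate screen and MGE-category plurality voting.
* **Specificity** (`cluster_sequences`, `classify_site_specific`,
  `classify_multi_targeting`, `select_motif_eligible`) — greedy identity
  clustering and target-site specificity classification.
* **Motifs** (`score_core_dinucleotides`, `align_on_core`, `build_motif`,
  `build_posthoc_motif`, `scan_motif`, `roc_auc`) — core-anchored
  position-frequency motifs, database-derived post hoc motifs, log-odds
  scanning, and ROC/AUROC evaluation.
* **Genome targeting** (`search_sites`, `assign_roles`,
  `read_blast_hits`) — seed-and-extend search of attachment sites against
  a target genome with Karlin-Altschul E-values and attA/attD/attH role
  assignment.
* **Integration-site mapping** (`filter_reads`, `consensus_clips`,
  `call_sites`, `merge_loci`, `locus_motif`, `accessibility_enrichment`,
  `read_junction_sam`) — call genomic integration sites from donor-genome
  junction sequencing.
* **Enrichment** (`feature_enrichment`, `antiphage_proximity_test`) —
  Fisher-exact feature enrichment with BH adjustment, rank-sum proximity
  tests.
* **Barcodes** (`count_barcodes`, `reporter_log_ratio`) — quality-gated
  amplicon barcode tallies over the 4,096-barcode universe, dropout sets,
  and the pooled-reporter log2(ON:OFF) statistic.
* **Synthetic data** (`make_genome`, `plant_integration`,
  `simulate_junction_reads`, `simulate_barcode_reads`) — seeded
  generators with recorded ground truth, so the whole pipeline is
  testable without external data.

## Worked example

```r
library(attforge)

genome  <- make_genome(4000, gc_fraction = 0.45, seed = 11)
element <- make_genome(1200, gc_fraction = 0.55, seed = 12)
planted <- plant_integration(genome, element, position = 1800, duplication_len = 3)

calls <- find_insertion(planted$pre_genome, planted$post_genome)
calls[[1]]
#> Insertion call at reference offset 1800 (|D| = 3, |E| = 1200, query interval [1803, 3003))

pair <- reconstruct_sites(calls[[1]])
pair
#> Attachment-site pair (window 50 bp)
#>   attB: GTGCCTTCCCAGTCGTTACACATTTTAGCATCGAAAATCGCCATGTTAAA
#>   attP: GGCTGCAATGGGTGTAGGTCCGCTTTCAACCCCTCCGAGGCGGGTCCACT
#>   center (3 bp): TTT  core: TT

identical(pair$attB, planted$truth$true_attB)
#> [1] TRUE
```

The insertion call places the element at reference offset 1800 with a 3-bp
target-site duplication; the reconstructed attB is the exact 50-bp window
of the pre-integration genome around the site, and the shared center
(`TTT`, containing the `TT` core) marks the predicted crossover. Motif
scanning and ROC evaluation work from the same building blocks:

```r
m <- nucleotide_motif(matrix(rep(c(0.7, 0.1, 0.1, 0.1), 3), nrow = 3, byrow = TRUE))
scan_motif(m, c(x = "AAA"))
#>   seq_id   score position strand
#> 1      x 4.45628        0      +

roc_auc(c(5, 6, 7), c(1, 2, 3))
#> ROC over 7 cutoffs; AUC = 1
```

(The score is 3 x log2(0.7/0.25) = 4.456: three positions each preferring
A at 0.7 over a uniform background.)

See `vignettes/attforge-methods.Rmd` for the full model description,
parameter defaults, and design rationale.

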