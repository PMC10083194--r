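---
title: "Methods: attachment-site discovery and integration-site mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attachment-site discovery and integration-site mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attforge)
```

## The biological model

Large serine recombinases (LSRs) are phage- and mobile-element-encoded
integrases that catalyze unidirectional recombination between two short DNA
attachment sites: **attB**, carried by the bacterial genome, and **attP**,
carried by the mobile genetic element (MGE). Integration splices the element
into the genome and converts the site pair into the junction sites attL and
attR. The crossover occurs at a 2-bp **core dinucleotide** that is identical
between attB and attP and sits inside the attachment-site **center**, the
stretch of sequence homologous between the two sites.

When a genome carrying an integrated element is compared against a close
relative lacking it, the post-integration locus has the structure

```
B1 - D - P1 - E - P2 - D - B2
```

where B1/B2 are the genomic flanks, D is the target-site duplication (length
zero or more), E is the element, and P1/P2 are the element's terminal
segments. Both attachment sites can then be reconstructed by concatenation:

```
attB = B1 + D + B2        attP = P2 + D + P1
```

attforge implements this comparative reconstruction and the downstream
analyses that consume it: candidate quality control, target-site specificity
classification, core-anchored motif construction with log-odds scanning and
ROC evaluation, attachment-site search against target genomes (with the
attA/attD/attH role nomenclature for genome-targeting candidates),
integration-site calling from donor-genome junction sequencing, enrichment
statistics, and amplicon barcode counting.

## Boundary detection and canonicalization

`find_insertion()` compares assembled genome pairs directly, rather than
inferring boundaries from read alignments: the synthetic fixtures provide
assembled pre/post pairs, so exact string comparison is both deterministic
and fast at desk scale. The scan walks both genomes in parallel, and at each
divergence re-anchors with an exact-match seed k-mer (default k = 21,
verified by a `min_flank` extension) to measure the inserted segment.

Two canonicalization rules make decompositions unique in the presence of
microhomology:

* **Leftmost breakpoint.** When the junction is ambiguous (for example
  inside a homopolymer run), the reported `site_position` is the smallest
  offset that reproduces the query. This is property-tested by shifting
  planted junctions through homopolymer runs.
* **Duplication by maximal prefix.** The target-site duplication D is the
  longest prefix of the inserted segment that matches the reference at the
  breakpoint (capped so the element keeps at least one base). A coincidental
  extra match at the element edge therefore joins D on both sides of the
  comparison; the synthetic-truth generator applies the identical rule, so
  planted truths and recovered calls compare with exact string equality.

Elements longer than the quality-control cap are still reported here:
detection and policy are deliberately separate, and the QC stage rejects
them later. Nested or adjacent insertions are reported separately by
iterative re-anchoring; a difference that cannot be explained by an
insertion stops the scan with a warning rather than guessing.

`measure_ani()` estimates average nucleotide identity at the fragment level:
non-overlapping fragments (default 1 kb) are anchored in the partner genome
by modal exact 15-mer offsets and scored by ungapped identity, averaged over
both directions. Unrelated genomes anchor no fragments and return the
`NA` no-match sentinel. Under a 5% substitution model the estimate is 95%
by construction, which the tests verify within half a percentage point.

## Attachment-site windows, centers, and cores

`reconstruct_sites()` reports both sites as windows (default 50 bp) centered
on the duplicated segment, using the flanks from the post-integration
chromosome — these most closely represent the pre-integration attB. The
window anchor rule is a design choice: the duplication (or, when |D| = 0,
the breakpoint) is the only sequence-defined anchor available at
reconstruction time, and centering on it keeps the core near the window
midpoint.

The attachment-site center is found by extending the homologous stretch
outward from the duplication region. A generic longest-common-substring
search (`find_center()`, with ties broken by proximity to the sequence
midpoints, then leftmost) is used as a fallback and as the exported
operation for site pairs of unknown provenance. The distinction matters on
synthetic data: two random 50-mers share a ~6-8 bp common substring by
chance, so for short duplications an unanchored search can land on
coincidental homology away from the junction. The core is reported as the
central 2-mer of the center; when centers exceed 2 bp we do not additionally
require that they contain the experimentally realized crossover
dinucleotide, since nothing at reconstruction time distinguishes it.

`derive_attL_attR()` splices the post-recombination junctions at the core
and is an involution: applying it again with the roles swapped restores the
original pair.

## Quality control

`apply_filters()` applies the eight candidate filters with literal boundary
semantics: "more than X removed" thresholds are strict (exactly X passes)
and "between A and B" is inclusive. Defaults: genome-pair ANI >= 95%;
center <= 20 bp; ambiguous nucleotides <= 5%; protein length 400-650 aa;
at least one of Resolvase/Recombinase/Zn_ribbon_recom; ambiguous amino
acids <= 5%; element < 200 kb; LSR within 500 nt of its attachment site.
Domain calling is consumed as an input table — the filter checks set
membership only. The ANI filter is applied against the comparison genome
that yielded the call (an assumption: with several comparison genomes one
could instead demand that all pass). Missing fields mark a filter
indeterminate and fail the candidate, so incomplete records cannot pass
silently. `vote_mge_category()` implements plurality voting over MGE
annotations with the fixed tie order dsDNA Phage > ICE/IME > Plasmid >
Other replicon, and maps empty annotation sets to "Other".

## Specificity classification

`cluster_sequences()` is a deterministic greedy centroid clusterer:
sequences sorted by length (ties by id) join the first centroid meeting the
identity threshold. Identity is matches / global-alignment length under
unit match score and affine gaps (open 10, extend 1) — the precise identity
definition of the original protein clustering tool is not pinned down, so
ours is explicit and configurable via `identity_fun`.

Site-specific calls use LSR and target-gene clusters at 50% identity:
target clusters hit by at least three LSR clusters are retained, and LSR
clusters whose retained edges cover exactly one target cluster are
site-specific. Multi-targeting calls use 90% LSR clusters: per-cluster
distinct-target counts, single-target clusters removed, bins {2, 3, >3}
with ">3" fully multi-targeting, and each 50% cluster promoted to the
maximum bin of its members. Edges are unweighted — occurrence counts play
no role in the stated rules. Both classifiers are tested against
brute-force rule application on random bipartite graphs.

## Motifs, scanning, and ROC

Candidate core dinucleotides are ranked by a score that equally weights the
mean modal-base frequency of the column pair (gaps excluded) and one minus
the normalized distance to the alignment center. Modal-base frequency was
chosen over information content for the conservation term because it is the
more literal reading of "conservation of the most frequent nucleotides";
the two orderings agree on the fixtures tested. `align_on_core()` then
stacks sites on their predicted cores without any internal gaps.

`build_posthoc_motif()` reconstructs a target-site motif for a query LSR
from database relatives: relatives at >= 30% amino-acid identity are
visited in decreasing identity order (ties by id, making the construction
deterministic), their attBs oriented by the strand with the higher global
alignment score to the query's attB, and accumulated—skipping any attB more
than 95% identical to one already selected—until the requested count
(typically 20, 50, or 100). Rather than running a full progressive multiple
alignment, each selected attB is globally aligned to the query attB and
projected onto its coordinates (insertions relative to the query dropped):
the final frequencies are mapped onto the query attB coordinates anyway, so
a reference-anchored profile delivers the same quantity deterministically;
`align_fun` is the natural extension point if a full MSA is preferred.
Columns with more than 50% gaps are excluded, the middle 60 of the
remaining columns are kept (centered on the post-exclusion midpoint), and
gap cells contribute equal weight to all four bases.

`scan_motif()` scores every window on both strands as the sum of
log2(frequency/background) per position — log base 2 and a uniform
background are the defaults, both configurable; non-ACGT bases contribute
zero. `roc_auc()` sweeps thresholds over the union of observed scores and
integrates by trapezoid, which credits tied scores 0.5 and makes the AUC
equal to the Mann-Whitney U statistic divided by n1*n2 — an identity the
tests verify exactly on random score sets.

## Genome-target search

`search_sites()` performs seed-and-extend local alignment (word size 11,
match +2, mismatch -3, affine gaps) on both strands, refining each seeded
diagonal with a local alignment over its surrounding window. Scores convert
to E-values with the Karlin-Altschul formula E = K m n exp(-lambda S);
lambda is solved numerically from the scoring scheme under uniform base
composition, and K is a calibration constant (default 0.21, configurable) —
adequate for the strict E < 1e-3 screen, where planted sites score twenty
orders of magnitude below threshold. The hit table matches the BLAST
tabular layout closely enough that `read_blast_hits()` can substitute an
external search engine bit-compatibly. `assign_roles()` renames the
best-hit site attA (acceptor), its cognate attD (donor), and the genomic
span attH, breaking exact E-value ties by bit score and then preferring
attB.

## Integration-site mapping

The junction-sequencing caller consumes alignments against a composite
donor + genome reference (donor contig named `donor`). Reads are kept when
they map to both references, begin at the primer, and lack an intact attD
(undeterminable status is kept, since short reads cannot prove intactness);
supplementary alignments, mapping quality < 30, and insert sizes > 1,500 bp
are removed; duplicates collapse on (chrom, position, orientation, mate
position), or include the UMI when the donor library carries one.
"Uniquely mapped" is operationalized as a primary alignment at mapq >= 30.

Clipped donor-side sequences are grouped by their junction coordinate
(strand-aware: leftmost aligned base for plus reads, right end for minus
reads) and reduced to a per-position majority consensus with ties written
as N. Anchors supported by a single read are kept by default — the
downstream identity and core-distance gates already discard noise — with
`min_support` exposed for stricter settings. Each consensus must share a
9-mer with the attD subsequence (primer to 25 bp past the attD end), reach
80% identity in the full local alignment or its longest gap- and
ambiguity-free contiguous run (Smith-Waterman, match 2 / mismatch -2 /
open 4 / extend 1; the published pipeline names no scoring scheme), and
place its crossover within 15 bp of the predicted core. Sites merge into
loci by single linkage at 500 bp (deliberately joining opposite-orientation
events at one site), with unique-read or UMI counts and percent shares.
Per-locus motifs use the most-supported site, extracting the core-centered
window on the strand of integration. Accessibility enrichment draws two
seeded background positions within 100 kb of each true site and applies a
two-sided Fisher's exact test; the sample odds ratio is reported with an
infinity sentinel for empty cells.

## Enrichment statistics and barcode counting

`feature_enrichment()` tests only features present in at least five target
genes (two-sided Fisher), adjusting with Benjamini-Hochberg — the stated
intent is FDR control, so BH is used rather than the generic default of the
adjustment routine. The background:target gene ratio is the caller's
choice (default 1:1 in the examples). `antiphage_proximity_test()` uses
the exact rank-sum distribution for combined n <= 25 and the
continuity-corrected normal approximation otherwise; fully tied input
returns p = 1 with a degenerate flag.

`count_barcodes()` filters reads at mean Phred >= 30 overall and minimum
Phred >= 30 over the k-bp barcode region, then tallies exact matches
against the complete 4^k universe (4,096 at k = 6) with no mismatch
rescue; barcodes at 0-1 counts form the dropout set.
`reporter_log_ratio()` computes log2(ON:OFF) per element after
counts-per-million depth normalization — CPM was chosen as the
normalization since the ratio is invariant to uniform depth changes under
it, which the tests assert.

## Synthetic data: what it emulates and what it does not

The generator produces i.i.d. base-composition genomes, planted
integrations with target-site duplications of 0-10 bp, junction reads with
uniform substitution errors at configurable rates and Q37-baseline
qualities with seeded per-base degradation (so the Q30 filters are
exercised deterministically), and uniformly drawn barcode libraries. Study
conditions mirrored from the assayed workflow: 50-bp attachment-site
windows; elements of 0.5-5 kb on 3-5 kb genome fragments for boundary
recovery; 20 planted integration sites sequenced at 2,000 junction reads
with a 0.001 substitution rate; 6-bp barcodes over the 4,096 universe at
~3x depth.

What the fixtures deliberately do **not** model: genome repeats and mobile
element families (which would stress seed anchoring), indel sequencing
errors and quality-correlated error profiles, GC-skewed or
position-dependent coverage, multi-contig draft assemblies, and chimeric
PCR artifacts. Passing tests therefore demonstrate correctness of the
decomposition, gating, and counting logic under clean conditions — not
robustness to repeat-rich genomes or degraded libraries, where the seeded
anchoring and consensus steps would face ambiguity the fixtures never
produce.

## Numerical choices and problem sizes

Determinism is enforced throughout: every stochastic generator takes a
seed and restores the caller's RNG state; greedy orders and tie-breaks are
fixed (length then id for clustering; score, centrality, leftmost for core
ranking; E-value, bit score, attB for role assignment). Pseudocounts
default to 0.01 in frequency matrices; motif backgrounds default to
uniform. Degenerate inputs are outcomes, not errors: empty insertion sets,
all-gap motif columns (uniform with a flag), fully tied rank-sum input
(p = 1 with a flag), hit-free searches (empty tables, no role assignment).

The test suite and the acceptance script run at desk scale on one CPU:
100 planted genome pairs (5 kb), a 0.5-Mb genome for the junction pipeline,
a 1-Mb genome for the planted-site search, 200 random bipartite graphs,
and 1,000 random p-vectors — a few minutes in total. These sizes are the
package's own verification conditions; the algorithms have no intrinsic
dependence on them.

## A worked example

```{r example}
genome <- make_genome(4000, gc_fraction = 0.45, seed = 11)
element <- make_genome(1200, gc_fraction = 0.55, seed = 12)
planted <- plant_integration(genome, element, position = 1800, duplication_len = 3)

calls <- find_insertion(planted$pre_genome, planted$post_genome)
calls[[1]]

pair <- reconstruct_sites(calls[[1]])
pair

identical(pair$attB, planted$truth$true_attB)
identical(pair$attP, planted$truth$true_attP)

derive_attL_attR(pair)
```

## Known limitations

* Boundary detection requires assembled genome pairs; read-level boundary
  inference from isolate sequencing BAMs is out of scope.
* The E-value calibration constant K is approximate; absolute E-values
  near the threshold should not be over-interpreted, and an external
  search engine can be substituted through the tabular ingest path.
* The greedy clusterer is quadratic in sequence count and intended for
  candidate sets of hundreds, not databases of millions.
* The post hoc motif's reference-anchored alignment discards insertions
  relative to the query attB; sites with large indel variation relative to
  the query are better served by plugging in a full MSA.
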