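---
title: "splicescape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicescape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescape)
```

This vignette documents the models, definitions, and numerical choices
behind the package, in the spirit of a methods section: what each stage
computes, which knobs matter, and what the simulation-based tests do and
do not establish about real data.

## Coordinate model

All interval types (exons, introns, CDS anchors) are 1-based closed
genomic intervals, the GTF convention, on a single chromosome and strand
per gene. Transcripts require exons separated by at least one nucleotide:
a zero-length gap would imply a zero-length intron, which no downstream
definition (splice-site extraction, retention, PTC mapping) can interpret.
Genes whose isoforms sit on conflicting strands are rejected rather than
split, because every event definition below is strand-dependent.
Duplicate transcript ids are an error; distinct ids with identical exon
sets are retained, since they legitimately affect per-transcript counts.

## The seven event types

Events are found by comparing every unordered pair of isoforms of a gene
and testing the configurations below ("5′"/"3′" always in transcript
orientation; on the minus strand the donor is the genomic-right end of an
intron):

* **IR** — an intron of the spliced form lies inside a single exon of the
  retaining form, and the spliced form's flanking exons share that exon's
  outer boundaries on both sides.
* **ES** — an internal exon of one form lies strictly inside an intron of
  the other whose boundaries match the flanking splice sites.
* **A5 / A3** — two introns share one boundary and differ at the other;
  A5 when the differing boundary is the donor side, A3 the acceptor side.
* **MX** — between a shared donor and a shared acceptor each form has
  exactly one internal exon, and the two internal exons do not overlap.
* **AF / AL** — the two first (AF) or last (AL) exons are non-overlapping
  and the adjacent introns share the boundary on the internal side.

One refinement is needed to make these definitions mutually exclusive: a
literal reading of A5/A3 ("introns sharing one boundary, differing at the
other") also fires on every ES, MX, AF and AL configuration, because the
skipping/terminal intron always shares one boundary with a shorter
intron. We therefore require for A5/A3 that the exons flanking the
*differing* boundary overlap each other — the configuration in which a
donor or acceptor genuinely shifts within the same exon context. This
matches how the SUPPA event taxonomy separates the types. With this rule,
each planted configuration in the simulator yields exactly one event of
exactly its type, and the independent brute-force enumerator used in the
tests encodes the same discipline.

Two consequences worth noting. First, a strand mirror of a whole fixture
preserves every event type (a donor shift stays a donor shift); the test
suite asserts this rather than expecting A5 to "become" A3. Second,
single-exon transcripts can participate only as the retaining partner of
IR: AF/AL require an adjacent intron on *both* isoforms, which an
intronless transcript cannot supply. An isoform catalog in which a
reference single-exon gene acquires multi-exon novel isoforms will still
show AS at such genes — through the multi-exon pair, or IR against the
single-exon form.

Events are deduplicated per gene by (type, signature), where the
signature is the ascending tuple of defining genomic coordinates
(arity 2 for IR, 4 for ES, 3 for A5/A3, 6 for MX, 5 for AF/AL); the
inclusion/exclusion transcript sets of merged duplicates are unioned.
Deduplication by signature — rather than counting transcript pairs —
reflects that an event is a property of a splicing decision, not of a
pair enumeration; published per-type totals do not state which convention
was used, so this package's counts are defined by the signature rule.

## PTC classification

A retained-intron transcript is classified against a per-gene *reference
ORF*: the longest annotated CDS if any isoform carries one, otherwise the
longest ATG-initiated ORF across isoforms, accepted only at or above 100
codons (configurable) — the field's usual fallback when no curation
exists. The reference start codon is mapped into the retaining
transcript; translation proceeds codon by codon; the call is **PTC⁺** iff
the first in-frame stop maps genomically upstream, in transcript
orientation, of the reference stop codon, **PTC⁻** otherwise, and
*undetermined* when no reference resolves or the start does not map.

We deliberately do not use the 50-nt last-junction rule as the verdict:
a premature stop is a positional fact, whereas NMD targeting is a
physiological prediction, and not every PTC⁺ transcript is degraded. The
50-nt rule is computed as an auxiliary column (`nmd_50nt_flag`) for users
who want the classical NMD-candidate subset.

Expression enters twice. Retained transcripts with FPKM below 1 in every
tissue are removed before classification; a transcript counts as present
in a tissue when the *mean of its replicates* reaches the threshold. The
mean is the least surprising pooling of replicates (any-replicate
presence is available by lowering the threshold) and is applied
uniformly in the census, the tissue-specificity calls and the IR filter.

## Splice sites and gene features

Intron terminal dinucleotides are read in transcript orientation (minus
strand: reverse complement, donor at the genomic-right end); introns
shorter than 4 nt are counted under a degenerate `NN`–`NN` key rather
than dropped, preserving the conservation property that profile totals
equal the number of introns processed. By default introns are pooled per
transcript — an intron shared by two isoforms counts twice — which is the
deterministic reading of per-transcript extraction; `unique_introns =
TRUE` switches to one count per distinct genomic intron (the mode used
when comparing against the simulator's per-intron truth).

Per-gene structure metrics use a *representative isoform*: the transcript
with the most exons, ties broken by spliced length then id. The published
analyses aggregate per gene without stating the rule; most-exons is the
representative that exposes the gene's full intron structure. Averages
that are undefined (intron metrics of single-exon genes) are reported as
`NA` and excluded from group statistics, never zero-filled. Group
summaries use linear-interpolation quantiles (`stats::quantile` type 7,
recorded in the output) at the 5/25/50/75/95 percent points, matching the
usual box-and-whisker presentation.

The noncoding flag is the conventional lncRNA screen — length ≥ 200 nt
and longest ATG-initiated ORF < 100 codons — standing in for multi-tool
coding-potential intersections, which are out of scope; a gene counts as
an AS lncRNA when every isoform is flagged.

## Coexpression

The network stage follows the signed-WGCNA recipe at reduced complexity:

* variance pre-filter keeping the top 60% of genes by FPKM variance;
* signed adjacency `a_ij = ((1 + cor)/2)^β` with β either fixed (16 is
  the conventional choice at transcriptome scale) or chosen as the
  smallest candidate whose scale-free fit R² (regression of log binned
  degree frequency on log degree, sign-corrected) reaches 0.80;
* topological overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1
  − a_ij)`;
* average-linkage clustering of `1 − TOM` with a **static cut**: by
  default the tree is cut in the middle of the largest gap among the
  upper half of merge heights. The lower half of the merge sequence is
  within-cluster structure; the module/background transition, when one
  exists, is the dominant gap above it. This replaces dynamic tree
  cutting with something deterministic and testable; an explicit
  `cut_height` overrides it. Clusters below `min_size` (300 in the
  original design; far less at desk scale) are relabeled 0 and modules
  renumbered by size.
* hubs: within each module, weighted intramodular degree (sum of
  adjacency to same-module genes) ranks genes; the top ⌈10%⌉ are hubs,
  ties broken by id. This is the weighted analogue of exporting the
  network and taking top-degree nodes; an edge-weight threshold before
  counting reproduces the unweighted variant.

Module counts at transcriptome scale are not reproducible from
annotations alone and are not a target of this package; what is testable
is recovery of *planted* structure, below.

## The simulator

`simulate_annotation()` emulates the study conditions: 500 genes by
default, 17.56% of them AS, event types allocated over AS genes at the
published proportions (IR .2839, A3 .2029, ES .1668, A5 .1527, AF .1166,
AL .0634, MX .0137), 90% canonical GT–AG splice sites, a 1:2 PTC⁺:PTC⁻
target among coding retained-intron transcripts, 5% of AS genes built as
noncoding, and seven tissues × three replicates for expression. Where the
study conditions do not pin a value we chose once: exon counts 4–8 (AS)
and 2–6 (non-AS, a quarter single-exon, echoing the catalog's single-exon
fraction), exon lengths 90–240 nt, intron lengths 81–180 nt with 60–90 nt
for IR genes (retained introns tend to be short), and half the genes on
the minus strand so all strand logic is exercised.

Design points that make recovery tests exact rather than statistical:

* **Largest-remainder allocation** instead of multinomial sampling for
  event types, splice-site composition, PTC statuses, strand and
  single-exon assignment: realized proportions equal configured
  proportions deterministically.
* Each AS gene carries a base isoform plus one alternative isoform
  realizing its event by a coordinate edit (intron kept for IR, internal
  exon dropped for ES, donor/acceptor extended into the intron for A5/A3,
  a swapped internal exon inside the downstream intron for MX,
  alternative terminal exons in the flanking buffers for AF/AL). Each
  edit was checked against the full event taxonomy to plant *exactly one*
  event — e.g. the A5/A3 overlap rule is what keeps an ES edit from also
  scoring as A3.
* Genes are built in transcript-forward local coordinates and mirrored
  onto the genome for minus-strand genes.
* Coding sequence uses T-free filler codons, so no reading frame anywhere
  in the CDS can contain a stop; planted retained introns use a {C,G}
  body with forced GT/AG termini and, for PTC⁺, a TAA placed at the
  retained transcript's codon boundary. PTC truth is therefore exact by
  construction, including across exon–intron junctions.
* Splice-site dinucleotides are allocated over *unique* introns; introns
  of AS genes stay canonical because alternative isoforms share boundary
  positions there, and the non-canonical quota (AA–AG, GT–TG, GT–TT,
  GC–AG) is placed among non-AS genes. The generator errors if the quota
  cannot be carried.

`simulate_expression()` plants gene-level coexpression through a factor
model: module members follow `√ρ·z_m + √(1−ρ)·ε` with `z_m` a
standardized tissue-structured sample profile (ρ = 0.8 within modules by
default). The planted hub of each module *is* the consensus profile
(loading 1, no idiosyncratic noise): a hub planted as a merely
higher-loading member is not reliably the top-degree gene at 21 samples,
so "most connected by construction" is taken literally. Background genes
get amplitude 0.6, so the variance pre-filter preferentially retains
networked genes — the stated rationale for that filter. FPKM is
log-normal around the scores; all non-tissue-specific transcripts are
floored at FPKM 1.5 so presence calls match planted truth exactly, and
planted tissue-specific transcripts are high (FPKM ≈ 5–16) in one tissue
and exactly zero elsewhere.

### What the simulations do and do not show

Planted-recovery tests establish that the implementations are faithful to
their definitions: enumeration agrees with an independently coded
brute-force oracle on 1,000 random gene models, recovers planted events
with recall = precision = 1, reproduces planted splice-site composition
exactly, classifies planted PTC statuses perfectly, and recovers planted
modules at adjusted Rand ≥ 0.9 with planted hubs in the top-degree sets
in ≥95 of 100 runs. They do *not* show that real isoform catalogs are as
clean: real data have overlapping genes, fuzzy boundaries from collapsed
long reads, incomplete CDS annotation, library-size artifacts in FPKM,
and correlated replicate noise. In particular, hub recovery through the
full FPKM chain (replicate noise, presence floor, log transform) is
noticeably below the score-level guarantee; on real matrices hub calls
should be read as rankings, not certainties.

## Numerical and degenerate-input conventions

* Quantiles: type 7; rounding of percentages to 2 decimals at reporting
  boundaries only.
* Zero-variance rows: excluded (with a warning) from correlation
  networks; assigned distance 1 to everything in the expression heatmap
  clustering.
* Empty inputs: an empty annotation yields an empty gene collection; an
  all-zero count vector yields a defined "no events" summary; an empty
  PTC call set yields zero censuses and an undefined (NaN) ratio.
* Determinism: a fixed seed makes the simulator byte-identical, the
  pipeline's TSVs replay identically from the manifest settings, and all
  tie-breaks (variance ranking, hub degree, dedup ordering) fall back to
  lexicographic ids.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in about a minute: oracle equivalence on 1,000
random genes, planted-event recovery at 500 genes, module recovery at 300
genes × 21 samples, hub recovery on 100 seeded 60-gene designs. All are
configurable upward through `simulation_config()`.
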