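---
title: "Finding and characterizing ultraconserved elements with ucetools"
author: "ucetools maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and characterizing ultraconserved elements with ucetools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucetools)
```

## The problem

Ultraconserved elements (UCEs) are genomic segments that remain essentially
unchanged over very long evolutionary times. Operationally, a UCE is a
reference-genome interval of length at least $L$ whose sequence is present,
gaplessly and at identity at least $p$, in at least a fraction $f$ of a
defined set of $Y$ genomes (the reference counts as one of the $Y$). The
package defaults — $L = 100$ bp, $p = 0.97$, $f = 0.5$ — correspond to the
standard placental-mammal definition; older definitions (e.g. perfect
identity over 200 bp in three genomes) are particular corners of the same
parameter space and are reachable by setting the thresholds accordingly.

`ucetools` implements a staged discovery pipeline over multi-FASTA genome
assemblies, an exhaustive reference implementation used to validate it, a
cross-species tracer built on glocal alignment with Karlin–Altschul
statistics, a genomic-context annotator, a flanking-gene synteny test, and
a simulator that generates genome sets with implanted conserved elements
and exact ground truth.

## The discovery pipeline

Discovery proceeds in four stages, each exposed as a function:

1. **Core k-mer indexing** (`build_kmer_index`). All N-free k-mers
   (default $k = 50$) of every genome are collected in canonical form (the
   lexicographic minimum of a k-mer and its reverse complement, collapsing
   strand), with per-species occurrence counts.
2. **Core k-mer selection** (`select_core_kmers`). K-mers exactly present
   in at least $\lceil \text{core\_fraction} \cdot Y \rceil$ genomes are
   kept (default core fraction 0.5); k-mers occurring more than
   `kmer_map_limit` times (default 1,000) in any genome are discarded as
   repetitive before the expensive mapping stage.
3. **Approximate mapping** (`map_kmer_approx`). Each core k-mer is mapped
   to every position, on either strand of every genome, where the genomic
   window differs by at most $\lfloor (1-p)k \rfloor$ substitutions. The
   search is seed-and-verify: the k-mer is split into $m + 1$ disjoint
   segments; in any window with at most $m$ mismatches at least one
   segment must match exactly (pigeonhole), so exact lookup of the
   segments followed by Hamming verification is complete under the
   gapless model. This internal mapper replaces an external approximate
   aligner deliberately: it is provably complete at these identity
   levels, so no multi-threshold rescue is needed for correctness (the
   cumulative scan is still provided as an operating mode).
4. **Candidate merging and window calling** (`build_candidates`,
   `extend_and_call`). Reference hits of the core k-mers are merged
   (book-ended intervals included, as `bedtools merge` would) into
   candidate regions. Each candidate, padded on both sides, is scanned
   exhaustively for *maximal* windows $[s, e)$ with $e - s \ge L$ such
   that at least $\lceil f Y \rceil$ species (reference included) carry a
   gapless match of the whole window at identity $\ge p$ on either
   strand. The scan rests on a prefix-sum transform: with $c(t)$ the
   number of mismatches along a species diagonal up to boundary $t$ and
   $h(t) = c(t) - (1-p)t$, a window meets the identity threshold on that
   diagonal iff $h(e) \le h(s)$, which turns every per-window test into a
   constant-time comparison. Species diagonals inside a candidate region
   are discovered by exact matching of the region's $w$-mers, where
   $w = \lfloor pL / ((1-p)L + 1) \rfloor$ is the pigeonhole bound on the
   longest exact run any qualifying window must contain; this search is
   again complete, not heuristic. If a qualifying window touches the
   region boundary the region is expanded and rescanned.
5. **Repeat filtering** (`apply_multimap_cap`). A called window is
   removed when its reference sequence occurs more than `multimap_cap`
   times (default 100) at identity $\ge p$ in any single genome.
   Surviving overlapping windows are merged into the reported UCEs.

`find_uces` wires the stages together; `cumulative_scan` repeats the whole
pipeline along a strictly decreasing identity ladder (default
1.00/0.99/0.98/0.97) and merges the union of the runs, the conventional
guard against single-threshold mapping misses when an external heuristic
aligner is used for stage 3.

### Numerical conventions

* Coordinates are 0-based half-open (BED) everywhere internally; GTF input
  is converted on read.
* Identity thresholds are compared with a $10^{-9}$ epsilon so that
  budgets such as $\lfloor 0.03 \times 100 \rfloor$ are immune to binary
  floating-point representation of $p$.
* Windows containing N in the reference are ineligible; N in another
  species counts as a mismatch for that species only (an assembly gap in
  one genome should not veto an element, which is also why the species
  fraction exists).
* Per-species best hits are tie-broken by higher identity, longer span,
  lower target coordinate, then + strand, making outputs byte-identical
  across reruns.
* `min_identity` below 0.85 is rejected: the pigeonhole seed width would
  drop below the practical lower bound of the exact-lookup tables, and
  such identities are outside the ultraconserved regime in any case.

### The multi-mapping cap and window maximality

The cap is evaluated on the species-maximal windows *before* overlapping
windows are merged, mirroring a post-hoc repeat filter applied to called
elements. Occurrence counts of nested windows are not monotone at
identity thresholds below 1 (a shorter window has a smaller absolute
mismatch budget), so folding the cap into window qualification could give
slightly different results in contrived cases; the package uses one
definition in both the pipeline and the exhaustive oracle.

## The exhaustive oracle

`oracle_find_uces` computes the same window definition by a structurally
different route: every alignment diagonal of every genome against the
reference (both strands) is examined for an exact run of at least $w$
bases — either literally (the quadratic per-offset walk) or through an
equivalent hash join of all $w$-mer positions; the two modes are proven
equal in the test suite — and qualifying windows are then enumerated from
per-diagonal suffix minima of $h$. Because it never relies on shared core
k-mers, the oracle's completeness is independent of the pipeline's
discovery heuristics, which is exactly what makes the base-for-base
equality tests informative. The oracle refuses genome sets over 1 Mb
aggregate.

## The tracer

`trace_queries` maps query sequences (typically UCEs, or length-matched
CDS controls from `sample_control_cds`) onto arbitrary target genomes
with `Biostrings::pairwiseAlignment` in global-local mode: global in the
query, local in the target, affine gaps (match +5, mismatch −4, gap open
12, gap extend 4; a gap of length $g$ costs $12 + 4g$). The best hit per
(query, species) is selected by raw score. Bit-scores and E-values use
ungapped Karlin–Altschul parameters computed numerically from the
match/mismatch scores and the target base composition: $\lambda$ solves
$\sum_s p_s e^{\lambda s} = 1$ and $K$ comes from the classical series
over convolutions of the score distribution. Applying ungapped statistics
to the gapped score is an approximation; the downstream filters
(aligned length ≥ 30, E ≤ 0.01, detection at ≥ 70% identity) dominate
behaviour, and the computed $(\lambda, K, H)$ agree with standard
published values for these scoring schemes. Reported identity divides
matches by alignment columns, gap columns included. A full quadratic
affine-gap dynamic program (compiled) serves as the scoring oracle in the
tests.

`flank_profile` anchors each UCE in each species on its best gapless core
placement and records per-offset identity across the core and its flanks,
the summary behind the familiar conserved-core / divergent-flank profile.

## The annotator

`classify_context` assigns each UCE exactly one category against an
Ensembl-style gene annotation. Precedence, which the source material
defines only partially, is fixed as follows: a UCE not wholly contained
in any single gene (straddling a gene/intergenic boundary or spanning
genes) is a `complex_locus`, as is one wholly inside both a
protein-coding and a lncRNA gene, one wholly exonic but straddling
CDS/UTR boundaries, or one whose containing same-biotype genes disagree
on the category; otherwise the within-gene categories (CDS, 5′/3′ UTR,
intron, intron–exon junction, lncRNA analogues, `other_gene`) apply, and
`intergenic` requires no gene overlap at all. "Wholly within" means every
base inside the feature; junction categories need at least one base on
each side. Protein-coding classification outranks lncRNA, which outranks
other biotypes, when a UCE is contained in genes of several classes that
the complex rule does not already catch.

`assess_synteny` takes the nearest flanking protein-coding genes on both
sides (all distance ties kept, overlapping genes at distance 0 on both
sides) in the reference and at the traced location in the second species,
and calls the UCE syntenic when any flank gene name matches on either
side — orientation-agnostic, since UCEs are not strand-specific, and
case-insensitive. No manual curation of nomenclature mismatches is
attempted; the verdict records the gene-name sets so downstream curation
remains possible.

## The simulator, and what passing tests do and do not show

`simulate_genomes` builds one reference and $Y - 1$ sibling genomes:

* **Background** is i.i.d. per species at 41% GC (a mammalian-like
  value), so any cross-species conservation is attributable to implants —
  the probability of a chance 100-bp near-identical window between
  independent sequences is negligible.
* **Elements** are reference segments (default 150–400 bp; the
  desk-scale validation fixtures use 180–400 bp) copied into each
  species at random positions and strands with Bernoulli substitutions at
  per-species rates. Defaults centre on ~1% (validation fixtures cycle
  0.4–2%), the divergence scale implied by a 97%-identity definition.
* **Flanks** (default 150 bp each side) are copied with the element at a
  10% substitution rate, reproducing conserved cores with measurably
  diverged flanks; at permissive thresholds called windows legitimately
  extend into flanks, which is why recovery tests treat core ± flank as
  the planted footprint.
* **A repeat family**: the first element, with its flanking context plus
  a 50 bp margin, can be implanted `n_repeat_copies` times (default 150)
  into one species with ~1% divergence between members — a young
  transposon-like family that exercises the multi-mapping cap. Copies
  carry their context so that any called window over the element lies
  inside every family member; bare-core copies would not be excluded by
  a full-sequence occurrence cap, because the maximal window always
  overruns a context-free repeated unit on its leftover mismatch budget.
* **Indels** (optional, default off) exercise the tracer's gapped
  aligner; the discovery fixtures stay substitution-only so the gapless
  oracle remains exact.

Truth output records, per element and species, the realized coordinates,
strand, substitution count and identity — exactly, not approximately.

The validation suite runs 20 seeded fixtures cycling $Y \in \{3, 6, 8\}$
with genomes of 16/12/10 kb and 8/7/6 elements, over the full grid
$L \in \{100, 120\}$, $p \in \{1.0, 0.97, 0.95\}$, $f \in \{0.5, 1.0\}$,
and asserts exact pipeline/oracle base-set equality, 100% recall of
elements whose realized identities satisfy the thresholds, zero calls
outside planted footprints, threshold monotonicity and species-fraction
nesting, cumulative-scan consistency, strand invariance, and byte-level
determinism. Genome sizes are a desk-scale choice: the oracle is
quadratic per species pair, and these sizes let the whole grid be
validated exhaustively in minutes while still being two to three orders
of magnitude longer than the elements being recovered. What these tests
show is that the implementation computes its stated definition exactly
under substitution-type divergence and realistic repeat structure. What
they cannot show: behaviour under assembly errors, segmental
duplications, indel-rich divergence at the discovery stage (gapless by
design), phylogenetically correlated background (the simulator draws
species independently rather than down a tree), or genome-scale resource
use.

## Known limitations

* Discovery is gapless by construction; an element interrupted by an
  indel in a species contributes that species only up to the breakpoint.
  Tracing is gapped and will still find such copies.
* The species-fraction rule counts the reference as one species; with
  very small $Y$ this makes thresholds coarse.
* Karlin–Altschul parameters are ungapped and composition-based, so
  E-values for gapped alignments are approximate (conservative for the
  filters used here).
* The annotator resolves overlapping-gene ambiguity by fixed precedence
  rather than transcript-level reasoning.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_genomes(sim_config(n_species = 6, genome_length = 12000,
                                   n_elements = 7, n_repeat_copies = 0,
                                   seed = 2))
res <- find_uces(sim$genome_set, uce_params())
res
uce_bed(res)
oracle_find_uces(sim$genome_set, uce_params())   # identical intervals
```
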