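# ucetools

Discovery, tracing and annotation of ultraconserved elements (UCEs)
across multiple genome assemblies.

UCEs are genomic segments that stay essentially unchanged across large
evolutionary distances. Formally, given a set of `Y` genomes with one
designated reference, a UCE is a reference interval of length `>= L`
whose sequence is present — gaplessly, on either strand, at identity
`>= p` — in at least `ceil(f * Y)` of the genomes (the reference counts
as one). The package defaults, `L = 100` bp, `p = 0.97`, `f = 0.5`,
correspond to the standard placental-mammal definition; stricter
classics such as "perfectly identical over 200 bp in three genomes" are
just other corners of the same `(L, p, f)` space.

`ucetools` provides:

* a staged k-mer discovery pipeline (`find_uces`): canonical k-mer
  indexing across genomes, core k-mer selection (exact presence in a
  species fraction, per-genome occurrence limit), provably complete
  pigeonhole seed-and-verify approximate mapping, merging of hits into
  candidate regions, exhaustive maximal-window calling, a per-genome
  multi-mapping cap for repeats (default 100 positions), and cumulative
  multi-identity scans (`cumulative_scan`);
* an exhaustive brute-force UCE finder (`oracle_find_uces`) that
  inspects every alignment diagonal of every genome and is used to
  validate the pipeline base-for-base;
* a cross-species tracer (`trace_queries`, `align_glocal`): glocal
  (global-in-query, local-in-target) affine-gap alignment with
  numerically computed Karlin–Altschul bit-scores and E-values, the
  printed filters (aligned length >= 30, E <= 0.01), 70%-identity
  detection counting, length-matched CDS controls and core/flank
  identity profiles;
* a genomic-context annotator (`classify_context`,
  `genes_containing_uces`, `gc_content`) over Ensembl-style GTF gene
  models, and a flanking-protein-coding-gene synteny test
  (`assess_synteny`, orientation-agnostic, all ties kept);
* a synthetic-genome simulator (`simulate_genomes`) implanting
  conserved elements with controlled per-species divergence, diverged
  flanks, an optional high-copy repeat family, optional indels, and
  exact ground truth;
* a command-line tool `uce` with `find`, `trace`, `annotate`, `synteny`
  and `simulate` subcommands (installed under `exec/`).

## A worked example

```r
library(ucetools)

sim <- simulate_genomes(sim_config(n_species = 6, genome_length = 12000,
                                   n_elements = 7, n_repeat_copies = 0,
                                   seed = 2))
res <- find_uces(sim$genome_set, uce_params())
res
#> uce_set: 7 UCEs on reference sp01 (L >= 100, identity >= 0.97, species fraction >= 0.50)
#>  total bases: 3356 | mean length: 479.4 | mean identity: 0.9781

head(uce_bed(res), 3)
#>   seq_name start  end     name score strand
#> 1     chr1   363  988 UCE00001   977      +
#> 2     chr1  1528 2092 UCE00002   976      +
#> 3     chr1  2260 2794 UCE00003   978      +

orc <- oracle_find_uces(sim$genome_set, uce_params())
identical(res$uces$start, orc$start) && identical(res$uces$end, orc$end)
#> [1] TRUE
```

Each reported UCE is a merged maximal reference window; `score` is the
mean cross-species identity in per-mille (985 = 98.5%), and
`res$species_hits` holds the best per-species projection (coordinates,
strand, identity) for every passing species. The oracle line recomputes
the same intervals by exhaustive diagonal enumeration — the two agree
exactly, which is the package's core correctness property.

The same run from the shell:

```sh
uce simulate --seed 2 --n-species 6 --genome-length 12000 \
    --n-elements 7 --n-repeat-copies 0 --out-dir fixtures/
uce find --genomes fixtures/ --reference sp01 --out uces.bed --hits-tsv hits.tsv
uce trace --uces uces.bed --reference fixtures/sp01.fa --targets fixtures/ --out trace.tsv
```

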