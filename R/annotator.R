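# Genomic correlates of UCEs: context classification against gene models,
# per-gene UCE counts, GC content, and flanking-gene synteny between two
# annotated species.

CONTEXT_CATEGORIES <- c(
  "CDS", "five_prime_UTR", "three_prime_UTR", "pc_intron",
  "pc_intron_exon_junction", "lncRNA_exon", "lncRNA_intron",
  "lncRNA_intron_exon_junction", "other_gene", "complex_locus",
  "intergenic")

wholly_within <- function(uce, parts) {
  if (nrow(parts) == 0L) return(FALSE)
  is_covered_by(data.frame(seq_name = uce$seq_name, start = uce$start,
                           end = uce$end),
                parts[, c("seq_name", "start", "end")])
}

overlaps_any <- function(uce, parts) {
  if (nrow(parts) == 0L) return(FALSE)
  any(parts$seq_name == uce$seq_name & parts$start < uce$end &
        parts$end > uce$start)
}

# category of a UCE relative to ONE containing gene
classify_within_gene <- function(uce, gm, gid, biotype) {
  sel <- function(x) x[x$gene_id == gid, , drop = FALSE]
  exons <- sel(gm$exons)
  introns <- gene_introns(gm, gid)
  in_exon <- overlaps_any(uce, exons)
  in_intron <- overlaps_any(uce, introns)
  if (biotype == "protein_coding") {
    if (in_exon && in_intron) return("pc_intron_exon_junction")
    if (!in_exon) return("pc_intron")
    if (wholly_within(uce, sel(gm$cds))) return("CDS")
    if (wholly_within(uce, sel(gm$utr5))) return("five_prime_UTR")
    if (wholly_within(uce, sel(gm$utr3))) return("three_prime_UTR")
    # wholly exonic but straddling CDS/UTR boundaries: irreducible
    return("complex_locus")
  }
  if (biotype == "lncRNA") {
    if (in_exon && in_intron) return("lncRNA_intron_exon_junction")
    if (in_exon) return("lncRNA_exon")
    return("lncRNA_intron")
  }
  "other_gene"
}

#' Classify the genomic context of a UCE
#'
#' Assigns exactly one category per UCE. Precedence: a UCE straddling a
#' gene/intergenic boundary, spanning several genes without being wholly
#' inside any one, or wholly inside both a protein-coding and a lncRNA
#' gene, is a `complex_locus`; otherwise it is classified within its
#' containing gene (CDS, 5'/3' UTR, intron, intron-exon junction, lncRNA
#' analogues, `other_gene`), and with no gene overlap it is `intergenic`.
#'
#' @param uce one-row data.frame (seq_name, start, end).
#' @param gm a [gene_models()] object.
#' @return one of the context category strings.
#' @export
classify_context <- function(uce, gm) {
  g <- gm$genes
  ov <- g[g$seq_name == uce$seq_name & g$start < uce$end &
            g$end > uce$start, , drop = FALSE]
  if (nrow(ov) == 0L) return("intergenic")
  containing <- ov[ov$start <= uce$start & ov$end >= uce$end, ,
                   drop = FALSE]
  if (nrow(containing) == 0L) return("complex_locus")
  bts <- unique(containing$biotype)
  if (all(c("protein_coding", "lncRNA") %in% bts)) return("complex_locus")
  # protein_coding outranks lncRNA outranks other when mixed with "other"
  bt <- if ("protein_coding" %in% bts) "protein_coding" else
    if ("lncRNA" %in% bts) "lncRNA" else "other"
  cats <- unique(vapply(
    containing$gene_id[containing$biotype == bt | bt == "other"],
    function(gid) classify_within_gene(
      uce, gm, gid, g$biotype[g$gene_id == gid]), character(1)))
  if (length(cats) > 1L) return("complex_locus")
  cats
}

#' Classify every UCE in a set
#'
#' @param uces data.frame of UCE intervals (seq_name, start, end, name
#'   optional).
#' @param gm a [gene_models()] object.
#' @return input with a `context` column appended.
#' @export
classify_contexts <- function(uces, gm) {
  uces$context <- vapply(seq_len(nrow(uces)), function(i)
    classify_context(uces[i, , drop = FALSE], gm), character(1))
  uces
}

#' Count UCEs contained in (overlapping) each gene
#'
#' A UCE overlapping several genes counts toward each of them (all ties
#' kept).
#'
#' @param uces data.frame of UCE intervals.
#' @param gm a [gene_models()] object.
#' @return data.frame gene_id, gene_name, biotype, n_uces (genes with no
#'   UCE omitted).
#' @export
genes_containing_uces <- function(uces, gm) {
  g <- gm$genes
  if (nrow(uces) == 0L || nrow(g) == 0L)
    return(data.frame(gene_id = character(), gene_name = character(),
                      biotype = character(), n_uces = integer()))
  ov <- intersect_intervals(uces, g)
  if (nrow(ov) == 0L)
    return(data.frame(gene_id = character(), gene_name = character(),
                      biotype = character(), n_uces = integer()))
  cnt <- data.table::as.data.table(ov)[, .(n_uces = .N), by = b_idx]
  out <- data.frame(gene_id = g$gene_id[cnt$b_idx],
                    gene_name = g$gene_name[cnt$b_idx],
                    biotype = g$biotype[cnt$b_idx],
                    n_uces = cnt$n_uces)
  out[order(-out$n_uces, out$gene_id), ]
}

#' GC content of a sequence
#'
#' (G + C) / (A + C + G + T); N excluded from the denominator; NA when no
#' unambiguous base remains.
#'
#' @param sequence character vector of sequences.
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    r <- charToRaw(toupper(s))
    gc <- sum(r == charToRaw("G") | r == charToRaw("C"))
    acgt <- gc + sum(r == charToRaw("A") | r == charToRaw("T"))
    if (acgt == 0L) NA_real_ else gc / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

# nearest protein-coding gene-name sets up/downstream of an interval
# (overlapping genes belong to both sides at distance 0); all ties kept
flank_gene_names <- function(interval, genes) {
  pc <- genes[genes$biotype == "protein_coding" &
                genes$seq_name == interval$seq_name, , drop = FALSE]
  res <- list(upstream = character(), downstream = character())
  if (nrow(pc) == 0L) return(res)
  ovl <- pc$start < interval$end & pc$end > interval$start
  up <- pc[ovl | pc$end <= interval$start, , drop = FALSE]
  dn <- pc[ovl | pc$start >= interval$end, , drop = FALSE]
  if (nrow(up)) {
    d <- interval_gap(interval$start, interval$end, up$start, up$end)
    res$upstream <- unique(up$gene_name[d == min(d)])
  }
  if (nrow(dn)) {
    d <- interval_gap(interval$start, interval$end, dn$start, dn$end)
    res$downstream <- unique(dn$gene_name[d == min(d)])
  }
  res
}

#' Assess synteny of one UCE between two annotated species
#'
#' The UCE is syntenic when any nearest flanking protein-coding gene name
#' on the reference side (upstream or downstream, all ties included)
#' matches any flanking gene name at the traced location in the other
#' species -- orientation-agnostic, since UCEs are not strand specific.
#' Gene names are compared case-insensitively.
#'
#' @param uce one-row data.frame of the reference UCE interval.
#' @param ref_genes reference [gene_models()] (or its `genes` data.frame).
#' @param other_location one-row data.frame of the UCE's best trace hit in
#'   the other species (identity >= 0.70 filtering is the caller's
#'   responsibility), or NULL when unmapped.
#' @param other_genes other-species gene models.
#' @return one-row data.frame: ref/other upstream/downstream gene-name
#'   sets (comma-joined), `syntenic`, `reason`.
#' @export
assess_synteny <- function(uce, ref_genes, other_location, other_genes) {
  gtab <- function(x) if (inherits(x, "gene_models")) x$genes else x
  rf <- flank_gene_names(uce, gtab(ref_genes))
  join <- function(x) paste(x, collapse = ",")
  if (is.null(other_location) || nrow(other_location) == 0L) {
    return(data.frame(
      ref_upstream = join(rf$upstream), ref_downstream = join(rf$downstream),
      other_upstream = "", other_downstream = "",
      syntenic = FALSE, reason = "unmapped"))
  }
  of <- flank_gene_names(other_location, gtab(other_genes))
  refset <- toupper(unique(c(rf$upstream, rf$downstream)))
  otherset <- toupper(unique(c(of$upstream, of$downstream)))
  syntenic <- length(intersect(refset, otherset)) > 0L
  data.frame(
    ref_upstream = join(rf$upstream), ref_downstream = join(rf$downstream),
    other_upstream = join(of$upstream),
    other_downstream = join(of$downstream),
    syntenic = syntenic, reason = if (syntenic) "shared_flank" else
      "no_shared_flank")
}
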