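# Gene annotation. GTF input follows the Ensembl dialect (gene_id /
# gene_name / gene_biotype attributes; feature rows gene, exon, CDS,
# five_prime_utr, three_prime_utr). GTF is 1-based closed on disk and is
# converted to the package-wide 0-based half-open convention on read.

#' Construct a gene-model container
#'
#' @param genes data.frame: gene_id, gene_name, biotype, seq_name, start,
#'   end, strand (0-based half-open coordinates).
#' @param exons,cds,utr5,utr3 data.frames with gene_id, seq_name, start,
#'   end. May be empty.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, exons = NULL, cds = NULL, utr5 = NULL,
                        utr3 = NULL) {
  blank <- data.frame(gene_id = character(), seq_name = character(),
                      start = integer(), end = integer())
  fix <- function(x) {
    if (is.null(x) || nrow(x) == 0L) return(blank)
    data.table::setDF(data.table::as.data.table(
      x[, c("gene_id", "seq_name", "start", "end")]))
  }
  genes <- data.table::setDF(data.table::as.data.table(genes))
  genes$biotype <- ifelse(
    genes$biotype %in% c("protein_coding", "lncRNA"), genes$biotype, "other")
  gm <- structure(list(genes = genes, exons = fix(exons), cds = fix(cds),
                       utr5 = fix(utr5), utr3 = fix(utr3)),
                  class = "gene_models")
  validate_gene_models(gm)
  gm
}

validate_gene_models <- function(gm) {
  g <- data.table::as.data.table(gm$genes)
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id in gene models")
  for (part in c("exons", "cds", "utr5", "utr3")) {
    p <- data.table::as.data.table(gm[[part]])
    if (nrow(p) == 0L) next
    m <- merge(p, g[, .(gene_id, gstart = start, gend = end,
                        gseq = seq_name)], by = "gene_id")
    if (nrow(m) < nrow(p)) stop(part, " reference unknown gene_id")
    bad <- m[start < gstart | end > gend | seq_name != gseq]
    if (nrow(bad)) stop(part, " interval outside its gene: ",
                        bad$gene_id[1])
  }
  # CDS must lie within the exon union of its gene
  cds <- data.table::as.data.table(gm$cds)
  if (nrow(cds)) {
    ex <- data.table::as.data.table(gm$exons)
    for (gid in unique(cds$gene_id)) {
      if (!is_covered_by(cds[gene_id == gid], ex[gene_id == gid]))
        stop("CDS outside exons for gene ", gid)
    }
  }
  invisible(gm)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes (",
      sum(x$genes$biotype == "protein_coding"), "protein_coding,",
      sum(x$genes$biotype == "lncRNA"), "lncRNA,",
      sum(x$genes$biotype == "other"), "other )\n")
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' @param path Ensembl-dialect GTF.
#' @return a [gene_models()] object in 0-based half-open coordinates.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!"type" %in% names(df)) stop("GTF has no feature type column")
  df$start0 <- df$start - 1L          # 1-based closed -> 0-based half-open
  bt <- if ("gene_biotype" %in% names(df)) df$gene_biotype else
    if ("gene_type" %in% names(df)) df$gene_type else "other"
  df$biotype <- ifelse(is.na(bt), "other", bt)
  gname <- if ("gene_name" %in% names(df)) df$gene_name else df$gene_id
  df$gname <- ifelse(is.na(gname), df$gene_id, gname)
  pick <- function(types) {
    sel <- df[df$type %in% types, , drop = FALSE]
    data.frame(gene_id = sel$gene_id, seq_name = as.character(sel$seqnames),
               start = sel$start0, end = sel$end)
  }
  g <- df[df$type == "gene", , drop = FALSE]
  if (nrow(g) == 0L) stop("GTF contains no gene features: ", path)
  genes <- data.frame(
    gene_id = g$gene_id, gene_name = g$gname, biotype = g$biotype,
    seq_name = as.character(g$seqnames), start = g$start0, end = g$end,
    strand = as.character(g$strand))
  gene_models(genes,
              exons = pick("exon"), cds = pick("CDS"),
              utr5 = pick(c("five_prime_utr", "5UTR")),
              utr3 = pick(c("three_prime_utr", "3UTR")))
}

#' Write gene models as an Ensembl-dialect GTF
#'
#' Used to materialize synthetic annotations; coordinates are converted
#' back to the 1-based closed GTF convention.
#'
#' @param gm a [gene_models()] object.
#' @param path output file.
#' @export
write_gtf <- function(gm, path) {
  g <- gm$genes
  attr_str <- function(gid) {
    i <- match(gid, g$gene_id)
    sprintf(
      'gene_id "%s"; transcript_id "%s.t1"; gene_name "%s"; gene_biotype "%s";',
      gid, gid, g$gene_name[i], g$biotype[i])
  }
  row_lines <- function(x, type) {
    if (nrow(x) == 0L) return(character())
    strand <- g$strand[match(x$gene_id, g$gene_id)]
    sprintf("%s\tucetools\t%s\t%d\t%d\t.\t%s\t.\t%s",
            x$seq_name, type, x$start + 1L, x$end, strand,
            attr_str(x$gene_id))
  }
  lines <- c(
    row_lines(g, "gene"),
    row_lines(gm$exons, "exon"),
    row_lines(gm$cds, "CDS"),
    row_lines(gm$utr5, "five_prime_utr"),
    row_lines(gm$utr3, "three_prime_utr"))
  writeLines(lines, path)
  invisible(path)
}

# Introns of one gene: gene span minus union of its exons.
gene_introns <- function(gm, gid) {
  g <- gm$genes[gm$genes$gene_id == gid, , drop = FALSE]
  ex <- gm$exons[gm$exons$gene_id == gid, , drop = FALSE]
  if (nrow(ex) == 0L)
    return(data.frame(gene_id = character(), seq_name = character(),
                      start = integer(), end = integer()))
  exm <- merge_intervals(ex)
  bounds <- c(g$start, rbind(exm$start, exm$end), g$end)
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ends > starts
  data.frame(gene_id = rep(gid, sum(keep)),
             seq_name = rep(g$seq_name, sum(keep)),
             start = starts[keep], end = ends[keep])
}
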