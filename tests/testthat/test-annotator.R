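# A small synthetic annotation used across classification tests:
#   pc gene g1 [100, 1000): exons [100,300)+[600,1000); CDS [150,300)+
#     [600,800); UTR5 [100,150); UTR3 [800,1000); intron [300,600)
#   lnc gene l1 [2000, 3000): exons [2000,2200)+[2800,3000)
#   other gene o1 [4000, 4500)
#   pc gene g2 [5000, 6000) overlapping lnc l2 [4900, 6100) (both
#     intronic across [5200, 5800))
annot_fixture <- function() {
  gene_models(
    genes = data.frame(
      gene_id = c("g1", "l1", "o1", "g2", "l2"),
      gene_name = c("ALPHA", "LINC1", "MIR9", "BETA", "LINC2"),
      biotype = c("protein_coding", "lncRNA", "other", "protein_coding",
                  "lncRNA"),
      seq_name = "chr1",
      start = c(100L, 2000L, 4000L, 5000L, 4900L),
      end = c(1000L, 3000L, 4500L, 6000L, 6100L),
      strand = c("+", "+", "-", "+", "-")),
    exons = data.frame(
      gene_id = c("g1", "g1", "l1", "l1", "o1", "g2", "g2", "l2", "l2"),
      seq_name = "chr1",
      start = c(100L, 600L, 2000L, 2800L, 4000L, 5000L, 5900L, 4900L,
                6050L),
      end = c(300L, 1000L, 2200L, 3000L, 4500L, 5200L, 6000L, 5100L,
              6100L)),
    cds = data.frame(gene_id = c("g1", "g1", "g2"), seq_name = "chr1",
                     start = c(150L, 600L, 5050L),
                     end = c(300L, 800L, 5200L)),
    utr5 = data.frame(gene_id = c("g1", "g2"), seq_name = "chr1",
                      start = c(100L, 5000L), end = c(150L, 5050L)),
    utr3 = data.frame(gene_id = c("g1", "g2"), seq_name = "chr1",
                      start = c(800L, 5900L), end = c(1000L, 6000L)))
}

uce_at <- function(start, end) data.frame(seq_name = "chr1",
                                          start = start, end = end)

test_that("context classification follows the documented precedence", {
  gm <- annot_fixture()
  expect_identical(classify_context(uce_at(160L, 290L), gm), "CDS")
  expect_identical(classify_context(uce_at(105L, 145L), gm),
                   "five_prime_UTR")
  expect_identical(classify_context(uce_at(850L, 990L), gm),
                   "three_prime_UTR")
  expect_identical(classify_context(uce_at(350L, 550L), gm), "pc_intron")
  expect_identical(classify_context(uce_at(250L, 350L), gm),
                   "pc_intron_exon_junction")
  expect_identical(classify_context(uce_at(2050L, 2150L), gm),
                   "lncRNA_exon")
  expect_identical(classify_context(uce_at(2300L, 2700L), gm),
                   "lncRNA_intron")
  expect_identical(classify_context(uce_at(2100L, 2300L), gm),
                   "lncRNA_intron_exon_junction")
  expect_identical(classify_context(uce_at(4100L, 4300L), gm),
                   "other_gene")
  expect_identical(classify_context(uce_at(8000L, 8200L), gm),
                   "intergenic")
  # intronic in both a protein-coding and a lncRNA gene -> complex locus
  expect_identical(classify_context(uce_at(5300L, 5700L), gm),
                   "complex_locus")
  # straddling a gene/intergenic boundary -> complex locus
  expect_identical(classify_context(uce_at(950L, 1100L), gm),
                   "complex_locus")
})

test_that("every UCE receives exactly one category and fractions sum to 1", {
  gm <- annot_fixture()
  set.seed(15)
  uces <- data.frame(seq_name = "chr1",
                     start = sample(0:8000, 60, replace = TRUE))
  uces$end <- uces$start + 100L
  out <- classify_contexts(uces, gm)
  expect_true(all(out$context %in% ucetools:::CONTEXT_CATEGORIES))
  frac <- table(out$context) / nrow(out)
  expect_equal(sum(frac), 1)
  # order of gene rows must not matter
  gm2 <- gm
  perm <- rev(seq_len(nrow(gm2$genes)))
  gm2$genes <- gm2$genes[perm, ]
  out2 <- classify_contexts(uces, gm2)
  expect_identical(out$context, out2$context)
})

test_that("genes containing UCEs count every overlap, ties included", {
  gm <- annot_fixture()
  uces <- rbind(uce_at(200L, 320L), uce_at(400L, 520L), uce_at(700L, 820L),
                uce_at(5050L, 5150L))
  cnt <- genes_containing_uces(uces, gm)
  expect_identical(cnt$n_uces[cnt$gene_id == "g1"], 3L)
  # the last UCE overlaps both g2 and l2 -> counted for both
  expect_identical(cnt$n_uces[cnt$gene_id == "g2"], 1L)
  expect_identical(cnt$n_uces[cnt$gene_id == "l2"], 1L)
  expect_identical(
    nrow(genes_containing_uces(uce_at(9000L, 9100L), gm)), 0L)
})

test_that("gc_content excludes N from the denominator", {
  expect_identical(gc_content(c("ACGT", "GGCC", "AGNT")),
                   c(0.5, 1.0, 1/3))
  expect_true(is.na(gc_content("NNNN")))
})

test_that("synteny verdicts follow the orientation-agnostic flank rule", {
  mk_genes <- function(names, starts) data.frame(
    gene_id = paste0("id_", names), gene_name = names,
    biotype = "protein_coding", seq_name = "chr1",
    start = starts, end = starts + 500L, strand = "+")
  ref <- mk_genes(c("A", "B"), c(1000L, 5000L))
  uce <- uce_at(3000L, 3150L)
  # shared flank on the same side
  other <- mk_genes(c("B", "C"), c(500L, 8000L))
  rec <- assess_synteny(uce, ref, uce_at(2000L, 2150L), other)
  expect_true(rec$syntenic)
  # no shared flank
  other2 <- mk_genes(c("C", "D"), c(500L, 8000L))
  rec2 <- assess_synteny(uce, ref, uce_at(2000L, 2150L), other2)
  expect_false(rec2$syntenic)
  # ref upstream A matches other downstream A (orientation-agnostic)
  other3 <- mk_genes(c("X", "A"), c(500L, 8000L))
  rec3 <- assess_synteny(uce, ref, uce_at(2000L, 2150L), other3)
  expect_identical(rec3$other_downstream, "A")
  expect_true(rec3$syntenic)
  # unmapped in the other species
  rec4 <- assess_synteny(uce, ref, NULL, other)
  expect_false(rec4$syntenic)
  expect_identical(rec4$reason, "unmapped")
  # gene-name matching is case-insensitive
  other5 <- mk_genes(c("a", "Z"), c(500L, 8000L))
  expect_true(assess_synteny(uce, ref, uce_at(2000L, 2150L),
                             other5)$syntenic)
  # ties at equal distance are all reported
  reftie <- mk_genes(c("T1", "T2"), c(2000L, 2000L))
  rec6 <- assess_synteny(uce_at(3000L, 3100L), reftie,
                         uce_at(100L, 200L), mk_genes("T2", 1000L))
  expect_identical(rec6$ref_upstream, "T1,T2")
  expect_true(rec6$syntenic)
})
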