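test_that("FASTA reading normalizes case and ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgtN", ">chr2", "ACRYGT"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(chr1 = "ACGTN", chr2 = "ACNNGT"))
})

test_that("FASTA parser reports malformed input with line numbers", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "line 3.*duplicate sequence name")
  writeLines(c("ACGT"), f)
  expect_error(read_fasta(f), "line 1.*expected '>'")
  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">a", "ACGT", ">b"), f)
  expect_error(read_fasta(f), "line 3.*no sequence")
})

test_that("write_fasta / read_fasta round-trips arbitrary record sets", {
  set.seed(11)
  seqs <- setNames(
    vapply(c(5L, 140L, 71L), rand_seq, character(1)),
    c("chrA", "chr2", "scaffold_9"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 60L)
  expect_identical(read_fasta(f), seqs)
})

test_that("genome_set validates species and sequence naming", {
  expect_error(genome_set(list(a = c(chr1 = "ACGT")), "b"),
               "reference_id")
  expect_error(genome_set(list(c(chr1 = "ACGT")), "a"), "named list")
  gs <- genome_set(list(a = c(chr1 = "acgtRR"), b = c(chr1 = "ACGT")), "a")
  expect_identical(gs$sequences$a[["chr1"]], "ACGTNN")
  expect_identical(length(gs), 2L)
})

test_that("merge_intervals unions overlapping and book-ended intervals", {
  x <- data.frame(seq_name = "c", start = c(0L, 100L), end = c(100L, 150L))
  expect_identical(merge_intervals(x)$end, 150L)
  x <- data.frame(seq_name = "c", start = c(0L, 50L), end = c(100L, 120L))
  expect_identical(merge_intervals(x),
                   data.frame(seq_name = "c", start = 0L, end = 120L))
  x <- data.frame(seq_name = c("c", "d"), start = c(0L, 0L),
                  end = c(100L, 100L))
  expect_identical(nrow(merge_intervals(x)), 2L)
})

test_that("merge_intervals is idempotent and preserves covered bases", {
  set.seed(5)
  for (rep in 1:5) {
    x <- data.frame(
      seq_name = sample(c("c1", "c2"), 60, TRUE),
      start = sample(0:500, 60, TRUE))
    x$end <- x$start + sample(1:80, 60, TRUE)
    m <- merge_intervals(x)
    expect_identical(merge_intervals(m), m)
    # covered bases equal the size of the set union of the inputs
    base_union <- unique(unlist(lapply(seq_len(nrow(x)), function(i)
      paste(x$seq_name[i], x$start[i]:(x$end[i] - 1L)))))
    expect_identical(covered_bases(m), length(base_union))
  }
})

test_that("intersect_intervals matches half-open bedtools semantics", {
  a <- data.frame(seq_name = "c", start = 0L, end = 100L)
  expect_identical(
    intersect_intervals(a, data.frame(seq_name = "c", start = 99L,
                                      end = 200L))$overlap, 1L)
  expect_identical(
    nrow(intersect_intervals(a, data.frame(seq_name = "c", start = 100L,
                                           end = 200L))), 0L)
})

test_that("intersect_intervals agrees with a quadratic all-pairs scan", {
  set.seed(77)
  mk <- function(n) {
    x <- data.frame(seq_name = sample(c("c1", "c2", "c3"), n, TRUE),
                    start = sample(0:2000, n, TRUE))
    x$end <- x$start + sample(1:150, n, TRUE)
    x
  }
  a <- mk(500); b <- mk(500)
  got <- intersect_intervals(a, b)
  # brute force oracle: test every pair
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$seq_name[i] == b$seq_name[j] &&
        max(a$start[i], b$start[j]) < min(a$end[i], b$end[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        a_idx = i, b_idx = j,
        overlap = min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
  }
  want <- do.call(rbind, rows)
  want <- want[order(want$a_idx, want$b_idx), ]
  rownames(want) <- NULL
  expect_identical(got, want)
  # overlap detection is symmetric
  got_ba <- intersect_intervals(b, a)
  expect_setequal(paste(got$a_idx, got$b_idx),
                  paste(got_ba$b_idx, got_ba$a_idx))
})

test_that("closest_features returns all ties and overlap distance 0", {
  feats <- data.frame(seq_name = "c", start = c(0L, 250L),
                      end = c(50L, 300L), name = c("f1", "f2"))
  got <- closest_features(data.frame(seq_name = "c", start = 100L,
                                     end = 200L), feats)
  expect_identical(got$name, c("f1", "f2"))
  expect_identical(got$distance, c(50L, 50L))
  got <- closest_features(data.frame(seq_name = "c", start = 40L,
                                     end = 60L), feats)
  expect_identical(got$name, "f1")
  expect_identical(got$distance, 0L)
  expect_identical(
    nrow(closest_features(data.frame(seq_name = "zz", start = 0L,
                                     end = 5L), feats)), 0L)
})

test_that("closest_features agrees with a naive linear scan", {
  set.seed(31)
  feats <- data.frame(seq_name = sample(c("c1", "c2"), 300, TRUE),
                      start = sample(0:5000, 300, TRUE))
  feats$end <- feats$start + sample(1:100, 300, TRUE)
  for (rep in 1:20) {
    q <- data.frame(seq_name = sample(c("c1", "c2"), 1),
                    start = sample(0:5000, 1))
    q$end <- q$start + sample(1:100, 1)
    got <- closest_features(q, feats)
    dmin <- Inf; best <- integer()
    for (i in seq_len(nrow(feats))) {
      if (feats$seq_name[i] != q$seq_name) next
      d <- max(0L, max(q$start, feats$start[i]) - min(q$end, feats$end[i]))
      if (d < dmin) { dmin <- d; best <- i } else
        if (d == dmin) best <- c(best, i)
    }
    expect_setequal(paste(got$start, got$end),
                    paste(feats$start[best], feats$end[best]))
  }
})

test_that("GTF round-trip preserves gene models in BED coordinates", {
  gm <- gene_models(
    genes = data.frame(
      gene_id = c("g1", "g2"), gene_name = c("ALPHA", "BETA"),
      biotype = c("protein_coding", "lncRNA"), seq_name = "chr1",
      start = c(100L, 1000L), end = c(600L, 1500L), strand = c("+", "-")),
    exons = data.frame(gene_id = c("g1", "g1", "g2"), seq_name = "chr1",
                       start = c(100L, 400L, 1000L),
                       end = c(250L, 600L, 1500L)),
    cds = data.frame(gene_id = "g1", seq_name = "chr1", start = 150L,
                     end = 250L),
    utr5 = data.frame(gene_id = "g1", seq_name = "chr1", start = 100L,
                      end = 150L))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gm, f)
  back <- read_gtf(f)
  expect_identical(back$genes$start, gm$genes$start)
  expect_identical(back$genes$end, gm$genes$end)
  expect_identical(back$genes$biotype, gm$genes$biotype)
  expect_identical(back$exons$start, gm$exons$start)
  expect_identical(back$cds$end, gm$cds$end)
})

test_that("gene model invariants are enforced", {
  expect_error(gene_models(
    genes = data.frame(gene_id = "g1", gene_name = "A",
                       biotype = "protein_coding", seq_name = "c",
                       start = 100L, end = 200L, strand = "+"),
    exons = data.frame(gene_id = "g1", seq_name = "c", start = 50L,
                       end = 150L)),
    "outside its gene")
})
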