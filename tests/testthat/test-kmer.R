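test_that("k-mer index stores canonical N-free k-mers with counts", {
  gs <- genome_set(list(a = c(chr1 = "ACGTACGTACGTAC")), "a")
  idx <- build_kmer_index(gs, k = 8L)
  # ACGTACGT occurs at positions 0 and 4 (and is its own revcomp)
  expect_s3_class(idx, "kmer_index")
  acgt <- idx$counts[idx$counts$kmer == pmin("ACGTACGT",
                                             revcomp("ACGTACGT")), ]
  expect_gte(acgt$count, 2L)
  # all-N genome indexes nothing
  expect_warning(idx0 <- build_kmer_index(
    genome_set(list(a = c(chr1 = strrep("N", 30))), "a"), k = 8L),
    "empty")
  expect_identical(nrow(idx0$counts), 0L)
})

test_that("indexing is strand-symmetric via canonicalization", {
  set.seed(3)
  s <- rand_seq(300)
  gs1 <- genome_set(list(a = c(chr1 = s)), "a")
  gs2 <- genome_set(list(a = c(chr1 = revcomp(s))), "a")
  i1 <- build_kmer_index(gs1, 21L)$counts
  i2 <- build_kmer_index(gs2, 21L)$counts
  ord <- function(x) {
    x <- x[order(x$kmer), ]
    rownames(x) <- NULL
    x
  }
  expect_identical(ord(i1), ord(i2))
})

test_that("core k-mer selection applies species and map-limit thresholds", {
  counts <- data.frame(
    kmer = c("AAACCC", "AAACCC", "AAAGGG", "CCCGGG", "CCCGGG"),
    species = c("a", "b", "a", "a", "b"),
    count = c(1L, 3L, 1L, 1L, 1001L))
  idx <- structure(list(k = 6L, counts = counts,
                        species_ids = c("a", "b", "c", "d")),
                   class = "kmer_index")
  core <- select_core_kmers(idx, core_fraction = 0.5, kmer_map_limit = 1000L)
  # AAACCC: in 2/4 genomes at fraction .5 -> kept
  expect_true("AAACCC" %in% core$kmer)
  # AAAGGG: 1/4 genomes -> dropped
  expect_false("AAAGGG" %in% core$kmer)
  # CCCGGG: 1001 occurrences in one genome -> dropped by the map limit
  expect_false("CCCGGG" %in% core$kmer)
})

test_that("approximate mapping respects the mismatch budget exactly", {
  set.seed(23)
  kmer <- rand_seq(50)
  mk <- function(seg) genome_set(
    list(a = c(chr1 = paste0(rand_seq(60), seg, rand_seq(60)))), "a")
  # identical -> hit with 0 mismatches at 97%
  h0 <- map_kmer_approx(kmer, mk(kmer), 0.97)
  expect_identical(h0$mismatches, 0L)
  expect_identical(h0$start, 60L)
  # 1 mismatch: 49/50 = 98% >= 97% -> hit
  h1 <- map_kmer_approx(kmer, mk(mutate_at(kmer, 25)), 0.97)
  expect_identical(h1$mismatches, 1L)
  # 2 mismatches: 48/50 = 96% < 97% -> no hit
  h2 <- map_kmer_approx(kmer, mk(mutate_at(kmer, c(10, 40))), 0.97)
  expect_identical(nrow(h2), 0L)
})

test_that("approximate mapping agrees with a naive full-window scan", {
  set.seed(101)
  gs <- simulate_genomes(sim_config(
    n_species = 3, genome_length = 3000, n_elements = 3,
    element_length = c(120, 200), substitution_rate = 0.02,
    n_repeat_copies = 0, seed = 101))$genome_set
  k <- 20L
  refstr <- gs$sequences[["sp01"]][["chr1"]]
  kmers <- unique(substring(refstr, seq(1000, 1400, by = 40),
                            seq(1000, 1400, by = 40) + k - 1L))
  kmers <- kmers[!grepl("N", kmers)]
  p <- 0.9
  m <- floor((1 - p) * k + 1e-9)   # identity (k - m)/k >= p
  got <- map_kmer_approx(kmers, gs, p)
  # oracle: every window of every genome, both strands, literal Hamming
  ham <- function(a, b) sum(charToRaw(a) != charToRaw(b))
  rows <- list()
  for (sp in gs$species_ids) {
    s <- gs$sequences[[sp]][["chr1"]]
    n <- nchar(s)
    for (st in seq_len(n - k + 1L)) {
      win <- substr(s, st, st + k - 1L)
      wrc <- revcomp(win)
      for (km in kmers) {
        plus <- ham(win, km) <= m
        minus <- ham(wrc, km) <= m
        if (plus || minus)
          rows[[length(rows) + 1L]] <- data.frame(
            kmer = km, species = sp, start = st - 1L,
            strand = if (plus) "+" else "-")
      }
    }
  }
  want <- do.call(rbind, rows)
  expect_setequal(paste(got$kmer, got$species, got$start),
                  paste(want$kmer, want$species, want$start))
})

test_that("mapping hit sets shrink as identity rises; exact = index match", {
  set.seed(55)
  gs <- simulate_genomes(sim_config(
    n_species = 3, genome_length = 4000, n_elements = 3,
    element_length = c(150, 220), substitution_rate = 0.03,
    n_repeat_copies = 0, seed = 55))$genome_set
  idx <- build_kmer_index(gs, 30L)
  core <- select_core_kmers(idx, 0.5, 1000L)
  prev <- NULL
  for (p in c(0.9, 0.95, 1.0)) {
    h <- map_kmer_approx(core, gs, p)
    keyset <- paste(h$kmer, h$species, h$start, h$strand)
    if (!is.null(prev)) expect_true(all(keyset %in% prev))
    prev <- keyset
  }
  # at identity 1.0, hit counts equal exact index counts
  h1 <- map_kmer_approx(core, gs, 1.0)
  cnt <- table(paste(h1$kmer, h1$species))
  for (i in seq_len(nrow(idx$counts))) {
    key <- paste(idx$counts$kmer[i], idx$counts$species[i])
    if (idx$counts$kmer[i] %in% core$kmer)
      expect_identical(unname(cnt[key]), idx$counts$count[i])
  }
})

test_that("k-mers exceeding the per-genome hit cap are discarded", {
  seg <- rand_seq(50, seed = 8)
  many <- paste(c(rand_seq(30), rep(c(seg, "TT"), 5), rand_seq(30)),
                collapse = "")
  gs <- genome_set(list(a = c(chr1 = many)), "a")
  h <- map_kmer_approx(seg, gs, 1.0, kmer_map_limit = 4L)
  expect_identical(nrow(h), 0L)
  expect_identical(attr(h, "dropped"), seg)
  h5 <- map_kmer_approx(seg, gs, 1.0, kmer_map_limit = 5L)
  expect_identical(nrow(h5), 5L)
})

test_that("gapless occurrence search finds every hit on either strand", {
  set.seed(19)
  q <- rand_seq(120)
  target <- paste0(rand_seq(200), q, rand_seq(100), revcomp(q),
                   rand_seq(50), mutate_at(q, c(5, 60, 110)), rand_seq(80))
  occ <- gapless_occurrences(q, c(chr1 = target), 0.97)
  expect_identical(nrow(occ), 3L)
  expect_setequal(occ$strand, c("+", "-", "+"))
  expect_identical(sort(occ$mismatches), c(0L, 0L, 3L))
  # and the batch counter used by the multimap cap agrees
  gs <- genome_set(list(a = c(chr1 = target)), "a")
  tabs <- ucetools:::build_seed_tables(gs, ucetools:::pigeonhole_w(0.97, 100))
  occ2 <- ucetools:::count_occurrences_batch(q, "a", tabs, 0.97,
                                             ucetools:::pigeonhole_w(0.97, 100))
  expect_identical(unname(occ2[1, "a"]), 3L)
})
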