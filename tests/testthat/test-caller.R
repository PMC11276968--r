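test_that("uce_params validates thresholds and the identity ladder", {
  expect_error(uce_params(min_identity = 1.2), "min_identity")
  expect_error(uce_params(min_length = 40L), "core_k")
  expect_error(uce_params(cumulative_identities = c(0.97, 0.98)),
               "decreasing")
  expect_error(uce_params(min_identity = 0.97,
                          cumulative_identities = c(1, 0.99)),
               "must equal min_identity")
  p <- uce_params()
  expect_identical(p$min_length, 100L)
  expect_identical(p$core_k, 50L)
  expect_identical(p$kmer_map_limit, 1000L)
  expect_identical(p$multimap_cap, 100L)
})

test_that("candidate regions merge overlapping reference k-mer hits", {
  hits <- data.frame(
    kmer = c("K1", "K2", "K1", "K2", "K3", "K3"),
    species = c("ref", "ref", "spB", "spB", "ref", "spB"),
    seq_name = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(0L, 40L, 500L, 530L, 10L, 700L),
    strand = "+", mismatches = 0L)
  gs <- genome_set(list(ref = c(chr1 = rand_seq(900, 1),
                                chr2 = rand_seq(200)),
                        spB = c(chr1 = rand_seq(900))), "ref")
  cand <- build_candidates(hits, gs, core_k = 50L)
  expect_identical(norm_intervals(cand),
                   data.frame(seq_name = c("chr1", "chr2"),
                              start = c(0L, 10L), end = c(90L, 60L)))
  sup <- attr(cand, "support")
  expect_true(all(c("ref", "spB") %in% sup$species[sup$cand_id == 1]))
})

test_that("a shared identical segment is called at its exact extent", {
  seg <- rand_seq(150, seed = 41)
  gs <- segment_genome_set(list(ref = seg, spB = seg, spC = seg))
  prm <- uce_params(min_identity = 1.0, min_species_fraction = 0.5,
                    cumulative_identities = 1.0)
  res <- find_uces(gs, prm)
  expect_identical(norm_intervals(res$uces),
                   data.frame(seq_name = "chr1", start = 300L, end = 450L))
  expect_identical(res$uces$n_species_passing, 3L)
  # 90 bp falls below the minimum length: nothing is called
  seg90 <- rand_seq(90, seed = 42)
  gs90 <- segment_genome_set(list(ref = seg90, spB = seg90, spC = seg90))
  expect_identical(nrow(find_uces(gs90, prm)$uces), 0L)
})

test_that("the mismatch budget spans a 200 bp window with 3 substitutions", {
  seg <- rand_seq(200, seed = 43)
  gs <- segment_genome_set(list(
    ref = seg, spB = seg, spC = mutate_at(seg, c(30, 100, 170))))
  # identity of spC over the full window: 197/200 = 98.5% >= 97%
  prm <- uce_params(min_identity = 0.97, min_species_fraction = 1.0,
                    cumulative_identities = 0.97)
  res <- find_uces(gs, prm)
  # the UCE covers the whole 200 bp segment; the maximal window may take
  # in a few extra pad bases while the mismatch budget lasts, and the
  # exhaustive oracle must agree on the exact extent
  expect_identical(nrow(res$uces), 1L)
  expect_lte(res$uces$start, 300L)
  expect_gte(res$uces$end, 500L)
  expect_lt(res$uces$length, 240L)
  expect_identical(norm_intervals(res$uces),
                   norm_intervals(oracle_find_uces(gs, prm)))
  expect_identical(res$uces$n_species_passing, 3L)
  hits <- res$species_hits
  expect_identical(sort(unique(hits$species)), c("ref", "spB", "spC"))
  expect_true(all(hits$identity >= 0.97))
})

test_that("multimap cap removes repetitive windows; cap = Inf is identity", {
  seg <- rand_seq(120, seed = 44)
  copies <- paste(vapply(1:6, function(i) paste0(seg, rand_seq(40)),
                         character(1)), collapse = "")
  gs <- genome_set(list(
    ref = c(chr1 = paste0(rand_seq(200), seg, rand_seq(200))),
    spB = c(chr1 = paste0(rand_seq(100), copies, rand_seq(100)))), "ref")
  win <- data.frame(seq_name = "chr1", start = 200L, end = 320L)
  prm5 <- uce_params(min_identity = 1.0, multimap_cap = 5L,
                     cumulative_identities = 1.0)
  kept <- apply_multimap_cap(win, gs, prm5)
  expect_identical(nrow(kept), 0L)
  expect_identical(attr(kept, "removed")$genome, "spB")
  expect_identical(attr(kept, "removed")$n_occurrences, 6L)
  prm6 <- uce_params(min_identity = 1.0, multimap_cap = 6L,
                     cumulative_identities = 1.0)
  expect_identical(nrow(apply_multimap_cap(win, gs, prm6)), 1L)
  prmInf <- uce_params(min_identity = 1.0, multimap_cap = Inf,
                       cumulative_identities = 1.0)
  expect_identical(norm_intervals(apply_multimap_cap(win, gs, prmInf)),
                   norm_intervals(win))
})

test_that("single-identity cumulative ladder equals a plain run", {
  sim <- acceptance_fixture(1)
  prm <- uce_params(min_identity = 0.97, cumulative_identities = 0.97)
  plain <- find_uces(sim$genome_set, prm)
  cum <- cumulative_scan(sim$genome_set, prm)
  expect_identical(norm_intervals(cum), norm_intervals(plain$uces))
})

test_that("find_uces is deterministic and reports identities within [p, 1]", {
  sim <- acceptance_fixture(2)
  prm <- uce_params()
  r1 <- find_uces(sim$genome_set, prm)
  r2 <- find_uces(sim$genome_set, prm)
  expect_identical(r1$uces, r2$uces)
  expect_identical(r1$species_hits, r2$species_hits)
  expect_true(all(r1$species_hits$identity >= prm$min_identity - 1e-9))
  expect_true(all(r1$species_hits$identity <= 1))
  expect_true(all(r1$uces$length >= prm$min_length))
  Y <- length(sim$genome_set)
  expect_true(all(r1$uces$n_species_passing >=
                    ceiling(prm$min_species_fraction * Y)))
})

test_that("BED export carries per-mille identity scores", {
  sim <- acceptance_fixture(1)
  res <- find_uces(sim$genome_set, uce_params())
  bed <- uce_bed(res)
  expect_identical(names(bed),
                   c("seq_name", "start", "end", "name", "score", "strand"))
  expect_true(all(bed$score >= 970L & bed$score <= 1000L))
  expect_identical(bed$score,
                   as.integer(round(res$uces$mean_identity * 1000)))
})
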