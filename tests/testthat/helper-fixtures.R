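# Shared fixture builders and caches for the test suite. Heavy objects are
# computed once per session and memoized in `.fixture_cache`.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand-constructed genome set: each species is left-pad + (shared segment,
# possibly mutated) + right-pad, with pads chosen so the bases adjacent to
# the segment always mismatch the reference (deterministic window ends)
segment_genome_set <- function(segment_by_species, pad = 300L, seed = 1L) {
  set.seed(seed)
  seqs <- list()
  first <- TRUE
  for (sp in names(segment_by_species)) {
    lpad <- rand_seq(pad)
    rpad <- rand_seq(pad)
    seg <- segment_by_species[[sp]]
    if (!first) {
      # force a mismatch at both junctions relative to the reference
      flip <- function(ch) c(A = "C", C = "A", G = "T", T = "G", N = "A")[[ch]]
      ref <- segment_by_species[[1L]]
      refseq <- seqs[[1L]][["chr1"]]
      refstart <- pad + 1L
      substr(lpad, pad, pad) <- flip(substr(refseq, pad, pad))
      substr(rpad, 1L, 1L) <- flip(substr(refseq, pad + nchar(ref) + 1L,
                                          pad + nchar(ref) + 1L))
    }
    seqs[[sp]] <- c(chr1 = paste0(lpad, seg, rpad))
    first <- FALSE
  }
  genome_set(seqs, reference_id = names(segment_by_species)[1L],
             normalize = FALSE)
}

mutate_at <- function(seq, positions) {
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) ch[p] <- flip[[ch[p]]]
  paste(ch, collapse = "")
}

norm_intervals <- function(x) {
  x <- as.data.frame(x)[, c("seq_name", "start", "end")]
  x <- x[order(x$seq_name, x$start), ]
  rownames(x) <- NULL
  x
}

# acceptance-scale fixture family: 20 seeds cycling species counts 3/6/8
acceptance_fixture_spec <- function(seed) {
  i <- ((seed - 1L) %% 3L) + 1L
  list(seed = seed,
       n_species = c(3L, 6L, 8L)[i],
       genome_length = c(16000L, 12000L, 10000L)[i],
       n_elements = c(8L, 7L, 6L)[i])
}

acceptance_fixture <- function(seed) {
  cache_get(sprintf("fix%02d", seed), {
    fs <- acceptance_fixture_spec(seed)
    rates <- rep(c(.004, .008, .012, .016, .02),
                 length.out = fs$n_species - 1L)
    simulate_genomes(sim_config(
      n_species = fs$n_species, genome_length = fs$genome_length,
      n_elements = fs$n_elements, element_length = c(180L, 400L),
      substitution_rate = rates, n_repeat_copies = 0L, seed = fs$seed))
  })
}

acceptance_grid <- function() {
  grid <- expand.grid(L = c(100L, 120L), p = c(1, 0.97, 0.95),
                      f = c(0.5, 1))
  grid$params <- lapply(seq_len(nrow(grid)), function(i)
    uce_params(min_length = grid$L[i], min_identity = grid$p[i],
               min_species_fraction = grid$f[i],
               cumulative_identities = grid$p[i]))
  grid
}

# full pipeline over the parameter grid with shared staged objects;
# returns list of merged interval data.frames (one per grid row)
pipeline_grid <- function(sim, grid = acceptance_grid()) {
  key <- sprintf("pipe%02d", sim$config$seed)
  cache_get(key, {
    gs <- sim$genome_set
    index <- build_kmer_index(gs, 50L)
    core <- select_core_kmers(index, 0.5, 1000L)
    out <- vector("list", nrow(grid))
    for (p in unique(grid$p)) {
      hits <- map_kmer_approx(core, gs, p, 1000L)
      cand <- build_candidates(hits, gs, 50L)
      for (L in unique(grid$L)) {
        tabs <- ucetools:::build_seed_tables(
          gs, ucetools:::pigeonhole_w(p, L))
        for (f in unique(grid$f)) {
          i <- which(grid$L == L & grid$p == p & grid$f == f)
          prm <- grid$params[[i]]
          called <- extend_and_call(cand, gs, prm, tabs)
          capped <- apply_multimap_cap(called$windows, gs, prm, tabs)
          out[[i]] <- merge_intervals(capped)
        }
      }
    }
    out
  })
}

oracle_grid <- function(sim, grid = acceptance_grid()) {
  key <- sprintf("orc%02d", sim$config$seed)
  cache_get(key, oracle_find_uces_grid(sim$genome_set, grid$params))
}
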