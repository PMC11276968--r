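# Core k-mer machinery: canonical k-mer indexing across genomes, selection
# of core k-mers (exact presence in at least a threshold fraction of
# species), and approximate (gapless, substitution-only) mapping of core
# k-mers back into every genome by pigeonhole seeding.
#
# Pigeonhole argument used throughout: a window matching a query of length
# k with at most m mismatches must contain at least one of m+1 disjoint
# query segments exactly, so exact-matching every segment and verifying
# candidates by Hamming distance is complete under the gapless model.

mismatch_budget <- function(k, min_identity) {
  # identity (k - d)/k >= p  <=>  d <= (1 - p) * k ; small epsilon guards
  # against floating-point representation of p
  as.integer(floor((1 - min_identity) * k + 1e-9))
}

# disjoint seed segment bounds (1-based [from, to]) covering 1..k
seed_segments <- function(k, n_seg) {
  cuts <- as.integer(round(seq(0L, k, length.out = n_seg + 1L)))
  data.frame(from = cuts[-length(cuts)] + 1L, to = cuts[-1L])
}

# all k-mer start positions (1-based) whose window is N-free
nfree_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer())
  isN <- charToRaw(seq) == charToRaw("N")
  if (!any(isN)) return(seq_len(n - k + 1L))
  cs <- c(0L, cumsum(isN))
  starts <- seq_len(n - k + 1L)
  starts[cs[starts + k] - cs[starts] == 0L]
}

canonicalize <- function(kmers) {
  rc <- revcomp_kmers(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# vectorized reverse complement for many equal-length short strings:
# complement via chartr, reverse via substring matrix
revcomp_kmers <- function(kmers) {
  if (length(kmers) == 0L) return(character())
  k <- nchar(kmers[1L])
  comp <- chartr("ACGTN", "TGCAN", kmers)
  out <- substring(comp, k, k)
  for (j in seq_len(k - 1L))
    out <- paste0(out, substring(comp, k - j, k - j))
  out
}

#' Build a canonical k-mer index over a genome set
#'
#' Stores, for every N-free canonical k-mer (lexicographic minimum of the
#' k-mer and its reverse complement), the number of occurrences in each
#' species. Each genomic locus is counted once; strand is collapsed by
#' canonicalization, so a genome and its reverse complement index
#' identically.
#'
#' @param genome_set a [genome_set()].
#' @param k k-mer length (>= 8; default 50).
#' @return object of class `kmer_index`: fields `k`, `counts` (data.frame
#'   kmer/species/count) and `species_ids`.
#' @export
build_kmer_index <- function(genome_set, k = 50L) {
  k <- as.integer(k)
  if (k < 8L) stop("k must be >= 8")
  tabs <- vector("list", length(genome_set$species_ids))
  for (i in seq_along(genome_set$species_ids)) {
    sp <- genome_set$species_ids[i]
    per_seq <- lapply(genome_set$sequences[[sp]], function(s) {
      starts <- nfree_starts(s, k)
      if (length(starts) == 0L) return(NULL)
      kmers <- substring(s, starts, starts + k - 1L)
      # canonical via the mirrored window of the reverse-complement string
      n <- nchar(s)
      rcs <- revcomp(s)
      rckmers <- substring(rcs, n - (starts + k - 1L) + 1L, n - starts + 1L)
      data.table::data.table(kmer = pmin(kmers, rckmers))
    })
    per_seq <- data.table::rbindlist(per_seq)
    if (nrow(per_seq) == 0L) next
    tabs[[i]] <- per_seq[, .(count = .N), by = kmer][, species := sp]
  }
  counts <- data.table::rbindlist(tabs)
  if (nrow(counts) == 0L) {
    warning("no sequence of length >= k: empty k-mer index")
    counts <- data.table::data.table(kmer = character(),
                                     species = character(),
                                     count = integer())
  }
  structure(list(k = k, counts = data.table::setDF(counts),
                 species_ids = genome_set$species_ids),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, ",",
      length(unique(x$counts$kmer)), "canonical k-mers over",
      length(x$species_ids), "species\n")
  invisible(x)
}

#' Select core k-mers
#'
#' Core k-mers are canonical k-mers exactly present in at least
#' `ceil(core_fraction * Y)` of the Y genomes and occurring at most
#' `kmer_map_limit` times in every genome (high-copy k-mers are repetitive
#' and are excluded before the expensive mapping stage).
#'
#' @param index a [build_kmer_index()] result.
#' @param core_fraction minimum fraction of species with an exact
#'   occurrence (0 < fraction <= 1; default 0.5).
#' @param kmer_map_limit maximum exact occurrences per genome
#'   (default 1000).
#' @return data.frame with columns kmer, n_species, total_hits.
#' @export
select_core_kmers <- function(index, core_fraction = 0.5,
                              kmer_map_limit = 1000L) {
  stopifnot(inherits(index, "kmer_index"))
  if (core_fraction <= 0 || core_fraction > 1)
    stop("core_fraction must be in (0, 1]")
  if (kmer_map_limit < 1L) stop("kmer_map_limit must be >= 1")
  need <- as.integer(ceiling(core_fraction * length(index$species_ids) - 1e-9))
  dt <- data.table::as.data.table(index$counts)
  agg <- dt[, .(n_species = .N, max_count = max(count),
                total_hits = sum(count)), by = kmer]
  keep <- agg[n_species >= need & max_count <= kmer_map_limit]
  data.table::setorder(keep, kmer)
  data.table::setDF(keep[, .(kmer, n_species, total_hits)])
}

#' Map k-mers into every genome within an identity threshold
#'
#' Finds every position, on either strand of every sequence of every
#' genome, where the genomic window differs from the k-mer by at most
#' `floor((1 - min_identity) * k)` substitutions (gapless Hamming model; a
#' window N never matches). K-mers exceeding `kmer_map_limit` hits in any
#' single genome are discarded.
#'
#' @param kmers character vector of (canonical) k-mers, all the same
#'   length, or the data.frame returned by [select_core_kmers()].
#' @param genome_set a [genome_set()].
#' @param min_identity minimum identity per hit (default 0.97).
#' @param kmer_map_limit per-genome hit cap (default 1000).
#' @return data.frame of hits: kmer, species, seq_name, start (0-based),
#'   strand, mismatches; attribute `dropped` lists k-mers removed by the
#'   cap.
#' @export
map_kmer_approx <- function(kmers, genome_set, min_identity = 0.97,
                            kmer_map_limit = 1000L) {
  if (is.data.frame(kmers)) kmers <- kmers$kmer
  empty <- data.frame(kmer = character(), species = character(),
                      seq_name = character(), start = integer(),
                      strand = character(), mismatches = integer())
  if (length(kmers) == 0L) return(structure(empty, dropped = character()))
  k <- nchar(kmers[1L])
  if (any(nchar(kmers) != k)) stop("all k-mers must share one length")
  m <- mismatch_budget(k, min_identity)
  segs <- seed_segments(k, m + 1L)
  seed_dt <- data.table::rbindlist(lapply(seq_len(nrow(segs)), function(i) {
    data.table::data.table(
      kmer_id = seq_along(kmers),
      seed = substring(kmers, segs$from[i], segs$to[i]),
      offset = segs$from[i],
      w = segs$to[i] - segs$from[i] + 1L)
  }))
  out <- list()
  for (sp in genome_set$species_ids) {
    for (sq in names(genome_set$sequences[[sp]])) {
      s <- genome_set$sequences[[sp]][[sq]]
      n <- nchar(s)
      if (n < k) next
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") s else revcomp(s)
        cand <- seed_join(seed_dt, subject, k)
        if (nrow(cand) == 0L) next
        mm <- hamming_at(subject, cand$start1, kmers[cand$kmer_id], k)
        hit <- cand[mm <= m]
        if (nrow(hit) == 0L) next
        hit[, mismatches := mm[mm <= m]]
        start1 <- hit$start1
        start0 <- if (strand == "+") start1 - 1L else n - (start1 + k - 1L)
        out[[length(out) + 1L]] <- data.table::data.table(
          kmer = kmers[hit$kmer_id], species = sp, seq_name = sq,
          start = start0, strand = strand, mismatches = hit$mismatches)
      }
    }
  }
  hits <- data.table::rbindlist(out)
  if (nrow(hits) == 0L) return(structure(empty, dropped = character()))
  # palindromic double-counting: same locus on both strands -> keep '+'
  data.table::setorder(hits, kmer, species, seq_name, start, strand)
  hits <- unique(hits, by = c("kmer", "species", "seq_name", "start"))
  per_gen <- hits[, .N, by = .(kmer, species)]
  dropped <- unique(per_gen[N > kmer_map_limit]$kmer)
  hits <- hits[!kmer %in% dropped]
  structure(data.table::setDF(hits), dropped = dropped)
}

# exact seed lookup: join the seed table against all genome windows of the
# needed width(s); returns candidate k-mer placements (1-based start1)
seed_join <- function(seed_dt, subject, k) {
  n <- nchar(subject)
  cands <- lapply(unique(seed_dt$w), function(wlen) {
    if (n < wlen) return(NULL)
    pos <- seq_len(n - wlen + 1L)
    gdt <- data.table::data.table(
      seed = substring(subject, pos, pos + wlen - 1L), pos = pos)
    sel <- seed_dt[w == wlen]
    hit <- gdt[sel, on = "seed", allow.cartesian = TRUE, nomatch = NULL]
    hit[, .(kmer_id, start1 = pos - offset + 1L)]
  })
  cand <- data.table::rbindlist(cands)
  if (nrow(cand) == 0L) return(cand)
  cand <- unique(cand[start1 >= 1L & start1 + k - 1L <= n])
  cand
}

# Hamming distance between genome windows [start1, start1+k) and the
# corresponding query strings (vectorized across candidates)
hamming_at <- function(subject, start1, queries, k) {
  mm <- integer(length(start1))
  for (j in seq_len(k)) {
    mm <- mm + (substring(subject, start1 + j - 1L, start1 + j - 1L) !=
                  substring(queries, j, j))
  }
  mm
}

#' Find gapless occurrences of one query sequence in a genome
#'
#' Complete seed-and-verify search for all positions (either strand) where
#' a genome window matches `query` with identity at least `min_identity`
#' under the substitution-only model. Used for the UCE multi-mapping cap.
#'
#' @param query query sequence (A/C/G/T; no N).
#' @param sequences named character vector (one genome).
#' @param min_identity minimum identity.
#' @return data.frame: seq_name, start (0-based), strand, mismatches.
#' @export
gapless_occurrences <- function(query, sequences, min_identity) {
  len <- nchar(query)
  m <- mismatch_budget(len, min_identity)
  segs <- seed_segments(len, m + 1L)
  out <- list()
  for (sq in names(sequences)) {
    s <- sequences[[sq]]
    n <- nchar(s)
    if (n < len) next
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") s else revcomp(s)
      subj_dna <- Biostrings::DNAString(subject)
      starts <- integer()
      for (i in seq_len(nrow(segs))) {
        seed <- substr(query, segs$from[i], segs$to[i])
        # matchPattern reports all (including overlapping) exact matches
        hit <- Biostrings::start(
          Biostrings::matchPattern(seed, subj_dna, fixed = TRUE))
        if (length(hit))
          starts <- c(starts, hit - segs$from[i] + 1L)
      }
      starts <- unique(starts[starts >= 1L & starts + len - 1L <= n])
      if (length(starts) == 0L) next
      qraw <- charToRaw(query)
      mm <- vapply(starts, function(st) {
        sum(charToRaw(substr(subject, st, st + len - 1L)) != qraw)
      }, integer(1))
      keep <- mm <= m
      if (!any(keep)) next
      st1 <- starts[keep]
      start0 <- if (strand == "+") st1 - 1L else n - (st1 + len - 1L)
      out[[length(out) + 1L]] <- data.table::data.table(
        seq_name = sq, start = start0, strand = strand,
        mismatches = mm[keep])
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L)
    return(data.frame(seq_name = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  data.table::setorder(res, seq_name, start, strand)
  res <- unique(res, by = c("seq_name", "start"))
  data.table::setDF(res)
}
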