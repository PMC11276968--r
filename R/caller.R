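# UCE calling: merge core k-mer hits into candidate regions on the
# reference, then search each candidate neighbourhood exhaustively for
# maximal reference windows of length >= L in which at least ceil(f * Y)
# species (the reference counts as one) carry a gapless match at identity
# >= p, apply the multi-mapping cap, and merge surviving windows.
#
# Window qualification uses a prefix-sum transform: with c(t) the number of
# mismatches on a diagonal up to reference boundary t and
# h(t) = c(t) - (1 - p) * t, a window [s, e) meets identity p on that
# diagonal iff h(e) <= h(s). This makes per-window tests O(1) and the whole
# region scan a small set of vectorized comparisons.

EPS_ID <- 1e-9

#' Parameter set for UCE discovery
#'
#' Defaults follow the standard placental-mammal definition: minimum length
#' 100 bp, minimum identity 97%, minimum species fraction 50%, core k-mer
#' length 50, core threshold 50% of species, core k-mer map limit 1,000
#' positions per genome, UCE multi-mapping cap 100 positions per genome,
#' and a cumulative identity ladder 100/99/98/97%.
#'
#' @param min_length minimum UCE length L in bp.
#' @param min_identity minimum per-species identity p in (0, 1].
#' @param min_species_fraction minimum fraction f of species (reference
#'   included) required to carry the element.
#' @param core_k core k-mer length.
#' @param core_fraction fraction of species in which a core k-mer must
#'   occur exactly.
#' @param kmer_map_limit per-genome cap on core k-mer occurrences.
#' @param multimap_cap per-genome cap on UCE-sequence occurrences.
#' @param cumulative_identities strictly decreasing identity ladder for
#'   [cumulative_scan()]; its minimum must equal `min_identity`.
#' @return a validated list of class `uce_params`.
#' @export
uce_params <- function(min_length = 100L, min_identity = 0.97,
                       min_species_fraction = 0.5, core_k = 50L,
                       core_fraction = 0.5, kmer_map_limit = 1000L,
                       multimap_cap = 100L,
                       cumulative_identities = c(1.00, 0.99, 0.98, 0.97)) {
  p <- list(min_length = as.integer(min_length),
            min_identity = min_identity,
            min_species_fraction = min_species_fraction,
            core_k = as.integer(core_k),
            core_fraction = core_fraction,
            kmer_map_limit = as.integer(kmer_map_limit),
            multimap_cap = if (is.finite(multimap_cap))
              as.integer(multimap_cap) else Inf,
            cumulative_identities = cumulative_identities)
  if (p$min_identity <= 0 || p$min_identity > 1)
    stop("min_identity must be in (0, 1]")
  if (p$min_identity < 0.85)
    stop("min_identity below 0.85 is outside the ultraconserved regime ",
         "supported by the seeded search")
  if (p$min_species_fraction <= 0 || p$min_species_fraction > 1)
    stop("min_species_fraction must be in (0, 1]")
  if (p$min_length < p$core_k)
    stop("min_length must be >= core_k")
  ci <- p$cumulative_identities
  if (length(ci)) {
    if (any(diff(ci) >= 0)) stop("cumulative_identities must be strictly ",
                                 "decreasing")
    if (abs(min(ci) - p$min_identity) > EPS_ID)
      stop("min(cumulative_identities) must equal min_identity")
  }
  structure(p, class = "uce_params")
}

# minimum guaranteed exact-run length inside any gapless match of length
# >= L at identity >= p (pigeonhole over the mismatch partition); floor()
# keeps a safety margin
pigeonhole_w <- function(p, L) {
  if (p >= 1 - EPS_ID) return(as.integer(L))
  max(4L, as.integer(floor(p * L / ((1 - p) * L + 1))))
}

species_threshold <- function(f, n_species) {
  as.integer(ceiling(f * n_species - EPS_ID))
}

#' Build candidate regions from core k-mer hits
#'
#' Reference-genome hits of the core k-mers are merged (overlapping or
#' book-ended) into candidate intervals; each candidate records which
#' species have hits from its constituent k-mers and their merged hit
#' intervals.
#'
#' @param hits data.frame from [map_kmer_approx()].
#' @param genome_set a [genome_set()].
#' @param core_k k-mer length used for the hits.
#' @return data.frame of candidate intervals (seq_name, start, end,
#'   n_species_support) with attribute `support` holding per-species merged
#'   hit intervals per candidate.
#' @export
build_candidates <- function(hits, genome_set, core_k = 50L) {
  ref <- genome_set$reference_id
  empty <- data.frame(seq_name = character(), start = integer(),
                      end = integer(), n_species_support = integer())
  hdt <- data.table::as.data.table(hits)
  if (nrow(hdt) == 0L) return(structure(empty, support = list()))
  # only k-mers mapped in the reference can anchor a candidate
  ref_kmers <- unique(hdt[species == ref]$kmer)
  hdt <- hdt[kmer %in% ref_kmers]
  if (nrow(hdt) == 0L) return(structure(empty, support = list()))
  rhits <- hdt[species == ref,
               .(seq_name, start = start, end = start + core_k)]
  cand <- merge_intervals(rhits)
  cdt <- data.table::as.data.table(cand)
  cdt[, cand_id := .I]
  # attribute each k-mer (via its ref hits) to the candidate(s) it overlaps
  rk <- hdt[species == ref, .(kmer, seq_name, start, end = start + core_k)]
  ov <- intersect_intervals(rk, cdt)
  km2cand <- data.table::data.table(kmer = rk$kmer[ov$a_idx],
                                    cand_id = cdt$cand_id[ov$b_idx])
  allh <- merge(hdt, unique(km2cand), by = "kmer", allow.cartesian = TRUE)
  support <- allh[, {
    m <- merge_intervals(data.frame(seq_name = seq_name, start = start,
                                    end = start + core_k))
    list(seq_name = m$seq_name, start = m$start, end = m$end)
  }, by = .(cand_id, species)]
  nsup <- support[, .(n_species_support = data.table::uniqueN(species)),
                  by = cand_id]
  cand$n_species_support <- nsup$n_species_support[
    match(seq_len(nrow(cand)), nsup$cand_id)]
  structure(cand, support = data.table::setDF(support))
}

# -- window engine ----------------------------------------------------------

# genome w-mer lookup tables for one run: per species/seq/strand a keyed
# data.table of exact w-mers
build_seed_tables <- function(gs, w, species = NULL) {
  if (is.null(species)) species <- gs$species_ids
  tabs <- structure(list(), occ_cache = new.env(parent = emptyenv()))
  for (sp in species) {
    for (sq in names(gs$sequences[[sp]])) {
      s <- gs$sequences[[sp]][[sq]]
      n <- nchar(s)
      if (n < w) next
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") s else revcomp(s)
        pos <- seq_len(n - w + 1L)
        dt <- data.table::data.table(
          seed = substring(subject, pos, pos + w - 1L), pos = pos)
        data.table::setkey(dt, seed)
        tabs[[paste(sp, sq, strand, sep = "\r")]] <-
          list(species = sp, seq_name = sq, strand = strand, dt = dt,
               subject = mask_n_other(subject), n = n)
      }
    }
  }
  tabs
}

# Scan one reference region [lo, hi) (0-based) for maximal qualifying
# windows. Returns list(windows = data.frame(start, end), hits = per-window
# per-species qualifying projections, touch_lo/touch_hi flags).
scan_region <- function(refstr, refN_pref, seq_name, lo, hi, seed_tabs,
                        params, n_species, ref_id) {
  L <- params$min_length
  p <- params$min_identity
  TT <- species_threshold(params$min_species_fraction, n_species)
  W <- hi - lo
  if (W < L) return(NULL)
  w <- pigeonhole_w(p, L)
  region <- substr(refstr, lo + 1L, hi)
  # seeds: N-free w-mers of the region, keyed by sequence
  spos <- nfree_starts(region, w)
  if (length(spos) == 0L) return(NULL)
  seeds <- data.table::data.table(
    seed = substring(region, spos, spos + w - 1L), roff = spos)
  # diagonals per species: (seq, strand, off) with off = subject1 - ref1;
  # the reference participates via its own self-match, not via diagonals
  seed_tabs <- Filter(function(t) t$species != ref_id, seed_tabs)
  diags <- list()
  for (tab in seed_tabs) {
    hitdt <- tab$dt[seeds, on = "seed", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hitdt) == 0L) next
    # absolute 1-based ref position of seed = lo + roff ; diagonal offset
    off <- unique(hitdt$pos - (lo + hitdt$roff))
    for (o in off)
      diags[[length(diags) + 1L]] <-
        list(species = tab$species, seq_name = tab$seq_name,
             strand = tab$strand, off = o, subject = tab$subject, n = tab$n)
  }
  if (length(diags) == 0L) return(NULL)

  # boundary grid t = 0..W at reference positions lo + t
  rawreg <- charToRaw(region)
  sp_ids <- unique(vapply(diags, `[[`, "", "species"))
  hS_list <- list(); hE_list <- list()
  dmeta <- list()
  for (i in seq_along(diags)) {
    d <- diags[[i]]
    # valid ref 1-based positions r in region: subject pos r + off in [1, n]
    a <- max(lo + 1L, 1L - d$off)
    b <- min(hi, d$n - d$off)
    if (b - a + 1L < L) next
    sub <- substr(d$subject, a + d$off, b + d$off)
    mism <- as.integer(charToRaw(substr(refstr, a, b)) != charToRaw(sub))
    pref <- c(0L, cumsum(mism))
    tA <- a - 1L - lo              # first valid boundary index (0-based)
    tB <- b - lo                   # last valid boundary index
    h <- rep(NA_real_, W + 1L)
    h[(tA:tB) + 1L] <- pref - (1 - p) * ((tA:tB) - tA)
    hS <- h; hS[is.na(hS)] <- -Inf     # invalid start boundary: never usable
    hE <- h; hE[is.na(hE)] <- Inf      # invalid end boundary: never usable
    hS_list[[length(hS_list) + 1L]] <- hS
    hE_list[[length(hE_list) + 1L]] <- hE
    dmeta[[length(dmeta) + 1L]] <- d
  }
  if (length(dmeta) == 0L) return(NULL)
  dspecies <- vapply(dmeta, `[[`, "", "species")

  W1 <- W + 1L
  count <- matrix(0L, W1, W1)
  Q_sp <- list()
  for (sp in unique(dspecies)) {
    idx <- which(dspecies == sp)
    Q <- NULL
    for (i in idx) {
      # Qi[s, e] <- hE[e] <= hS[s] + eps, via column-recycled comparison
      Qi <- matrix(hE_list[[i]], W1, W1, byrow = TRUE) <=
        (hS_list[[i]] + EPS_ID)
      Q <- if (is.null(Q)) Qi else (Q | Qi)
    }
    Q_sp[[sp]] <- Q
    count <- count + Q
  }
  # reference self-match: +1 for every N-free window
  nref <- refN_pref[lo + (0:W) + 1L]      # N count up to boundary
  refok <- matrix(nref, W1, W1, byrow = TRUE) == nref
  bnd <- 0:W
  lenok <- matrix(bnd, W1, W1, byrow = TRUE) - bnd >= L
  qual <- refok & lenok & (count + 1L >= TT)
  if (!any(qual)) return(list(windows = NULL, touch_lo = FALSE,
                              touch_hi = FALSE))
  # last TRUE column per row (max.col on the column-reversed matrix)
  firstrev <- max.col(qual[, W1:1, drop = FALSE] * 1L,
                      ties.method = "first")
  e_col <- W1 + 1L - firstrev
  has <- qual[cbind(seq_len(W1), e_col)]
  s_idx <- which(has) - 1L                # start boundaries (0-based grid)
  e_idx <- e_col[has] - 1L
  # dominated windows: keep only those not contained in an earlier one
  keep <- e_idx > c(-1L, cummax(e_idx))[seq_along(e_idx)]
  s_idx <- s_idx[keep]; e_idx <- e_idx[keep]
  windows <- data.frame(seq_name = seq_name, start = lo + s_idx,
                        end = lo + e_idx)
  # per-window, per-species best qualifying projection
  hit_rows <- list()
  for (wi in seq_along(s_idx)) {
    si <- s_idx[wi] + 1L; ei <- e_idx[wi] + 1L
    for (sp in names(Q_sp)) {
      if (!Q_sp[[sp]][si, ei]) next
      best <- NULL
      for (i in which(dspecies == sp)) {
        hs <- hS_list[[i]][si]; he <- hE_list[[i]][ei]
        if (!(he <= hs + EPS_ID)) next
        d <- dmeta[[i]]
        len <- e_idx[wi] - s_idx[wi]
        # h(e) - h(s) = mismatches - (1 - p) * len
        mm <- as.integer(round((he - hs) + (1 - p) * len))
        ident <- (len - mm) / len
        sub1 <- lo + s_idx[wi] + 1L + d$off   # subject 1-based start
        g_start <- if (d$strand == "+") sub1 - 1L else d$n - (sub1 + len - 1L)
        cand <- list(species = sp, seq_name = d$seq_name, strand = d$strand,
                     g_start = g_start, identity = ident, len = len)
        if (is.null(best) ||
            cand$identity > best$identity + EPS_ID ||
            (abs(cand$identity - best$identity) <= EPS_ID &&
             (cand$g_start < best$g_start ||
              (cand$g_start == best$g_start && cand$strand == "+" &&
               best$strand == "-"))))
          best <- cand
      }
      if (!is.null(best))
        hit_rows[[length(hit_rows) + 1L]] <- data.table::data.table(
          ref_seq = seq_name,
          win_start = lo + s_idx[wi], win_end = lo + e_idx[wi],
          species = sp, seq_name = best$seq_name, start = best$g_start,
          end = best$g_start + best$len, strand = best$strand,
          identity = best$identity)
    }
  }
  hits <- data.table::rbindlist(hit_rows)
  list(windows = windows, hits = hits,
       touch_lo = any(s_idx == 0L) && lo > 0L,
       touch_hi = any(e_idx == W) && hi < nchar(refstr))
}

#' Extend candidate regions and call maximal UCE windows
#'
#' Searches each candidate neighbourhood (candidate plus padding, expanded
#' while qualifying windows touch the boundary) for every maximal
#' reference window of length >= `min_length` in which at least
#' `ceil(min_species_fraction * Y)` species -- the reference included --
#' carry a gapless match at identity >= `min_identity` on either strand.
#'
#' @param candidates data.frame from [build_candidates()].
#' @param genome_set a [genome_set()].
#' @param params a [uce_params()].
#' @return list with `windows` (maximal qualifying windows, may overlap)
#'   and `hits` (per-window best species projections).
#' @export
extend_and_call <- function(candidates, genome_set, params,
                            seed_tabs = NULL) {
  gs <- genome_set
  Y <- length(gs$species_ids)
  w <- pigeonhole_w(params$min_identity, params$min_length)
  if (is.null(seed_tabs)) seed_tabs <- build_seed_tables(gs, w)
  refseqs <- ref_sequences(gs)
  refN <- lapply(refseqs, function(s) c(0L, cumsum(charToRaw(s) ==
                                                     charToRaw("N"))))
  pad <- max(200L, params$min_length + 50L)
  win_list <- list(); hit_list <- list()
  for (ci in seq_len(nrow(candidates))) {
    sq <- candidates$seq_name[ci]
    refstr <- refseqs[[sq]]
    n <- nchar(refstr)
    lo <- max(0L, candidates$start[ci] - pad)
    hi <- min(n, candidates$end[ci] + pad)
    for (iter in 1:25) {
      res <- scan_region(refstr, refN[[sq]], sq, lo, hi, seed_tabs,
                         params, Y, gs$reference_id)
      if (is.null(res) || is.null(res$windows)) break
      grew <- FALSE
      if (res$touch_lo) { lo <- max(0L, lo - pad); grew <- TRUE }
      if (res$touch_hi) { hi <- min(n, hi + pad); grew <- TRUE }
      if (!grew) break
    }
    if (is.null(res) || is.null(res$windows)) next
    win_list[[length(win_list) + 1L]] <- res$windows
    if (!is.null(res$hits) && nrow(res$hits))
      hit_list[[length(hit_list) + 1L]] <- res$hits
  }
  windows <- unique(data.table::rbindlist(win_list))
  hits <- data.table::rbindlist(hit_list)
  if (nrow(windows)) {
    data.table::setorder(windows, seq_name, start, end)
    if (nrow(hits)) hits <- unique(hits)
  } else {
    windows <- data.table::data.table(seq_name = character(),
                                      start = integer(), end = integer())
  }
  list(windows = data.table::setDF(windows),
       hits = if (nrow(hits)) data.table::setDF(hits) else NULL)
}

#' Remove UCE windows exceeding the multi-mapping cap
#'
#' A window is removed when its reference sequence occurs, at identity
#' `>= min_identity`, more than `multimap_cap` times in any single genome
#' (the occurrence at its own reference locus included).
#'
#' @param windows data.frame of reference windows (seq_name, start, end).
#' @param genome_set a [genome_set()].
#' @param params a [uce_params()]; `multimap_cap = Inf` disables the
#'   filter.
#' @return the retained windows, with attribute `removed` logging each
#'   removed window and the genome that triggered removal.
#' @export
apply_multimap_cap <- function(windows, genome_set, params,
                               seed_tabs = NULL) {
  cap <- params$multimap_cap
  removed <- data.frame(seq_name = character(), start = integer(),
                        end = integer(), genome = character(),
                        n_occurrences = integer())
  if (nrow(windows) == 0L || is.infinite(cap))
    return(structure(windows, removed = removed))
  p <- params$min_identity
  w <- pigeonhole_w(p, params$min_length)
  if (is.null(seed_tabs)) seed_tabs <- build_seed_tables(genome_set, w)
  refseqs <- ref_sequences(genome_set)
  qseqs <- vapply(seq_len(nrow(windows)), function(i)
    substr(refseqs[[windows$seq_name[i]]], windows$start[i] + 1L,
           windows$end[i]), character(1))
  occ <- count_occurrences_batch(qseqs, genome_set$species_ids, seed_tabs,
                                 p, w)
  keep <- rep(TRUE, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    if (grepl("N", qseqs[i], fixed = TRUE)) next  # N windows never called
    over <- which(occ[i, ] > cap)
    if (length(over)) {
      keep[i] <- FALSE
      sp <- colnames(occ)[over[1L]]
      removed <- rbind(removed, data.frame(
        seq_name = windows$seq_name[i], start = windows$start[i],
        end = windows$end[i], genome = sp, n_occurrences = occ[i, over[1L]]))
    }
  }
  structure(windows[keep, , drop = FALSE], removed = removed)
}

# Count genomic positions where each query occurs at identity >= p, per
# genome, via the shared w-mer tables. Seeds are the first w bases of each
# of (m+1) disjoint segments of a query; pigeonhole-complete because any
# qualifying occurrence (length >= L at identity >= p) contains an exact
# run of at least w = pigeonhole_w(p, L) bases aligned to one segment.
# Returns a matrix [query, species]; results are memoized in the cache
# environment attached to the seed tables.
count_occurrences_batch <- function(qseqs, species_ids, seed_tabs, p, w) {
  occ <- matrix(0L, length(qseqs), length(species_ids),
                dimnames = list(NULL, species_ids))
  if (length(qseqs) == 0L) return(occ)
  cache <- attr(seed_tabs, "occ_cache") %||% new.env(parent = emptyenv())
  ckey <- sprintf("%.6f|%s", p, qseqs)
  todo <- which(!vapply(ckey, exists, logical(1), envir = cache))
  if (length(todo)) {
    qd_list <- lapply(todo, function(i) {
      len <- nchar(qseqs[i])
      m <- mismatch_budget(len, p)
      segs <- seed_segments(len, m + 1L)
      data.table::data.table(
        win = i, len = len, m = m,
        seed = substring(qseqs[i], segs$from, segs$from + w - 1L),
        qoff = segs$from)
    })
    qdt <- data.table::rbindlist(qd_list)
    hits_per_win <- vector("list", length(qseqs))
    for (tab in seed_tabs) {
      hit <- tab$dt[qdt, on = "seed", nomatch = NULL]
      if (nrow(hit) == 0L) next
      hit[, cand := pos - qoff + 1L]
      hit <- unique(hit[, .(win, len, m, cand)])
      hit <- hit[cand >= 1L & cand + len - 1L <= tab$n]
      if (nrow(hit) == 0L) next
      for (r in seq_len(nrow(hit))) {
        st <- hit$cand[r]; len <- hit$len[r]
        sub <- charToRaw(substr(tab$subject, st, st + len - 1L))
        if (sum(sub != charToRaw(qseqs[hit$win[r]])) <= hit$m[r]) {
          start0 <- if (tab$strand == "+") st - 1L else
            tab$n - (st + len - 1L)
          i <- hit$win[r]
          hits_per_win[[i]] <- rbind(hits_per_win[[i]], data.frame(
            species = tab$species, seq_name = tab$seq_name, start = start0))
        }
      }
    }
    for (i in todo) {
      h <- hits_per_win[[i]]
      cnt <- stats::setNames(integer(length(species_ids)), species_ids)
      if (!is.null(h)) {
        u <- unique(h)
        tb <- table(u$species)
        cnt[names(tb)] <- as.integer(tb)
      }
      assign(ckey[i], cnt, envir = cache)
    }
  }
  for (i in seq_along(qseqs))
    occ[i, ] <- get(ckey[i], envir = cache)[species_ids]
  occ
}

#' Discover UCEs in a genome set
#'
#' Runs the full pipeline at a single identity threshold: canonical k-mer
#' indexing, core k-mer selection, approximate mapping, candidate merging,
#' exhaustive window calling, the multi-mapping cap, and merging of
#' overlapping maximal windows into reported UCEs.
#'
#' @param genome_set a [genome_set()].
#' @param params a [uce_params()].
#' @param index optionally, a precomputed [build_kmer_index()] for this
#'   genome set (the index does not depend on the identity threshold, so
#'   callers sweeping thresholds can reuse it).
#' @return object of class `uce_set`: `uces` (data.frame uce_id, seq_name,
#'   start, end, length, n_species_passing, mean_identity, score),
#'   `species_hits` (per-UCE best hits per passing species, reference
#'   included), `removed` (multimap-cap log) and `params`.
#' @export
find_uces <- function(genome_set, params = uce_params(), index = NULL) {
  stopifnot(inherits(params, "uce_params"))
  if (is.null(index)) index <- build_kmer_index(genome_set, params$core_k)
  core <- select_core_kmers(index, params$core_fraction,
                            params$kmer_map_limit)
  hits <- map_kmer_approx(core, genome_set, params$min_identity,
                          params$kmer_map_limit)
  cand <- build_candidates(hits, genome_set, params$core_k)
  w <- pigeonhole_w(params$min_identity, params$min_length)
  seed_tabs <- build_seed_tables(genome_set, w)
  called <- extend_and_call(cand, genome_set, params, seed_tabs)
  capped <- apply_multimap_cap(called$windows, genome_set, params,
                               seed_tabs)
  removed <- attr(capped, "removed")
  uces <- merge_intervals(capped)
  new_uce_set(uces, capped, called$hits, genome_set, params, removed)
}

new_uce_set <- function(uces, windows, win_hits, genome_set, params,
                        removed) {
  ref <- genome_set$reference_id
  if (nrow(uces) == 0L) {
    return(structure(list(
      uces = data.frame(uce_id = character(), seq_name = character(),
                        start = integer(), end = integer(),
                        length = integer(), n_species_passing = integer(),
                        mean_identity = numeric(), score = integer()),
      species_hits = data.frame(uce_id = character(), species = character(),
                                seq_name = character(), start = integer(),
                                end = integer(), strand = character(),
                                identity = numeric()),
      removed = removed, params = params,
      reference_id = ref), class = "uce_set"))
  }
  uces$uce_id <- sprintf("UCE%05d", seq_len(nrow(uces)))
  sh_list <- list()
  for (i in seq_len(nrow(uces))) {
    # reference's own hit
    sh_list[[length(sh_list) + 1L]] <- data.frame(
      uce_id = uces$uce_id[i], species = ref, seq_name = uces$seq_name[i],
      start = uces$start[i], end = uces$end[i], strand = "+", identity = 1)
    if (is.null(win_hits)) next
    # windows overlapping this UCE contribute their species projections;
    # windows removed by the cap do not (they are absent from `windows`)
    wh <- win_hits[win_hits$ref_seq == uces$seq_name[i] &
                     win_hits$win_start < uces$end[i] &
                     win_hits$win_end > uces$start[i], , drop = FALSE]
    okwin <- paste(windows$seq_name, windows$start, windows$end)
    wh <- wh[paste(wh$ref_seq, wh$win_start, wh$win_end) %in% okwin,
             , drop = FALSE]
    if (nrow(wh) == 0L) next
    wdt <- data.table::as.data.table(wh)
    best <- wdt[order(-identity, -(win_end - win_start), start,
                      strand)][, .SD[1L], by = species]
    sh_list[[length(sh_list) + 1L]] <- data.frame(
      uce_id = uces$uce_id[i], species = best$species,
      seq_name = best$seq_name, start = best$start, end = best$end,
      strand = best$strand, identity = best$identity)
  }
  species_hits <- do.call(rbind, sh_list)
  agg <- data.table::as.data.table(species_hits)[
    , .(n = data.table::uniqueN(species), mid = mean(identity)),
    by = uce_id]
  uces$length <- uces$end - uces$start
  uces$n_species_passing <- agg$n[match(uces$uce_id, agg$uce_id)]
  uces$mean_identity <- agg$mid[match(uces$uce_id, agg$uce_id)]
  uces$score <- as.integer(round(uces$mean_identity * 1000))
  structure(list(uces = uces, species_hits = species_hits,
                 removed = removed, params = params, reference_id = ref),
            class = "uce_set")
}

#' @export
print.uce_set <- function(x, ...) {
  cat("uce_set:", nrow(x$uces), "UCEs on reference", x$reference_id,
      sprintf("(L >= %d, identity >= %.2f, species fraction >= %.2f)\n",
              x$params$min_length, x$params$min_identity,
              x$params$min_species_fraction))
  if (nrow(x$uces)) {
    cat(" total bases:", sum(x$uces$length),
        "| mean length:", round(mean(x$uces$length), 1),
        "| mean identity:", sprintf("%.4f", mean(x$uces$mean_identity)),
        "\n")
  }
  if (nrow(x$removed))
    cat(" multimap cap removed", nrow(x$removed), "window(s)\n")
  invisible(x)
}

#' Export a UCE set as a BED6 data.frame
#'
#' Score is the mean cross-species identity in per-mille (0..1000).
#'
#' @param uce_set a [find_uces()] result.
#' @return BED6-shaped data.frame.
#' @export
uce_bed <- function(uce_set) {
  u <- uce_set$uces
  data.frame(seq_name = u$seq_name, start = u$start, end = u$end,
             name = u$uce_id, score = u$score,
             strand = rep("+", nrow(u)))
}

#' Cumulative multi-identity scan
#'
#' Runs the full pipeline at each identity of the ladder (strictest first)
#' and merges the union of the reference intervals, guarding against
#' single-threshold mapping misses.
#'
#' @param genome_set a [genome_set()].
#' @param params a [uce_params()]; `cumulative_identities` defines the
#'   ladder.
#' @return merged BED-shaped data.frame of UCE intervals with per-run
#'   provenance in attribute `runs`.
#' @export
cumulative_scan <- function(genome_set, params = uce_params()) {
  stopifnot(inherits(params, "uce_params"))
  ladder <- sort(params$cumulative_identities, decreasing = TRUE)
  index <- build_kmer_index(genome_set, params$core_k)
  runs <- list()
  beds <- list()
  for (p in ladder) {
    pi <- params
    pi$min_identity <- p
    pi$cumulative_identities <- p
    res <- find_uces(genome_set, pi, index = index)
    runs[[sprintf("%.4f", p)]] <- res
    if (nrow(res$uces))
      beds[[length(beds) + 1L]] <- res$uces[, c("seq_name", "start", "end")]
  }
  merged <- if (length(beds)) merge_intervals(do.call(rbind, beds)) else
    data.frame(seq_name = character(), start = integer(), end = integer())
  if (nrow(merged)) {
    merged$name <- sprintf("UCE%05d", seq_len(nrow(merged)))
    merged$score <- 0L
    merged$strand <- "+"
    # score: best per-mille identity among contributing runs' UCEs
    for (r in runs) {
      if (nrow(r$uces) == 0L) next
      ov <- intersect_intervals(merged, r$uces)
      if (nrow(ov))
        for (j in seq_len(nrow(ov)))
          merged$score[ov$a_idx[j]] <- max(merged$score[ov$a_idx[j]],
                                           r$uces$score[ov$b_idx[j]])
    }
  }
  structure(merged, runs = runs)
}
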