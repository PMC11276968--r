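# Exhaustive UCE finder used as the validation oracle. Unlike the staged
# pipeline it inspects EVERY alignment diagonal of every genome against the
# reference (both strands), so its completeness does not depend on shared
# exact core k-mers. A reference base is reported iff it lies in some
# window of length >= L for which at least ceil(f * Y) species (reference
# included) have a gapless match at identity >= p, subject to the
# multi-mapping cap evaluated on species-maximal windows exactly as the
# caller evaluates it.
#
# The per-diagonal full scan is O(len) per offset, O(n^2) per sequence
# pair, which is the exhaustive guarantee; window enumeration afterwards is
# restricted to diagonals carrying an exact run of length >= w, which is
# complete by the pigeonhole lemma (any >= p match of length >= L contains
# an exact run of at least floor(pL / ((1-p)L + 1)) bases).

ORACLE_MAX_BASES <- 1e6

#' Exhaustive oracle UCE finder
#'
#' @param genome_set a [genome_set()]; aggregate size must be <= 1 Mb.
#' @param params a [uce_params()] (or list of them sharing one genome
#'   sweep via [oracle_find_uces_grid()]).
#' @return merged data.frame of qualifying reference intervals.
#' @export
oracle_find_uces <- function(genome_set, params) {
  oracle_find_uces_grid(genome_set, list(params))[[1L]]
}

#' Exhaustive oracle over a parameter grid
#'
#' Shares the (expensive) exhaustive diagonal sweep across parameter sets.
#'
#' @param genome_set a [genome_set()].
#' @param params_list list of [uce_params()].
#' @return list of merged interval data.frames, one per parameter set.
#' @export
oracle_find_uces_grid <- function(genome_set, params_list) {
  gs <- genome_set
  total <- sum(vapply(gs$sequences, function(ss) sum(nchar(ss)), numeric(1)))
  if (total > ORACLE_MAX_BASES)
    stop("oracle refuses genome sets over ", ORACLE_MAX_BASES,
         " aggregate bases (got ", total, ")")
  w_min <- min(vapply(params_list, function(p)
    pigeonhole_w(p$min_identity, p$min_length), integer(1)))
  sweep <- oracle_diagonal_sweep(gs, w_min)
  lapply(params_list, function(p) oracle_eval_params(gs, sweep, p))
}

# Diagonals of every (reference seq, genome seq, strand) pair carrying an
# exact match run of length >= w. Two equivalent formulations:
#  - "quadratic": literally walk every diagonal and test for a zero-
#    mismatch run (the textbook exhaustive scan);
#  - "join": an exact run of length >= w exists on a diagonal iff the two
#    sequences share a w-mer on that diagonal, so a hash join of all w-mer
#    positions enumerates exactly the same diagonal set in O(n) per pair.
# The join form is the default; the quadratic form validates it in tests.
oracle_diagonal_sweep <- function(gs, w, method = c("join", "quadratic")) {
  method <- match.arg(method)
  ref <- gs$reference_id
  out <- list()
  for (rseq in names(ref_sequences(gs))) {
    R <- ref_sequences(gs)[[rseq]]
    rawR <- charToRaw(R)
    nr <- length(rawR)
    rpos <- seq_len(max(nr - w + 1L, 0L))
    rdt <- data.table::data.table(seed = substring(R, rpos, rpos + w - 1L),
                                  rpos = rpos)
    rdt <- rdt[!grepl("N", seed, fixed = TRUE)]
    data.table::setkey(rdt, seed)
    for (sp in gs$species_ids) {
      for (sq in names(gs$sequences[[sp]])) {
        s <- gs$sequences[[sp]][[sq]]
        for (strand in c("+", "-")) {
          subject <- mask_n_other(if (strand == "+") s else revcomp(s))
          rawS <- charToRaw(subject)
          ns <- length(rawS)
          if (ns < w) next
          if (method == "join") {
            gpos <- seq_len(ns - w + 1L)
            gdt <- data.table::data.table(
              seed = substring(subject, gpos, gpos + w - 1L), gpos = gpos)
            hit <- rdt[gdt, on = "seed", nomatch = NULL]
            offs <- if (nrow(hit)) sort(unique(hit$gpos - hit$rpos)) else
              integer()
            for (off in offs) {
              a <- max(1L, 1L - off)
              b <- min(nr, ns - off)
              out[[length(out) + 1L]] <- list(
                ref_seq = rseq, species = sp, seq_name = sq,
                strand = strand, off = off, a = a, b = b)
            }
          } else {
            for (off in (1L - nr):(ns - 1L)) {
              a <- max(1L, 1L - off)
              b <- min(nr, ns - off)
              len <- b - a + 1L
              if (len < w) next
              mism <- rawR[a:b] != rawS[(a + off):(b + off)]
              pref <- cumsum(mism)
              has_run <- any(pref[w:len] - c(0L, pref)[1:(len - w + 1L)] == 0L)
              if (has_run)
                out[[length(out) + 1L]] <- list(
                  ref_seq = rseq, species = sp, seq_name = sq,
                  strand = strand, off = off, a = a, b = b)
            }
          }
        }
      }
    }
  }
  out
}

oracle_eval_params <- function(gs, sweep, params) {
  ref <- gs$reference_id
  Y <- length(gs$species_ids)
  L <- params$min_length
  p <- params$min_identity
  TT <- species_threshold(params$min_species_fraction, Y)
  cap <- params$multimap_cap
  empty <- data.frame(seq_name = character(), start = integer(),
                      end = integer())
  all_windows <- list()
  for (rseq in names(ref_sequences(gs))) {
    R <- ref_sequences(gs)[[rseq]]
    rawR <- charToRaw(R)
    nr <- length(rawR)
    refN <- c(0L, cumsum(rawR == charToRaw("N")))
    dset <- Filter(function(d) d$ref_seq == rseq, sweep)
    if (length(dset) == 0L) next
    # per-diagonal prefix transforms
    diags <- lapply(dset, function(d) {
      s <- gs$sequences[[d$species]][[d$seq_name]]
      subject <- if (d$strand == "+") s else revcomp(s)
      rawS <- charToRaw(mask_n_other(subject))
      mism <- as.integer(rawR[d$a:d$b] != rawS[(d$a + d$off):(d$b + d$off)])
      len <- d$b - d$a + 1L
      h <- c(0, cumsum(mism)) - (1 - p) * (0:len)
      suffmin <- rev(cummin(rev(h)))
      list(species = d$species, genome = d$species, A0 = d$a - 1L,
           len = len, h = h, suffmin = suffmin,
           is_ref_genome = d$species == ref)
    })
    nonref_idx <- which(vapply(diags, function(d) !d$is_ref_genome,
                               logical(1)))
    sp_of <- vapply(diags, `[[`, "", "species")
    win_s <- integer(); win_e <- integer()
    if (TT <= 1L) {
      # degenerate threshold: the reference alone qualifies, so windows are
      # exactly the maximal N-free reference runs of length >= L
      nfree <- rle(as.integer(rawR != charToRaw("N")))
      ends <- cumsum(nfree$lengths)
      begs <- ends - nfree$lengths
      ok <- nfree$values == 1L & nfree$lengths >= L
      win_s <- begs[ok]; win_e <- ends[ok]
    } else {
      # last index with v[i] <= thr in a non-decreasing vector (0 if none);
      # findInterval re-checks sortedness on every call, so roll our own
      bsearch_last_le <- function(v, thr) {
        if (v[1L] > thr) return(0L)
        lo <- 1L; hi <- length(v)
        while (lo < hi) {
          mid <- lo + ((hi - lo + 1L) %/% 2L)
          if (v[mid] <= thr) lo <- mid else hi <- mid - 1L
        }
        lo
      }
      # last end boundary with h <= thr on a diagonal, via the
      # non-decreasing suffix minimum (exact; -1 if none at distance >= L)
      diag_last_end <- function(d, s) {
        t <- s - d$A0
        if (t < 0L || t + L > d$len) return(-1L)
        last <- bsearch_last_le(d$suffmin, d$h[t + 1L] + EPS_ID) - 1L
        if (last >= t + L) d$A0 + last else -1L
      }
      # candidate starts: boundaries s from which some diagonal admits a
      # qualifying end boundary at distance >= L
      starts <- integer()
      for (d in diags[nonref_idx]) {
        tt <- 0:(d$len)
        ok <- tt + L <= d$len &
          d$suffmin[pmin(tt + L, d$len) + 1L] <= d$h[tt + 1L] + EPS_ID
        starts <- c(starts, d$A0 + tt[ok])
      }
      starts <- sort(unique(starts))
      for (s in starts) {
        ends_d <- vapply(diags[nonref_idx], diag_last_end, integer(1), s = s)
        live <- which(ends_d >= s + L)
        if (length(live) == 0L) next
        ecap <- max(ends_d[live])
        evec <- (s + L):ecap
        cnt <- integer(length(evec))
        for (spn in unique(sp_of[nonref_idx][live])) {
          any_sp <- rep(FALSE, length(evec))
          for (j in live[sp_of[nonref_idx][live] == spn]) {
            d <- diags[nonref_idx][[j]]
            t <- s - d$A0
            te <- evec - d$A0
            valid <- te >= 0L & te <= d$len
            qe <- rep(FALSE, length(evec))
            qe[valid] <- d$h[te[valid] + 1L] <= d$h[t + 1L] + EPS_ID
            any_sp <- any_sp | qe
          }
          cnt <- cnt + any_sp
        }
        refok <- (refN[evec + 1L] - refN[s + 1L]) == 0L
        qual <- refok & (cnt + 1L >= TT)
        if (!any(qual)) next
        win_s <- c(win_s, s)
        win_e <- c(win_e, max(evec[qual]))
      }
    }
    if (length(win_s) == 0L) next
    # dominated-window removal (same staircase rule as the caller)
    ord <- order(win_s, win_e)
    win_s <- win_s[ord]; win_e <- win_e[ord]
    keep <- win_e > c(-1L, cummax(win_e))[seq_along(win_e)]
    win_s <- win_s[keep]; win_e <- win_e[keep]
    # multimap cap on species-maximal windows: count matching diagonals
    # (i.e. genomic positions) per genome, reference genome included
    if (is.finite(cap)) {
      okcap <- logical(length(win_s))
      for (i in seq_along(win_s)) {
        counts <- list()
        for (d in diags) {
          t <- win_s[i] - d$A0
          te <- win_e[i] - d$A0
          if (t < 0L || te > d$len) next
          if (d$h[te + 1L] <= d$h[t + 1L] + EPS_ID)
            counts[[d$genome]] <- (counts[[d$genome]] %||% 0L) + 1L
        }
        okcap[i] <- all(vapply(counts, identity, integer(1)) <= cap)
      }
      win_s <- win_s[okcap]; win_e <- win_e[okcap]
    }
    if (length(win_s))
      all_windows[[length(all_windows) + 1L]] <- data.frame(
        seq_name = rseq, start = win_s, end = win_e)
  }
  if (length(all_windows) == 0L) return(empty)
  merge_intervals(do.call(rbind, all_windows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
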