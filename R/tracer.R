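# Cross-species tracing of UCE (or control) sequences: glocal alignment
# (global in the query, local in the target) of each query against every
# target sequence on both strands, best-bit-score hit selection, the
# printed length/E-value filters, and detection/identity summaries.
#
# Scoring defaults are the classic DNA scheme match +5 / mismatch -4 with
# affine gaps (open 12, extend 4; a gap of length g costs 12 + 4g).
# Ungapped Karlin-Altschul lambda and K are computed numerically from the
# match/mismatch scores and the target base composition and applied to the
# gapped score as a documented approximation: the downstream filters
# (>= 30 bp, E <= 0.01, >= 70% identity) dominate behaviour.

#' Alignment scoring scheme
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap penalties (positive numbers; a
#'   gap of length g costs `gap_open + g * gap_extend`).
#' @return list of class `trace_scoring`.
#' @export
trace_scoring <- function(match = 5, mismatch = -4, gap_open = 12,
                          gap_extend = 4) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "trace_scoring")
}

#' Ungapped Karlin-Altschul parameters for a match/mismatch scheme
#'
#' `lambda` solves sum(p_s exp(lambda s)) = 1 for the two-point score
#' distribution induced by the base composition; `K` is computed by the
#' classical series over convolutions of the score distribution; `H` is
#' the relative entropy per aligned pair (nats).
#'
#' @param match,mismatch substitution scores (integers).
#' @param base_freqs named frequencies of A/C/G/T in the target (defaults
#'   to uniform).
#' @return list with lambda, K, H.
#' @export
karlin_altschul <- function(match = 5, mismatch = -4,
                            base_freqs = c(A = .25, C = .25, G = .25,
                                           T = .25)) {
  bf <- base_freqs / sum(base_freqs)
  p_match <- sum(bf^2)
  scores <- c(match, mismatch)
  probs <- c(p_match, 1 - p_match)
  ev <- sum(scores * probs)
  if (ev >= 0) stop("expected score must be negative for local statistics")
  f <- function(l) sum(probs * exp(l * scores)) - 1
  lambda <- stats::uniroot(f, c(1e-9, 10), tol = 1e-12)$root
  H <- lambda * sum(scores * probs * exp(lambda * scores))
  # series for K (Karlin & Altschul 1990): sigma over k-fold convolutions
  lo <- min(scores); hi <- max(scores)
  # pmf vector over lo:hi
  base <- numeric(hi - lo + 1L)
  base[scores - lo + 1L] <- probs
  pk <- base
  off <- lo                       # value of first cell of pk
  sigma <- 0
  for (k in 1:80) {
    vals <- seq(off, off + length(pk) - 1L)
    neg <- vals < 0
    # sigma = sum_k (1/k) [ P(S_k >= 0) + E(exp(lambda S_k); S_k < 0) ]
    sigma <- sigma + (sum(pk[!neg]) + sum(pk[neg] * exp(lambda *
                                                          vals[neg]))) / k
    # next convolution
    pk <- stats::convolve(pk, rev(base), type = "open")
    pk[pk < 0] <- 0
    off <- off + lo
  }
  K <- lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda)))
  list(lambda = lambda, K = K, H = H)
}

target_base_freqs <- function(sequences) {
  tab <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in sequences) {
    r <- charToRaw(s)
    tab <- tab + c(A = sum(r == charToRaw("A")),
                   C = sum(r == charToRaw("C")),
                   G = sum(r == charToRaw("G")),
                   T = sum(r == charToRaw("T")))
  }
  if (sum(tab) == 0) return(c(A = .25, C = .25, G = .25, T = .25))
  tab / sum(tab)
}

trace_submat <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", ] <- scoring$mismatch    # N never matches, itself included
  m[, "N"] <- scoring$mismatch
  m
}

#' Glocal alignment of one query against a target genome
#'
#' Global in the query, local in the target: affine-gap dynamic
#' programming over both strands of every target sequence; the single
#' highest-scoring hit is returned (ties broken by lower E-value, longer
#' alignment, lower target coordinate, then + strand).
#'
#' @param query query sequence (character).
#' @param target named character vector of target sequences (one genome).
#' @param scoring a [trace_scoring()].
#' @param ka optional precomputed [karlin_altschul()] parameters for this
#'   target.
#' @param query_id id recorded in the hit.
#' @return one-row data.frame (query_id, seq_name, start, end, strand,
#'   aligned_length, matches, identity, score, bit_score, evalue), or NULL
#'   when the target is empty.
#' @export
align_glocal <- function(query, target, scoring = trace_scoring(),
                         ka = NULL, query_id = "query") {
  if (length(target) == 0L || nchar(query) < 1L) return(NULL)
  if (is.null(ka))
    ka <- karlin_altschul(scoring$match, scoring$mismatch,
                          target_base_freqs(target))
  submat <- trace_submat(scoring)
  n_total <- sum(nchar(target))
  best <- NULL
  for (sq in names(target)) {
    subj <- Biostrings::DNAString(target[[sq]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") query else revcomp(query)
      pa <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(pat), subject = subj,
        type = "global-local", substitutionMatrix = submat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      sc <- Biostrings::score(pa)
      al_len <- nchar(as.character(Biostrings::alignedPattern(pa)))
      matches <- Biostrings::nmatch(pa)
      sstart <- Biostrings::start(Biostrings::subject(pa))
      send <- Biostrings::end(Biostrings::subject(pa))
      hit <- data.frame(
        query_id = query_id, seq_name = sq,
        start = sstart - 1L, end = send, strand = strand,
        aligned_length = al_len, matches = matches,
        identity = matches / al_len, score = sc,
        bit_score = (ka$lambda * sc - log(ka$K)) / log(2),
        evalue = ka$K * nchar(query) * n_total * exp(-ka$lambda * sc))
      if (is.null(best) ||
          hit$score > best$score ||
          (hit$score == best$score &&
           (hit$evalue < best$evalue ||
            (hit$aligned_length > best$aligned_length) ||
            (hit$aligned_length == best$aligned_length &&
             (hit$start < best$start ||
              (hit$start == best$start && hit$strand == "+" &&
               best$strand == "-"))))))
        best <- hit
    }
  }
  best
}

#' Trace a set of query sequences across target genomes
#'
#' @param queries named character vector of query sequences (e.g. UCE
#'   sequences extracted from the reference).
#' @param targets named list of genomes: species -> named character vector
#'   of sequences.
#' @param scoring a [trace_scoring()].
#' @return data.frame of best hits per (query, species); queries with no
#'   alignment are absent.
#' @export
trace_queries <- function(queries, targets, scoring = trace_scoring()) {
  rows <- list()
  for (sp in names(targets)) {
    tg <- targets[[sp]]
    ka <- karlin_altschul(scoring$match, scoring$mismatch,
                          target_base_freqs(tg))
    for (qi in names(queries)) {
      hit <- align_glocal(queries[[qi]], tg, scoring, ka, query_id = qi)
      if (!is.null(hit)) {
        hit$species <- sp
        rows[[length(rows) + 1L]] <- hit
      }
    }
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) return(NULL)
  data.table::setcolorder(out, c("query_id", "species"))
  data.table::setDF(out)
}

#' Filter trace hits by aligned length and E-value
#'
#' @param hits data.frame from [trace_queries()].
#' @param min_len minimum aligned length (columns), default 30.
#' @param max_evalue maximum E-value, default 0.01.
#' @return the retained hits.
#' @export
filter_hits <- function(hits, min_len = 30L, max_evalue = 0.01) {
  if (is.null(hits) || nrow(hits) == 0L) return(hits)
  hits[hits$aligned_length >= min_len & hits$evalue <= max_evalue, ,
       drop = FALSE]
}

#' Per-species detection and identity summary
#'
#' Detection counts drop hits below the identity cutoff; identity
#' summaries use all supplied (filtered) hits, matching the practice of
#' filtering identity and detection separately.
#'
#' @param hits filtered hits ([filter_hits()]).
#' @param identity_cutoff detection cutoff (default 0.70).
#' @param n_queries total number of queries traced (for detection
#'   percentages); defaults to the number of distinct query ids in `hits`.
#' @return data.frame per species: n_queries, n_detected, mean/min/max
#'   identity (NA when no hit).
#' @export
count_detected <- function(hits, identity_cutoff = 0.70, n_queries = NULL) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(species = character(), n_queries = integer(),
                      n_detected = integer(), mean_identity = numeric(),
                      min_identity = numeric(), max_identity = numeric()))
  if (is.null(n_queries)) n_queries <- length(unique(hits$query_id))
  dt <- data.table::as.data.table(hits)
  out <- dt[, .(n_queries = n_queries,
                n_detected = sum(identity >= identity_cutoff),
                mean_identity = mean(identity),
                min_identity = min(identity),
                max_identity = max(identity)), by = species]
  data.table::setDF(out)
}

#' Sample control CDS sequences
#'
#' Uniform sample, without replacement, of CDS intervals with length
#' between `min_len` and `max_len` (the UCE size range), reproducible
#' under `seed`.
#'
#' @param gm a [gene_models()] object.
#' @param sequences named character vector holding the genome the models
#'   annotate.
#' @param n sample size.
#' @param min_len,max_len inclusive CDS length bounds (default 100-1300).
#' @param seed RNG seed.
#' @return named character vector of CDS sequences.
#' @export
sample_control_cds <- function(gm, sequences, n, min_len = 100L,
                               max_len = 1300L, seed) {
  if (missing(seed)) stop("a seed is required")
  cds <- gm$cds
  lens <- cds$end - cds$start
  elig <- which(lens >= min_len & lens <= max_len)
  if (length(elig) < n)
    stop("only ", length(elig), " eligible CDS intervals (need ", n, ")")
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  take <- if (length(elig) == n) elig else sort(sample(elig, n))
  out <- vapply(take, function(i) {
    substr(sequences[[cds$seq_name[i]]], cds$start[i] + 1L, cds$end[i])
  }, character(1))
  names(out) <- sprintf("%s_cds%d", cds$gene_id[take], take)
  out
}

#' Cross-species identity profile across UCE cores and flanks
#'
#' For each UCE, locates the homologous copy in every non-reference
#' species (best gapless diagonal of the core at a permissive identity)
#' and records, for each position offset in `[-flank_bp, length +
#' flank_bp)`, whether the species base matches the reference base.
#'
#' @param uce_set a [find_uces()] result (or data.frame seq_name, start,
#'   end, name).
#' @param genome_set the [genome_set()] the UCEs were called from.
#' @param flank_bp flank width in bp (>= 0).
#' @param locate_identity minimum core identity used to anchor the copy
#'   (default 0.85, permissive enough for diverged copies).
#' @return data.frame: uce_id, offset (relative to UCE start), region
#'   (flank5/core/flank3), n_species, identity (mean match fraction).
#' @export
flank_profile <- function(uce_set, genome_set, flank_bp = 100L,
                          locate_identity = 0.85) {
  uces <- if (inherits(uce_set, "uce_set")) uce_set$uces else uce_set
  if (is.null(uces$uce_id))
    uces$uce_id <- uces$name %||% sprintf("UCE%05d", seq_len(nrow(uces)))
  gs <- genome_set
  ref <- gs$reference_id
  others <- setdiff(gs$species_ids, ref)
  w <- pigeonhole_w(locate_identity, 100L)
  tabs <- build_seed_tables(gs, w, species = others)
  rows <- list()
  for (i in seq_len(nrow(uces))) {
    refstr <- ref_sequences(gs)[[uces$seq_name[i]]]
    nref <- nchar(refstr)
    core <- substr(refstr, uces$start[i] + 1L, uces$end[i])
    len <- nchar(core)
    offs <- seq(-flank_bp, len + flank_bp - 1L)
    acc <- rep(0, length(offs)); nsp <- rep(0L, length(offs))
    for (sp in others) {
      anchor <- locate_best_copy(core, sp, tabs, locate_identity)
      if (is.null(anchor)) next
      # walk the diagonal across core plus flanks (anchor$pos1 is the
      # 1-based subject position aligned to the core start)
      ref1 <- uces$start[i] + 1L + offs        # 1-based ref positions
      sub1 <- anchor$pos1 + offs
      ok <- ref1 >= 1L & ref1 <= nref & sub1 >= 1L & sub1 <= anchor$n
      refch <- substring(refstr, ref1[ok], ref1[ok])
      subch <- substring(anchor$subject, sub1[ok], sub1[ok])
      match <- refch == subch & refch != "N"
      acc[ok] <- acc[ok] + match
      nsp[ok] <- nsp[ok] + 1L
    }
    keep <- nsp > 0L
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      uce_id = uces$uce_id[i], offset = offs[keep],
      region = ifelse(offs[keep] < 0L, "flank5",
                      ifelse(offs[keep] >= len, "flank3", "core")),
      n_species = nsp[keep], identity = acc[keep] / nsp[keep])
  }
  if (length(rows) == 0L)
    return(data.frame(uce_id = character(), offset = integer(),
                      region = character(), n_species = integer(),
                      identity = numeric()))
  do.call(rbind, rows)
}

# best gapless placement (fewest mismatches) of `qseq` in species `sp`
# using the shared seed tables; returns subject string and 1-based anchor
locate_best_copy <- function(qseq, sp, seed_tabs, p) {
  len <- nchar(qseq)
  m <- mismatch_budget(len, p)
  segs <- seed_segments(len, m + 1L)
  w <- nchar(seed_tabs[[1L]]$dt$seed[1L])
  qdt <- data.table::data.table(
    seed = substring(qseq, segs$from, pmin(segs$from + w - 1L, len)),
    qoff = segs$from)
  qdt <- qdt[nchar(seed) == w]
  qraw <- charToRaw(qseq)
  best <- NULL
  for (tab in seed_tabs) {
    if (tab$species != sp) next
    hit <- tab$dt[qdt, on = "seed", nomatch = NULL]
    if (nrow(hit) == 0L) next
    cand <- unique(hit$pos - hit$qoff + 1L)
    cand <- cand[cand >= 1L & cand + len - 1L <= tab$n]
    for (st in cand) {
      mm <- sum(charToRaw(substr(tab$subject, st, st + len - 1L)) != qraw)
      if (mm <= m && (is.null(best) || mm < best$mm))
        best <- list(mm = mm, pos1 = st, subject = tab$subject,
                     n = tab$n, strand = tab$strand, seq_name = tab$seq_name)
    }
  }
  best
}
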