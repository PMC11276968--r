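# Multi-species genome simulator with implanted conserved elements.
# Background sequence is drawn i.i.d. per species, so (with overwhelming
# probability) no long exact k-mer is shared between species by chance and
# every cross-species conserved window is attributable to an implant.
# Elements are copied from the reference -- together with their flanking
# context, which receives a higher substitution rate, emulating the
# conserved-core / divergent-flank structure of real UCE loci -- into each
# species at random positions and strands.

#' Simulation configuration
#'
#' Defaults emulate a small placental-mammal-style study: near-identical
#' element cores (per-species substitution rates around 1%, the scale
#' implied by a >= 97% identity definition), flanks at 10% divergence, 41%
#' GC background, and one high-copy element replicated 150 times in a
#' designated species to exercise repeat filtering.
#'
#' @param n_species number of genomes Y (reference included).
#' @param genome_length background length per species, bp.
#' @param n_elements number of implanted conserved elements.
#' @param element_length length range (min, max) of element cores, bp.
#' @param substitution_rate per-base element substitution rate for
#'   non-reference species; scalar or vector of length `n_species - 1`.
#' @param flank_length conserved-flank context length copied on each side
#'   of an element core, bp.
#' @param flank_substitution_rate per-base substitution rate in flanks.
#' @param background_gc background GC fraction.
#' @param n_repeat_copies extra copies of the first element (core plus
#'   flanking context) implanted into `repeat_species` as a young repeat
#'   family (0 disables).
#' @param repeat_species species receiving the repeat copies (default:
#'   first non-reference species).
#' @param repeat_divergence per-base substitution rate between repeat
#'   family members (default 0.01, a young family).
#' @param indel_rate per-base probability of opening an indel in an
#'   implanted segment (0 = substitution-only, the default; keep the
#'   gapless callers exact).
#' @param indel_max maximum indel length, bp.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 4L, genome_length = 60000L,
                       n_elements = 20L, element_length = c(150L, 400L),
                       substitution_rate = 0.01, flank_length = 150L,
                       flank_substitution_rate = 0.10,
                       background_gc = 0.41, n_repeat_copies = 150L,
                       repeat_species = NULL, repeat_divergence = 0.01,
                       indel_rate = 0, indel_max = 3L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(n_species = as.integer(n_species),
              genome_length = as.integer(genome_length),
              n_elements = as.integer(n_elements),
              element_length = as.integer(element_length),
              substitution_rate = substitution_rate,
              flank_length = as.integer(flank_length),
              flank_substitution_rate = flank_substitution_rate,
              background_gc = background_gc,
              n_repeat_copies = as.integer(n_repeat_copies),
              repeat_species = repeat_species,
              repeat_divergence = repeat_divergence,
              indel_rate = indel_rate, indel_max = as.integer(indel_max),
              seed = as.integer(seed))
  rates <- c(cfg$substitution_rate, cfg$flank_substitution_rate,
             cfg$repeat_divergence, cfg$indel_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (cfg$background_gc <= 0 || cfg$background_gc >= 1)
    stop("background_gc must be in (0, 1)")
  if (cfg$n_species < 2L) stop("need at least 2 species")
  if (length(cfg$element_length) == 1L)
    cfg$element_length <- rep(cfg$element_length, 2L)
  if (cfg$element_length[1] > cfg$element_length[2])
    stop("element_length must be (min, max)")
  nr <- cfg$n_species - 1L
  if (!length(cfg$substitution_rate) %in% c(1L, nr))
    stop("substitution_rate must be scalar or one per non-reference species")
  structure(cfg, class = "sim_config")
}

random_background <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute bases at `rate`; every substitution goes to a different base
substitute_bases <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_sub = 0L, pos = integer()))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate & chars != "N")
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  list(seq = paste(chars, collapse = ""), n_sub = length(hit), pos = hit)
}

apply_indels <- function(seq, rate, indel_max) {
  if (rate <= 0) return(list(seq = seq, n_indel = 0L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- character(0)
  n_indel <- 0L
  i <- 1L
  while (i <= length(chars)) {
    if (stats::runif(1L) < rate) {
      n_indel <- n_indel + 1L
      len <- sample.int(indel_max, 1L)
      if (stats::runif(1L) < 0.5) {           # deletion
        i <- i + len
        next
      } else {                                # insertion
        out <- c(out, sample(c("A", "C", "G", "T"), len, replace = TRUE))
      }
    }
    out <- c(out, chars[i])
    i <- i + 1L
  }
  list(seq = paste(out, collapse = ""), n_indel = n_indel)
}

# choose `k` non-overlapping placement start positions for segments of the
# given lengths within [1, n], keeping `gap` bases between segments
place_segments <- function(n, lengths, gap, max_tries = 200L) {
  k <- length(lengths)
  slack <- n - sum(lengths) - gap * (k + 1L)
  if (slack < 0L)
    stop("cannot place ", k, " segments totalling ", sum(lengths),
         " bp (plus spacing) in ", n, " bp")
  cuts <- sort(stats::runif(k))
  extra <- floor(c(cuts, 1) * slack) - floor(c(0, cuts) * slack)
  starts <- integer(k)
  pos <- 1L
  ord <- sample.int(k)          # random order of elements along the genome
  for (i in seq_len(k)) {
    pos <- pos + gap + extra[i]
    starts[ord[i]] <- pos
    pos <- pos + lengths[ord[i]]
  }
  starts
}

#' Simulate a genome set with implanted conserved elements
#'
#' @param config a [sim_config()].
#' @return list with `genome_set` (a [genome_set()], reference = "sp01")
#'   and `truth` (data.frame: element_id, ref coordinates of the core,
#'   per-species realized coordinates, strand, substitution/indel counts,
#'   realized identity, is_repeat flag).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  Y <- config$n_species
  ids <- sprintf("sp%02d", seq_len(Y))
  ref <- ids[1L]
  fl <- config$flank_length
  n <- config$genome_length
  len_range <- seq(config$element_length[1L], config$element_length[2L])
  lens <- if (config$n_elements == 0L) integer() else
    if (length(len_range) == 1L) rep(len_range, config$n_elements) else
      sample(len_range, config$n_elements, replace = TRUE)
  repeat_species <- config$repeat_species %||%
    (if (Y >= 2L) ids[2L] else ref)
  if (config$n_repeat_copies > 0L && config$n_elements > 0L)
    lens[1L] <- min(lens[1L], 200L)   # keep the high-copy element compact
  # reference: pure background; element cores are reference segments
  refseq <- random_background(n, config$background_gc)
  core_starts <- if (config$n_elements > 0L)
    place_segments(n, lens, gap = 2L * fl + 60L) else integer()
  elements <- data.frame(
    element_id = sprintf("elem%03d", seq_len(config$n_elements)),
    ref_start = core_starts - 1L,               # 0-based
    ref_end = core_starts - 1L + lens,
    length = lens,
    is_repeat = seq_len(config$n_elements) == 1L &
      config$n_repeat_copies > 0L)
  rates <- config$substitution_rate
  if (length(rates) == 1L) rates <- rep(rates, Y - 1L)
  seqs <- list()
  seqs[[ref]] <- c(chr1 = refseq)
  truth_rows <- list()
  for (el in seq_len(nrow(elements)))
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      element_id = elements$element_id[el], species = ref,
      seq_name = "chr1", start = elements$ref_start[el],
      end = elements$ref_end[el], strand = "+", n_sub = 0L, n_indel = 0L,
      identity = 1)
  for (si in seq_len(Y - 1L)) {
    sp <- ids[si + 1L]
    rate <- rates[si]
    n_extra <- if (sp == repeat_species) config$n_repeat_copies else 0L
    # repeat copies carry the full element context (core + flanks + margin)
    # so that, like a real repeat family, every called window over the
    # element lies inside every copy
    rep_margin <- 50L
    rep_lo <- if (n_extra > 0L)
      max(1L, elements$ref_start[1L] + 1L - fl - rep_margin) else 1L
    rep_hi <- if (n_extra > 0L)
      min(n, elements$ref_end[1L] + fl + rep_margin) else 1L
    seg_lens <- c(lens + 2L * fl, rep(rep_hi - rep_lo + 1L, n_extra))
    if (length(seg_lens) == 0L) {
      seqs[[sp]] <- c(chr1 = random_background(n, config$background_gc))
      next
    }
    bg_n <- max(n, sum(seg_lens) + 60L * (length(seg_lens) + 1L))
    bg <- random_background(bg_n, config$background_gc)
    starts <- place_segments(bg_n, seg_lens, gap = 60L)
    chars <- strsplit(bg, "", fixed = TRUE)[[1L]]
    for (el in seq_len(nrow(elements))) {
      src_lo <- max(1L, elements$ref_start[el] + 1L - fl)
      src_hi <- min(n, elements$ref_end[el] + fl)
      seg <- substr(refseq, src_lo, src_hi)
      core_off <- elements$ref_start[el] + 1L - src_lo   # bases before core
      core_len <- elements$length[el]
      left <- substr(seg, 1L, core_off)
      core <- substr(seg, core_off + 1L, core_off + core_len)
      right <- substr(seg, core_off + core_len + 1L, nchar(seg))
      lsub <- substitute_bases(left, config$flank_substitution_rate)
      csub <- substitute_bases(core, rate)
      rsub <- substitute_bases(right, config$flank_substitution_rate)
      mut <- paste0(lsub$seq, csub$seq, rsub$seq)
      core_start_in_seg <- nchar(lsub$seq)
      core_end_in_seg <- core_start_in_seg + nchar(csub$seq)
      n_ind <- 0L
      if (config$indel_rate > 0) {
        ind <- apply_indels(mut, config$indel_rate, config$indel_max)
        mut <- ind$seq
        n_ind <- ind$n_indel
        # realized core bounds after indels are approximate; record the
        # whole segment in that case
        core_start_in_seg <- 0L
        core_end_in_seg <- nchar(mut)
      }
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        mut_ins <- revcomp(mut)
        cs <- nchar(mut) - core_end_in_seg
        ce <- nchar(mut) - core_start_in_seg
      } else {
        mut_ins <- mut
        cs <- core_start_in_seg
        ce <- core_end_in_seg
      }
      at <- starts[el]
      chars[at:(at + nchar(mut_ins) - 1L)] <-
        strsplit(mut_ins, "", fixed = TRUE)[[1L]]
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        element_id = elements$element_id[el], species = sp,
        seq_name = "chr1", start = at - 1L + cs, end = at - 1L + ce,
        strand = strand, n_sub = csub$n_sub, n_indel = n_ind,
        identity = 1 - csub$n_sub / core_len)
    }
    if (n_extra > 0L) {
      unit <- substr(refseq, rep_lo, rep_hi)
      for (ci in seq_len(n_extra)) {
        at <- starts[nrow(elements) + ci]
        copy <- substitute_bases(unit, config$repeat_divergence)$seq
        chars[at:(at + nchar(copy) - 1L)] <-
          strsplit(copy, "", fixed = TRUE)[[1L]]
      }
    }
    seqs[[sp]] <- c(chr1 = paste(chars, collapse = ""))
  }
  gs <- genome_set(seqs, reference_id = ref, normalize = FALSE)
  truth <- do.call(rbind, truth_rows)
  list(genome_set = gs, truth = truth,
       elements = elements, config = config)
}

#' Write a simulated fixture to disk
#'
#' Per-species FASTA files, the truth BED (reference core coordinates) and
#' a truth TSV with per-species realized coordinates and divergence.
#'
#' @param sim result of [simulate_genomes()].
#' @param out_dir output directory (created if needed).
#' @param deterministic drop the timestamp from provenance headers.
#' @export
write_fixture <- function(sim, out_dir, deterministic = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- sim$genome_set
  for (sp in gs$species_ids)
    write_fasta(gs$sequences[[sp]], file.path(out_dir, paste0(sp, ".fa")))
  hdr <- provenance_header("simulate",
                           list(seed = sim$config$seed,
                                n_species = sim$config$n_species),
                           deterministic)
  ref_truth <- sim$truth[sim$truth$species == gs$reference_id, ]
  write_bed(data.frame(seq_name = ref_truth$seq_name,
                       start = ref_truth$start, end = ref_truth$end,
                       name = ref_truth$element_id, score = 1000L,
                       strand = "+"),
            file.path(out_dir, "truth.bed"), header = hdr)
  write_tsv_report(sim$truth, file.path(out_dir, "truth.tsv"), header = hdr)
  invisible(out_dir)
}
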