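#' @useDynLib ucetools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

#' Normalize a nucleotide sequence
#'
#' Folds lowercase to uppercase and any character other than A, C, G, T to N
#' (ambiguity codes carry no usable identity information for conservation
#' scoring, and assembly gaps must never count as matches).
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' Reverse complement
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", intToUtf8(rev(utf8ToInt(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a genome set
#'
#' A genome set is an ordered collection of named genomes (one per species),
#' each a named list of uppercase A/C/G/T/N sequences, with one species
#' designated as the reference onto which UCE coordinates are reported.
#'
#' @param sequences named list; one element per species, each a named
#'   character vector of sequences (names are sequence names, e.g. "chr1").
#' @param reference_id name of the reference species; must be one of
#'   `names(sequences)`.
#' @param normalize fold case and non-ACGT codes (default TRUE). Set FALSE
#'   only when sequences are already normalized.
#' @return an object of class `genome_set` with fields `species_ids`,
#'   `sequences` and `reference_id`.
#' @export
genome_set <- function(sequences, reference_id, normalize = TRUE) {
  if (!is.list(sequences) || is.null(names(sequences)) ||
      any(names(sequences) == ""))
    stop("'sequences' must be a named list (one element per species)")
  ids <- names(sequences)
  if (anyDuplicated(ids))
    stop("duplicate species ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!reference_id %in% ids)
    stop("reference_id '", reference_id, "' is not among the species ids")
  sequences <- lapply(sequences, function(ss) {
    if (is.null(names(ss)) || any(names(ss) == ""))
      stop("every sequence must be named")
    if (anyDuplicated(names(ss)))
      stop("duplicate sequence names within a genome")
    if (normalize) ss[] <- normalize_sequence(ss)
    ss
  })
  structure(
    list(species_ids = ids, sequences = sequences,
         reference_id = reference_id),
    class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  sizes <- vapply(x$sequences, function(ss) sum(nchar(ss)), numeric(1))
  cat("genome_set:", length(x$species_ids), "species, reference =",
      x$reference_id, "\n")
  for (id in x$species_ids)
    cat(sprintf("  %s%s: %d sequence(s), %s bp\n", id,
                if (id == x$reference_id) " [ref]" else "",
                length(x$sequences[[id]]),
                format(sizes[[id]], big.mark = ",")))
  invisible(x)
}

#' @export
length.genome_set <- function(x) length(x$species_ids)

ref_sequences <- function(gs) gs$sequences[[gs$reference_id]]

# Map an N to a character that never equals anything in the other sequence
# of a comparison (N must not match N). Reference side keeps "N", the
# non-reference side gets "n", so raw byte comparison treats every N as a
# mismatch while ACGT compare normally.
mask_n_other <- function(x) chartr("N", "n", x)
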