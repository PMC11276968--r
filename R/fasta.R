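#' Read a (multi-)FASTA file
#'
#' Sequence names are taken up to the first whitespace in the header line.
#' Sequences are normalized (uppercase; non-ACGT folded to N). The parser is
#' deliberately strict so that malformed inputs fail with the offending line
#' number rather than propagating silently.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    stop("FASTA format error in '", path, "': file is empty")
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop("FASTA format error in '", path, "': file is empty")
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("FASTA format error in '", path, "' at line ", nonblank[1],
         ": expected '>' header")
  hdr <- which(startsWith(lines, ">"))
  names_full <- sub("^>\\s*", "", lines[hdr])
  seq_names <- sub("\\s.*$", "", names_full)
  if (any(seq_names == ""))
    stop("FASTA format error in '", path, "' at line ",
         hdr[which(seq_names == "")[1]], ": empty sequence name")
  if (anyDuplicated(seq_names)) {
    dup <- seq_names[duplicated(seq_names)][1]
    stop("FASTA format error in '", path, "' at line ",
         hdr[which(seq_names == dup)[2]], ": duplicate sequence name '",
         dup, "'")
  }
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return("")
    paste0(trimws(lines[starts[i]:ends[i]]), collapse = "")
  }, character(1))
  empty <- which(out == "")
  if (length(empty))
    stop("FASTA format error in '", path, "' at line ", hdr[empty[1]],
         ": record '", seq_names[empty[1]], "' has no sequence")
  names(out) <- seq_names
  normalize_sequence(out)
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    n <- nchar(s)
    if (n == 0L) stop("empty sequence: ", names(sequences)[i])
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a directory of genomes into a genome set
#'
#' Each `.fa`/`.fasta` file becomes one species, named after the file
#' (extension stripped).
#'
#' @param dir directory containing one FASTA per species.
#' @param reference_id species name of the reference.
#' @return a [genome_set()].
#' @export
read_genome_dir <- function(dir, reference_id) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files found in ", dir)
  seqs <- lapply(files, read_fasta)
  names(seqs) <- tools::file_path_sans_ext(basename(files))
  genome_set(seqs, reference_id = reference_id, normalize = FALSE)
}
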