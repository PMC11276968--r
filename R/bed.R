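# BED reading/writing. Output BED6 columns: seq_name, start, end, name,
# score (per-mille identity as an integer, 0..1000), strand. Comment lines
# beginning with '#' carry provenance and are skipped on read.

#' Write intervals as BED
#'
#' @param x data.frame with seq_name/start/end and optionally name, score,
#'   strand.
#' @param path output file.
#' @param header character vector of comment lines to prepend (without the
#'   leading `#`).
#' @export
write_bed <- function(x, path, header = NULL) {
  dt <- as_interval_dt(x)
  cols <- list(
    seq_name = dt$seq_name,
    start = dt$start,
    end = dt$end)
  if (!is.null(dt$name) || !is.null(dt$score) || !is.null(dt$strand)) {
    cols$name <- if (is.null(dt$name)) "." else dt$name
    cols$score <- if (is.null(dt$score)) 0L else dt$score
    cols$strand <- if (is.null(dt$strand)) "+" else dt$strand
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  if (nrow(dt))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED3/BED6 file; `#` comment lines ignored.
#' @return data.frame with seq_name, start, end and, when present, name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(seq_name = character(), start = integer(),
                      end = integer()))
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t")
  nm <- c("seq_name", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, nm[seq_len(min(ncol(dt), 6L))])
  data.table::setDF(dt)
  dt
}

provenance_header <- function(command, params = list(), deterministic = FALSE) {
  ver <- tryCatch(as.character(utils::packageVersion("ucetools")),
                  error = function(e) "dev")
  h <- c(paste0("ucetools ", ver, " :: ", command),
         if (length(params))
           paste0("param ", names(params), " = ",
                  vapply(params, function(p) paste(format(p), collapse = ","),
                         character(1))))
  if (!deterministic)
    h <- c(h, paste0("date ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  h
}

#' Write a TSV report with a provenance header
#'
#' @param x data.frame.
#' @param path output file.
#' @param header comment lines (without `#`).
#' @export
write_tsv_report <- function(x, path, header = NULL) {
  con <- file(path, open = "wt")
  if (length(header)) writeLines(paste0("# ", header), con)
  close(con)
  suppressWarnings(data.table::fwrite(x, path, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  data.table::fread(text = lines, sep = "\t", header = TRUE,
                    data.table = FALSE)
}
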