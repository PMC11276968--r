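# Interval algebra on 0-based half-open (BED) coordinates. Every function
# takes and returns plain data.frames with at least seq_name/start/end, so
# results round-trip through BED files unchanged.

as_interval_dt <- function(x) {
  if (!is.data.frame(x)) stop("intervals must be a data.frame")
  need <- c("seq_name", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing interval columns: ",
                         paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(x)
  if (nrow(dt)) {
    if (any(dt$start < 0)) stop("interval start must be >= 0")
    if (any(dt$end <= dt$start)) stop("interval end must be > start")
  }
  dt
}

#' Merge overlapping and book-ended intervals
#'
#' Union of intervals per sequence, in the half-open BED convention.
#' Book-ended intervals (end of one equals start of the next) are merged,
#' matching `bedtools merge` with its default distance of 0.
#'
#' @param x data.frame with columns seq_name, start, end.
#' @return data.frame of disjoint, non-book-ended intervals sorted by
#'   (seq_name, start).
#' @export
merge_intervals <- function(x) {
  dt <- as_interval_dt(x)[, c("seq_name", "start", "end"), with = FALSE]
  if (nrow(dt) == 0L)
    return(data.frame(seq_name = character(), start = integer(),
                      end = integer()))
  data.table::setorder(dt, seq_name, start, end)
  dt[, run_end := cummax(end), by = seq_name]
  prev_end <- dt[, data.table::shift(run_end, fill = -1L), by = seq_name]$V1
  dt[, grp := cumsum(start > prev_end)]
  out <- dt[, .(seq_name = seq_name[1L], start = min(start),
                end = max(end)), by = grp][, grp := NULL]
  data.table::setorder(out, seq_name, start)
  data.table::setDF(out)
  out
}

#' Intersect two interval sets
#'
#' For each interval in `a`, reports every interval in `b` overlapping it by
#' at least one base (half-open overlap test: max(starts) < min(ends)),
#' matching `bedtools intersect` semantics.
#'
#' @param a,b data.frames with seq_name, start, end.
#' @return data.frame with one row per overlapping pair: `a_idx`, `b_idx`
#'   (row numbers into the inputs) and `overlap` (overlap length in bases).
#' @export
intersect_intervals <- function(a, b) {
  adt <- as_interval_dt(a)[, .(seq_name, start, end)]
  bdt <- as_interval_dt(b)[, .(seq_name, start, end)]
  empty <- data.frame(a_idx = integer(), b_idx = integer(),
                      overlap = integer())
  if (nrow(adt) == 0L || nrow(bdt) == 0L) return(empty)
  adt[, a_idx := .I]
  bdt[, b_idx := .I]
  # closed-coordinate view for foverlaps: [start, end-1]
  adt[, `:=`(s = start, e = end - 1L)]
  bdt[, `:=`(s = start, e = end - 1L)]
  data.table::setkey(bdt, seq_name, s, e)
  ov <- data.table::foverlaps(adt, bdt, by.x = c("seq_name", "s", "e"),
                              type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) return(empty)
  out <- ov[, .(a_idx, b_idx,
                overlap = pmin(end, i.end) - pmax(start, i.start))]
  data.table::setorder(out, a_idx, b_idx)
  data.table::setDF(out)
  out
}

# gap between two half-open intervals on the same sequence (0 if they
# overlap or are book-ended)
interval_gap <- function(qs, qe, fs, fe) {
  pmax(0L, pmax(qs, fs) - pmin(qe, fe))
}

#' Closest features to a query interval, with all ties
#'
#' Distance is the half-open gap (0 for overlapping or book-ended
#' intervals). All features at the minimal distance are returned, matching
#' `bedtools closest` run with tie reporting.
#'
#' @param query single-row data.frame (seq_name, start, end).
#' @param features data.frame of candidate features.
#' @return data.frame of the tied nearest features with a `distance`
#'   column; zero rows if no feature shares the query's seq_name.
#' @export
closest_features <- function(query, features) {
  qdt <- as_interval_dt(query)
  if (nrow(qdt) != 1L) stop("'query' must be a single interval")
  fdt <- as_interval_dt(features)
  fdt <- fdt[seq_name == qdt$seq_name]
  if (nrow(fdt) == 0L) {
    out <- features[0, , drop = FALSE]
    out$distance <- integer()
    return(out)
  }
  d <- interval_gap(qdt$start, qdt$end, fdt$start, fdt$end)
  keep <- which(d == min(d))
  out <- data.table::setDF(fdt[keep])
  out$distance <- d[keep]
  out
}

#' Total bases covered by a set of intervals
#'
#' @param x data.frame of intervals.
#' @return integer number of distinct covered bases.
#' @export
covered_bases <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0L) return(0L)
  sum(m$end - m$start)
}

# TRUE iff every base of `x` is covered by `cover` (both interval sets)
is_covered_by <- function(x, cover) {
  if (nrow(as_interval_dt(x)) == 0L) return(TRUE)
  both <- merge_intervals(rbind(
    as_interval_dt(x)[, .(seq_name, start, end)],
    as_interval_dt(cover)[, .(seq_name, start, end)]))
  covered_bases(both) == covered_bases(cover)
}
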