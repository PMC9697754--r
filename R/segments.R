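#' Residue segment sets
#'
#' A `SegmentSet` is a set of inclusive integer residue-number intervals,
#' stored normalized: sorted by start, pairwise non-overlapping (adjacent or
#' overlapping input intervals are merged). Residue numbering is 1-based
#' author numbering and intervals are inclusive, matching the "A34-L275"
#' style used to describe modeled capsid-protein segments.
#'
#' @param starts,ends integer vectors of equal length; `starts <= ends`.
#' @return An object of class `SegmentSet`: a data.frame with columns
#'   `start`, `end`.
#' @examples
#' segment_set(c(34, 332, 625), c(275, 609, 894))
#' @export
segment_set <- function(starts = integer(0), ends = integer(0)) {
  if (length(starts) != length(ends))
    stop_cp("starts and ends must have equal length")
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (anyNA(starts) || anyNA(ends)) stop_cp("segment endpoints must be integers")
  if (any(starts > ends)) stop_cp("segment start > end")
  df <- data.frame(start = starts, end = ends)
  df <- df[order(df$start, df$end), , drop = FALSE]
  # merge overlapping or adjacent intervals
  if (nrow(df) > 1) {
    out <- df[1, , drop = FALSE]
    for (i in 2:nrow(df)) {
      k <- nrow(out)
      if (df$start[i] <= out$end[k] + 1L) {
        out$end[k] <- max(out$end[k], df$end[i])
      } else {
        out <- rbind(out, df[i, ])
      }
    }
    df <- out
  }
  rownames(df) <- NULL
  structure(df, class = c("SegmentSet", "data.frame"))
}

#' Parse a residue-range specification string
#'
#' Parses comma-separated inclusive ranges such as `"34-275,332-609,625-894"`
#' (single residues may be written `"5"` or `"5-5"`) into a normalized
#' [segment_set()].
#'
#' @param spec character scalar.
#' @return A `SegmentSet`.
#' @examples
#' parse_segment_spec("34-275,332-609,625-894")
#' parse_segment_spec("10-20,15-30")  # merged to 10-30
#' @export
parse_segment_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  spec <- gsub("[[:space:]]", "", spec)
  if (spec == "") return(segment_set())
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  starts <- integer(0); ends <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1]]
    if (length(m) == 0) stop_cp("cannot parse segment '%s'", p)
    s <- suppressWarnings(as.integer(m[2]))
    e <- if (m[3] == "") s else suppressWarnings(as.integer(m[3]))
    if (is.na(s) || is.na(e)) stop_cp("non-integer endpoint in '%s'", p)
    if (s > e) stop_cp("segment start %d > end %d", s, e)
    starts <- c(starts, s); ends <- c(ends, e)
  }
  segment_set(starts, ends)
}

#' Render a SegmentSet back to its specification string
#' @param s a `SegmentSet`.
#' @return character scalar, e.g. `"34-275,332-609"`.
#' @export
render_segments <- function(s) {
  stopifnot(inherits(s, "SegmentSet"))
  if (nrow(s) == 0) return("")
  paste(sprintf("%d-%d", s$start, s$end), collapse = ",")
}

#' Subtract one segment set from another
#'
#' Interval set difference `a \ b`, e.g. removing unmodeled ranges from
#' modeled ones. Both inputs and the result are normalized.
#'
#' @param a,b `SegmentSet` objects.
#' @return A `SegmentSet` (possibly empty).
#' @examples
#' subtract_segments(parse_segment_spec("34-275"), parse_segment_spec("239-243"))
#' @export
subtract_segments <- function(a, b) {
  stopifnot(inherits(a, "SegmentSet"), inherits(b, "SegmentSet"))
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(a))) {
    pieces <- list(c(a$start[i], a$end[i]))
    for (j in seq_len(nrow(b))) {
      nxt <- list()
      for (p in pieces) {
        bs <- b$start[j]; be <- b$end[j]
        if (be < p[1] || bs > p[2]) { nxt <- c(nxt, list(p)); next }
        if (bs > p[1]) nxt <- c(nxt, list(c(p[1], bs - 1L)))
        if (be < p[2]) nxt <- c(nxt, list(c(be + 1L, p[2])))
      }
      pieces <- nxt
    }
    for (p in pieces) { starts <- c(starts, p[1]); ends <- c(ends, p[2]) }
  }
  segment_set(starts, ends)
}

#' Intersect two segment sets
#' @param a,b `SegmentSet` objects.
#' @return A `SegmentSet`.
#' @export
intersect_segments <- function(a, b) {
  subtract_segments(a, subtract_segments(a, b))
}

#' Total residue count of a segment set
#' @param s a `SegmentSet`.
#' @return integer.
#' @export
segment_count <- function(s) {
  stopifnot(inherits(s, "SegmentSet"))
  if (nrow(s) == 0) return(0L)
  sum(s$end - s$start + 1L)
}

#' Count modeled residues after removing unmodeled ranges
#'
#' Total residue count of `modeled \ unmodeled`. This is the accounting used
#' to report how many residues of a capsid polyprotein were built into a
#' density map: e.g. modeled ranges 34-275, 332-609, 625-894 minus the
#' invisible stretch 239-243 give 785 residues.
#'
#' @param modeled,unmodeled `SegmentSet` objects.
#' @return integer.
#' @examples
#' count_modeled_residues(parse_segment_spec("34-275,332-609,625-894"),
#'                        parse_segment_spec("239-243"))
#' @export
count_modeled_residues <- function(modeled, unmodeled) {
  segment_count(subtract_segments(modeled, unmodeled))
}

#' Membership of residue numbers in a segment set
#' @param s a `SegmentSet`.
#' @param x integer vector of residue numbers.
#' @return logical vector.
#' @export
in_segments <- function(s, x) {
  stopifnot(inherits(s, "SegmentSet"))
  res <- rep(FALSE, length(x))
  for (i in seq_len(nrow(s))) res <- res | (x >= s$start[i] & x <= s$end[i])
  res
}

#' @export
print.SegmentSet <- function(x, ...) {
  cat("SegmentSet:", if (nrow(x) == 0) "(empty)" else render_segments(x),
      sprintf(" [%d residues]\n", segment_count(x)))
  invisible(x)
}

#' Write a modeled-residue accounting table
#'
#' For each labeled pair of modeled/unmodeled specifications, reports the
#' modeled count, the unmodeled count (within the modeled ranges) and the
#' net modeled total, as a TSV.
#'
#' @param labels character vector.
#' @param modeled,unmodeled lists of `SegmentSet`, parallel to `labels`.
#' @param path optional output TSV path.
#' @return data.frame with columns label, modeled_count, unmodeled_count, net
#'   (invisibly if `path` given).
#' @export
account_modeled <- function(labels, modeled, unmodeled, path = NULL) {
  stopifnot(length(labels) == length(modeled),
            length(labels) == length(unmodeled))
  rows <- lapply(seq_along(labels), function(i) {
    gross <- segment_count(modeled[[i]])
    net <- count_modeled_residues(modeled[[i]], unmodeled[[i]])
    data.frame(label = labels[i], modeled_count = gross,
               unmodeled_count = gross - net, net = net)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
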