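#' Read amino-acid sequences from a FASTA file
#'
#' Reads via \pkg{seqinr}. Letters are uppercased, stop characters (`*`)
#' stripped; gap characters are rejected unless `aligned = TRUE` (use this
#' when reading a multiple sequence alignment). Duplicate labels and empty
#' files are errors.
#'
#' @param path FASTA file path.
#' @param aligned logical; allow `-` gap characters.
#' @return named list of sequence records, each a
#'   `list(label = , seq = )`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop_cp("file not found: %s", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE),
    error = function(e) stop_cp("cannot read FASTA '%s': %s", path,
                                conditionMessage(e)))
  if (length(recs) == 0) stop_cp("empty FASTA file: %s", path)
  labels <- names(recs)
  if (anyDuplicated(labels))
    stop_cp("duplicate FASTA labels: %s",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  out <- lapply(seq_along(recs), function(i) {
    s <- toupper(gsub("\\*", "", recs[[i]]))
    if (!aligned && grepl("-", s, fixed = TRUE))
      stop_cp("gap characters in unaligned record '%s'", labels[i])
    bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX-]", "", s)
    if (nzchar(bad))
      stop_cp("illegal characters '%s' in record '%s'", bad, labels[i])
    if (!nzchar(s)) stop_cp("empty sequence for record '%s'", labels[i])
    list(label = labels[i], seq = s)
  })
  names(out) <- labels
  out
}

#' Write sequence records to FASTA
#'
#' Lines wrapped at 60 columns; round-trips with [read_fasta()].
#'
#' @param records list of `list(label=, seq=)` records (or a named character
#'   vector of sequences).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    stopifnot(!is.null(names(records)))
    records <- lapply(names(records),
                      function(l) list(label = l, seq = unname(records[[l]])))
  }
  labels <- vapply(records, function(r) r$label, "")
  if (anyDuplicated(labels)) stop_cp("duplicate labels on write")
  seqinr::write.fasta(lapply(records, function(r) r$seq),
                      names = labels, file.out = path, nbchar = 60,
                      as.string = TRUE)
  invisible(path)
}

#' Named character vector view of FASTA records
#' @param records as returned by [read_fasta()].
#' @return named character vector.
#' @export
fasta_as_vector <- function(records) {
  setNames(vapply(records, function(r) r$seq, ""),
           vapply(records, function(r) r$label, ""))
}
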