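#' Read and write Newick trees
#'
#' Thin wrappers over \pkg{ape}'s Newick parser/serializer with the
#' package's validation: unique leaf labels are enforced, bootstrap
#' supports travel as internal-node labels, and branch lengths are
#' preserved to at least 9 significant digits on a round trip.
#'
#' @param text Newick string (or `path` to a file containing one).
#' @param path optional file path (used instead of `text`).
#' @return an \pkg{ape} `phylo` for the reader; a Newick string (invisibly
#'   written to `path` when given) for the writer.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  tr <- tryCatch(
    if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop_cp("Newick parse error: %s", conditionMessage(e)))
  if (is.null(tr)) stop_cp("Newick parse error: no tree found")
  if (anyDuplicated(tr$tip.label))
    stop_cp("duplicate leaf labels: %s",
            paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
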