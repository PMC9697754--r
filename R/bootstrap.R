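#' Bootstrap support for a neighbor-joining sequence tree
#'
#' Builds the full-data NJ tree from the alignment's p-distances, then
#' resamples alignment columns with replacement `n_reps` times, rebuilds
#' NJ on each replicate, and scores each internal bipartition of the
#' full-data tree by the percentage of replicates whose tree contains it.
#' Supports are attached as internal-node labels (the convention used when
#' serializing to Newick). Replicates in which some pair has no comparable
#' columns are skipped, counted, and reported via a warning and the
#' `n_skipped` attribute; supports are percentages of the completed
#' replicates.
#'
#' @param m an [msa()].
#' @param n_reps number of bootstrap replicates (>= 1; 1000 mirrors common
#'   practice, tests use 100).
#' @param seed integer RNG seed; fixed seed gives identical supports.
#' @param correction distance correction, as in [pdistance_matrix()].
#' @return the full-data `phylo` tree with `node.label` supports in
#'   \[0, 100\] (empty for the basal node); attributes `support_table`
#'   (split key -> percentage) and `n_skipped`.
#' @export
bootstrap_support <- function(m, n_reps = 1000L, seed = 1L,
                              correction = "none") {
  stopifnot(inherits(m, "Msa"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1) stop_cp("n_reps must be >= 1")
  full <- nj_build(pdistance_matrix(m, correction))
  keys <- tree_bipartitions(full)
  counts <- setNames(rep(0L, length(keys)), keys)
  ncol_aln <- ncol(m$mat)
  skipped <- 0L
  set.seed(as.integer(seed))
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rep_m <- structure(list(labels = m$labels,
                            mat = m$mat[, cols, drop = FALSE]), class = "Msa")
    dmat <- tryCatch(pdistance_matrix(rep_m, correction),
                     error = function(e) NULL)
    if (is.null(dmat)) { skipped <- skipped + 1L; next }
    bp <- tree_bipartitions(nj_build(dmat))
    hit <- keys %in% bp
    counts[hit] <- counts[hit] + 1L
  }
  done <- n_reps - skipped
  if (skipped > 0)
    warning(sprintf("%d of %d bootstrap replicates skipped (no comparable columns)",
                    skipped, n_reps), call. = FALSE)
  if (done == 0) stop_cp("all bootstrap replicates were degenerate")
  support <- 100 * counts / done

  # attach supports as internal-node labels
  ntip <- length(full$tip.label)
  labels <- rep("", full$Nnode)
  sets <- .edge_tipsets(full)
  for (e in seq_len(nrow(full$edge))) {
    child <- full$edge[e, 2]
    if (child <= ntip) next
    key <- .canon_split(sets[[e]], full$tip.label)
    if (key %in% names(support))
      labels[child - ntip] <- format(round(support[[key]], 1), trim = TRUE)
  }
  full$node.label <- labels
  attr(full, "support_table") <- support
  attr(full, "n_skipped") <- skipped
  full
}
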