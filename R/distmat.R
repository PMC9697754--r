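#' Labeled symmetric distance matrix
#'
#' Validates and classes a square symmetric distance matrix (zero diagonal,
#' non-negative entries, unique labels). Used both for structural RMSD
#' distances (Angstrom) and sequence distances (substitutions/site).
#'
#' @param d square numeric matrix with dimnames, or unnamed with `labels`.
#' @param labels optional label vector.
#' @return matrix of class `DistanceMatrix`.
#' @export
distance_matrix <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop_cp("distance matrix must be square")
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d))) stop_cp("distance matrix must be labeled")
  if (anyDuplicated(rownames(d))) stop_cp("duplicate labels")
  if (!isTRUE(all.equal(rownames(d), colnames(d))))
    stop_cp("row and column labels differ")
  if (max(abs(d - t(d))) >= 1e-9) stop_cp("matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_cp("diagonal must be zero")
  if (any(d < 0)) stop_cp("negative distances")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  class(d) <- c("DistanceMatrix", "matrix")
  d
}

#' All-vs-all structural RMSD distance matrix
#'
#' For every unordered pair of structures: optionally trim the N-terminal
#' arm, run [pair_align()], then [core_rmsd()] under `params$core_cutoff`.
#' The matrix entry is the core RMSD in Angstrom (computed once per pair,
#' i < j, so the result is symmetric by construction). RMSD distances are
#' used raw — note they need not satisfy the triangle inequality.
#'
#' @param structures list of >= 3 `CaStructure`s with unique labels.
#' @param params an [align_params()].
#' @param trim_boundaries optional named vector/list: label -> N-terminal
#'   boundary passed to [trim_nterm_arm()].
#' @return `DistanceMatrix` (and attribute `n_core`, the matching matrix of
#'   core sizes).
#' @export
all_vs_all_matrix <- function(structures, params = align_params(),
                              trim_boundaries = NULL) {
  if (length(structures) < 3) stop_cp("need at least 3 structures")
  labels <- vapply(structures, function(s) s$label, "")
  if (anyDuplicated(labels)) stop_cp("duplicate structure labels")
  if (!is.null(trim_boundaries)) {
    structures <- lapply(structures, function(s) {
      bnd <- trim_boundaries[[s$label]]
      if (is.null(bnd) || is.na(bnd)) s else trim_nterm_arm(s, bnd)
    })
  }
  n <- length(structures)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  ncore <- matrix(NA_integer_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      res <- tryCatch({
        al <- pair_align(structures[[i]], structures[[j]], params)
        core_rmsd(structures[[i]], structures[[j]], al$correspondence,
                  params$core_cutoff)
      }, error = function(e)
        stop_cp("alignment failed for pair (%s, %s): %s",
                labels[i], labels[j], conditionMessage(e)))
      d[i, j] <- d[j, i] <- res$rmsd
      ncore[i, j] <- ncore[j, i] <- res$n_core
    }
  }
  out <- distance_matrix(d)
  attr(out, "n_core") <- ncore
  out
}

#' Read/write PHYLIP square distance matrices
#'
#' Standard relaxed PHYLIP format: first line the taxon count, then one row
#' per taxon (`label` followed by the full row of distances, whitespace
#' separated).
#'
#' @param path file path.
#' @return `DistanceMatrix` for the reader; `path` (invisibly) for the
#'   writer.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) != n + 1)
    stop_cp("malformed PHYLIP matrix in %s", path)
  labels <- character(n)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 1]), "[[:space:]]+")[[1]]
    if (length(toks) != n + 1) stop_cp("row %d has %d fields, expected %d",
                                       i, length(toks), n + 1)
    labels[i] <- toks[1]
    d[i, ] <- as.numeric(toks[-1])
  }
  distance_matrix(d, labels)
}

#' @rdname read_phylip_dist
#' @param m a `DistanceMatrix`.
#' @export
write_phylip_dist <- function(m, path) {
  stopifnot(inherits(m, "DistanceMatrix"))
  n <- nrow(m)
  rows <- vapply(seq_len(n), function(i) {
    paste(c(sprintf("%-10s", rownames(m)[i]),
            sprintf("%.9g", m[i, ])), collapse = " ")
  }, "")
  writeLines(c(sprintf("%5d", n), rows), path)
  invisible(path)
}
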