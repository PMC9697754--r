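# descendant tip-label sets for every edge of a phylo tree (child side)
.edge_tipsets <- function(tr) {
  n <- length(tr$tip.label)
  m <- n + tr$Nnode
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  below <- vector("list", m)
  for (i in seq_len(n)) below[[i]] <- tr$tip.label[i]
  # postorder: process internal nodes children-first
  po <- rev(unique(tr$edge[order(tr$edge[, 1]), 1]))
  # simple fixed-point accumulation (trees are small here)
  repeat {
    done <- TRUE
    for (v in po) {
      if (!is.null(below[[v]])) next
      ch <- kids[[as.character(v)]]
      if (all(!vapply(below[ch], is.null, TRUE))) {
        below[[v]] <- unlist(below[ch])
      } else done <- FALSE
    }
    if (done) break
  }
  lapply(seq_len(nrow(tr$edge)), function(e) below[[tr$edge[e, 2]]])
}

# canonical string for one side of a bipartition: take the side containing
# the alphabetically-first leaf, sort, join
.canon_split <- function(side, all_tips) {
  first <- min(all_tips)
  if (!(first %in% side)) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "\r")
}

#' Internal bipartitions of an unrooted tree
#'
#' Canonicalized non-trivial splits (both sides of size >= 2), treating the
#' tree as unrooted. Used for Robinson-Foulds distances, bootstrap support
#' and monophyly tests.
#'
#' @param tr a `phylo`.
#' @return character vector of canonical split keys (unique).
#' @export
tree_bipartitions <- function(tr) {
  tips <- tr$tip.label
  n <- length(tips)
  sets <- .edge_tipsets(tr)
  keep <- vapply(sets, function(s) length(s) >= 2 && length(s) <= n - 2, TRUE)
  unique(vapply(sets[keep], .canon_split, "", all_tips = tips))
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' The number of internal bipartitions present in exactly one of the two
#' trees (identical leaf sets required). Zero iff the unrooted topologies
#' agree; at most `2(n-3)` for binary trees on n leaves.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label))
    stop_cp("trees have different leaf sets")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Host-taxon monophyly report for an annotated tree
#'
#' For each host taxon in the map, reports whether its leaves form a clade
#' of the unrooted tree (one bipartition side exactly equals the host's
#' leaf set; singleton and all-leaf hosts are trivially monophyletic), and
#' a best-clade purity: the maximum, over bipartition sides containing all
#' of the host's leaves, of (host leaves / side size). Purity is 1 exactly
#' when the host is monophyletic; a stray leaf of another host inside the
#' smallest enclosing clade drives it below 1.
#'
#' @param tree a `phylo`.
#' @param hosts named character vector or data.frame (columns `label`,
#'   `host`) mapping every leaf to a host taxon.
#' @return data.frame with columns `host`, `n_leaves`, `monophyletic`,
#'   `purity`.
#' @export
host_monophyly <- function(tree, hosts) {
  if (is.data.frame(hosts)) hosts <- setNames(hosts$host, hosts$label)
  tips <- tree$tip.label
  unknown <- setdiff(names(hosts), tips)
  if (length(unknown))
    stop_cp("host map has unknown leaves: %s", paste(unknown, collapse = ", "))
  missing <- setdiff(tips, names(hosts))
  if (length(missing))
    stop_cp("leaves missing from host map: %s", paste(missing, collapse = ", "))
  n <- length(tips)
  sets <- .edge_tipsets(tree)
  # all bipartition sides (both sides of every edge), plus the full leaf set
  sides <- c(sets, lapply(sets, function(s) setdiff(tips, s)), list(tips))
  sides <- sides[vapply(sides, length, 1L) >= 1]
  rows <- lapply(sort(unique(unname(hosts))), function(h) {
    L <- names(hosts)[hosts == h]
    mono <- length(L) == 1 || length(L) == n ||
      any(vapply(sides, function(s) setequal(s, L), TRUE))
    containing <- sides[vapply(sides, function(s) all(L %in% s), TRUE)]
    purity <- max(vapply(containing, function(s) length(L) / length(s), 1.0))
    data.frame(host = h, n_leaves = length(L), monophyletic = mono,
               purity = purity)
  })
  do.call(rbind, rows)
}

#' Read/write TSV host maps
#' @param path TSV with columns `label`, `host`.
#' @return named character vector (label -> host).
#' @export
read_host_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("label", "host") %in% names(df)))
    stop_cp("host map needs columns 'label' and 'host'")
  setNames(df$host, df$label)
}

#' @rdname read_host_map
#' @param hosts named character vector.
#' @export
write_host_map <- function(hosts, path) {
  write.table(data.frame(label = names(hosts), host = unname(hosts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
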