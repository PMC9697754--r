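#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration implemented in full: at each step the pair
#' minimizing `Q_ij = (n-2) d_ij - sum_k d_ik - sum_k d_jk` is joined;
#' branch lengths follow the rate-corrected split formula
#' `l_i = d_ij/2 + (r_i - r_j)/(2(n-2))` and distances to the new node the
#' reduction formula `d(u,k) = (d_ik + d_jk - d_ij)/2`. Ties on Q are broken
#' deterministically by joining the pair earliest in label-sorted order
#' (internal nodes are ordered by the smallest leaf label of their subtree).
#' Negative branch lengths are clamped to zero with the deficit moved to the
#' sibling branch. The result is the standard unrooted NJ tree with a
#' trifurcating base, returned as an \pkg{ape} `phylo` object.
#'
#' On an additive (tree-metric) input, the generating topology and all
#' branch lengths are recovered exactly.
#'
#' @param m a [distance_matrix()] (or plain labeled symmetric matrix).
#' @param method `"nj"` (default) or `"upgma"` (average-linkage sensitivity
#'   alternative).
#' @return an \pkg{ape} `phylo` tree.
#' @examples
#' m <- distance_matrix(matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
#'                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
#' nj_build(m)  # branch lengths 0.5, 1.5, 2.5
#' @export
nj_build <- function(m, method = c("nj", "upgma")) {
  method <- match.arg(method)
  if (!inherits(m, "DistanceMatrix")) m <- distance_matrix(m)
  n <- nrow(m)
  if (n < 3) stop_cp("need at least 3 taxa")
  if (method == "upgma") {
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    tr <- ape::as.phylo(hc)
    tr$edge.length <- pmax(tr$edge.length, 0)
    return(tr)
  }

  labels <- rownames(m)
  D <- unclass(m); attributes(D) <- list(dim = dim(m))
  # node bookkeeping: ids 1..n are tips; internal ids appended
  active <- seq_len(n)            # node ids of current cluster roots
  rep_lab <- labels               # representative (smallest) leaf label
  edges <- matrix(numeric(0), 0, 3)   # parent id, child id, length
  next_id <- n + 1L

  while (length(active) > 3) {
    k <- length(active)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break: earliest pair in label-sorted order
    key <- apply(cand, 1, function(ij) {
      ls <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(ls, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    # clamp negatives, deficit to sibling
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    v <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges, c(v, active[i], li), c(v, active[j], lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dnew <- pmax(dnew[-c(i, j)], 0)
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    new_rep <- min(rep_lab[i], rep_lab[j])
    rep_lab <- c(rep_lab[-c(i, j)], new_rep)
    active <- c(active[-c(i, j)], v)
  }

  # final trifurcation via the three-point formulas
  dd <- D
  l1 <- (dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2
  l2 <- (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2
  l3 <- (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2
  v <- next_id
  edges <- rbind(edges,
                 c(v, active[1], max(l1, 0)),
                 c(v, active[2], max(l2, 0)),
                 c(v, active[3], max(l3, 0)))

  .edges_to_phylo(edges, labels, root_id = v)
}

# convert a (parent id, child id, length) edge list over ids 1..n (tips,
# labeled) plus internal ids into an ape phylo rooted at root_id
.edges_to_phylo <- function(edges, tip_labels, root_id) {
  n <- length(tip_labels)
  children <- split(seq_len(nrow(edges)), edges[, 1])
  n_internal <- length(unique(edges[, 1]))
  newnum <- integer(max(edges[, 1:2]))
  newnum[seq_len(n)] <- seq_len(n)
  # preorder internal numbering from the root
  counter <- n
  stack <- root_id
  order_edges <- integer(0)
  while (length(stack)) {
    node <- stack[length(stack)]; stack <- stack[-length(stack)]
    counter <- counter + 1L
    newnum[node] <- counter
    ce <- children[[as.character(node)]]
    order_edges <- c(order_edges, ce)
    kids <- edges[ce, 2]
    stack <- c(stack, rev(kids[kids > n]))
  }
  em <- cbind(newnum[edges[order_edges, 1]], newnum[edges[order_edges, 2]])
  tr <- list(edge = em, edge.length = edges[order_edges, 3],
             tip.label = tip_labels, Nnode = n_internal)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}
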