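#' Residue correspondence between two structures
#'
#' An ordered, crossing-free set of matched residue indices (row numbers
#' into each structure's residue table). Both index columns are strictly
#' increasing and repeat-free.
#'
#' @param ai,bi integer indices into structures a and b.
#' @param label_a,label_b source structure labels.
#' @return object of class `Correspondence` (data.frame with columns `ai`,
#'   `bi`; attributes `label_a`, `label_b`).
#' @export
correspondence <- function(ai, bi, label_a = "a", label_b = "b") {
  ai <- as.integer(ai); bi <- as.integer(bi)
  if (length(ai) != length(bi)) stop_cp("index columns differ in length")
  if (length(ai) > 1) {
    if (any(diff(ai) <= 0) || any(diff(bi) <= 0))
      stop_cp("correspondence indices must be strictly increasing")
  }
  structure(data.frame(ai = ai, bi = bi),
            class = c("Correspondence", "data.frame"),
            label_a = label_a, label_b = label_b)
}

#' @export
print.Correspondence <- function(x, ...) {
  cat(sprintf("Correspondence %s ~ %s: %d matched residues\n",
              attr(x, "label_a"), attr(x, "label_b"), nrow(x)))
  invisible(x)
}

# squared-distance matrix between rows of two n x 3 matrices
.sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# TM-style per-pair score matrix after applying sup to b's coordinates
.tm_score_matrix <- function(ca, cb, sup, d0) {
  bt <- apply_superposition(sup, cb)
  1 / (1 + .sqdist(ca, bt) / d0^2)
}

# Needleman-Wunsch global alignment of two aa strings (BLOSUM62, affine
# gaps -11/-1), returning matched position pairs.
.seq_seed <- function(aa_a, aa_b) {
  B62 <- blosum62()
  a <- strsplit(aa_a, "")[[1]]; b <- strsplit(aa_b, "")[[1]]
  a[!a %in% rownames(B62)] <- "X"; b[!b %in% rownames(B62)] <- "X"
  S <- B62[a, b, drop = FALSE]
  storage.mode(S) <- "double"
  .gotoh_align(S, -11, -1, FALSE)
}

# best gapless-threading seed: try every offset with >= minov overlap,
# superpose on the threaded pairs, keep the offset maximizing the summed
# TM-style score
.threading_seed <- function(ca, cb, d0, minov = 10L) {
  na <- nrow(ca); nb <- nrow(cb)
  best <- NULL; best_score <- -Inf
  for (off in seq(-(nb - minov), na - minov)) {
    i0 <- max(1L, 1L + off); i1 <- min(na, nb + off)
    if (i1 - i0 + 1L < minov) next
    ai <- i0:i1; bi <- ai - off
    sup <- kabsch_superpose(ca[ai, , drop = FALSE], cb[bi, , drop = FALSE])
    d2 <- rowSums((ca[ai, , drop = FALSE] -
                   apply_superposition(sup, cb[bi, , drop = FALSE]))^2)
    sc <- sum(1 / (1 + d2 / d0^2))
    if (sc > best_score) { best_score <- sc; best <- cbind(ai, bi) }
  }
  best
}

.refine_from_seed <- function(pairs, ca, cb, params) {
  best <- NULL
  seen_score <- -Inf
  for (iter in seq_len(params$max_iter)) {
    if (is.null(pairs) || nrow(pairs) < 3) break
    sup <- kabsch_superpose(ca[pairs[, 1], , drop = FALSE],
                            cb[pairs[, 2], , drop = FALSE])
    S <- .tm_score_matrix(ca, cb, sup, params$d0)
    score <- sum(S[pairs])
    if (score > seen_score) {
      seen_score <- score
      best <- list(pairs = pairs, sup = sup, score = score)
    }
    new_pairs <- .gotoh_align(S, params$gap_open, params$gap_extend, TRUE)
    if (nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)) break
    pairs <- new_pairs
  }
  best
}

#' Structure-based pairwise alignment
#'
#' Iterative superposition/re-alignment in the TM-align style: the residue
#' correspondence is seeded from (i) a global Needleman-Wunsch alignment of
#' the amino-acid sequences (BLOSUM62, affine gaps) and (ii) the best
#' gapless threading of one chain along the other; each seed is refined by
#' alternating Kabsch superposition on the current pairs with an affine-gap
#' dynamic program on the score matrix `S(i,j) = 1 / (1 + (d_ij/d0)^2)`,
#' until the pair set is stationary or `max_iter` is reached. The
#' best-scoring correspondence across seeds and iterations is returned.
#'
#' @param a,b `CaStructure` objects with at least 10 residues each.
#' @param params an [align_params()] object.
#' @return list with `correspondence` (a [correspondence()]),
#'   `superposition` (Kabsch fit on the returned pairs), and `score`
#'   (summed TM-style score).
#' @export
pair_align <- function(a, b, params = align_params()) {
  stopifnot(inherits(a, "CaStructure"), inherits(b, "CaStructure"))
  if (length(a) < 10 || length(b) < 10)
    stop_cp("pair_align needs structures of >= 10 residues")
  ca <- ca_coords(a); cb <- ca_coords(b)

  seeds <- list()
  sq <- .seq_seed(ca_sequence(a), ca_sequence(b))
  if (nrow(sq) >= 3) seeds <- c(seeds, list(sq))
  th <- .threading_seed(ca, cb, params$d0)
  if (!is.null(th)) seeds <- c(seeds, list(th))

  best <- NULL
  for (s in seeds) {
    r <- .refine_from_seed(s, ca, cb, params)
    if (!is.null(r) && (is.null(best) || r$score > best$score)) best <- r
  }
  if (is.null(best) || nrow(best$pairs) < 5)
    stop_cp("alignment failure: no correspondence of >= 5 pairs between '%s' and '%s'",
            a$label, b$label)
  sup <- kabsch_superpose(ca[best$pairs[, 1], , drop = FALSE],
                          cb[best$pairs[, 2], , drop = FALSE])
  list(correspondence = correspondence(best$pairs[, 1], best$pairs[, 2],
                                       a$label, b$label),
       superposition = sup, score = best$score)
}

#' Core RMSD with iterative outlier trimming
#'
#' Starting from a residue correspondence, repeatedly superposes on the
#' current core and drops pairs deviating by more than `core_cutoff`, to a
#' fixed point. This mimics the "core Calpha" counting of structural
#' comparison tools, where the reported RMSD covers a well-superposing
#' subset rather than every aligned residue. `core_cutoff = Inf` reproduces
#' the plain all-pair Kabsch RMSD.
#'
#' @param a,b `CaStructure` objects.
#' @param corr a [correspondence()] between them.
#' @param core_cutoff deviation cutoff, Angstrom.
#' @return list with `rmsd`, `n_core`, `superposition` (fit on the final
#'   core), `core` (logical vector over the input pairs).
#' @export
core_rmsd <- function(a, b, corr, core_cutoff = 4.0) {
  stopifnot(inherits(corr, "Correspondence"))
  if (nrow(corr) == 0) stop_cp("empty correspondence")
  ca <- ca_coords(a)[corr$ai, , drop = FALSE]
  cb <- ca_coords(b)[corr$bi, , drop = FALSE]
  keep <- rep(TRUE, nrow(corr))
  repeat {
    if (sum(keep) < 5)
      stop_cp("degenerate core: fewer than 5 pairs within %.2f A", core_cutoff)
    sup <- kabsch_superpose(ca[keep, , drop = FALSE], cb[keep, , drop = FALSE])
    dev <- sqrt(rowSums((ca - apply_superposition(sup, cb))^2))
    new_keep <- keep & (dev <= core_cutoff)
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  list(rmsd = sup$rmsd, n_core = sum(keep), superposition = sup, core = keep)
}
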