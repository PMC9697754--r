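#' Multiple sequence alignment container
#'
#' Equal-length gapped amino-acid sequences with unique labels.
#'
#' @param seqs named character vector of gapped sequences (alphabet: the 20
#'   amino acids, X, and `-`).
#' @return object of class `Msa`: list with `labels` and `mat` (character
#'   matrix, one row per sequence).
#' @export
msa <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop_cp("duplicate MSA labels")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop_cp("aligned rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  bad <- setdiff(unique(as.vector(mat)), c(rownames(blosum62()), "-"))
  if (length(bad)) stop_cp("illegal alignment characters: %s",
                           paste(bad, collapse = ""))
  structure(list(labels = names(seqs), mat = mat), class = "Msa")
}

#' @export
print.Msa <- function(x, ...) {
  cat(sprintf("Msa: %d sequences x %d columns\n", nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Gapped row strings of an Msa
#' @param x an `Msa`.
#' @return named character vector.
#' @export
msa_strings <- function(x) {
  stopifnot(inherits(x, "Msa"))
  setNames(apply(x$mat, 1, paste, collapse = ""), x$labels)
}

# fractional common-k-mer distance between two sequences
.kmer_dist <- function(s1, s2, k = 3L) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(table(s))
    table(substring(s, 1:(n - k + 1), k:n))
  }
  t1 <- km(s1); t2 <- km(s2)
  shared <- intersect(names(t1), names(t2))
  common <- sum(pmin(t1[shared], t2[shared]))
  denom <- min(nchar(s1), nchar(s2)) - k + 1
  if (denom < 1) denom <- 1
  max(0, 1 - common / denom)
}

# 22-char scoring matrix: BLOSUM62 extended with a zero-scoring gap char
.b62_gapped <- function() {
  B <- blosum62()
  B <- rbind(cbind(B, `-` = 0L), `-` = 0L)
  colnames(B)[22] <- "-"
  storage.mode(B) <- "double"
  B
}

# column frequency profile of an alignment block (22 x ncol)
.profile_of <- function(mat, alphabet) {
  P <- matrix(0, length(alphabet), ncol(mat), dimnames = list(alphabet, NULL))
  for (i in seq_len(nrow(mat))) {
    idx <- match(mat[i, ], alphabet)
    P[cbind(idx, seq_len(ncol(mat)))] <- P[cbind(idx, seq_len(ncol(mat)))] + 1
  }
  P / nrow(mat)
}

# merge two alignment blocks with profile-profile affine-gap DP
.merge_blocks <- function(m1, m2, gap_open, gap_extend, B) {
  alphabet <- rownames(B)
  P1 <- .profile_of(m1, alphabet)
  P2 <- .profile_of(m2, alphabet)
  S <- crossprod(P1, B %*% P2)          # ncol1 x ncol2 expected scores
  pairs <- .gotoh_align(S, gap_open, gap_extend, FALSE)
  n1 <- ncol(m1); n2 <- ncol(m2)
  # rebuild the merged column order from the matched pairs
  cols1 <- integer(0); cols2 <- integer(0)   # 0 = gap column
  i <- 1L; j <- 1L
  emit <- function(a, b) { cols1 <<- c(cols1, a); cols2 <<- c(cols2, b) }
  if (nrow(pairs) == 0) pairs <- matrix(integer(0), 0, 2)
  for (r in seq_len(nrow(pairs))) {
    while (i < pairs[r, 1]) { emit(i, 0L); i <- i + 1L }
    while (j < pairs[r, 2]) { emit(0L, j); j <- j + 1L }
    emit(i, j); i <- i + 1L; j <- j + 1L
  }
  while (i <= n1) { emit(i, 0L); i <- i + 1L }
  while (j <= n2) { emit(0L, j); j <- j + 1L }
  g1 <- matrix("-", nrow(m1), length(cols1))
  g1[, cols1 > 0] <- m1[, cols1[cols1 > 0], drop = FALSE]
  g2 <- matrix("-", nrow(m2), length(cols2))
  g2[, cols2 > 0] <- m2[, cols2[cols2 > 0], drop = FALSE]
  out <- rbind(g1, g2)
  rownames(out) <- c(rownames(m1), rownames(m2))
  out
}

#' Progressive multiple sequence alignment
#'
#' A simple progressive aligner: the guide tree is neighbor-joining on
#' fractional common-k-mer distances (k = 3), and blocks are merged by
#' profile-profile Needleman-Wunsch under BLOSUM62 with affine gap
#' penalties (gap columns score 0 against everything). It targets
#' topology-level fidelity of downstream distances, not column-identical
#' agreement with production aligners.
#'
#' @param records list of sequence records (`list(label=, seq=)`) or a
#'   named character vector; >= 2 sequences.
#' @param gap_open,gap_extend affine gap penalties (<= 0), BLOSUM62 scale.
#' @return an [msa()].
#' @export
progressive_msa <- function(records, gap_open = -11, gap_extend = -1) {
  if (!is.character(records)) records <- fasta_as_vector(records)
  if (length(records) < 2) stop_cp("need at least 2 sequences")
  if (anyDuplicated(names(records))) stop_cp("duplicate labels")
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", records)
  if (!all(ok))
    stop_cp("illegal characters in sequence(s): %s",
            paste(names(records)[!ok], collapse = ", "))
  B <- .b62_gapped()
  # collapse duplicate sequences: identical strings align identically, and
  # collapsing keeps the guide tree (hence all columns) invariant under
  # added duplicates
  uniq <- !duplicated(unname(records))
  reps <- names(records)[uniq]
  rep_of <- reps[match(unname(records), unname(records[uniq]))]
  urec <- records[uniq]
  n <- length(urec)
  blocks <- lapply(names(urec), function(l) {
    m <- matrix(strsplit(urec[[l]], "")[[1]], 1)
    rownames(m) <- l
    m
  })
  names(blocks) <- names(urec)
  if (n == 1) {
    merged <- blocks[[1]]
  } else if (n == 2) {
    merged <- .merge_blocks(blocks[[1]], blocks[[2]], gap_open, gap_extend, B)
  } else {
    labs <- names(urec)
    D <- matrix(0, n, n, dimnames = list(labs, labs))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- .kmer_dist(urec[[i]], urec[[j]])
    guide <- nj_build(distance_matrix(D))
    merged <- .merge_by_guide(guide, blocks, gap_open, gap_extend, B)
  }
  # re-expand duplicates onto their representative rows, in input order
  full <- merged[rep_of, , drop = FALSE]
  rownames(full) <- names(records)
  msa(setNames(apply(full, 1, paste, collapse = ""), names(records)))
}

# postorder merge following the guide tree
.merge_by_guide <- function(guide, blocks, gap_open, gap_extend, B) {
  n <- length(guide$tip.label)
  kids <- split(guide$edge[, 2], guide$edge[, 1])
  build <- function(v) {
    if (v <= n) return(blocks[[guide$tip.label[v]]])
    ch <- kids[[as.character(v)]]
    acc <- build(ch[1])
    for (c2 in ch[-1]) acc <- .merge_blocks(acc, build(c2),
                                            gap_open, gap_extend, B)
    acc
  }
  build(n + 1L)
}

#' p-distance matrix from a multiple sequence alignment
#'
#' For each pair of rows, the proportion of differing sites over columns
#' where neither row is gapped. An optional Poisson correction
#' `-log(1 - p)` is available for multiple-hit adjustment.
#'
#' @param m an [msa()].
#' @param correction `"none"` (p-distance, default) or `"poisson"`.
#' @return a [distance_matrix()] (substitutions/site).
#' @export
pdistance_matrix <- function(m, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  stopifnot(inherits(m, "Msa"))
  n <- nrow(m$mat)
  d <- matrix(0, n, n, dimnames = list(m$labels, m$labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m$mat[i, ] != "-" & m$mat[j, ] != "-"
      if (!any(ok))
        stop_cp("no comparable columns between '%s' and '%s'",
                m$labels[i], m$labels[j])
      p <- mean(m$mat[i, ok] != m$mat[j, ok])
      if (correction == "poisson") {
        if (p >= 1) stop_cp("saturated pair ('%s','%s'): Poisson correction undefined",
                            m$labels[i], m$labels[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  distance_matrix(d)
}
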