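# Independent oracles and fixture builders used across the suite.

# Horn's quaternion characteristic-polynomial RMSD: the optimal proper-
# rotation RMSD equals sqrt((Ga + Gb - 2*lambda_max)/n) where lambda_max is
# the largest eigenvalue of the 4x4 key matrix of the correlation R.
# Independent of the SVD route used by the package.
quaternion_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  R <- crossprod(b, a)  # R[k,l] = sum_i b[i,k] a[i,l]
  K <- matrix(c(
    R[1,1]+R[2,2]+R[3,3], R[2,3]-R[3,2],        R[3,1]-R[1,3],        R[1,2]-R[2,1],
    R[2,3]-R[3,2],        R[1,1]-R[2,2]-R[3,3], R[1,2]+R[2,1],        R[3,1]+R[1,3],
    R[3,1]-R[1,3],        R[1,2]+R[2,1],       -R[1,1]+R[2,2]-R[3,3], R[2,3]+R[3,2],
    R[1,2]-R[2,1],        R[3,1]+R[1,3],        R[2,3]+R[3,2],       -R[1,1]-R[2,2]+R[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)))
}

# a randomly jittered helix: breaks the ideal helix's screw symmetry so
# structure-based correspondences are unique
noisy_fold <- function(n, seed = 42, label = "fold", jitter = 0.8) {
  set.seed(seed)
  base <- helix_fold(n, label = label)
  xyz <- ca_coords(base) + matrix(rnorm(3 * n, sd = jitter), n, 3)
  ca_structure(label, seq_id = seq_len(n), xyz = xyz,
               aa = sample(c("A","C","D","E","F","G","H","I","K","L"),
                           n, replace = TRUE))
}

# apply a rigid transform (rotation about z by theta + translation)
rigid_copy <- function(s, theta = 0.7, shift = c(5, -3, 11), label = NULL) {
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta),  cos(theta), 0),
             c(0, 0, 1))
  ca_structure(label %||% paste0(s$label, "_moved"), s$residues$seq_id,
               ca_coords(s) %*% t(R) + matrix(shift, length(s), 3, byrow = TRUE),
               aa = s$residues$aa)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# score of a pairwise gapped alignment under BLOSUM62 + affine gaps
# (gap_open for the first gapped column of a run, gap_extend after)
aln_score <- function(row1, row2, gap_open = -11, gap_extend = -1) {
  B <- blosum62()
  c1 <- strsplit(row1, "")[[1]]; c2 <- strsplit(row2, "")[[1]]
  sc <- 0; prev <- "M"
  for (k in seq_along(c1)) {
    if (c1[k] != "-" && c2[k] != "-") { sc <- sc + B[c1[k], c2[k]]; prev <- "M" }
    else {
      state <- if (c1[k] == "-") "G1" else "G2"
      sc <- sc + if (prev == state) gap_extend else gap_open
      prev <- state
    }
  }
  sc
}

# exhaustive enumeration of all global pairwise alignments (tiny inputs),
# returning the optimal affine-gap score; oracle for the DP
brute_align_score <- function(s1, s2, gap_open = -11, gap_extend = -1) {
  B <- blosum62()
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, B[a[i], b[j]] + rec(i + 1, j + 1, "M"))
    if (j <= length(b))
      best <- max(best, (if (prev == "G1") gap_extend else gap_open) +
                  rec(i, j + 1, "G1"))
    if (i <= length(a))
      best <- max(best, (if (prev == "G2") gap_extend else gap_open) +
                  rec(i + 1, j, "G2"))
    best
  }
  rec(1, 1, "M")
}

# MSA with perfect congruent signal: a conserved backbone shared by all,
# two clades of internally identical sequences, and clade-distinguishing
# columns at every 4th position
congruent_seqs <- function(ncol = 40) {
  set.seed(101)
  base <- sample(c("A","C","D","E","F","G","H","I","K","L"), ncol, TRUE)
  other <- base
  idx <- seq(4, ncol, by = 4)
  other[idx] <- ifelse(base[idx] == "W", "Y", "W")
  a <- paste(base, collapse = ""); b <- paste(other, collapse = "")
  c(A1 = a, A2 = a, B1 = b, B2 = b)
}

# write a minimal PDB fixture from (resno, x, y, z[, extra]) rows
write_pdb_fixture <- function(path, rows) {
  lines <- vapply(rows, function(r) r, "")
  writeLines(c(lines, "END"), path)
}

pdb_atom <- function(serial, name, resname, resno, x, y, z, alt = " ",
                     occ = 1, b = 0, chain = "A", icode = " ") {
  sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, formatC(name, width = -4), alt, resname, chain, resno,
          icode, x, y, z, occ, b)
}
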