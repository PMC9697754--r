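#' Optimal rigid-body superposition (Kabsch/SVD)
#'
#' Least-squares fit of point set `coords_b` onto `coords_a`: the rotation
#' and translation minimizing the RMSD between matched points. Reflections
#' are suppressed by the standard sign flip of the smallest singular vector,
#' so the returned rotation always has determinant +1 (biological chirality
#' is preserved).
#'
#' @param coords_a,coords_b numeric n x 3 matrices of matched points
#'   (n >= 3, not all collinear), Angstrom.
#' @return object of class `Superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom) and `n_pairs`. The fit maps
#'   b onto a: `b_fitted = b %*% t(rotation) + translation`.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' kabsch_superpose(a, a)$rmsd  # 0
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (ncol(a) != 3 || ncol(b) != 3) stop_cp("coordinates must be n x 3")
  if (nrow(a) != nrow(b)) stop_cp("point sets differ in length (%d vs %d)",
                                  nrow(a), nrow(b))
  n <- nrow(a)
  if (n < 3) stop_cp("at least 3 points are required")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  C <- crossprod(B, A)                 # 3x3 covariance
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(ca - R %*% cb)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - fitted)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd, n_pairs = n),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.4f A over %d pairs\n", x$rmsd, x$n_pairs))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a `Superposition`.
#' @param coords numeric n x 3 matrix (the 'b' frame).
#' @return transformed n x 3 matrix in the 'a' frame.
#' @export
apply_superposition <- function(sup, coords) {
  stopifnot(inherits(sup, "Superposition"))
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, -sup$translation)
}

#' Alignment parameters for structure-based correspondence
#'
#' @param d0 distance scale (Angstrom) of the TM-style score
#'   `1 / (1 + (d/d0)^2)`.
#' @param gap_open,gap_extend affine gap penalties (<= 0) applied to that
#'   score.
#' @param max_iter maximum superpose/re-align iterations.
#' @param tol unused convergence slack, kept for forward compatibility.
#' @param core_cutoff deviation cutoff (Angstrom) for core-RMSD trimming.
#' @return list of class `AlignParams`.
#' @export
align_params <- function(d0 = 5.0, gap_open = -1.0, gap_extend = -0.1,
                         max_iter = 20L, tol = 1e-6, core_cutoff = 4.0) {
  if (d0 <= 0) stop_cp("d0 must be positive")
  if (gap_open > 0 || gap_extend > 0) stop_cp("gap penalties must be <= 0")
  if (max_iter < 1) stop_cp("max_iter must be >= 1")
  if (core_cutoff <= 0) stop_cp("core_cutoff must be positive")
  structure(list(d0 = d0, gap_open = gap_open, gap_extend = gap_extend,
                 max_iter = as.integer(max_iter), tol = tol,
                 core_cutoff = core_cutoff),
            class = "AlignParams")
}

#' Trim the N-terminal arm of a structure
#'
#' Removes all residues with `seq_id` strictly below `boundary`. Capsid
#' protein N-terminal arms are conformationally variable (and poorly
#' predicted), so they are excluded before computing structural distances.
#'
#' @param s a `CaStructure`.
#' @param boundary author residue number; residues numbered below it are
#'   dropped.
#' @return trimmed `CaStructure` (label preserved).
#' @export
trim_nterm_arm <- function(s, boundary) {
  stopifnot(inherits(s, "CaStructure"))
  keep <- s$residues$seq_id >= boundary
  if (!any(keep))
    stop_cp("trimming at %d leaves structure '%s' empty", boundary, s$label)
  r <- s$residues[keep, , drop = FALSE]
  ca_structure(s$label, r$seq_id, as.matrix(r[, c("x", "y", "z")]),
               aa = r$aa, ins_code = r$ins_code, confidence = r$confidence)
}
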