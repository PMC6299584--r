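# Kabsch rigid-body superposition and RMSD utilities.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, via singular value decomposition of the
#' cross-covariance matrix with reflection correction. The transform maps
#' `coords_mov` onto `coords_ref`: `fitted = coords_mov %*% rotation +
#' translation` (row vectors).
#'
#' @param coords_ref,coords_mov N x 3 matrices of paired coordinates (Å),
#'   N >= 3.
#' @return Object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length-3), `rmsd` (Å) and `n_atoms`.
#' @examples
#' a <- matrix(rnorm(15), 5, 3)
#' kabsch_superpose(a, a)$rmsd
#' @export
kabsch_superpose <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref)
  coords_mov <- as.matrix(coords_mov)
  if (!identical(dim(coords_ref), dim(coords_mov)))
    stop("coordinate sets must have identical dimensions", call. = FALSE)
  n <- nrow(coords_ref)
  if (n < 3L) stop("need at least 3 atom pairs", call. = FALSE)
  cr <- colMeans(coords_ref)
  cm <- colMeans(coords_mov)
  A <- sweep(coords_ref, 2, cr)
  B <- sweep(coords_mov, 2, cm)
  H <- crossprod(B, A)               # 3x3 cross-covariance (mov -> ref)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    warning("degenerate (near-collinear) geometry; superposition ill-conditioned")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)   # B %*% R approximates A
  fitted <- B %*% R
  rmsd <- sqrt(sum((fitted - A)^2) / n)
  structure(list(rotation = R,
                 translation = as.numeric(cr - cm %*% R),
                 rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: RMSD %.4f Å\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sp A `superposition`.
#' @param xyz N x 3 coordinate matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  sweep(as.matrix(xyz) %*% sp$rotation, 2, sp$translation, `+`)
}

# Minimal-RMSD between two coordinate sets without forming the rotation:
# rmsd^2 = (|A_c|^2 + |B_c|^2 - 2 (s1 + s2 +/- s3)) / N. Used in the
# clustering inner loop where only the distance is needed.
.rmsd_superposed <- function(A, B, centered = FALSE) {
  if (!centered) {
    A <- sweep(A, 2, colMeans(A))
    B <- sweep(B, 2, colMeans(B))
  }
  H <- crossprod(B, A)
  sv <- svd(H)
  s <- sv$d
  if (det(sv$v %*% t(sv$u)) < 0) s[3] <- -s[3]
  v <- (sum(A * A) + sum(B * B) - 2 * sum(s)) / nrow(A)
  sqrt(max(v, 0))
}

# Plain (no superposition) RMSD
.rmsd_raw <- function(A, B) sqrt(sum((A - B)^2) / nrow(A))

#' RMSD between two coordinate sets
#'
#' @param A,B N x 3 matrices.
#' @param superpose If `TRUE` (default) the minimal RMSD after optimal
#'   rigid-body superposition is returned; otherwise the raw RMSD.
#' @return RMSD in Å.
#' @export
coord_rmsd <- function(A, B, superpose = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B))) stop("dimension mismatch", call. = FALSE)
  if (superpose) .rmsd_superposed(A, B) else .rmsd_raw(A, B)
}
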