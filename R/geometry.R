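# Rigid-body superposition, RMSD matrices, radius of gyration and PCA of
# coordinates. All distances in Angstrom, variances in Angstrom^2.

# n x 3 coordinate slice of selected atoms at frame f
.slice <- function(traj, sel, f) {
  matrix(traj$coords[sel, , f], ncol = 3L)
}

.center_coords <- function(x, w = NULL) {
  if (is.null(w)) {
    com <- colMeans(x)
  } else {
    com <- colSums(x * w) / sum(w)
  }
  list(centered = sweep(x, 2L, com), com = com)
}

#' Optimal rigid-body superposition (Kabsch, SVD form)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' (optionally mass-weighted) RMSD between `mobile %*% t(R) + t` and
#' `reference`. The determinant sign of the SVD solution is corrected so a
#' reflection is never returned, including for degenerate (planar or
#' collinear) inputs.
#'
#' @param mobile,reference numeric `n x 3` matrices, n >= 3.
#' @param weights optional positive per-atom weights (e.g. masses).
#' @return list with `rotation` (3x3, applied as `x %*% t(rotation)`),
#'   `translation` (length-3), and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference shapes differ")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 atoms for superposition")
  if (ncol(mobile) != 3L) stop("coordinates must be n x 3")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) stop("bad weights")

  cm <- .center_coords(mobile, weights)
  cr <- .center_coords(reference, weights)
  P <- cm$centered; Q <- cr$centered
  H <- crossprod(P * weights, Q)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- P %*% t(R)
  msd <- sum(weights * rowSums((rot - Q)^2)) / sum(weights)
  list(
    rotation = R,
    translation = as.numeric(cr$com - cm$com %*% t(R)),
    rmsd = sqrt(max(msd, 0))
  )
}

#' Apply a superposition result to coordinates
#' @param x numeric `n x 3` matrix.
#' @param sp result of [kabsch_superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(x, sp) {
  sweep(as.matrix(x) %*% t(sp$rotation), 2L, sp$translation, `+`)
}

#' All-to-all RMSD matrix over trajectory frames
#'
#' Entry (i, j) is the Kabsch RMSD between frames i and j on the selected
#' atoms; the matrix is symmetric with a zero diagonal.
#'
#' @param traj a `Trajectory`.
#' @param sel a `Selection` (default: all C-alpha atoms).
#' @param weights optional per-atom weights.
#' @return symmetric numeric matrix `n_frames x n_frames` (Angstrom).
#' @export
rmsd_all_to_all <- function(traj, sel = NULL, weights = NULL) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames")
  if (is.null(sel)) sel <- select_atoms(traj, atom_names = "CA")
  if (length(sel) == 0L) stop("empty selection")
  frames <- lapply(seq_len(nf), function(f) .slice(traj, sel, f))
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in seq(i + 1L, nf)) {
      r <- kabsch_superpose(frames[[j]], frames[[i]], weights)$rmsd
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  dimnames(m) <- list(seq_len(nf), seq_len(nf))
  m
}

#' Mass-weighted radius of gyration of one frame
#'
#' `RoG = sqrt( sum(m_i |r_i - r_com|^2) / sum(m_i) )`, invariant under
#' rigid motion.
#'
#' @param frame numeric `n x 3` matrix.
#' @param masses per-atom masses (amu); unit masses give the geometric RoG.
#' @return RoG in Angstrom.
#' @export
radius_of_gyration <- function(frame, masses = NULL) {
  frame <- as.matrix(frame)
  if (nrow(frame) < 1L) stop("empty frame")
  if (is.null(masses)) masses <- rep(1, nrow(frame))
  if (sum(masses) <= 0) stop("zero total mass")
  cc <- .center_coords(frame, masses)
  sqrt(sum(masses * rowSums(cc$centered^2)) / sum(masses))
}

#' Radius-of-gyration series along a trajectory
#'
#' @param traj a `Trajectory`.
#' @param sel a `Selection` (default all atoms); masses come from the
#'   topology.
#' @return list with `values` (per-frame RoG, Angstrom), `mean`, `sd`.
#' @export
gyration_series <- function(traj, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(n_atoms(traj))
  masses <- traj$topology$mass[sel]
  v <- vapply(seq_len(n_frames(traj)), function(f) {
    radius_of_gyration(.slice(traj, sel, f), masses)
  }, numeric(1L))
  list(values = v, mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
}

#' Principal component analysis of selected-atom motion
#'
#' Frames are superposed onto a reference frame on the selected atoms
#' (C-alpha, mass-unweighted by convention), flattened to `3m`-dimensional
#' configuration vectors, column-centered, and the covariance matrix is
#' diagonalised. Mode vectors are orthonormal; each mode's
#' largest-magnitude component is made positive so output signs are
#' deterministic. The retained eigenvalue sum over the full spectrum equals
#' the total variance of the superposed, centered coordinates.
#'
#' @param traj a `Trajectory`.
#' @param sel a `Selection` (default: all C-alpha atoms).
#' @param n_modes number of modes to retain (default: full spectrum).
#' @param reference_frame frame index used as superposition target.
#' @param superpose superpose frames onto the reference before the
#'   covariance (default TRUE); FALSE analyses raw coordinates.
#' @return list with `mean` (`m x 3`), `modes` (`3m x k`), `variances`
#'   (Angstrom^2, descending), `variance_fraction`, `projections`
#'   (`n_frames x k`), `total_variance`.
#' @export
pca_modes <- function(traj, sel = NULL, n_modes = NULL, reference_frame = 1L,
                      superpose = TRUE) {
  nf <- n_frames(traj)
  if (nf < 3L) stop("need at least 3 frames for PCA")
  if (is.null(sel)) sel <- select_atoms(traj, atom_names = "CA")
  m <- length(sel)
  if (!is.null(n_modes) && n_modes > 3L * m)
    stop("n_modes exceeds 3 * n_atoms")
  ref <- .slice(traj, sel, reference_frame)
  X <- t(vapply(seq_len(nf), function(f) {
    fr <- .slice(traj, sel, f)
    if (superpose) {
      sp <- kabsch_superpose(fr, ref)
      fr <- apply_superposition(fr, sp)
    }
    as.numeric(fr)
  }, numeric(3L * m)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  cv <- crossprod(Xc) / (nf - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  total <- sum(vals)
  k <- if (is.null(n_modes)) min(3L * m, nf - 1L) else n_modes
  modes <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(modes[, j]))
    if (modes[i_max, j] < 0) modes[, j] <- -modes[, j]
  }
  list(
    mean = matrix(mu, ncol = 3L),
    modes = modes,
    variances = vals[seq_len(k)],
    variance_fraction = if (total > 0) vals[seq_len(k)] / total else
      rep(0, k),
    projections = Xc %*% modes,
    total_variance = total
  )
}

#' Write a square matrix as CSV with frame indices as header
#' @param m numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- colnames(m) %||% as.character(seq_len(ncol(m)))
  utils::write.csv(cbind(frame = rownames(m) %||%
                           as.character(seq_len(nrow(m))), df),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
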