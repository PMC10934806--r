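# RMSD-based conformational clustering (GROMOS greedy neighbour
# counting), representative extraction, U-shape classification of
# monomer conformations, the cluster-weighted U-shape percentage, and
# C-alpha contact maps.

#' GROMOS-style greedy RMSD clustering
#'
#' Repeatedly takes the unassigned frame with the most unassigned
#' neighbours within `cutoff` as a cluster centre, assigns centre plus
#' neighbours, removes them, and repeats. Ties break to the lowest frame
#' index, making the partition deterministic. Each cluster's
#' representative is the member minimising the mean RMSD to all members
#' (ties again to the lowest index).
#'
#' @param rmsd_matrix square symmetric matrix with a zero diagonal
#'   (Angstrom), e.g. from [rmsd_all_to_all()].
#' @param cutoff neighbour cutoff in Angstrom (default 3.0).
#' @return object of class `ClusterSet`: list with `assignment` (per-frame
#'   cluster id), `clusters` (data.frame id / population / population_pct /
#'   representative).
#' @export
cluster_gromos <- function(rmsd_matrix, cutoff = 3.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  m <- as.matrix(rmsd_matrix)
  n <- nrow(m)
  if (n != ncol(m)) stop("rmsd matrix must be square")
  if (max(abs(m - t(m))) > 1e-8 || any(abs(diag(m)) > 1e-8))
    stop("rmsd matrix must be symmetric with zero diagonal")
  within <- m <= cutoff
  assignment <- rep(NA_integer_, n)
  cl <- 0L
  remaining <- rep(TRUE, n)
  reps <- integer(0)
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- colSums(within[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    centre <- which.max(counts)      # first max = lowest index
    members <- which(remaining & within[, centre])
    assignment[members] <- cl
    remaining[members] <- FALSE
    mean_r <- colMeans(m[members, members, drop = FALSE])
    reps[cl] <- members[which.min(mean_r)]
  }
  pops <- tabulate(assignment, nbins = cl)
  structure(list(
    assignment = assignment,
    clusters = data.frame(id = seq_len(cl), population = pops,
                          population_pct = 100 * pops / n,
                          representative = reps)
  ), class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d frames in %d clusters\n",
              length(x$assignment), nrow(x$clusters)))
  print(utils::head(x$clusters, 10L))
  invisible(x)
}

.window_axis <- function(ca) {
  cc <- sweep(ca, 2L, colMeans(ca))
  ax <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1L]
  if (sum(ax * (ca[nrow(ca), ] - ca[1L, ])) < 0) ax <- -ax
  ax
}

#' Classify one monomer conformation as U-shaped or not
#'
#' A frame is U-shaped when (a) the best-fit axes of the two arm windows,
#' directed N-terminal to C-terminal, make an angle of at least
#' `angle_min` degrees (antiparallel arms), (b) the minimum inter-arm
#' C-alpha distance is at most `contact_max` Angstrom, and (c) the turn
#' window contains the chain direction reversal (the projections of
#' successive C-alpha steps on the arm-1 axis change sign inside it).
#' This geometric operationalisation has no literature-standard
#' definition; every threshold is exposed and echoed in reports.
#'
#' @param frame numeric `n_atoms x 3` matrix.
#' @param topology topology data.frame (single 42-residue chain expected).
#' @param arm1,arm2 inclusive residue windows of the two arms (defaults
#'   12-21 and 28-39).
#' @param turn inclusive turn window (default 22-28).
#' @param angle_min arm-axis angle threshold, degrees (default 120).
#' @param contact_max inter-arm contact threshold, Angstrom (default 12).
#' @return list (`UShapeReport`): `is_U`, `arm1`, `arm2`, `turn`, `angle`
#'   (degrees), `min_interarm` (Angstrom), `reversal` (logical).
#' @export
classify_u <- function(frame, topology, arm1 = c(12L, 21L),
                       arm2 = c(28L, 39L), turn = c(22L, 28L),
                       angle_min = 120, contact_max = 12) {
  ca_rows <- which(topology$name == "CA")
  res <- topology$res_seq[ca_rows]
  ca_of <- function(r) {
    i <- ca_rows[match(r, res)]
    if (anyNA(i)) stop("missing C-alpha for residue ",
                       paste(r[is.na(match(r, res))], collapse = ","))
    frame[i, , drop = FALSE]
  }
  w1 <- ca_of(seq(arm1[1L], arm1[2L]))
  w2 <- ca_of(seq(arm2[1L], arm2[2L]))
  a1 <- .window_axis(w1)
  a2 <- .window_axis(w2)
  angle <- acos(pmin(pmax(sum(a1 * a2), -1), 1)) / .deg
  dmin <- min(sqrt(outer(rowSums(w1^2), rowSums(w2^2), `+`) -
                     2 * w1 %*% t(w2)))
  steps <- seq(turn[1L], turn[2L] - 1L)
  proj <- vapply(steps, function(i) {
    sum((ca_of(i + 1L) - ca_of(i)) * a1)
  }, numeric(1L))
  reversal <- max(proj) > 0 && min(proj) < 0
  list(is_U = angle >= angle_min && dmin <= contact_max && reversal,
       arm1 = arm1, arm2 = arm2, turn = turn,
       angle = angle, min_interarm = dmin, reversal = reversal)
}

#' Cluster-weighted U-shape percentage
#'
#' Classifies each cluster's representative frame and sums the population
#' percentages of clusters whose representative is U-shaped (the
#' cluster-counting convention; a per-frame mode is available via
#' `per_frame = TRUE`).
#'
#' @param clusterset a `ClusterSet`.
#' @param traj the clustered `Trajectory`.
#' @param per_frame classify every frame instead of representatives only.
#' @param ... thresholds passed to [classify_u()].
#' @return list with `percent` and `per_cluster` (data.frame id,
#'   population_pct, representative, is_U).
#' @export
u_percentage <- function(clusterset, traj, per_frame = FALSE, ...) {
  if (per_frame) {
    isu <- vapply(seq_len(n_frames(traj)), function(f) {
      classify_u(get_frame(traj, f), traj$topology, ...)$is_U
    }, logical(1L))
    return(list(percent = 100 * mean(isu), per_cluster = NULL))
  }
  cl <- clusterset$clusters
  isu <- vapply(cl$representative, function(f) {
    classify_u(get_frame(traj, f), traj$topology, ...)$is_U
  }, logical(1L))
  list(percent = sum(cl$population_pct[isu]),
       per_cluster = cbind(cl, is_U = isu))
}

#' C-alpha contact-frequency map
#'
#' Entry (i, j) is the fraction of frames in which the C-alpha atoms of
#' residues i and j lie within `cutoff` Angstrom; the diagonal is 1 by
#' construction and the matrix is symmetric.
#'
#' @param traj a `Trajectory`.
#' @param sel a `Selection` of C-alpha atoms (default: all CA).
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @return numeric matrix with residue numbers as dimnames.
#' @export
contact_map <- function(traj, sel = NULL, cutoff = 8) {
  if (is.null(sel)) sel <- select_atoms(traj, atom_names = "CA")
  nf <- n_frames(traj)
  k <- length(sel)
  acc <- matrix(0, k, k)
  for (f in seq_len(nf)) {
    x <- .slice(traj, sel, f)
    d2 <- outer(rowSums(x^2), rowSums(x^2), `+`) - 2 * tcrossprod(x)
    acc <- acc + (d2 <= cutoff^2 + 1e-12)
  }
  m <- acc / nf
  labs <- as.character(traj$topology$res_seq[sel])
  dimnames(m) <- list(labs, labs)
  m
}
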