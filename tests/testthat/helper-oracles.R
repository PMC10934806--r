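# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms than the package code.

# Horn quaternion-eigenvalue RMSD: the optimal superposition RMSD is
# obtained from the largest eigenvalue of the 4x4 key matrix, with no SVD
# and no explicit rotation.
quaternion_rmsd_oracle <- function(P, Q, w = NULL) {
  n <- nrow(P)
  if (is.null(w)) w <- rep(1, n)
  P <- sweep(P, 2, colSums(P * w) / sum(w))
  Q <- sweep(Q, 2, colSums(Q * w) / sum(w))
  S <- crossprod(P * w, Q)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],       S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],       S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],       S[3,1]+S[1,3],       S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  g <- sum(w * rowSums(P^2)) + sum(w * rowSums(Q^2))
  sqrt(max(0, (g - 2 * lam) / sum(w)))
}

# Exhaustive re-implementation of the greedy neighbour-counting rule:
# recompute the full neighbour census from scratch each round.
greedy_cluster_oracle <- function(m, cutoff) {
  n <- nrow(m)
  assignment <- rep(NA_integer_, n)
  cl <- 0L
  repeat {
    left <- which(is.na(assignment))
    if (!length(left)) break
    best <- -1L; centre <- NA_integer_
    for (i in left) {
      cnt <- 0L
      for (j in left) if (m[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; centre <- i }
    }
    cl <- cl + 1L
    for (j in left) if (m[centre, j] <= cutoff) assignment[j] <- cl
  }
  assignment
}

# Reference DSSP labels via the MDAnalysis implementation (pure Python, in
# the runtime image); returns a character matrix n_res x n_frames over
# {"H","E","-"}.
dssp_oracle <- function(pdb_path) {
  script <- system.file("oracle", "dssp_oracle.py", package = "abconform")
  out <- system2("python", c(shQuote(script), shQuote(pdb_path)),
                 stdout = TRUE, stderr = FALSE)
  do.call(cbind, strsplit(out, ""))
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
}
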