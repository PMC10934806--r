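# Fibril tertiary-structure descriptors: the five compactness distances
# and the fan-like motion amplitude on multi-strand trajectories.
#
# Strand indices are 1-based along the inferred stacking axis (so
# "3-Gly33" is residue Gly33 of the third strand along the axis),
# mirroring the naming of the measures:
#   D_HC  horizontal core      Gly33 of strand 3 <-> Gly33 of strand 8
#   D_VC  vertical core        Phe19-Val39 within each core strand, mean
#   D_HE  horizontal external  Gln15 of strand 3 <-> Gln15 of strand 8
#   D_VE  vertical external    Glu11-Val39 within each core strand, mean
#   D_IS  interstrand          His14 of consecutive core strands, per pair
# All measures use C-alpha positions.

.DEFAULT_FIBRIL_REFS <- list(HC = 33L, VC = c(19L, 39L), HE = 15L,
                             VE = c(11L, 39L), IS = 14L)

#' Infer fibril stacking topology from geometry
#'
#' The stacking axis is the leading principal axis of the strand (chain)
#' C-alpha centroids, its sign fixed so the largest-magnitude component is
#' positive; strands are ordered by centroid projection on it, so chain
#' labels never matter. Core strands are all but `margin` outermost at
#' each end.
#'
#' @param traj a multi-chain `Trajectory`.
#' @param frame frame index used for the geometry (default 1).
#' @param margin number of outer strands excluded from the core at each
#'   end (default 2).
#' @param refs named list of reference residues (defaults: HC Gly33,
#'   VC Phe19/Val39, HE Gln15, VE Glu11/Val39, IS His14).
#' @return object of class `FibrilTopology`: list with `strand_chains`
#'   (chain ids ordered along the axis), `core` (core strand indices),
#'   `axis`, `refs`, `n_strands`.
#' @export
infer_fibril_topology <- function(traj, frame = 1L, margin = 2L,
                                  refs = .DEFAULT_FIBRIL_REFS) {
  chains <- unique(traj$topology$chain_id)
  if (length(chains) < 2L) stop("need at least 2 chains; got ",
                                length(chains))
  ranges <- lapply(chains, function(ch)
    range(traj$topology$res_seq[traj$topology$chain_id == ch]))
  lo <- max(vapply(ranges, `[`, numeric(1L), 1L))
  hi <- min(vapply(ranges, `[`, numeric(1L), 2L))
  if (lo > hi) stop("chains have no overlapping residue range")
  xyz <- get_frame(traj, frame)
  cent <- t(vapply(chains, function(ch) {
    rows <- which(traj$topology$chain_id == ch & traj$topology$name == "CA")
    colMeans(xyz[rows, , drop = FALSE])
  }, numeric(3L)))
  cc <- sweep(cent, 2L, colMeans(cent))
  axis <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1L]
  if (axis[which.max(abs(axis))] < 0) axis <- -axis
  proj <- as.numeric(cc %*% axis)
  ord <- order(proj)
  gaps <- diff(sort(proj))
  if (any(gaps < 0.5))
    stop("ambiguous strand ordering: two strands within 0.5 A projection")
  n <- length(chains)
  if (margin < 0L || 2L * margin >= n) stop("invalid core margin")
  structure(list(strand_chains = chains[ord],
                 core = seq(margin + 1L, n - margin),
                 axis = axis, refs = refs, n_strands = n,
                 margin = margin),
            class = "FibrilTopology")
}

#' @export
print.FibrilTopology <- function(x, ...) {
  cat(sprintf("FibrilTopology: %d strands (%s), core %d-%d\n",
              x$n_strands, paste(x$strand_chains, collapse = ""),
              min(x$core), max(x$core)))
  invisible(x)
}

# C-alpha of residue `res` in the strand at position `strand` along the
# stacking axis.
.strand_ca <- function(frame, topology, topo, strand, res) {
  ch <- topo$strand_chains[strand]
  row <- which(topology$chain_id == ch & topology$res_seq == res &
                 topology$name == "CA")
  if (length(row) != 1L)
    stop("strand ", strand, " (chain ", ch, ") lacks C-alpha of residue ",
         res)
  frame[row, ]
}

.pair_dist <- function(frame, topology, topo, s1, s2, res) {
  sqrt(sum((.strand_ca(frame, topology, topo, s1, res) -
              .strand_ca(frame, topology, topo, s2, res))^2))
}

.intra_mean <- function(frame, topology, topo, res_pair) {
  mean(vapply(topo$core, function(s) {
    sqrt(sum((.strand_ca(frame, topology, topo, s, res_pair[1L]) -
                .strand_ca(frame, topology, topo, s, res_pair[2L]))^2))
  }, numeric(1L)))
}

#' The five fibril compactness distances for one frame
#'
#' @param frame numeric `n_atoms x 3` matrix.
#' @param topology topology data.frame.
#' @param topo a `FibrilTopology`.
#' @return `d_hc`, `d_he`: single distances (strand 3 <-> 8, needing at
#'   least 8 strands); `d_vc`, `d_ve`: means over core strands; `d_is`:
#'   list with per-adjacent-core-pair distances and their mean.
#' @rdname fibril_distances
#' @export
d_hc <- function(frame, topology, topo) {
  if (topo$n_strands < 8L) stop("strand 3 <-> 8 measure needs >= 8 strands")
  .pair_dist(frame, topology, topo, 3L, 8L, topo$refs$HC)
}

#' @rdname fibril_distances
#' @export
d_he <- function(frame, topology, topo) {
  if (topo$n_strands < 8L) stop("strand 3 <-> 8 measure needs >= 8 strands")
  .pair_dist(frame, topology, topo, 3L, 8L, topo$refs$HE)
}

#' @rdname fibril_distances
#' @export
d_vc <- function(frame, topology, topo)
  .intra_mean(frame, topology, topo, topo$refs$VC)

#' @rdname fibril_distances
#' @export
d_ve <- function(frame, topology, topo)
  .intra_mean(frame, topology, topo, topo$refs$VE)

#' @rdname fibril_distances
#' @export
d_is <- function(frame, topology, topo) {
  core <- topo$core
  pairs <- cbind(core[-length(core)], core[-1L])
  v <- vapply(seq_len(nrow(pairs)), function(k) {
    .pair_dist(frame, topology, topo, pairs[k, 1L], pairs[k, 2L],
               topo$refs$IS)
  }, numeric(1L))
  names(v) <- paste0(pairs[, 1L], "-", pairs[, 2L])
  list(pairs = v, mean = mean(v))
}

#' Per-frame descriptor series over a fibril trajectory
#'
#' @param traj a `Trajectory`.
#' @param topo a `FibrilTopology`.
#' @return object of class `DescriptorSeries`: list with `frames`
#'   (data.frame frame, D_HC, D_VC, D_HE, D_VE, D_IS_mean), `is_pairs`
#'   (matrix of per-adjacent-pair interstrand distances), `summary`
#'   (mean/sd per descriptor).
#' @export
descriptor_series <- function(traj, topo) {
  nf <- n_frames(traj)
  top <- traj$topology
  rows <- vector("list", nf)
  is_list <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    is_f <- d_is(fr, top, topo)
    rows[[f]] <- data.frame(
      frame = f,
      D_HC = d_hc(fr, top, topo), D_VC = d_vc(fr, top, topo),
      D_HE = d_he(fr, top, topo), D_VE = d_ve(fr, top, topo),
      D_IS_mean = is_f$mean)
    is_list[[f]] <- is_f$pairs
  }
  frames <- do.call(rbind, rows)
  is_pairs <- do.call(rbind, is_list)
  rownames(is_pairs) <- NULL
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  summ <- data.frame(
    descriptor = c("D_HC", "D_VC", "D_HE", "D_VE", "D_IS_mean"),
    mean = vapply(frames[, -1L], mean, numeric(1L)),
    sd = vapply(frames[, -1L], sd0, numeric(1L)),
    row.names = NULL)
  structure(list(frames = frames, is_pairs = is_pairs, summary = summ),
            class = "DescriptorSeries")
}

#' @export
print.DescriptorSeries <- function(x, ...) {
  cat(sprintf("DescriptorSeries over %d frames\n", nrow(x$frames)))
  print(transform(x$summary, mean = round(mean, 2), sd = round(sd, 2)))
  invisible(x)
}

#' Fan-like motion amplitude and dominant-mode variance fraction
#'
#' The fan amplitude is the range (max - min) of the per-frame D_VE
#' series; the collectivity of the motion is summarised by the variance
#' fraction of the first C-alpha PCA mode.
#'
#' @param traj a `Trajectory` with at least 10 frames.
#' @param topo a `FibrilTopology`.
#' @param series optional precomputed [descriptor_series()].
#' @return list with `amplitude` (Angstrom), `mode1_variance_fraction`,
#'   `dve_range` (min/max).
#' @export
fan_amplitude <- function(traj, topo, series = NULL) {
  if (n_frames(traj) < 10L) stop("need at least 10 frames")
  if (is.null(series)) series <- descriptor_series(traj, topo)
  dve <- series$frames$D_VE
  pca <- pca_modes(traj, n_modes = 1L)
  list(amplitude = max(dve) - min(dve),
       mode1_variance_fraction = pca$variance_fraction[1L],
       dve_range = range(dve))
}
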