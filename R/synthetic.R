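# Synthetic conformation and trajectory generators: ideal helices and
# strands from dihedral schedules (NeRF internal-coordinate chain
# extension), U-shaped hairpins, monomer ensembles mixing conformer
# classes, and S-shaped fibril stacks with programmable rise, fan-opening
# schedules and strand dissociation. Every generated trajectory carries a
# machine-readable ground-truth log as the attribute "ground_truth".
#
# Bonded geometry: N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231,
# CA-CB 1.530 Angstrom; angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7,
# CA-C-O 120.8 degrees. CB is a placeholder pseudo-atom (no full
# sidechains); trace-derived backbones (fibril strands, hairpin turns) are
# geometrically approximate between C-alpha positions and are not intended
# for secondary-structure assignment.

.deg <- pi / 180

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Natural extension reference frame: place atom D bonded to c with given
# bond length, angle b-c-D and torsion a-b-c-D (degrees).
.nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- angle * .deg
  chi <- torsion * .deg
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi),
          bond * sin(th) * sin(chi))
  c + cbind(bc, m, n) %*% d2
}

#' Named dihedral-schedule presets
#'
#' `alpha` is the ideal alpha-helix (phi -57, psi -47), `beta` the extended
#' strand (phi -135, psi 135); omega is 180 (trans) in both.
#'
#' @param preset one of `"alpha"`, `"beta"`.
#' @param n number of residues.
#' @return data.frame with columns `phi`, `psi`, `omega` in degrees.
#' @export
dihedral_schedule <- function(preset = c("alpha", "beta"), n) {
  preset <- match.arg(preset)
  ang <- switch(preset,
                alpha = c(-57, -47, 180),
                beta  = c(-135, 135, 180))
  data.frame(phi = rep(ang[1L], n), psi = rep(ang[2L], n),
             omega = rep(ang[3L], n))
}

.place_cb <- function(N, CA, C) {
  u1 <- .unit(N - CA)
  u2 <- .unit(C - CA)
  bis <- -.unit(u1 + u2)
  nrm <- .unit(.cross(u1, u2))
  CA + 1.53 * .unit(bis * cos(0.96) + nrm * sin(0.96))
}

#' Build a peptide backbone from a dihedral schedule
#'
#' Sequential internal-coordinate (NeRF) chain extension placing N, CA, C,
#' O and a CB placeholder (non-Gly) per residue. Deterministic for fixed
#' inputs.
#'
#' @param sequence one-letter sequence (string or character vector).
#' @param schedule data.frame with per-residue `phi`, `psi`, `omega`
#'   (degrees), one row per residue; see [dihedral_schedule()].
#' @param res_start author number of the first residue (default 1).
#' @param chain_id chain identifier (default "A").
#' @return a single-frame [trajectory()].
#' @export
build_backbone <- function(sequence, schedule, res_start = 1L,
                           chain_id = "A") {
  seq1 <- if (length(sequence) == 1L && nchar(sequence) > 1L)
    strsplit(sequence, "")[[1L]] else sequence
  nres <- length(seq1)
  if (nrow(schedule) != nres) stop("schedule length != sequence length")
  res3 <- aa_three(seq1)

  N <- CA <- C <- O <- matrix(NA_real_, nres, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(1.458, 0, 0)
  C[1L, ] <- CA[1L, ] + 1.525 * c(cos((180 - 111.2) * .deg),
                                  sin((180 - 111.2) * .deg), 0)
  for (i in seq_len(nres)[-1L]) {
    N[i, ] <- .nerf_place(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                          1.329, 116.2, schedule$psi[i - 1L])
    CA[i, ] <- .nerf_place(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                           1.458, 121.7, schedule$omega[i])
    C[i, ] <- .nerf_place(C[i - 1L, ], N[i, ], CA[i, ],
                          1.525, 111.2, schedule$phi[i])
    # carbonyl O of i-1 in the peptide plane, anti to N(i)
    u_ca <- .unit(CA[i - 1L, ] - C[i - 1L, ])
    u_n <- .unit(N[i, ] - C[i - 1L, ])
    O[i - 1L, ] <- C[i - 1L, ] + 1.231 * .unit(-(u_ca + u_n))
  }
  O[nres, ] <- .nerf_place(N[nres, ], CA[nres, ], C[nres, ],
                           1.231, 120.8, schedule$psi[nres] + 180)

  rows <- list(); coords <- list()
  for (i in seq_len(nres)) {
    atoms <- c("N", "CA", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (res3[i] != "GLY") {
      atoms <- c(atoms, "CB")
      xyz <- rbind(xyz, t(.place_cb(N[i, ], CA[i, ], C[i, ])))
    }
    rows[[i]] <- data.frame(
      name = atoms, res_name = res3[i], chain_id = chain_id,
      res_seq = res_start + i - 1L, stringsAsFactors = FALSE)
    coords[[i]] <- xyz
  }
  top <- do.call(rbind, rows)
  top$serial <- seq_len(nrow(top))
  top$element <- infer_element(top$name)
  top$mass <- .element_mass(top$element)
  trajectory(top[, c("serial", "name", "res_name", "chain_id", "res_seq",
                     "element", "mass")],
             do.call(rbind, coords))
}

# Backbone atoms from a bare C-alpha trace: N toward the previous CA, C
# toward the next, O perpendicular to the local chain plane, CB outward.
# Approximate bonded geometry; adequate for CA-based descriptors and I/O.
.backbone_from_ca_trace <- function(ca, seq3, res_start, chain_id) {
  k <- nrow(ca)
  prev <- rbind(2 * ca[1L, ] - ca[2L, ], ca[-k, ])
  nxt <- rbind(ca[-1L, ], 2 * ca[k, ] - ca[k - 1L, ])
  rows <- list(); coords <- list()
  for (i in seq_len(k)) {
    tp <- .unit(ca[i, ] - prev[i, ])
    tn <- .unit(nxt[i, ] - ca[i, ])
    Ni <- ca[i, ] - 1.45 * tp
    Ci <- ca[i, ] + 1.52 * tn
    pl <- .cross(tp, tn)
    if (sqrt(sum(pl^2)) < 1e-6) {
      pl <- .cross(tn, c(0, 0, 1))
      if (sqrt(sum(pl^2)) < 1e-6) pl <- .cross(tn, c(0, 1, 0))
    }
    pl <- .unit(pl)
    Oi <- Ci + 1.23 * .unit(.cross(pl, tn))
    atoms <- c("N", "CA", "C", "O")
    xyz <- rbind(Ni, ca[i, ], Ci, Oi)
    if (seq3[i] != "GLY") {
      out <- tp - tn
      if (sqrt(sum(out^2)) < 1e-6) out <- pl
      atoms <- c(atoms, "CB")
      xyz <- rbind(xyz, ca[i, ] + 1.53 * .unit(out))
    }
    rows[[i]] <- data.frame(
      name = atoms, res_name = seq3[i], chain_id = chain_id,
      res_seq = res_start + i - 1L, stringsAsFactors = FALSE)
    coords[[i]] <- xyz
  }
  top <- do.call(rbind, rows)
  top$serial <- seq_len(nrow(top))
  top$element <- infer_element(top$name)
  top$mass <- .element_mass(top$element)
  list(topology = top[, c("serial", "name", "res_name", "chain_id",
                          "res_seq", "element", "mass")],
       coords = do.call(rbind, coords))
}

# Minimal rotation taking unit vector a onto unit vector b (Rodrigues).
.rotation_between <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .cross(a, b)
  s <- sqrt(sum(v^2))
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    p <- .unit(.cross(a, if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(2 * tcrossprod(p) - diag(3))
  }
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

.ca_indices <- function(top) which(top$name == "CA")

# Rigidly place a single-frame trajectory so its CA principal axis
# (directed first->last CA) maps onto `axis` and its CA centroid onto
# `centroid`.
.orient_segment <- function(seg, axis, centroid) {
  ca <- seg$coords[.ca_indices(seg$topology), , 1L, drop = TRUE]
  cc <- sweep(ca, 2L, colMeans(ca))
  ax <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1L]
  if (sum(ax * (ca[nrow(ca), ] - ca[1L, ])) < 0) ax <- -ax
  R <- .rotation_between(ax, axis)
  xyz <- seg$coords[, , 1L, drop = TRUE] %*% t(R)
  ca2 <- xyz[.ca_indices(seg$topology), , drop = FALSE]
  sweep(xyz, 2L, centroid - colMeans(ca2), `+`)
}

#' Build a U-shaped hairpin monomer conformation
#'
#' Two ideal alpha-helical arms (residues 1-21 and 28-42) are placed
#' antiparallel (axes along +x and -x) separated by `arm_sep` Angstrom in
#' y, and joined by an arc of C-alpha positions over the turn residues
#' 22-27. The arm windows 12-21 and 28-39 therefore make an inter-axis
#' angle near 180 degrees with a minimum inter-arm C-alpha distance near
#' `arm_sep`, and the chain direction reverses inside the 22-28 turn.
#'
#' @param sequence one-letter Abeta sequence (42 residues).
#' @param arm_sep inter-arm separation in Angstrom (default 9.5, keeping
#'   the minimum inter-arm C-alpha distance under the 10 Angstrom
#'   construction contract).
#' @return single-frame [trajectory()].
#' @export
build_hairpin <- function(sequence = ab42_sequence(), arm_sep = 9.5) {
  seq1 <- strsplit(sequence, "")[[1L]]
  if (length(seq1) != 42L) stop("hairpin builder expects 42 residues")
  segA <- build_backbone(seq1[1:21], dihedral_schedule("alpha", 21L))
  segB <- build_backbone(seq1[28:42], dihedral_schedule("alpha", 15L),
                         res_start = 28L)
  # helix rise ~1.5 A/residue; arm A runs +x ending near x = +15,
  # arm B runs -x starting near x = +13 at y = arm_sep
  xyzA <- .orient_segment(segA, c(1, 0, 0), c(0, 0, 0))
  xyzB <- .orient_segment(segB, c(-1, 0, 0), c(2.5, arm_sep, 0))

  caA <- xyzA[.ca_indices(segA$topology), , drop = FALSE]
  caB <- xyzB[.ca_indices(segB$topology), , drop = FALSE]
  p0 <- caA[21L, ]            # CA 21
  p1 <- caB[1L, ]             # CA 28
  ctrl <- (p0 + p1) / 2 + c(6.5, 0, 0)
  tt <- seq_len(6L) / 7
  arc <- t(vapply(tt, function(t) {
    (1 - t)^2 * p0 + 2 * t * (1 - t) * ctrl + t^2 * p1
  }, numeric(3L)))
  turn <- .backbone_from_ca_trace(rbind(p0, arc, p1)[2:7, , drop = FALSE],
                                  aa_three(seq1[22:27]), 22L, "A")

  topA <- segA$topology; topB <- segB$topology
  topB$chain_id <- "A"
  top <- rbind(topA, turn$topology, topB)
  top$serial <- seq_len(nrow(top))
  trajectory(top, rbind(xyzA, turn$coords, xyzB))
}

#' Build a two-strand antiparallel beta-sheet fixture
#'
#' Two identical ideal strands (beta dihedral preset), the second rotated
#' 180 degrees about the y axis and offset by `separation` Angstrom in the
#' hydrogen-bonding direction, giving a register in which the
#' Kabsch-Sander bridge pattern forms between the chains (A and B). With
#' the idealized flat strand geometry the bonding register sits at ~3.8
#' Angstrom centroid separation rather than the ~4.8 of a pleated sheet;
#' this is a fixture for assignment tests, not a physical sheet model.
#'
#' @param n_res residues per strand (default 10).
#' @param sequence one-letter sequence for one strand (default poly-Val).
#' @param separation inter-strand offset in Angstrom (default 3.8).
#' @param shift register shift along the strand axis in Angstrom.
#' @return single-frame two-chain [trajectory()].
#' @export
build_antiparallel_sheet <- function(n_res = 10L,
                                     sequence = strrep("V", n_res),
                                     separation = 3.8, shift = 0) {
  s <- build_backbone(sequence, dihedral_schedule("beta", n_res))
  xyz0 <- get_frame(s, 1L)
  topA <- s$topology
  ca <- xyz0[topA$name == "CA", , drop = FALSE]
  cc <- sweep(ca, 2L, colMeans(ca))
  ax <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1L]
  if (sum(ax * (ca[n_res, ] - ca[1L, ])) < 0) ax <- -ax
  R <- .rotation_between(ax, c(1, 0, 0))
  xyzA <- sweep(xyz0 %*% t(R), 2L, colMeans(ca %*% t(R)))
  flip <- diag(c(-1, 1, -1))            # 180 degrees about y
  xyzB <- sweep(xyzA %*% t(flip), 2L, c(shift, separation, 0), `+`)
  topB <- topA
  topB$chain_id <- "B"
  top <- rbind(topA, topB)
  top$serial <- seq_len(nrow(top))
  trajectory(top, rbind(xyzA, xyzB))
}

.coil_schedule <- function(n) {
  data.frame(phi = stats::runif(n, -150, -60),
             psi = stats::runif(n, 60, 180),
             omega = rep(180, n))
}

.build_conformer <- function(class, seq1) {
  n <- length(seq1)
  switch(class,
         helix = build_backbone(seq1, dihedral_schedule("alpha", n)),
         extended = build_backbone(seq1, dihedral_schedule("beta", n)),
         U = build_hairpin(paste(seq1, collapse = "")),
         coil = build_backbone(seq1, .coil_schedule(n)),
         stop("unknown conformer class: ", class))
}

# Largest-remainder apportionment of n frames to mixture weights.
.mixture_counts <- function(weights, n) {
  w <- weights / sum(weights)
  raw <- w * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_idx <- order(raw - counts, decreasing = TRUE)
    counts[order_idx[seq_len(rem)]] <- counts[order_idx[seq_len(rem)]] + 1L
  }
  as.integer(counts)
}

# Sidechain donor/acceptor atom used for scripted contacts, per residue.
.SCRIPT_DONOR <- c(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                   GLN = "NE2", LYS = "NZ", ARG = "NE", HIS = "NE2",
                   TRP = "NE1", CYS = "SG")
.SCRIPT_ACCEPTOR <- c(ASP = "OD1", GLU = "OE1", ASN = "OD1", GLN = "OE1",
                      SER = "OG", THR = "OG1", TYR = "OH", HIS = "ND1",
                      MET = "SD")

#' Generate a synthetic monomer ensemble
#'
#' Frames are drawn from a mixture of conformer classes (`helix`,
#' `U` hairpin, `extended`, `coil`) using exact largest-remainder counts in
#' a seed-determined order, then perturbed by isotropic Gaussian noise
#' (independent N(0, sigma^2) on every coordinate). Optional scripted
#' hydrogen-bond contacts add sidechain donor/acceptor pseudo-atoms placed
#' exactly (no noise) at bonding geometry in a deterministic, evenly
#' spaced subset of frames covering the requested fraction.
#'
#' @param n_frames number of frames (>= 1).
#' @param weights named non-negative weights over
#'   `c(helix, U, extended, coil)`; missing names mean 0.
#' @param sigma per-coordinate noise standard deviation, Angstrom.
#' @param seed RNG seed.
#' @param mutation optional point mutation(s), e.g. `"E22Q"`.
#' @param contacts optional list of scripted contacts, each a list with
#'   `donor_res`, `acceptor_res`, `fraction` (0..1).
#' @return a [trajectory()]; attribute `ground_truth` holds per-frame class
#'   labels and the scripted-contact frame schedule.
#' @export
make_monomer_ensemble <- function(n_frames = 100L,
                                  weights = c(helix = 1/3, U = 1/3,
                                              coil = 1/3),
                                  sigma = 1.0, seed = 1L,
                                  mutation = NULL, contacts = NULL) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  full <- c(helix = 0, U = 0, extended = 0, coil = 0)
  full[names(weights)] <- weights
  if (any(full < 0) || sum(full) <= 0) stop("invalid mixture weights")
  seq1 <- strsplit(ab42_sequence(mutation), "")[[1L]]

  counts <- .mixture_counts(full, n_frames)
  labels <- rep(names(full), counts)
  set.seed(seed)
  labels <- labels[sample.int(n_frames)]

  templates <- list()
  for (cl in unique(labels))
    if (cl != "coil") templates[[cl]] <- .build_conformer(cl, seq1)
  base_top <- if (length(templates)) templates[[1L]]$topology else
    .build_conformer("coil", seq1)$topology

  # scripted-contact pseudo-atom rows appended to the topology
  contact_rows <- NULL
  schedules <- list()
  if (!is.null(contacts)) {
    extra <- list()
    for (ci in seq_along(contacts)) {
      cc <- contacts[[ci]]
      dres3 <- aa_three(seq1[cc$donor_res])
      ares3 <- aa_three(seq1[cc$acceptor_res])
      datom <- .SCRIPT_DONOR[dres3]
      aatom <- .SCRIPT_ACCEPTOR[ares3]
      if (is.na(datom)) stop(dres3, cc$donor_res, " has no sidechain donor")
      if (is.na(aatom)) stop(ares3, cc$acceptor_res,
                             " has no sidechain acceptor")
      extra[[ci]] <- data.frame(
        serial = 0L,
        name = c(aatom, datom, "HX"),
        res_name = c(ares3, dres3, dres3),
        chain_id = "A",
        res_seq = c(cc$acceptor_res, cc$donor_res, cc$donor_res),
        element = c(infer_element(aatom), infer_element(datom), "H"),
        stringsAsFactors = FALSE)
      i <- seq_len(n_frames)
      on <- floor(i * cc$fraction) - floor((i - 1L) * cc$fraction) >= 1
      schedules[[ci]] <- list(donor_res = cc$donor_res,
                              acceptor_res = cc$acceptor_res,
                              fraction = cc$fraction, on_frames = which(on))
    }
    contact_rows <- do.call(rbind, extra)
    contact_rows$mass <- .element_mass(contact_rows$element)
  }

  top <- base_top
  if (!is.null(contact_rows)) top <- rbind(top, contact_rows)
  top$serial <- seq_len(nrow(top))

  anchor <- function(xyz, res, base_topology) {
    # attachment point: CB extended away from CA (CA itself for Gly)
    rows <- which(base_topology$res_seq == res)
    cb <- rows[base_topology$name[rows] == "CB"]
    ca <- rows[base_topology$name[rows] == "CA"]
    if (length(cb)) xyz[cb, ] + 1.4 * .unit(xyz[cb, ] - xyz[ca, ])
    else xyz[ca, ]
  }

  nb <- nrow(base_top)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    cl <- labels[f]
    xyz <- if (cl == "coil")
      .build_conformer("coil", seq1)$coords[, , 1L, drop = TRUE]
    else templates[[cl]]$coords[, , 1L, drop = TRUE]
    if (sigma > 0) xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, sigma),
                                       ncol = 3L)
    if (!is.null(contact_rows)) {
      pseudo <- matrix(NA_real_, nrow(contact_rows), 3L)
      for (ci in seq_along(schedules)) {
        sch <- schedules[[ci]]
        A <- anchor(xyz, sch$acceptor_res, base_top)
        Dref <- anchor(xyz, sch$donor_res, base_top)
        dir_da <- .unit(Dref - A)
        on <- f %in% sch$on_frames
        D <- A + (if (on) 2.9 else 6.0) * dir_da
        H <- if (on) D - 1.0 * dir_da else D + 1.0 * dir_da
        pseudo[3L * (ci - 1L) + 1:3, ] <- rbind(A, D, H)
      }
      xyz <- rbind(xyz, pseudo)
    }
    frames[[f]] <- xyz
  }
  traj <- trajectory(top, frames)
  attr(traj, "ground_truth") <- list(
    classes = data.frame(frame = seq_len(n_frames), class = labels,
                         stringsAsFactors = FALSE),
    contacts = schedules,
    sigma = sigma, seed = seed, weights = full)
  traj
}

# S-shaped strand template: C-alpha positions in the z = 0 plane for
# residues `res_start`..42. Three straight segments (3.5 A per residue)
# joined by two tight turns; the N-terminal tail below residue 11 extends
# the first segment.
.s_template_ca <- function(res_start = 11L) {
  res <- seq(res_start, 42L)
  ca <- matrix(NA_real_, length(res), 3L)
  pos <- function(r) {
    if (r <= 22L) c(3.5 * (r - 11L), 0, 0)
    else if (r <= 26L) {                     # turn 23-26 around (38.5, 4.5)
      a <- (-90 + (r - 22L) * 36) * .deg
      c(38.5 + 4.5 * cos(a), 4.5 + 4.5 * sin(a), 0)
    } else if (r <= 34L) c(38.5 - 3.5 * (r - 27L), 9, 0)
    else if (r <= 37L) {                     # turn 35-37 around (14, 13.5)
      a <- (-90 - (r - 34L) * 45) * .deg
      c(14 + 4.5 * cos(a), 13.5 + 4.5 * sin(a), 0)
    } else c(14 + 3.5 * (r - 38L), 18, 0)
  }
  for (k in seq_along(res)) ca[k, ] <- pos(res[k])
  list(res = res, ca = ca)
}

# Hinge: rotate CA of residues <= hinge_res_max about the vertical (z)
# axis through the pivot residue's CA by theta radians.
.apply_hinge <- function(tmpl, theta, hinge_res_max = 21L, pivot_res = 28L) {
  ca <- tmpl$ca
  piv <- ca[match(pivot_res, tmpl$res), ]
  sel <- tmpl$res <= hinge_res_max
  if (!any(sel)) return(tmpl)
  rel <- sweep(ca[sel, , drop = FALSE], 2L, piv)
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), 3L, 3L)
  ca[sel, ] <- sweep(rel %*% t(R), 2L, piv, `+`)
  tmpl$ca <- ca
  tmpl
}

.template_dve <- function(tmpl, ve = c(11L, 39L)) {
  i <- match(ve[1L], tmpl$res); j <- match(ve[2L], tmpl$res)
  if (is.na(i) || is.na(j)) stop("template lacks residues ",
                                 ve[1L], "/", ve[2L])
  sqrt(sum((tmpl$ca[i, ] - tmpl$ca[j, ])^2))
}

# Solve the hinge angle whose template D_VE equals `target`; root closest
# to zero on a +-143 degree sweep. Errors when unreachable.
.solve_hinge <- function(tmpl, target) {
  f <- function(th) .template_dve(.apply_hinge(tmpl, th)) - target
  grid <- seq(-2.5, 2.5, by = 0.05)
  vals <- vapply(grid, f, numeric(1L))
  sgn <- sign(vals)
  flips <- which(sgn[-1L] * sgn[-length(sgn)] <= 0 & sgn[-length(sgn)] != 0)
  if (!length(flips)) {
    if (any(vals == 0)) return(grid[which(vals == 0)[1L]])
    stop("fan target D_VE = ", target,
         " A unreachable by the hinge (template range ",
         sprintf("%.1f-%.1f", min(vals) + target, max(vals) + target), " A)")
  }
  roots <- vapply(flips, function(k) {
    stats::uniroot(f, c(grid[k], grid[k + 1L]), tol = 1e-10)$root
  }, numeric(1L))
  roots[which.min(abs(roots))]
}

#' Generate a synthetic S-shaped fibril stack
#'
#' An S-shaped strand template (residues `res_start`..42 of the Abeta
#' sequence) is replicated `n_strands` times along the z axis at the given
#' rise, in register. A fan schedule rotates each strand's N-terminal half
#' (residues <= 21) about the vertical axis through residue 28, with the
#' hinge angle solved per frame so the template Glu11-Val39 distance hits
#' the requested per-frame `fan_targets`. Dissociation offsets displace
#' whole strands along z. Isotropic Gaussian noise is added last.
#'
#' @param n_strands number of strands (chains A, B, ...; >= 2, <= 26).
#' @param n_frames number of frames.
#' @param rise inter-strand rise in Angstrom (default 4.8, the canonical
#'   cross-beta stacking distance).
#' @param res_start first residue of each strand (default 11, the 2MXU
#'   convention).
#' @param dve0 resting Glu11-Val39 distance of the strand template in
#'   Angstrom, realised by a fixed pre-opening of the hinge (default 32.1,
#'   the wild-type resting value; NULL keeps the raw S-template geometry).
#' @param fan_targets optional numeric vector (length `n_frames`) of target
#'   template D_VE values in Angstrom.
#' @param dissociation optional `n_strands x n_frames` matrix of axial
#'   offsets in Angstrom, or a list with `strand`, `offset`, `from_frame`:
#'   the convenience form ruptures the stack below `strand`, shifting that
#'   strand and every strand above it by `offset` from `from_frame` on, so
#'   only the one interstrand gap widens.
#' @param sigma per-coordinate noise SD in Angstrom (default 0: the stated
#'   world is a rigid crystal-like stack, noise is opt-in).
#' @param seed RNG seed (used only when `sigma > 0`).
#' @param mutation optional point mutation(s).
#' @return a [trajectory()]; attribute `ground_truth` carries the per-frame
#'   hinge angles, scheduled template D_VE, rise and offsets.
#' @export
make_fibril <- function(n_strands = 10L, n_frames = 1L, rise = 4.8,
                        res_start = 11L, dve0 = 32.1, fan_targets = NULL,
                        dissociation = NULL, sigma = 0, seed = 1L,
                        mutation = NULL) {
  if (n_strands < 2L) stop("need at least 2 strands")
  if (n_strands > 26L) stop("at most 26 strands (chain ids A-Z)")
  if (rise <= 0) stop("rise must be positive")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (!is.null(fan_targets) && length(fan_targets) != n_frames)
    stop("fan_targets length != n_frames")

  offsets <- matrix(0, n_strands, n_frames)
  if (!is.null(dissociation)) {
    if (is.matrix(dissociation)) {
      stopifnot(identical(dim(dissociation), dim(offsets)))
      offsets <- dissociation
    } else {
      fr <- dissociation$from_frame %||% 1L
      offsets[seq(dissociation$strand, n_strands),
              seq(fr, n_frames)] <- dissociation$offset
    }
  }

  seq1 <- strsplit(ab42_sequence(mutation), "")[[1L]]
  tmpl0 <- .s_template_ca(res_start)
  if (!is.null(dve0))
    tmpl0 <- .apply_hinge(tmpl0, .solve_hinge(tmpl0, dve0))
  seq3 <- aa_three(seq1[tmpl0$res])

  thetas <- numeric(n_frames)
  dve_sched <- rep(.template_dve(tmpl0), n_frames)
  if (!is.null(fan_targets)) {
    for (f in seq_len(n_frames)) thetas[f] <- .solve_hinge(tmpl0,
                                                           fan_targets[f])
    dve_sched <- fan_targets
  }

  chains <- LETTERS[seq_len(n_strands)]
  set.seed(seed)
  frames <- vector("list", n_frames)
  top <- NULL
  for (f in seq_len(n_frames)) {
    tmpl <- .apply_hinge(tmpl0, thetas[f])
    per_strand <- vector("list", n_strands)
    tops <- vector("list", n_strands)
    for (s in seq_len(n_strands)) {
      ca <- tmpl$ca
      ca[, 3L] <- ca[, 3L] + (s - 1L) * rise + offsets[s, f]
      bb <- .backbone_from_ca_trace(ca, seq3, res_start, chains[s])
      per_strand[[s]] <- bb$coords
      tops[[s]] <- bb$topology
    }
    xyz <- do.call(rbind, per_strand)
    if (sigma > 0) xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, sigma),
                                       ncol = 3L)
    frames[[f]] <- xyz
    if (f == 1L) {
      top <- do.call(rbind, tops)
      top$serial <- seq_len(nrow(top))
    }
  }
  traj <- trajectory(top, frames)
  attr(traj, "ground_truth") <- list(
    rise = rise, n_strands = n_strands,
    theta = thetas, template_dve = dve_sched,
    offsets = offsets, sigma = sigma, seed = seed)
  traj
}
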