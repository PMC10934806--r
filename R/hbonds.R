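# Geometric hydrogen-bond detection and per-residue-pair frequency tables.
#
# Defaults (donor-acceptor distance <= 3.5 A, D-H...A angle >= 135 deg)
# are the common MD-analysis criteria; the source data never states its
# own, so both are configurable. Sidechain donors/acceptors are typed from
# residue templates for the 20 standard residues, so salt bridges such as
# Glu22-Lys28 and sidechain contacts such as Asp23-Ser26 pass through the
# same geometric definition. Pairs aggregate at residue level: any
# donor/acceptor atom pair bonds the residue pair once per frame.

.DONOR_ATOMS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", CYS = "SG"
)

.ACCEPTOR_ATOMS <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

.typed_atoms <- function(topology, templates) {
  idx <- which(topology$name %in% templates$backbone)
  for (res3 in setdiff(names(templates), "backbone")) {
    idx <- c(idx, which(topology$res_name == res3 &
                          topology$name %in% templates[[res3]]))
  }
  sort(unique(idx))
}

#' Default donor / acceptor heavy-atom selections
#' @param traj a `Trajectory`.
#' @return integer atom indices.
#' @rdname hbond_selections
#' @export
default_donors <- function(traj) .typed_atoms(traj$topology, .DONOR_ATOMS)

#' @rdname hbond_selections
#' @export
default_acceptors <- function(traj) .typed_atoms(traj$topology,
                                                 .ACCEPTOR_ATOMS)

.angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) / .deg
}

#' Detect geometric hydrogen bonds in one frame
#'
#' Records every donor/H/acceptor triple with `d(D, A) <= d_cut` and
#' `angle(D-H-A) >= a_cut`. Backbone amide hydrogens are always rebuilt
#' from heavy atoms; explicit `H*` atoms within 1.3 A of a donor are used
#' for sidechain donors. Pairs within one residue are skipped, and
#' backbone N(i)-O(i +/- 1) pairs are excluded when `backbone_exclusion`
#' is set.
#'
#' @param frame numeric `n_atoms x 3` matrix.
#' @param topology topology data.frame.
#' @param donors,acceptors integer atom indices (defaults: template-typed
#'   donors/acceptors).
#' @param d_cut donor-acceptor distance cutoff, Angstrom.
#' @param a_cut D-H...A angle cutoff, degrees.
#' @param backbone_exclusion drop adjacent backbone N-O pairs.
#' @return data.frame with columns `donor_res`, `donor_atom`,
#'   `acceptor_res`, `acceptor_atom`, `distance`, `angle`.
#' @export
detect_hbonds <- function(frame, topology, donors = NULL, acceptors = NULL,
                          d_cut = 3.5, a_cut = 135,
                          backbone_exclusion = TRUE) {
  if (d_cut <= 0 || a_cut <= 0) stop("cutoffs must be positive")
  if (is.null(donors)) donors <- .typed_atoms(topology, .DONOR_ATOMS)
  if (is.null(acceptors)) acceptors <- .typed_atoms(topology,
                                                    .ACCEPTOR_ATOMS)
  if (length(donors) == 0L) stop("empty donor set")
  if (length(acceptors) == 0L) stop("empty acceptor set")

  amideH <- place_amide_hydrogens(frame, topology)
  res_tab <- attr(amideH, "residues")
  res_key <- paste(topology$chain_id, topology$res_seq, sep = "|")
  amide_of <- match(res_key, paste(res_tab$chain_id, res_tab$res_seq,
                                   sep = "|"))

  is_h <- startsWith(topology$name, "H")
  h_idx <- which(is_h)

  obs <- list()
  for (d in donors) {
    # hydrogens attached to this donor
    hs <- list()
    if (topology$name[d] == "N") {
      hrow <- amideH[amide_of[d], ]
      if (!any(is.na(hrow))) hs <- list(hrow)
    } else {
      near <- h_idx[res_key[h_idx] == res_key[d]]
      for (h in near) {
        if (sqrt(sum((frame[h, ] - frame[d, ])^2)) <= 1.3)
          hs <- c(hs, list(frame[h, ]))
      }
    }
    if (!length(hs)) next
    for (a in acceptors) {
      if (res_key[a] == res_key[d]) next
      if (backbone_exclusion && topology$name[d] == "N" &&
          topology$name[a] == "O" &&
          topology$chain_id[a] == topology$chain_id[d] &&
          abs(topology$res_seq[a] - topology$res_seq[d]) == 1L) next
      dist <- sqrt(sum((frame[a, ] - frame[d, ])^2))
      if (dist > d_cut) next
      for (hpos in hs) {
        ang <- .angle_deg(frame[d, ], hpos, frame[a, ])
        if (ang >= a_cut) {
          obs[[length(obs) + 1L]] <- data.frame(
            donor_res = topology$res_seq[d],
            donor_atom = topology$name[d],
            acceptor_res = topology$res_seq[a],
            acceptor_atom = topology$name[a],
            distance = dist, angle = ang,
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (!length(obs))
    return(data.frame(donor_res = integer(), donor_atom = character(),
                      acceptor_res = integer(), acceptor_atom = character(),
                      distance = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, obs)
}

#' Residue-pair hydrogen-bond frequency table over a trajectory
#'
#' `af(pair) = 100 * (#frames with >= 1 bond between the residues) /
#' n_frames`; both residues must lie in `region`. Pairs are canonical
#' (smaller residue number first) and unordered.
#'
#' @param traj a `Trajectory` (single chain).
#' @param region inclusive residue range `c(lo, hi)`; default 16-42, the
#'   turn-bearing region used for monomer contact tables.
#' @param ... passed to [detect_hbonds()].
#' @return data.frame of class `HBondFrequencyTable` with columns `res_i`,
#'   `res_j`, `af`; attribute `n_frames`.
#' @export
hbond_frequencies <- function(traj, region = c(16L, 42L), ...) {
  nf <- n_frames(traj)
  if (nf == 0L) stop("zero frames")
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    hb <- detect_hbonds(get_frame(traj, f), traj$topology, ...)
    if (!nrow(hb)) next
    keep <- hb$donor_res >= region[1L] & hb$donor_res <= region[2L] &
      hb$acceptor_res >= region[1L] & hb$acceptor_res <= region[2L]
    hb <- hb[keep, , drop = FALSE]
    if (!nrow(hb)) next
    pair <- unique(paste(pmin(hb$donor_res, hb$acceptor_res),
                         pmax(hb$donor_res, hb$acceptor_res), sep = "-"))
    for (p in pair)
      assign(p, (if (exists(p, counts)) get(p, counts) else 0L) + 1L,
             counts)
  }
  keys <- ls(counts)
  if (length(keys)) {
    ij <- do.call(rbind, strsplit(keys, "-"))
    tab <- data.frame(res_i = as.integer(ij[, 1L]),
                      res_j = as.integer(ij[, 2L]),
                      af = 100 * vapply(keys, get, numeric(1L),
                                        envir = counts) / nf,
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$af, tab$res_i, tab$res_j), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(res_i = integer(), res_j = integer(), af = numeric())
  }
  structure(tab, class = c("HBondFrequencyTable", "data.frame"),
            n_frames = nf)
}

#' Filter a frequency table at a minimum average frequency
#'
#' Keeps pairs with `af >= min_af` (default 10 percent), sorted by `af`
#' descending. An empty result renders as the literal token `"None"` in
#' reports (see [format_hb_contacts()]).
#'
#' @param table an `HBondFrequencyTable`.
#' @param min_af threshold in percent.
#' @return filtered `HBondFrequencyTable`.
#' @export
turn_contact_filter <- function(table, min_af = 10) {
  out <- table[table$af >= min_af, , drop = FALSE]
  out <- out[order(-out$af, out$res_i, out$res_j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("HBondFrequencyTable", "data.frame"),
            n_frames = attr(table, "n_frames"))
}

#' Render hydrogen-bond contacts for a report
#' @param table an `HBondFrequencyTable` (typically filtered).
#' @param traj optional `Trajectory` used to name residues.
#' @return character vector like `"Asp23-Ser26 (af 47.0%)"`, or `"None"`.
#' @export
format_hb_contacts <- function(table, traj = NULL) {
  if (!nrow(table)) return("None")
  nm <- function(res) {
    if (is.null(traj)) return(as.character(res))
    res3 <- traj$topology$res_name[match(res, traj$topology$res_seq)]
    paste0(substr(res3, 1, 1), tolower(substr(res3, 2, 3)), res)
  }
  sprintf("%s-%s (af %.1f%%)", nm(table$res_i), nm(table$res_j), table$af)
}
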