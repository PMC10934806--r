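# Three-class secondary structure (H/E/C) from backbone geometry.
#
# The assignment uses the Kabsch-Sander electrostatic hydrogen-bond energy
# with the minimal DSSP rules: an alpha-helix needs two consecutive
# i -> i+4 turns; a sheet residue sits in a parallel or antiparallel
# bridge (extended to ladders by adjacency of bridges). 3-10 and pi
# helices are NOT folded into H: the helix class here is strictly the
# alpha (i,i+4) pattern, matching content tables that report "alpha-helix"
# only. Amide hydrogens are always rebuilt from heavy atoms; hydrogens in
# the input file are ignored for this purpose.

.KS_COUPLING <- 27.888   # kcal/mol * Angstrom, q1*q2*332 factor
.KS_CUTOFF <- -0.5       # kcal/mol, bond threshold
.KS_CLASH <- 0.5         # Angstrom, minimum sane distance

#' Kabsch-Sander hydrogen-bond energy
#'
#' `E = 27.888 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol for a
#' C=O ... H-N geometry. Distances below the 0.5 Angstrom clash guard
#' return `+Inf` (no bond) with a warning.
#'
#' @param C,O,N,H numeric length-3 coordinates (Angstrom) of the acceptor
#'   carbonyl C and O and the donor N and its amide H.
#' @return energy in kcal/mol.
#' @export
ks_hbond_energy <- function(C, O, N, H) {
  r <- c(ON = sqrt(sum((O - N)^2)), CH = sqrt(sum((C - H)^2)),
         OH = sqrt(sum((O - H)^2)), CN = sqrt(sum((C - N)^2)))
  if (any(!is.finite(r))) stop("non-finite coordinates")
  if (any(r < .KS_CLASH)) {
    warning("clash guard: donor/acceptor atoms closer than ",
            .KS_CLASH, " A; no bond recorded")
    return(Inf)
  }
  .KS_COUPLING * (1 / r["ON"] + 1 / r["CH"] - 1 / r["OH"] - 1 / r["CN"])[[1L]]
}

# Residue table: one row per residue in topology order with backbone atom
# row indices and a linked-to-previous flag (same chain, consecutive
# author numbers).
.residue_table <- function(topology) {
  key <- paste(topology$chain_id, topology$res_seq, sep = "|")
  first <- !duplicated(key)
  res <- data.frame(chain_id = topology$chain_id[first],
                    res_seq = topology$res_seq[first],
                    res_name = topology$res_name[first],
                    stringsAsFactors = FALSE)
  idx_of <- function(nm) {
    i <- integer(nrow(res))
    hit <- topology$name == nm
    m <- match(paste(res$chain_id, res$res_seq, sep = "|"),
               key[hit])
    ifelse(is.na(m), NA_integer_, which(hit)[m])
  }
  res$iN <- idx_of("N"); res$iCA <- idx_of("CA")
  res$iC <- idx_of("C"); res$iO <- idx_of("O")
  res$linked <- c(FALSE,
                  res$chain_id[-1L] == res$chain_id[-nrow(res)] &
                    res$res_seq[-1L] == res$res_seq[-nrow(res)] + 1L)
  res
}

#' Rebuild backbone amide hydrogens
#'
#' H is placed 1.00 Angstrom from N, in the C(i-1)-N(i)-CA(i) plane,
#' opposite the bisector of the two N bonds (the standard trans-amide
#' construction). The chain-starting residue of each chain and prolines
#' get no H.
#'
#' @param frame numeric `n_atoms x 3` coordinate matrix.
#' @param topology topology data.frame of the trajectory.
#' @return numeric `n_residues x 3` matrix of H coordinates (NA rows where
#'   no H exists), with the residue table as attribute `residues`.
#' @export
place_amide_hydrogens <- function(frame, topology) {
  res <- .residue_table(topology)
  missing_bb <- which(is.na(res$iN) | is.na(res$iCA) | is.na(res$iC) |
                        is.na(res$iO))
  if (length(missing_bb))
    stop("missing backbone atoms for residue ",
         res$chain_id[missing_bb[1L]], res$res_seq[missing_bb[1L]])
  H <- matrix(NA_real_, nrow(res), 3L)
  for (i in seq_len(nrow(res))) {
    if (!res$linked[i] || res$res_name[i] == "PRO") next
    N <- frame[res$iN[i], ]
    CA <- frame[res$iCA[i], ]
    Cprev <- frame[res$iC[i - 1L], ]
    u1 <- .unit(N - Cprev)
    u2 <- .unit(N - CA)
    H[i, ] <- N + 1.00 * .unit(u1 + u2)
  }
  attr(H, "residues") <- res
  H
}

# Kabsch-Sander hydrogen-bond matrix: hb[i, j] TRUE when N-H of residue i
# donates to C=O of residue j. A 9 A CA-CA prefilter bounds the pair list.
.ks_hbond_matrix <- function(frame, res, H) {
  n <- nrow(res)
  hb <- matrix(FALSE, n, n)
  ca <- frame[res$iCA, , drop = FALSE]
  for (i in seq_len(n)) {
    if (any(is.na(H[i, ]))) next
    d2 <- rowSums(sweep(ca, 2L, ca[i, ])^2)
    for (j in which(d2 <= 81)) {
      if (j == i) next
      e <- suppressWarnings(
        ks_hbond_energy(frame[res$iC[j], ], frame[res$iO[j], ],
                        frame[res$iN[i], ], H[i, ]))
      if (is.finite(e) && e < .KS_CUTOFF) hb[i, j] <- TRUE
    }
  }
  hb
}

#' Assign per-residue secondary structure for one frame
#'
#' @param frame numeric `n_atoms x 3` matrix.
#' @param topology topology data.frame.
#' @return character vector over `{"H","E","C"}`, one per residue (in
#'   topology residue order), with the residue table as attribute
#'   `residues`.
#' @export
assign_secstruct <- function(frame, topology) {
  res <- .residue_table(topology)
  n <- nrow(res)
  lab <- rep("C", n)
  if (n < 5L) {
    attr(lab, "residues") <- res
    return(lab)
  }
  H <- place_amide_hydrogens(frame, topology)
  hb <- .ks_hbond_matrix(frame, res, H)

  # stretch of residues k..k+4 all consecutively linked within one chain
  run_ok <- function(k, len) {
    if (k < 1L || k + len > n) return(FALSE)
    all(res$linked[(k + 1L):(k + len)])
  }
  turn4 <- vapply(seq_len(n), function(k) {
    run_ok(k, 4L) && hb[k + 4L, k]
  }, logical(1L))

  for (k in seq_len(n - 1L)) {
    if (turn4[k] && turn4[k + 1L])
      lab[(k + 1L):(k + 4L)] <- "H"
  }

  # bridge patterns; i, j non-adjacent in the global residue order
  is_e <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 2L) next
      para <- (i > 1L && i < n && res$linked[i] && res$linked[i + 1L] &&
                 hb[j, i - 1L] && hb[i + 1L, j]) ||
              (j > 1L && j < n && res$linked[j] && res$linked[j + 1L] &&
                 hb[i, j - 1L] && hb[j + 1L, i])
      anti <- (hb[i, j] && hb[j, i]) ||
              (i > 1L && i < n && j > 1L && j < n &&
                 res$linked[i] && res$linked[i + 1L] &&
                 res$linked[j] && res$linked[j + 1L] &&
                 hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (para || anti) { is_e[i] <- TRUE; is_e[j] <- TRUE }
    }
  }
  lab[is_e & lab != "H"] <- "E"
  attr(lab, "residues") <- res
  lab
}

#' Secondary-structure timeline over a trajectory
#'
#' Column f holds the per-residue assignment of frame f. Content
#' percentages pool residue-frames: `H% = 100 * #H / (n_res * n_frames)`,
#' and likewise for E and C, so the three always sum to 100.
#'
#' @param traj a `Trajectory`.
#' @return object of class `SSTimeline`: list with `labels`
#'   (`n_res x n_frames` character matrix), `residues` (chain/number
#'   table), `content` (named percentages H/E/C).
#' @export
ss_timeline <- function(traj) {
  nf <- n_frames(traj)
  first <- assign_secstruct(get_frame(traj, 1L), traj$topology)
  res <- attr(first, "residues")
  labels <- matrix("C", nrow(res), nf)
  labels[, 1L] <- as.character(first)
  if (nf > 1L) for (f in seq(2L, nf))
    labels[, f] <- as.character(assign_secstruct(get_frame(traj, f),
                                                 traj$topology))
  total <- length(labels)
  content <- c(H = 100 * sum(labels == "H") / total,
               E = 100 * sum(labels == "E") / total,
               C = 100 * sum(labels == "C") / total)
  structure(list(labels = labels,
                 residues = res[, c("chain_id", "res_seq", "res_name")],
                 content = content),
            class = "SSTimeline")
}

#' @export
print.SSTimeline <- function(x, ...) {
  cat(sprintf("SSTimeline: %d residues x %d frames | H %.1f%%  E %.1f%%  C %.1f%%\n",
              nrow(x$labels), ncol(x$labels),
              x$content["H"], x$content["E"], x$content["C"]))
  invisible(x)
}

#' Write an SSTimeline as TSV (rows = residues, cols = frames)
#' @param tl an `SSTimeline`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeline_tsv <- function(tl, path) {
  df <- data.frame(chain = tl$residues$chain_id,
                   res_seq = tl$residues$res_seq,
                   tl$labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("chain", "res_seq", paste0("f", seq_len(ncol(tl$labels))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
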