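# Multi-model PDB reading/writing and atom selections.
#
# Coordinates are in Angstrom throughout. Residue numbering is the 1-based
# author numbering of the Abeta42 peptide (Asp1 ... Ala42); fibril chains
# built on the 2MXU topology may start at residue 11. The reader never
# renumbers.

.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971
)

.SOLVENT_RESNAMES <- c(
  "HOH", "WAT", "TIP", "TIP3", "SOL", "SPC",
  "NA", "NA+", "CL", "CL-", "K", "K+", "MG", "ZN", "CU", "AL", "CIM", "CIP"
)

.AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

.AA1 <- structure(names(.AA3), names = unname(.AA3))

#' Infer an element symbol from a PDB atom name
#'
#' Leading digits are stripped (e.g. "1HG1" is hydrogen); otherwise the first
#' alphabetic character decides, so "CA" is carbon (the calcium ion, if ever
#' present, arrives as a HETATM solvent record and is stripped on read).
#'
#' @param name character vector of PDB atom names.
#' @return character vector of element symbols.
#' @keywords internal
infer_element <- function(name) {
  nm <- gsub("^[0-9]+", "", trimws(name))
  toupper(substr(nm, 1L, 1L))
}

.element_mass <- function(element) {
  m <- .ELEMENT_MASS[toupper(element)]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Construct a Trajectory
#'
#' A `Trajectory` bundles one atom topology with an ordered set of frames
#' that share it: `topology` is a data.frame with columns `serial`, `name`,
#' `res_name`, `chain_id`, `res_seq`, `element`, `mass`, and `coords` is an
#' `n_atoms x 3 x n_frames` array in Angstrom.
#'
#' @param topology data.frame as described above.
#' @param coords numeric array `n_atoms x 3 x n_frames`, or a list of
#'   `n_atoms x 3` matrices, or a single matrix (one frame).
#' @return an object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords) {
  if (is.matrix(coords)) coords <- list(coords)
  if (is.list(coords)) {
    coords <- array(unlist(coords, use.names = FALSE),
                    dim = c(nrow(coords[[1L]]), 3L, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  if (dim(coords)[3L] < 1L) stop("Trajectory needs at least one frame")
  if (dim(coords)[1L] < 1L) stop("Trajectory needs at least one atom")
  if (dim(coords)[1L] != nrow(topology))
    stop("coordinate rows (", dim(coords)[1L], ") != topology atoms (",
         nrow(topology), ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  needed <- c("serial", "name", "res_name", "chain_id", "res_seq",
              "element", "mass")
  missing_cols <- setdiff(needed, names(topology))
  if (length(missing_cols))
    stop("topology lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(topology$mass <= 0)) stop("non-positive atomic mass in topology")
  structure(list(topology = topology, coords = coords), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frame(s), chains %s\n",
              n_atoms(x), n_frames(x),
              paste(unique(x$topology$chain_id), collapse = "")))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Number of atoms in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer.
#' @export
n_atoms <- function(traj) dim(traj$coords)[1L]

#' Extract one frame as an n_atoms x 3 matrix
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return numeric matrix `n_atoms x 3`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

.parse_atom_lines <- function(lines, line_numbers) {
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(lines, 31, 38))
  y <- num(substr(lines, 39, 46))
  z <- num(substr(lines, 47, 54))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("unparseable ATOM record at line ", line_numbers[bad[1L]])
  occ <- num(substr(lines, 55, 60))
  occ[is.na(occ)] <- 1
  element <- trimws(substr(lines, 77, 78))
  name <- trimws(substr(lines, 13, 16))
  blank <- element == ""
  element[blank] <- infer_element(name[blank])
  data.frame(
    serial = suppressWarnings(as.integer(substr(lines, 7, 11))),
    name = name,
    altloc = substr(lines, 17, 17),
    res_name = trimws(substr(lines, 18, 20)),
    chain_id = substr(lines, 22, 22),
    res_seq = suppressWarnings(as.integer(substr(lines, 23, 26))),
    icode = substr(lines, 27, 27),
    x = x, y = y, z = z, occ = occ,
    element = element,
    stringsAsFactors = FALSE
  )
}

.resolve_altloc <- function(df) {
  if (all(df$altloc %in% c(" ", ""))) return(df)
  key <- paste(df$chain_id, df$res_seq, df$icode, df$name, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- df[idx, ]
    best <- max(sub$occ)
    cand <- idx[sub$occ == best]
    if (length(cand) > 1L) {
      a <- cand[df$altloc[cand] == "A"]
      if (length(a)) cand <- a
    }
    cand[1L]
  }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

#' Read a multi-model PDB file as a Trajectory
#'
#' One `Frame` per `MODEL` record (a file without `MODEL` records yields a
#' single-frame trajectory). Alternate locations are resolved by keeping the
#' highest-occupancy copy (ties prefer altloc `A`); solvent and monoatomic
#' ion records are stripped by default; the element column is inferred from
#' the atom name when absent. All models must present the same atoms, in the
#' same order, as the first model.
#'
#' @param path PDB file path.
#' @param strip_solvent drop water/ion residues (default TRUE).
#' @return a [trajectory()] object.
#' @export
read_pdb_models <- function(path, strip_solvent = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) {
    groups <- list(which(is_atom))
  } else {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) < length(model_starts))
      ends <- c(ends, length(lines))
    groups <- lapply(seq_along(model_starts), function(k) {
      span <- seq(model_starts[k], ends[k])
      span[is_atom[span]]
    })
  }
  groups <- Filter(length, groups)
  if (length(groups) == 0L) stop("no ATOM records in ", path)

  frames <- vector("list", length(groups))
  topo <- NULL
  for (k in seq_along(groups)) {
    df <- .parse_atom_lines(lines[groups[[k]]], groups[[k]])
    df <- .resolve_altloc(df)
    if (strip_solvent) df <- df[!(df$res_name %in% .SOLVENT_RESNAMES), ,
                                drop = FALSE]
    if (k == 1L) {
      topo <- df
    } else {
      if (nrow(df) != nrow(topo) ||
          !all(df$name == topo$name) || !all(df$res_seq == topo$res_seq) ||
          !all(df$chain_id == topo$chain_id))
        stop("MODEL ", k, " atoms differ from MODEL 1 (", nrow(df), " vs ",
             nrow(topo), " atoms)")
    }
    frames[[k]] <- as.matrix(df[, c("x", "y", "z")])
  }
  topology <- data.frame(
    serial = topo$serial,
    name = topo$name,
    res_name = topo$res_name,
    chain_id = topo$chain_id,
    res_seq = topo$res_seq,
    element = topo$element,
    mass = .element_mass(topo$element),
    stringsAsFactors = FALSE
  )
  trajectory(topology, frames)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Fixed-width PDB v3.3 columns; coordinates are rounded to 3 decimals (the
#' format's precision), so a read/write round trip reproduces coordinates to
#' 5e-4 Angstrom and all identifiers exactly. `TER` records close each chain.
#'
#' @param traj a `Trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(traj, path) {
  if (!inherits(traj, "Trajectory")) stop("not a Trajectory")
  top <- traj$topology
  if (nrow(top) == 0L) stop("empty Trajectory")
  if (nrow(top) > 99999L) stop("PDB format limit: > 99999 atoms")
  name4 <- ifelse(nchar(top$name) >= 4L, substr(top$name, 1, 4),
                  sprintf("%-3s", top$name))
  name4 <- ifelse(nchar(top$name) >= 4L, name4, paste0(" ", name4))
  chain_end <- c(top$chain_id[-1L] != top$chain_id[-nrow(top)], TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f, drop = TRUE]
    writeLines(sprintf("MODEL     %4d", f), con)
    body <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(top)) %% 100000L, name4, top$res_name, top$chain_id,
      top$res_seq, xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, top$element
    )
    out <- character(0L)
    start <- 1L
    for (e in which(chain_end)) {
      out <- c(out, body[start:e], "TER")
      start <- e + 1L
    }
    writeLines(out, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms by chain, residue range and atom name
#'
#' Returns topology row indices (1-based), sorted, as a `Selection`. The
#' selection is deterministic in topology order and idempotent.
#'
#' @param traj a `Trajectory`.
#' @param chain single chain id, or NULL for all chains.
#' @param res_range inclusive 1-based `c(lo, hi)` in author numbering, or
#'   NULL.
#' @param atom_names character vector of PDB atom names, or NULL.
#' @param allow_empty permit an empty result (default FALSE).
#' @return integer vector of class `Selection`.
#' @export
select_atoms <- function(traj, chain = NULL, res_range = NULL,
                         atom_names = NULL, allow_empty = FALSE) {
  top <- traj$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(chain)) keep <- keep & top$chain_id %in% chain
  if (!is.null(res_range)) {
    stopifnot(length(res_range) == 2L, res_range[1L] <= res_range[2L])
    avail <- range(top$res_seq[keep])
    in_range <- top$res_seq >= res_range[1L] & top$res_seq <= res_range[2L]
    if (!any(keep & in_range))
      stop("res_range ", res_range[1L], "-", res_range[2L],
           " outside available range ", avail[1L], "-", avail[2L])
    keep <- keep & in_range
  }
  if (!is.null(atom_names)) keep <- keep & top$name %in% atom_names
  idx <- which(keep)
  if (length(idx) == 0L && !allow_empty)
    stop("empty selection (set allow_empty = TRUE to permit)")
  structure(idx,
            class = "Selection",
            expr = list(chain = chain, res_range = res_range,
                        atom_names = atom_names))
}

#' One-letter to three-letter residue code conversion
#' @param seq1 character scalar of 1-letter codes or vector of codes.
#' @return character vector of 3-letter codes.
#' @export
aa_three <- function(seq1) {
  if (length(seq1) == 1L && nchar(seq1) > 1L)
    seq1 <- strsplit(seq1, "")[[1L]]
  out <- .AA3[toupper(seq1)]
  if (anyNA(out)) stop("unknown residue code(s): ",
                       paste(unique(seq1[is.na(out)]), collapse = ", "))
  unname(out)
}

#' The wild-type Abeta42 sequence (Asp1 ... Ala42)
#'
#' @param mutation optional point mutation in `"E22Q"` notation; the familial
#'   variants E22Q (Dutch), E22G (Arctic), E22K (Italian) and D23N (Iowa) are
#'   the intended use, but any standard substitution is accepted.
#' @return character scalar, 42 one-letter codes.
#' @export
ab42_sequence <- function(mutation = NULL) {
  s <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
  if (!is.null(mutation)) {
    for (m in mutation) {
      wt <- substr(m, 1, 1)
      pos <- as.integer(substr(m, 2, nchar(m) - 1L))
      new <- substr(m, nchar(m), nchar(m))
      if (is.na(pos) || pos < 1L || pos > nchar(s))
        stop("bad mutation spec: ", m)
      if (substr(s, pos, pos) != wt)
        stop("mutation ", m, ": wild type at ", pos, " is ",
             substr(s, pos, pos))
      substr(s, pos, pos) <- new
    }
  }
  s
}
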