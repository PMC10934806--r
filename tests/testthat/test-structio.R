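test_that("multi-model PDB round trip preserves coordinates and identity", {
  hp <- build_hairpin()
  fb <- make_fibril(n_strands = 12L, n_frames = 2L)
  for (traj in list(hp, fb)) {
    path <- withr::local_tempfile(fileext = ".pdb")
    write_pdb_models(traj, path)
    back <- read_pdb_models(path)
    expect_equal(n_frames(back), n_frames(traj))
    expect_lt(max(abs(back$coords - traj$coords)), 5e-4)
    expect_identical(back$topology$res_seq, traj$topology$res_seq)
    expect_identical(back$topology$chain_id, traj$topology$chain_id)
    expect_identical(back$topology$name, traj$topology$name)
  }
  # chain order A..L preserved for the 12-strand fibril
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(fb, path)
  expect_identical(unique(read_pdb_models(path)$topology$chain_id),
                   LETTERS[1:12])
})

test_that("reader handles MODEL-less files, altlocs, and bad models", {
  h <- helix42()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(trajectory(h$topology,
                              list(get_frame(h, 1), get_frame(h, 1) + 1)),
                   path)
  tr <- read_pdb_models(path)
  expect_equal(n_frames(tr), 2L)
  expect_equal(length(unique(tr$topology$res_seq)), 42L)

  # strip MODEL/ENDMDL from a single-model file -> implicit single model
  write_pdb_models(h, path)
  lines <- readLines(path)
  writeLines(lines[!grepl("^(MODEL|ENDMDL)", lines)], path)
  expect_equal(n_frames(read_pdb_models(path)), 1L)

  # drop one atom from MODEL 2 -> hard error naming the model
  write_pdb_models(trajectory(h$topology,
                              list(get_frame(h, 1), get_frame(h, 1))),
                   path)
  lines <- readLines(path)
  second_model <- which(grepl("^MODEL", lines))[2]
  atom_in_2 <- which(seq_along(lines) > second_model &
                       startsWith(lines, "ATOM"))[1]
  writeLines(lines[-atom_in_2], path)
  expect_error(read_pdb_models(path), "MODEL 2")

  # altloc resolution: higher occupancy wins; tie prefers A
  alt <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C  BALA A   1       5.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  C  AALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "END")
  writeLines(alt, path)
  tr <- read_pdb_models(path)
  expect_equal(nrow(tr$topology), 3L)
  expect_equal(get_frame(tr, 1)[tr$topology$name == "CA", 1], 1.0)
  expect_equal(get_frame(tr, 1)[tr$topology$name == "C", 1], 2.0)
})

test_that("writer rejects empty and oversized systems", {
  h <- helix42()
  expect_error(trajectory(h$topology[0, ], matrix(0, 0, 3)))
  big_top <- h$topology[rep(1, 100000L), ]
  big <- trajectory(big_top, matrix(0, 100000L, 3))
  expect_error(write_pdb_models(big, tempfile()), "99999")
})

test_that("selections are counted, ordered and validated", {
  h <- helix42()
  sel <- select_atoms(h, res_range = c(16, 42), atom_names = "CA")
  expect_length(sel, 27L)
  expect_identical(as.integer(sel), sort(as.integer(sel)))
  # idempotent under re-selection
  expect_identical(as.integer(sel),
                   as.integer(select_atoms(h, res_range = c(16, 42),
                                           atom_names = "CA")))
  fb <- make_fibril(n_strands = 12L)
  expect_length(select_atoms(fb, chain = "C", res_range = c(33, 33),
                             atom_names = "CA"), 1L)
  expect_error(select_atoms(h, res_range = c(43, 50)), "available range")
  expect_error(select_atoms(h, atom_names = "XX"), "empty selection")
  expect_length(select_atoms(h, atom_names = "XX", allow_empty = TRUE), 0L)
})

test_that("selection is stable under atom permutation within residues", {
  h <- helix42()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(h, path)
  lines <- readLines(path)
  atom_idx <- which(startsWith(lines, "ATOM"))
  res <- as.integer(substr(lines[atom_idx], 23, 26))
  perm <- unlist(lapply(split(atom_idx, res), rev), use.names = FALSE)
  lines[sort(perm)] <- lines[perm]
  writeLines(lines, path)
  tr <- read_pdb_models(path)
  sel <- select_atoms(tr, res_range = c(16, 42), atom_names = "CA")
  expect_length(sel, 27L)
  expect_setequal(tr$topology$res_seq[sel], 16:42)
})

test_that("sequence utilities apply familial mutations", {
  expect_equal(nchar(ab42_sequence()), 42L)
  expect_equal(substr(ab42_sequence("E22K"), 22, 22), "K")
  expect_equal(substr(ab42_sequence("D23N"), 23, 23), "N")
  expect_error(ab42_sequence("E23Q"), "wild type")
})
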