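test_that("amide hydrogens follow the trans-amide construction", {
  h <- helix42()
  f <- get_frame(h, 1)
  H <- place_amide_hydrogens(f, h$topology)
  res <- attr(H, "residues")
  expect_true(all(is.na(H[1, ])))            # chain start has no amide H
  expect_equal(sum(!is.na(H[, 1])), 41L)     # 42 residues, no prolines
  for (i in c(2L, 20L, 42L)) {
    N <- f[res$iN[i], ]; CA <- f[res$iCA[i], ]
    expect_equal(sqrt(sum((H[i, ] - N)^2)), 1.00, tolerance = 1e-9)
    v1 <- H[i, ] - N; v2 <- CA - N
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(ang, 119, tolerance = 3)
  }
  # prolines get no H
  p <- build_backbone("APAAPA", dihedral_schedule("alpha", 6))
  Hp <- place_amide_hydrogens(get_frame(p, 1), p$topology)
  expect_true(all(is.na(Hp[c(1, 2, 5), ])))
  expect_equal(sum(!is.na(Hp[, 1])), 3L)
  # missing backbone atom is a named error
  broken <- h$topology[h$topology$name != "O" | h$topology$res_seq != 7, ]
  expect_error(place_amide_hydrogens(f[h$topology$name != "O" |
                                         h$topology$res_seq != 7, ],
                                     broken),
               "residue A7")
})

test_that("Kabsch-Sander energy matches hand evaluation", {
  # place four points realising the prescribed pairwise distances:
  # r_ON = 2.90, r_OH = 1.90, r_CN = 3.90, r_CH = 3.50
  N <- c(0, 0, 0)
  H <- c(1.0, 0, 0)
  O <- c((2.9^2 - 1.9^2 + 1) / 2, 0, 0)
  xC <- (3.9^2 - 3.5^2 + 1) / 2
  C <- c(xC, sqrt(3.9^2 - xC^2), 0)
  expect_equal(sqrt(sum((O - N)^2)), 2.9, tolerance = 1e-9)
  expect_equal(sqrt(sum((O - H)^2)), 1.9, tolerance = 1e-9)
  expect_equal(sqrt(sum((C - N)^2)), 3.9, tolerance = 1e-9)
  expect_equal(sqrt(sum((C - H)^2)), 3.5, tolerance = 1e-9)
  e <- ks_hbond_energy(C, O, N, H)
  expect_equal(e, 27.888 * (1 / 2.9 + 1 / 3.5 - 1 / 1.9 - 1 / 3.9),
               tolerance = 1e-9)
  expect_equal(e, -4.2441, tolerance = 1e-3)

  # all four distances equal (regular tetrahedron) -> zero by symmetry
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(ks_hbond_energy(tet[1, ], tet[2, ], tet[3, ], tet[4, ]), 0,
               tolerance = 1e-12)

  # distant acceptor -> weak interaction, no bond
  expect_lt(abs(ks_hbond_energy(c(10, 0, 0), c(10, 1, 0),
                                c(0, 0, 0), c(1, 0, 0))), 0.5)
  # clash guard
  expect_warning(e2 <- ks_hbond_energy(c(0.2, 0, 0), c(0.3, 0, 0),
                                       c(0, 0, 0), c(0.1, 0, 0)),
                 "clash")
  expect_identical(e2, Inf)
})

test_that("ideal helix and antiparallel sheet are assigned correctly", {
  h20 <- build_backbone(strrep("A", 20), dihedral_schedule("alpha", 20))
  lab <- assign_secstruct(get_frame(h20, 1), h20$topology)
  expect_gte(sum(lab == "H"), 16L)
  expect_equal(sum(lab == "E"), 0L)

  sheet <- build_antiparallel_sheet(n_res = 8L)
  labs <- assign_secstruct(get_frame(sheet, 1), sheet$topology)
  expect_gte(sum(labs == "E"), 10L)
  expect_equal(sum(labs == "H"), 0L)

  # assignment is invariant under rigid motion
  set.seed(9)
  R <- random_rotation()
  moved <- sweep(get_frame(sheet, 1) %*% t(R), 2, c(30, -12, 7), `+`)
  expect_identical(as.character(assign_secstruct(moved, sheet$topology)),
                   as.character(labs))

  # short chains are all coil
  tiny <- build_backbone("AAAA", dihedral_schedule("alpha", 4))
  expect_true(all(assign_secstruct(get_frame(tiny, 1), tiny$topology) == "C"))
})

test_that("assignment agrees with the reference DSSP implementation", {
  fixtures <- list(helix42(), build_antiparallel_sheet(n_res = 10L))
  for (tr in fixtures) {
    path <- withr::local_tempfile(fileext = ".pdb")
    write_pdb_models(tr, path)
    ref <- dssp_oracle(path)[, 1]
    ref[ref == "-"] <- "C"
    mine <- as.character(assign_secstruct(get_frame(tr, 1), tr$topology))
    expect_gte(mean(mine == ref), 0.95)
  }
})

test_that("random coil shows little helix or sheet", {
  hits <- replicate(5, {
    set.seed(sample.int(1e6, 1))
    tr <- make_monomer_ensemble(n_frames = 1, weights = c(coil = 1),
                                sigma = 0, seed = sample.int(1e6, 1))
    tl <- ss_timeline(tr)
    c(tl$content["H"], tl$content["E"])
  })
  expect_lt(mean(hits[1, ]), 10)
  expect_lt(mean(hits[2, ]), 10)
})

test_that("timeline pools residue-frames and tracks mixtures", {
  h <- helix42()
  f <- get_frame(h, 1)
  rep10 <- trajectory(h$topology, rep(list(f), 10))
  tl <- ss_timeline(rep10)
  expect_equal(sum(tl$content), 100, tolerance = 1e-9)
  # constant columns
  expect_true(all(apply(tl$labels, 1, function(r) length(unique(r)) == 1)))

  pure_h <- tl$content[["H"]]
  set.seed(4)
  coil_frames <- lapply(1:5, function(i)
    get_frame(make_monomer_ensemble(1, c(coil = 1), sigma = 0,
                                    seed = i), 1))
  # coil generator shares the helix topology (same atoms: backbone + CB)
  mix <- trajectory(h$topology, c(rep(list(f), 5), coil_frames))
  tl_mix <- ss_timeline(mix)
  coil_h <- mean(sapply(coil_frames, function(cf)
    100 * mean(assign_secstruct(cf, h$topology) == "H")))
  expect_equal(tl_mix$content[["H"]], (pure_h + coil_h) / 2, tolerance = 2)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_timeline_tsv(tl, tsv)
  got <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(nrow(got), 42L)
  expect_equal(ncol(got), 12L)  # chain, res_seq, 10 frames
})
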