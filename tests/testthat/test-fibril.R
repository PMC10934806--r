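test_that("topology inference is geometric, ordered and margin-aware", {
  fb <- make_fibril(n_strands = 10L)
  topo <- infer_fibril_topology(fb)
  expect_identical(topo$strand_chains, LETTERS[1:10])
  expect_identical(topo$core, 3:8)

  # relabelled chains give the same geometric strands
  fb2 <- fb
  fb2$topology$chain_id <- rev(LETTERS[1:10])[match(fb$topology$chain_id,
                                                    LETTERS[1:10])]
  topo2 <- infer_fibril_topology(fb2)
  fr <- get_frame(fb, 1)
  expect_equal(d_hc(fr, fb2$topology, topo2), d_hc(fr, fb$topology, topo))

  topo12 <- infer_fibril_topology(make_fibril(n_strands = 12L), margin = 2)
  expect_identical(topo12$core, 3:10)

  mono <- helix42()
  expect_error(infer_fibril_topology(mono), "2 chains")

  # two strands at identical axial projection are ambiguous
  amb <- make_fibril(n_strands = 3L)
  amb$coords[amb$topology$chain_id == "B", 3, 1] <-
    amb$coords[amb$topology$chain_id == "A", 3, 1]
  expect_error(infer_fibril_topology(amb), "ambiguous")
})

test_that("noise-free stack hits the closed-form descriptor values", {
  fb <- make_fibril(n_strands = 10L, rise = 4.8)
  topo <- infer_fibril_topology(fb)
  fr <- get_frame(fb, 1)
  top <- fb$topology
  expect_equal(d_hc(fr, top, topo), 24.0, tolerance = 1e-6)
  expect_equal(d_he(fr, top, topo), 24.0, tolerance = 1e-6)
  is_ <- d_is(fr, top, topo)
  expect_equal(unname(is_$pairs), rep(4.8, 5), tolerance = 1e-6)
  expect_equal(is_$mean, 4.8, tolerance = 1e-6)

  # intra-strand means equal the template single-strand distances
  ca <- function(res) fr[top$chain_id == "A" & top$res_seq == res &
                           top$name == "CA", ]
  expect_equal(d_vc(fr, top, topo),
               sqrt(sum((ca(19) - ca(39))^2)), tolerance = 1e-9)
  expect_equal(d_ve(fr, top, topo),
               sqrt(sum((ca(11) - ca(39))^2)), tolerance = 1e-9)

  # all five invariant under global rigid motion
  set.seed(6)
  R <- random_rotation()
  moved <- sweep(fr %*% t(R), 2, c(11, -3, 40), `+`)
  mfb <- trajectory(top, moved)
  mtopo <- infer_fibril_topology(mfb)
  expect_equal(d_hc(moved, top, mtopo), 24.0, tolerance = 1e-9)
  expect_equal(d_ve(moved, top, mtopo), d_ve(fr, top, topo),
               tolerance = 1e-9)
  expect_equal(d_is(moved, top, mtopo)$mean, 4.8, tolerance = 1e-9)

  expect_error(d_hc(fr, top, infer_fibril_topology(make_fibril(n_strands = 6L))),
               "8 strands")
})

test_that("single-atom displacement shifts the core mean by delta/n", {
  fb <- make_fibril(n_strands = 10L)
  topo <- infer_fibril_topology(fb)
  top <- fb$topology
  fr <- get_frame(fb, 1)
  before <- d_vc(fr, top, topo)
  # displace Val39 CA of core strand 5 (chain E) radially
  i <- which(top$chain_id == "E" & top$res_seq == 39 & top$name == "CA")
  j <- which(top$chain_id == "E" & top$res_seq == 19 & top$name == "CA")
  dir_out <- (fr[i, ] - fr[j, ]) / sqrt(sum((fr[i, ] - fr[j, ])^2))
  fr2 <- fr
  fr2[i, ] <- fr2[i, ] + 2 * dir_out
  delta <- sqrt(sum((fr2[i, ] - fr2[j, ])^2)) -
    sqrt(sum((fr[i, ] - fr[j, ])^2))
  expect_equal(d_vc(fr2, top, topo), before + delta / 6, tolerance = 1e-9)
})

test_that("descriptor series follows programmed schedules", {
  fb <- make_fibril(n_strands = 10L, n_frames = 5L)
  topo <- infer_fibril_topology(fb)
  ds <- descriptor_series(fb, topo)
  expect_equal(nrow(ds$frames), 5L)
  expect_true(all(ds$summary$sd == 0))          # static trajectory

  targets <- seq(32, 25, length.out = 20)
  fan <- make_fibril(n_strands = 10L, n_frames = 20L, fan_targets = targets)
  dsf <- descriptor_series(fan, infer_fibril_topology(fan))
  expect_equal(dsf$frames$D_VE, targets, tolerance = 1e-6)
  expect_true(all(diff(dsf$frames$D_VE) < 0))   # monotone
  # D_HE stays at the pure stacking value: hinge moves all strands alike
  expect_equal(dsf$frames$D_HE, rep(24, 20), tolerance = 1e-6)
})

test_that("dissociation shows up as a single-pair interstrand excursion", {
  fb <- make_fibril(n_strands = 10L, n_frames = 2L,
                    dissociation = list(strand = 5, offset = 6,
                                        from_frame = 2))
  ds <- descriptor_series(fb, infer_fibril_topology(fb))
  expect_equal(unname(ds$is_pairs[1, ]), rep(4.8, 5), tolerance = 1e-9)
  expect_equal(unname(ds$is_pairs[2, "4-5"]), 10.8, tolerance = 1e-9)
  others <- ds$is_pairs[2, colnames(ds$is_pairs) != "4-5"]
  expect_equal(unname(others), rep(4.8, 4), tolerance = 1e-9)
})

test_that("fan amplitude and PCA collectivity capture the hinge motion", {
  static <- make_fibril(n_strands = 10L, n_frames = 10L)
  topo <- infer_fibril_topology(static)
  fa <- fan_amplitude(static, topo)
  expect_equal(fa$amplitude, 0, tolerance = 1e-9)

  base <- abconform:::.template_dve(abconform:::.s_template_ca(11L))
  targets <- base + 5 * sin(seq(0, 2 * pi, length.out = 30))
  fan <- make_fibril(n_strands = 10L, n_frames = 30L, fan_targets = targets,
                     sigma = 0.1, seed = 2)
  topo <- infer_fibril_topology(fan)
  fa <- fan_amplitude(fan, topo)
  expect_equal(fa$amplitude, 10, tolerance = 0.5)
  expect_gte(fa$mode1_variance_fraction, 0.8)

  expect_error(fan_amplitude(make_fibril(n_strands = 10L, n_frames = 3L),
                             topo),
               "10 frames")
})
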