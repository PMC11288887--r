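demo_scaffold <- function(n_repeats = 4) {
  build_repeat_backbone(do.call(repeat_spec, modifyList(
    demo_repeat_spec(), list(n_repeats = n_repeats))))
}

test_that("repeat propagation is exact to machine precision", {
  m <- demo_scaffold(4)
  Tin <- attr(m, "inter_transform")
  u1 <- ca_matrix(m, buttress:::unit_resnos(m, 1))
  for (k in 2:4) {
    uk <- ca_matrix(m, buttress:::unit_resnos(m, k))
    expect_lt(max(abs(rt_apply(rt_power(Tin, k - 1), u1) - uk)), 1e-9)
  }
  # identity inter-unit transform: all units superpose exactly on unit 1
  spec <- do.call(repeat_spec, modifyList(demo_repeat_spec(),
                                          list(inter_unit = six_dof())))
  mid <- build_repeat_backbone(spec)
  u1 <- ca_matrix(mid, buttress:::unit_resnos(mid, 1))
  for (k in 2:4) {
    expect_lt(superpose_kabsch(
      ca_matrix(mid, buttress:::unit_resnos(mid, k)), u1)$rmsd, 1e-9)
  }
  # pure z-translation: constant inter-unit CA offset
  spec <- do.call(repeat_spec, modifyList(
    demo_repeat_spec(), list(inter_unit = six_dof(tz = 12))))
  mz <- build_repeat_backbone(spec)
  d12 <- ca_matrix(mz, buttress:::unit_resnos(mz, 2)) -
    ca_matrix(mz, buttress:::unit_resnos(mz, 1))
  expect_lt(max(abs(sweep(d12, 2, c(0, 0, 12)))), 1e-9)
})

test_that("termini distance filter applies the 18 A rule to each gap", {
  m <- demo_scaffold(3)
  td <- termini_distance_filter(m)
  expect_equal(nrow(td), 2)
  # forced geometries right at the threshold
  spec <- do.call(repeat_spec, modifyList(
    demo_repeat_spec(),
    list(inter_unit = six_dof(ty = 30), n_repeats = 2)))
  far <- build_repeat_backbone(spec)
  d <- termini_distance_filter(far)$distance[1]
  expect_false(termini_distance_filter(far)$pass[1] && d > 18)
  # cutoff is configurable; exact threshold logic via the cutoff argument
  m2 <- demo_scaffold(2)
  d2 <- termini_distance_filter(m2)$distance[1]
  expect_true(termini_distance_filter(m2, cutoff = d2 + 0.1)$pass[1])
  expect_false(termini_distance_filter(m2, cutoff = d2 - 0.1)$pass[1])
})

test_that("layer assignment matches a brute-force cone-count oracle", {
  m <- demo_scaffold(4)
  lay <- assign_layers(m)
  mm <- add_cb(m)
  rs <- mm$residues$resno
  cosmax <- cos(100 * pi / 180)
  for (i in sample(rs, 20)) {
    ca <- atom_xyz(mm, i, "CA"); cb <- atom_xyz(mm, i, "CB")
    v <- (cb - ca) / vnorm(cb - ca)
    cnt <- 0
    for (j in rs) {
      if (j == i) next
      cbj <- atom_xyz(mm, j, "CB")
      if (vnorm(cbj - cb) > 10) next
      w <- cbj - ca
      if (sum(w * v) / vnorm(w) >= cosmax) cnt <- cnt + 1
    }
    expect_equal(lay$neighbors[match(i, lay$resno)], cnt)
  }
  # a single isolated helix has no buried core
  cf <- core_fraction_filter(make_ideal_helix(16))
  expect_equal(cf$fraction, 0)
  expect_false(cf$pass)
  # min_frac configurable
  frac <- core_fraction_filter(m)$fraction
  expect_true(core_fraction_filter(m, min_frac = frac - 0.01)$pass)
  expect_false(core_fraction_filter(m, min_frac = frac + 0.01)$pass)
})

test_that("scaffold filters are invariant under global rigid motion", {
  m <- demo_scaffold(3)
  tr <- dof_to_transform(six_dof(5, -9, 2, 25, -35, 130))
  mt <- rt_apply(tr, m)
  attr(mt, "inter_transform") <- NULL  # distances must not depend on it
  expect_equal(termini_distance_filter(m)$distance,
               termini_distance_filter(mt)$distance, tolerance = 1e-9)
  expect_equal(core_fraction_filter(m)$fraction,
               core_fraction_filter(mt)$fraction)
})

test_that("short loops reconnect excised loops and reject unbridgeable gaps", {
  set.seed(41)
  # excision/re-closure oracle: delete the loop of a helix-loop-helix
  # fixture and ask the closure engine to rebuild a 4-residue bridge
  tor <- random_loop_torsions(4)
  fx <- hlh_fixture(tor, h1 = 12, h2 = 12)
  sols <- close_loop(fx$model, fx$anchor_start, fx$anchor_end, tor,
                     n_restarts = 5)
  expect_gte(length(sols), 1)
  rmsds <- vapply(sols, function(s) {
    seg <- buttress:::loop_segment_model(fx$model, fx$anchor_start,
                                         s$torsions)
    rmsd_raw(ca_matrix(seg), ca_matrix(fx$model, fx$loop_resnos))
  }, numeric(1))
  expect_lt(min(rmsds), 1.0)
  # termini 30 A apart cannot be bridged by at most 6 residues
  spec <- do.call(repeat_spec, modifyList(
    demo_repeat_spec(), list(intra_unit = six_dof(tx = 30, rx = 180),
                             n_repeats = 2)))
  wide <- build_repeat_backbone(spec)
  gap <- vnorm(atom_xyz(wide, min(buttress:::unit_resnos(wide, 1, "helix2")),
                        "N") -
               atom_xyz(wide, max(buttress:::unit_resnos(wide, 1, "helix1")),
                        "C"))
  if (gap > 26) {
    res <- connect_short_loops(wide, n_attempts = 2)
    expect_false(res$ok)
  }
})
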